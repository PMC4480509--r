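#' Universally expressed genes
#'
#' Genes with at least one read in every sample of the matrix.
#'
#' @param x A [count_matrix()].
#' @return Character vector of gene ids.
#' @export
universal_genes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rownames(x$counts)[rowSums(x$counts >= 1) == ncol(x$counts)]
}

#' Commonly expressed genes within one cell type
#'
#' Excluding universally expressed genes, genes are ranked by descending
#' minimum raw count across the type's cells (a gene highly expressed in
#' its least-expressing cell is common to the type); the top `top_n` are
#' returned. Ties at the cut are broken by descending mean count, then
#' gene id.
#'
#' @param x A [count_matrix()].
#' @param cell_type Group label selecting the cells.
#' @param universal Gene ids to exclude (from [universal_genes()]).
#' @param top_n List length.
#' @return Character vector of gene ids, ranked.
#' @export
common_genes_by_type <- function(x, cell_type, universal, top_n = 400) {
  stopifnot(inherits(x, "count_matrix"))
  samples <- .group_samples(x, cell_type)
  if (length(samples) < 2) stop("cell type needs at least 2 cells")
  counts <- x$counts[, samples, drop = FALSE]
  counts <- counts[!rownames(counts) %in% universal, , drop = FALSE]
  mins <- apply(counts, 1, min)
  means <- rowMeans(counts)
  ord <- order(-mins, -means, rownames(counts))
  if (top_n > nrow(counts)) {
    warning(sprintf("only %d candidate genes available (top_n = %d)",
                    nrow(counts), top_n))
    top_n <- nrow(counts)
  }
  rownames(counts)[ord][seq_len(top_n)]
}

#' Jaccard overlap of two gene lists with a permutation test
#'
#' The Jaccard index of A and B (identifiers already mapped to a common
#' homologue namespace) is compared against `n_perm` random draws of
#' equally sized lists from the two universes. The p-value is the
#' fraction of permuted indices at least as large as the observed one;
#' zero exceedances are reported as `p < 1/n_perm` rather than 0.
#'
#' @param a,b Gene id vectors (subsets of their universes).
#' @param universe_a,universe_b Candidate pools to draw matched-size
#'   random lists from.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutation draws.
#' @return List with `jaccard`, `p_value` (numeric, `1/n_perm` when no
#'   exceedance), `p_is_upper_bound` flag, `n_exceed`, `n_perm`, `seed`.
#' @export
jaccard_overlap_test <- function(a, b, universe_a, universe_b,
                                 n_perm = 10000, seed = 1) {
  if (!all(a %in% universe_a) || !all(b %in% universe_b))
    stop("gene lists must be subsets of their universes")
  if (length(union(a, b)) == 0) stop("empty union: Jaccard undefined")
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  obs <- jac(a, b)
  n_exceed <- .with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pa <- sample(universe_a, length(a))
      pb <- sample(universe_b, length(b))
      jac(pa, pb) >= obs
    }, logical(1)))
  })
  list(jaccard = obs,
       p_value = max(n_exceed, 1) / n_perm,
       p_is_upper_bound = n_exceed == 0,
       n_exceed = n_exceed, n_perm = n_perm, seed = seed)
}

#' Enrichment of annotation terms in a gene set
#'
#' Per term, a 2x2 table of (in query set vs rest of background) by
#' (annotated vs not) is built; enrichment is the fraction of query genes
#' with the term relative to the same fraction among the remaining
#' background genes. The p-value is a hypergeometric upper tail or a
#' chi-square test, Bonferroni-corrected across the terms tested. Terms
#' with no annotated gene in the background are skipped.
#'
#' @param genes Query gene set (subset of `background`).
#' @param background Background gene universe.
#' @param annotations `data.frame` with `gene_id` and `term`.
#' @param method `"hypergeometric"` (upper tail) or `"chi_square"`.
#' @return `data.frame` per term: counts, `enrichment`, `p_value`,
#'   `p_bonferroni`.
#' @export
enrichment_test <- function(genes, background, annotations,
                            method = c("hypergeometric", "chi_square")) {
  method <- match.arg(method)
  if (!all(genes %in% background))
    stop("query genes must be a subset of the background")
  annotations <- annotations[annotations$gene_id %in% background, ,
                             drop = FALSE]
  terms <- unique(annotations$term)
  n_bg <- length(background)
  n_q <- length(genes)
  rows <- lapply(terms, function(tm) {
    ann <- unique(annotations$gene_id[annotations$term == tm])
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- sum(genes %in% ann)
    rest_ann <- K - k
    rest_n <- n_bg - n_q
    enr <- (k / n_q) / (rest_ann / rest_n)
    p <- if (method == "hypergeometric") {
      phyper(k - 1, K, n_bg - K, n_q, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, n_q - k, rest_ann, rest_n - rest_ann), nrow = 2)
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(term = tm, query_with_term = k, query_size = n_q,
               background_with_term = K, background_size = n_bg,
               enrichment = enr, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable terms")
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}
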