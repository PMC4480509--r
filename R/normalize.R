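#' Sample quality-control filter
#'
#' A sample is kept iff its total unique exonic reads exceed
#' `min_exonic_reads` AND it satisfies at least `traits_required` of the
#' three library-quality traits: (1) percent uniquely mapping reads of at
#' least 50, (2) at least 1500 genes covered at depth greater than ten
#' reads, (3) less than 80 percent short fragments. Trait values missing
#' from the metadata are treated as unavailable and the requirement
#' shrinks accordingly (e.g. samples lacking the short-fragment statistic
#' need only one of the two remaining traits when `traits_required = 2`).
#'
#' Total exonic reads come from the `total_reads` metadata column when
#' present, otherwise from the sample's column sum. The genes-at-depth
#' trait is always computed from the matrix.
#'
#' @param x A [count_matrix()].
#' @param min_exonic_reads Mandatory depth gate (reads).
#' @param traits_required Number of traits required out of those
#'   available.
#' @param min_unique_pct,min_genes_covered,genes_depth,max_short_pct
#'   Trait cutoffs.
#'
#' @return List with `kept` (character vector of retained sample ids) and
#'   `report` (per-sample trait pass/fail table).
#' @export
qc_filter_samples <- function(x, min_exonic_reads = 5e6, traits_required = 2,
                              min_unique_pct = 50, min_genes_covered = 1500,
                              genes_depth = 10, max_short_pct = 80) {
  stopifnot(inherits(x, "count_matrix"))
  meta <- x$sample_meta
  totals <- if (!is.null(meta$total_reads) && !all(is.na(meta$total_reads)))
    meta$total_reads else colSums(x$counts)
  genes_cov <- colSums(x$counts > genes_depth)

  trait_unique <- if (!is.null(meta$percent_unique))
    ifelse(is.na(meta$percent_unique), NA, meta$percent_unique >= min_unique_pct)
  else rep(NA, ncol(x$counts))
  trait_genes <- genes_cov >= min_genes_covered
  trait_short <- if (!is.null(meta$percent_short_fragments))
    ifelse(is.na(meta$percent_short_fragments), NA,
           meta$percent_short_fragments < max_short_pct)
  else rep(NA, ncol(x$counts))

  traits <- cbind(unique_pct = trait_unique, genes_covered = trait_genes,
                  short_fragments = trait_short)
  n_available <- rowSums(!is.na(traits))
  n_pass <- rowSums(traits, na.rm = TRUE)
  required <- pmax(0L, traits_required - (ncol(traits) - n_available))
  depth_ok <- totals > min_exonic_reads
  kept <- depth_ok & n_pass >= required

  report <- data.frame(sample_id = colnames(x$counts),
                       exonic_reads = as.numeric(totals),
                       depth_pass = depth_ok,
                       traits,
                       traits_available = n_available,
                       traits_passed = n_pass,
                       traits_required = required,
                       kept = kept)
  rownames(report) <- NULL
  if (!any(kept)) warning("no samples pass quality control")
  list(kept = colnames(x$counts)[kept], report = report)
}

#' Median-of-ratios size factors and normalized matrices
#'
#' A pseudo-reference sample is built as the per-gene geometric mean
#' across samples of the ubiquitously expressed genes (non-zero in every
#' sample, computed in log space). Each sample's size factor is the
#' median over those genes of the ratio of its count to the
#' pseudo-reference; counts divided by the factor give normalized counts.
#' Relative frequencies (count over sample total) are carried alongside
#' since several downstream statistics are defined on that scale.
#'
#' @param x A [count_matrix()].
#' @return An object of class `normalized_matrix`: list with `counts`,
#'   `size_factors`, `normalized`, `relfreq`, `sample_meta`.
#' @export
compute_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  ubiq <- rowSums(counts == 0) == 0
  if (!any(ubiq))
    stop("no ubiquitously expressed gene: every gene has a zero in some ",
         "sample, so the median-of-ratios pseudo-reference is undefined; ",
         "filter samples or pool genes before normalizing")
  lg <- log(counts[ubiq, , drop = FALSE])
  ref <- exp(rowMeans(lg))
  sf <- apply(counts[ubiq, , drop = FALSE], 2, function(col)
    median(col / ref))
  if (any(sf <= 0)) stop("non-positive size factor")
  totals <- colSums(counts)
  structure(list(counts = counts,
                 size_factors = sf,
                 normalized = sweep(counts, 2, sf, "/"),
                 relfreq = sweep(counts, 2, totals, "/"),
                 sample_meta = x$sample_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples; size factors %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(signif(range(x$size_factors), 3), collapse = " - ")))
  invisible(x)
}

#' Subset a normalized matrix to a set of samples
#'
#' Size factors are kept as computed on the full sample set (relative
#' frequencies are per sample and unaffected). Useful for carving one
#' cell type's columns out of a jointly normalized dataset.
#'
#' @param nm A `normalized_matrix`.
#' @param samples Sample ids to keep.
#' @return A `normalized_matrix` restricted to `samples`.
#' @export
subset_samples <- function(nm, samples) {
  stopifnot(inherits(nm, "normalized_matrix"))
  keep <- colnames(nm$counts) %in% samples
  structure(list(counts = nm$counts[, keep, drop = FALSE],
                 size_factors = nm$size_factors[keep],
                 normalized = nm$normalized[, keep, drop = FALSE],
                 relfreq = nm$relfreq[, keep, drop = FALSE],
                 sample_meta = nm$sample_meta[keep, , drop = FALSE]),
            class = "normalized_matrix")
}

#' PCA projection of arcsine-transformed relative frequencies
#'
#' Relative frequencies are variance stabilized as
#' `asin(sqrt(relative frequency))` per gene and sample; genes with zero
#' counts in all samples are dropped; samples are then projected onto the
#' leading principal components (genes centred, not scaled). Axis labels
#' carry the percentage of total standard deviation explained.
#'
#' @param nm A `normalized_matrix`.
#' @param n_components Number of components to return.
#' @return List with `coordinates` (samples x components) and
#'   `percent_sd` (percentage standard deviation per axis).
#' @export
pca_projection <- function(nm, n_components = 3) {
  stopifnot(inherits(nm, "normalized_matrix"))
  keep <- rowSums(nm$counts) > 0
  y <- t(asin(sqrt(nm$relfreq[keep, , drop = FALSE])))
  max_rank <- min(nrow(y) - 1, ncol(y))
  if (n_components > max_rank) {
    warning(sprintf("n_components reduced from %d to the rank bound %d",
                    n_components, max_rank))
    n_components <- max_rank
  }
  p <- prcomp(y, center = TRUE, scale. = FALSE)
  pct <- 100 * p$sdev / sum(p$sdev)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       percent_sd = pct[seq_len(n_components)])
}

#' Saturation curve by read subsampling
#'
#' For each requested depth, reads of one sample are subsampled without
#' replacement (a multivariate hypergeometric draw over genes) `n_draws`
#' times; a gene counts as detected when at least one read survives.
#'
#' @param x A [count_matrix()].
#' @param sample Sample id.
#' @param depths Integer vector of subsampling depths; each must not
#'   exceed the sample total.
#' @param n_draws Draws per depth.
#' @param seed Seed for the subsampling RNG.
#' @return `data.frame` with `depth`, `mean_detected`, `sd_detected`.
#' @export
saturation_curve <- function(x, sample, depths, n_draws = 20, seed = 1) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts[, sample]
  total <- sum(counts)
  bad <- depths > total
  if (any(bad))
    stop(sprintf("depth %g exceeds the sample total of %g",
                 min(depths[bad]), total))
  .with_seed(seed, {
    res <- lapply(depths, function(d) {
      if (d == 0) return(c(mean = 0, sd = 0))
      detected <- .mvhyper_detected(counts, d, n_draws)
      c(mean = mean(detected), sd = sd(detected))
    })
    data.frame(depth = depths,
               mean_detected = vapply(res, `[[`, numeric(1), "mean"),
               sd_detected = vapply(res, `[[`, numeric(1), "sd"))
  })
}

## Multivariate hypergeometric draws via sequential univariate
## hypergeometrics, vectorized across draws; returns detected-gene counts.
.mvhyper_detected <- function(counts, depth, n_draws) {
  nz <- which(counts > 0)
  k_left <- rep(as.numeric(depth), n_draws)
  tot_rest <- sum(counts)
  detected <- integer(n_draws)
  for (g in nz) {
    cg <- counts[g]
    tot_rest <- tot_rest - cg
    xg <- rhyper(n_draws, m = cg, n = tot_rest, k = k_left)
    k_left <- k_left - xg
    detected <- detected + (xg > 0)
  }
  detected
}
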