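#' Outlier-sum statistic for one gene
#'
#' Values are median-centred and scaled by the median absolute deviation
#' from the median (unscaled, no consistency factor). When the MAD is
#' zero — common for genes expressed in a small subset of cells — the
#' scale falls back to the smallest non-zero value observed across the
#' transcriptome so that such genes are not filtered out. Standardized
#' values exceeding the upper Tukey fence (the 75th percentile of the
#' standardized values plus their interquartile range) are outliers; the
#' statistic is the sum of the outlying standardized values, 0 when
#' there is none. The fence is one-sided (upper) because the statistic
#' targets high expression in a subset of samples; set
#' `two_sided = TRUE` to also sum the magnitudes below the lower fence.
#'
#' @param values Per-cell expression of one gene (at least 4 values).
#' @param transcriptome_min Smallest non-zero value observed across the
#'   transcriptome (fallback scale; must be positive).
#' @param two_sided Use both fences.
#' @param mad_constant Multiplier of the median absolute deviation
#'   (1 = unscaled; 1.4826 gives the normal-consistent estimate).
#' @return The outlier-sum statistic (non-negative).
#' @export
outlier_sum <- function(values, transcriptome_min, two_sided = FALSE,
                        mad_constant = 1) {
  if (length(values) < 4) stop("need at least 4 values")
  if (transcriptome_min <= 0) stop("transcriptome_min must be positive")
  med <- median(values)
  scale <- mad_constant * median(abs(values - med))
  if (scale == 0) scale <- transcriptome_min
  z <- (values - med) / scale
  q <- quantile(z, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  os <- sum(z[z > q[2] + iqr])
  if (two_sided) os <- os + sum(-z[z < q[1] - iqr])
  os
}

#' Classify extreme-variability and consistency patterns per cell type
#'
#' For each cell type (on normalized read counts of genes above the
#' reliability threshold): the outlier-sum statistic flags a gene
#' `variable` when it ranks in the top `top_n` by the statistic and the
#' statistic reaches `os_min`; the Shapiro-Wilk statistic flags a gene
#' `consistent` when it ranks in the top `top_n` by W and the normality
#' p-value exceeds `sw_p_min`. A gene flagged variable in a type is never
#' simultaneously consistent in that type. A gene is `divergent` when it
#' is variable in at least one cell type and consistent in at least one
#' other. Running the same call on the pooled cells (positive control)
#' or the dilution replicates (negative control) gives the control sets.
#'
#' @param cells_by_type Named list (cell type -> `normalized_matrix`),
#'   each with at least 4 cells.
#' @param threshold A `reliability_threshold` or a relative frequency.
#' @param top_n Rank cut for both statistics.
#' @param os_min Minimum outlier-sum for the variable flag.
#' @param sw_p_min Minimum Shapiro-Wilk p for the consistent flag.
#'
#' @return List with `flags` (`data.frame`: gene, cell type, `os`,
#'   `sw_w`, `sw_p`, `variable`, `consistent`) and `divergent`
#'   (character vector of divergent gene ids).
#' @export
classify_patterns <- function(cells_by_type, threshold, top_n = 400,
                              os_min = 100, sw_p_min = 0.005) {
  stopifnot(is.list(cells_by_type), length(cells_by_type) >= 1)
  thr <- if (inherits(threshold, "reliability_threshold"))
    threshold$selected else as.numeric(threshold)
  rows <- list()
  for (ct in names(cells_by_type)) {
    nm <- cells_by_type[[ct]]
    if (ncol(nm$normalized) < 4)
      stop(sprintf("cell type %s has fewer than 4 cells", ct))
    keep <- rowMeans(nm$relfreq) >= thr
    y <- nm$normalized[keep, , drop = FALSE]
    if (nrow(y) == 0) next
    tn <- top_n
    if (tn > nrow(y)) {
      warning(sprintf("top_n exceeds gene count in %s; using all %d genes",
                      ct, nrow(y)))
      tn <- nrow(y)
    }
    tmin <- min(nm$normalized[nm$normalized > 0])
    os <- apply(y, 1, outlier_sum, transcriptome_min = tmin)
    sw <- apply(y, 1, function(v) {
      if (length(unique(v)) < 3) return(c(w = 0, p = 0))
      r <- tryCatch(shapiro.test(v), error = function(e) NULL)
      if (is.null(r)) c(w = 0, p = 0) else c(w = unname(r$statistic),
                                             p = r$p.value)
    })
    os_rank <- rank(-os, ties.method = "first")
    sw_rank <- rank(-sw["w", ], ties.method = "first")
    variable <- os_rank <= tn & os >= os_min
    consistent <- sw_rank <= tn & sw["p", ] > sw_p_min & !variable
    rows[[ct]] <- data.frame(gene_id = rownames(y), cell_type = ct,
                             os = os, sw_w = sw["w", ], sw_p = sw["p", ],
                             variable = variable, consistent = consistent,
                             row.names = NULL)
  }
  flags <- do.call(rbind, rows)
  rownames(flags) <- NULL
  # variable and consistent are mutually exclusive within a type, so any
  # gene carrying both flags carries them in different cell types
  divergent <- sort(intersect(unique(flags$gene_id[flags$variable]),
                              unique(flags$gene_id[flags$consistent])))
  list(flags = flags, divergent = divergent)
}

#' Association of expression-pattern class with RNA half-life
#'
#' Genes are ranked by half-life (ties broken by gene id); the upper
#' third is slow decaying, the lower third fast decaying, the middle
#' third dropped. Gene-level pattern labels come from the flags: variable
#' in at least one cell type vs consistent in at least one cell type
#' (genes qualifying for both, or neither, are excluded). The 2x2 table
#' of pattern by decay class is tested with a chi-square test (no
#' continuity correction).
#'
#' @param flags Flag table from [classify_patterns()] (`$flags`).
#' @param half_lives `data.frame` with `gene_id`, `half_life_hours`.
#' @param min_covered Minimum flagged genes with half-life data.
#' @return List with `table` (2x2 contingency), `statistic`, `p_value`.
#' @export
half_life_association <- function(flags, half_lives, min_covered = 100) {
  var_genes <- unique(flags$gene_id[flags$variable])
  con_genes <- unique(flags$gene_id[flags$consistent])
  both <- intersect(var_genes, con_genes)
  var_only <- setdiff(var_genes, both)
  con_only <- setdiff(con_genes, both)
  lab <- data.frame(gene_id = c(var_only, con_only),
                    pattern = rep(c("variable", "consistent"),
                                  c(length(var_only), length(con_only))))
  lab <- merge(lab, half_lives, by = "gene_id")
  if (nrow(lab) < min_covered)
    stop(sprintf("half-life table covers only %d flagged genes (< %d)",
                 nrow(lab), min_covered))
  ord <- order(lab$half_life_hours, lab$gene_id)
  n <- nrow(lab)
  third <- floor(n / 3)
  decay <- rep(NA_character_, n)
  decay[ord[seq_len(third)]] <- "fast"
  decay[ord[seq.int(n - third + 1, n)]] <- "slow"
  lab$decay <- decay
  lab <- lab[!is.na(lab$decay), , drop = FALSE]
  tab <- table(pattern = factor(lab$pattern,
                                levels = c("variable", "consistent")),
               decay = factor(lab$decay, levels = c("fast", "slow")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty contingency row/column; association test skipped")
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value)
}
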