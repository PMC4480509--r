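#' Expression-level-matched F-statistic of single-cell variability
#'
#' For each gene above the reliability threshold, the F-statistic is the
#' unbiased sample variance of relative frequencies across the cell
#' type's cells divided by the control-curve technical variance at the
#' gene's mean relative frequency. Values near 1 indicate purely
#' technical variation; values far above 1 indicate biological
#' variability. Applying the same operation to the dilution replicates
#' themselves provides the negative control.
#'
#' @param cells A `normalized_matrix` (one cell type, at least 3 cells).
#' @param curve Control curve from [build_control_curve()].
#' @param threshold A `reliability_threshold`, or a single relative
#'   frequency.
#'
#' @return A `data.frame` (the variability table) with per-gene `x`
#'   (mean relative frequency), `mean_norm` (mean normalized depth),
#'   `v_total`, `v_exp`, `f_stat`, `rank` (1 = most variable) and `top5`
#'   flag.
#' @export
f_statistic <- function(cells, curve, threshold) {
  stopifnot(inherits(cells, "normalized_matrix"),
            inherits(curve, "control_curve"))
  if (ncol(cells$relfreq) < 3) stop("need at least 3 cells")
  thr <- if (inherits(threshold, "reliability_threshold"))
    threshold$selected else as.numeric(threshold)
  x <- rowMeans(cells$relfreq)
  keep <- x >= thr
  if (!any(keep)) stop("no genes pass the reliability threshold")
  x <- x[keep]
  v_total <- apply(cells$relfreq[keep, , drop = FALSE], 1, var)
  v_exp <- lookup_control_curve(curve, x)
  f <- v_total / v_exp
  out <- data.frame(gene_id = rownames(cells$relfreq)[keep],
                    x = x,
                    mean_norm = rowMeans(cells$normalized[keep, , drop = FALSE]),
                    v_total = v_total, v_exp = v_exp, f_stat = f)
  out$rank <- rank(-out$f_stat, ties.method = "first")
  out$top5 <- out$gene_id %in% top_variable_genes(out, 0.05)
  rownames(out) <- NULL
  out
}

#' Most variable genes by F-statistic
#'
#' Selects `ceiling(fraction * n)` genes with the largest F-statistic.
#' Ties at the cut are broken by larger mean expression, then gene id.
#'
#' @param table A variability table from [f_statistic()].
#' @param fraction Fraction of genes to take, in (0, 1].
#' @return Character vector of gene ids.
#' @export
top_variable_genes <- function(table, fraction = 0.05) {
  if (nrow(table) == 0) stop("empty variability table")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(table))
  ord <- order(-table$f_stat, -table$x, table$gene_id)
  table$gene_id[ord][seq_len(k)]
}

#' Functional-category ANCOVA of log10 F-statistics
#'
#' Fits a linear model of log10 F on functional category and cell type
#' (factors) conditioning on log10 mean normalized read depth (the
#' covariate), then reports category adjusted means at the average
#' covariate value and all pairwise category contrasts with simultaneous
#' confidence intervals and family-wise error control from the joint
#' multivariate-t distribution (Tukey contrasts). Genes annotated to more
#' than one category are excluded as ambiguous factor levels; categories
#' with fewer than `min_genes` thresholded genes are dropped with a
#' warning.
#'
#' @param tables Named list (cell type -> variability table from
#'   [f_statistic()]).
#' @param categories `data.frame` with `gene_id` and `category`.
#' @param min_genes Minimum genes per retained category.
#' @param conf_level Confidence level of the simultaneous intervals.
#'
#' @return List with `adjusted_means` (per category), `contrasts`
#'   (pairwise differences with CI and adjusted p), `model` (the lm fit)
#'   and `n_excluded_ambiguous`.
#' @export
category_ancova <- function(tables, categories, min_genes = 10,
                            conf_level = 0.95) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ambiguous <- unique(categories$gene_id[duplicated(categories$gene_id)])
  categories <- categories[!categories$gene_id %in% ambiguous, , drop = FALSE]

  dat <- do.call(rbind, lapply(names(tables), function(ct) {
    t <- tables[[ct]]
    t$cell_type <- ct
    t
  }))
  dat <- merge(dat, categories, by = "gene_id")
  dat <- dat[dat$f_stat > 0 & dat$mean_norm > 0, , drop = FALSE]
  dat$log_f <- log10(dat$f_stat)
  dat$log_depth <- log10(dat$mean_norm)

  sizes <- table(dat$category)
  small <- names(sizes)[sizes < min_genes]
  if (length(small)) {
    warning("dropping categories with too few genes: ",
            paste(small, collapse = ", "))
    dat <- dat[!dat$category %in% small, , drop = FALSE]
  }
  if (length(unique(dat$category)) < 2)
    stop("need at least 2 categories with enough genes")
  dat$category <- factor(dat$category)
  dat$cell_type <- factor(dat$cell_type)

  fit <- if (nlevels(dat$cell_type) > 1)
    lm(log_f ~ category + cell_type + log_depth, data = dat)
  else
    lm(log_f ~ category + log_depth, data = dat)

  emm <- emmeans::emmeans(fit, "category")
  adj <- as.data.frame(emm)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(category = "Tukey"))
  ci <- confint(glht_fit, level = conf_level)$confint
  pv <- summary(glht_fit)$test$pvalues
  contrasts <- data.frame(comparison = rownames(ci),
                          estimate = ci[, "Estimate"],
                          lower = ci[, "lwr"], upper = ci[, "upr"],
                          p_adjusted = as.numeric(pv))
  rownames(contrasts) <- NULL
  list(adjusted_means = adj, contrasts = contrasts, model = fit,
       n_excluded_ambiguous = length(ambiguous))
}

#' Cross-species partial correlation of expression variability
#'
#' Restricts to one-to-one homologues present (and thresholded) in both
#' species' variability tables, regresses each species' log10 F on the
#' log10 mean expression of BOTH species, and correlates the residual
#' vectors. Conditioning on both expression levels removes similarity
#' that is due only to conserved expression level. Significance is a
#' two-sided t-test with n - 4 degrees of freedom (two covariates fitted
#' on each side).
#'
#' @param table_a,table_b Variability tables from [f_statistic()].
#' @param homologues Two-column one-to-one map; column 1 ids match
#'   `table_a`, column 2 `table_b`.
#'
#' @return List with `rho`, `p_value`, `n`, `coefficients` (per-species
#'   fits) and `residuals`.
#' @export
cross_species_partial_correlation <- function(table_a, table_b, homologues) {
  if (anyDuplicated(homologues[[1]]) || anyDuplicated(homologues[[2]]))
    stop("homologue map is ambiguous; filter to one-to-one pairs first")
  m <- data.frame(a = homologues[[1]], b = homologues[[2]])
  m <- merge(m, table_a[, c("gene_id", "x", "f_stat")],
             by.x = "a", by.y = "gene_id")
  names(m)[names(m) %in% c("x", "f_stat")] <- c("x_a", "f_a")
  m <- merge(m, table_b[, c("gene_id", "x", "f_stat")],
             by.x = "b", by.y = "gene_id")
  names(m)[names(m) %in% c("x", "f_stat")] <- c("x_b", "f_b")
  m <- m[m$f_a > 0 & m$f_b > 0, , drop = FALSE]
  n <- nrow(m)
  if (n < 30) stop("fewer than 30 shared homologue genes above threshold")

  X <- cbind(1, log10(m$x_a), log10(m$x_b))
  fit_a <- lm.fit(X, log10(m$f_a))
  fit_b <- lm.fit(X, log10(m$f_b))
  r_a <- fit_a$residuals
  r_b <- fit_b$residuals
  rho <- cor(r_a, r_b)
  df <- n - 2 - 2
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), df)
  list(rho = rho, p_value = p, n = n,
       coefficients = list(
         species_a = setNames(fit_a$coefficients, c("b0", "b1", "b2")),
         species_b = setNames(fit_b$coefficients, c("b0", "b1", "b2"))),
       residuals = data.frame(gene_a = m$a, gene_b = m$b,
                              resid_a = r_a, resid_b = r_b))
}

#' Within- and between-cell-type variance of expression
#'
#' On arcsine-transformed relative frequencies, the within-type variance
#' is the mean over genes of the per-gene variance across that type's
#' cells; the between-pair variance for two types is the mean over genes
#' of the per-gene variance across all cells of both types pooled.
#'
#' @param cell_matrices Named list (cell type -> `normalized_matrix`).
#' @return List with `within` (per type; `NA` for single-cell types) and
#'   `between` (per unordered pair).
#' @export
within_between_variance <- function(cell_matrices) {
  stopifnot(length(cell_matrices) >= 2)
  trans <- lapply(cell_matrices, function(nm) asin(sqrt(nm$relfreq)))
  within <- vapply(trans, function(y) {
    if (ncol(y) < 2) return(NA_real_)
    mean(apply(y, 1, var))
  }, numeric(1))
  types <- names(cell_matrices)
  pairs <- utils::combn(types, 2)
  between <- apply(pairs, 2, function(p) {
    y <- cbind(trans[[p[1]]], trans[[p[2]]])
    mean(apply(y, 1, var))
  })
  data_between <- data.frame(type_1 = pairs[1, ], type_2 = pairs[2, ],
                             between_variance = between)
  list(within = data.frame(cell_type = types, within_variance = within,
                           row.names = NULL),
       between = data_between)
}
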