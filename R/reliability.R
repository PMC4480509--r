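#' Technical-variance control curve from dilution replicates
#'
#' Per-gene sample variance of relative frequencies across the dilution
#' replicates, summarized at each expression level as the median over a
#' sliding window of `window_genes` neighbouring genes (genes ordered by
#' mean relative frequency). The curve acts as the expression-matched
#' technical-variance baseline V_exp(x): looking up an arbitrary level x
#' returns the windowed median at the gene with the nearest mean
#' expression (a kernel median, not a parametric fit, so no
#' interpolation).
#'
#' @param dilution A `normalized_matrix` of dilution replicates (at least
#'   two samples).
#' @param window_genes Sliding-window width in genes.
#' @return An object of class `control_curve`: `data.frame`-backed list
#'   with per-gene `x` (mean relative frequency), `variance` and `v_exp`
#'   (windowed median), sorted by `x`.
#' @export
build_control_curve <- function(dilution, window_genes = 500) {
  stopifnot(inherits(dilution, "normalized_matrix"))
  if (ncol(dilution$relfreq) < 2) stop("need at least 2 dilution replicates")
  if (window_genes < 3) stop("window_genes must be at least 3")
  if (window_genes > nrow(dilution$relfreq))
    stop("window_genes exceeds the number of genes")
  rf <- dilution$relfreq
  x <- rowMeans(rf)
  v <- apply(rf, 1, var)
  ord <- order(x, rownames(rf))
  x <- x[ord]; v <- v[ord]
  v_exp <- .sliding_stat(v, window_genes, median)
  structure(list(table = data.frame(gene_id = rownames(rf)[ord], x = x,
                                    variance = v, v_exp = v_exp),
                 window_genes = window_genes),
            class = "control_curve")
}

#' @export
print.control_curve <- function(x, ...) {
  cat(sprintf("control_curve: %d genes, window %d; V_exp range %s\n",
              nrow(x$table), x$window_genes,
              paste(signif(range(x$table$v_exp), 3), collapse = " - ")))
  invisible(x)
}

#' Look up the technical-variance baseline at given expression levels
#'
#' @param curve A [build_control_curve()] result.
#' @param x Relative-frequency levels.
#' @return V_exp at the nearest-expression gene for each element of `x`.
#' @export
lookup_control_curve <- function(curve, x) {
  stopifnot(inherits(curve, "control_curve"))
  # collapse ties so lookup positions are strictly increasing
  ux <- curve$table$x
  dup <- duplicated(ux)
  xs <- ux[!dup]
  vs <- curve$table$v_exp[!dup]
  i <- findInterval(x, xs, all.inside = TRUE)
  use_right <- (x - xs[i]) > (xs[pmin(i + 1, length(xs))] - x)
  vs[ifelse(use_right, pmin(i + 1, length(xs)), i)]
}

## Smallest expression level such that `ok` holds at that level and every
## higher one; genes assumed sorted by x. Returns +Inf when never.
.threshold_above_which <- function(x_sorted, ok) {
  bad <- which(!ok)
  if (length(bad) == 0) return(unname(x_sorted[1]))
  idx <- max(bad) + 1L
  if (idx > length(x_sorted)) return(Inf)
  unname(x_sorted[idx])
}

#' Reliable-quantification expression threshold from four criteria
#'
#' Evaluates, on genes ordered by mean dilution relative frequency, the
#' four reliability criteria: (1) at least half the genes in the window
#' have no zero (missing) count in any dilution replicate; (2) windowed
#' median variance across single cells exceeds twice the control
#' variance at matched expression; (3) windowed median Shapiro-Wilk
#' p-value of the dilution relative frequencies exceeds `sw_alpha`; and
#' (4), reported as a diagnostic only, the breakpoint of a two-segment
#' least-squares fit of log mean read depth against log expression rank.
#' Each criterion's threshold is the smallest expression level above
#' which the criterion holds at every higher level (enforced literally).
#' The selected threshold is the most stringent (maximum) of criteria
#' 1-3; the breakpoint criterion is excluded because no operational
#' decision rule accompanies "consistent functional relationship".
#'
#' @param dilution A `normalized_matrix` of dilution replicates.
#' @param cells A `normalized_matrix` of single cells.
#' @param curve Control curve built from the same dilution set.
#' @param window_genes Window for the criterion medians (reuses the
#'   curve's window by default).
#' @param complete_frac Required windowed fraction of fully observed
#'   genes (criterion 1).
#' @param var_ratio Required single-cell to control variance ratio
#'   (criterion 2).
#' @param sw_alpha Normality p-value floor (criterion 3).
#' @param molecules_per_cell,library_size Conversion assumptions for the
#'   reported molecule / read-depth equivalents of the selected
#'   threshold (reads omitted when `library_size` is `NULL`).
#' @param on_unattainable What to do when some criterion is never
#'   satisfied (its threshold is `Inf`): `"error"` (default) aborts
#'   because the selected threshold is undefined; `"na"` reports
#'   `selected = NA` and leaves the per-criterion thresholds for the
#'   caller.
#'
#' @return An object of class `reliability_threshold`: list with
#'   `criteria` (named thresholds, `Inf` when unattainable), `selected`,
#'   and `breakpoint` (criterion 4 diagnostic).
#' @export
evaluate_reliability_criteria <- function(dilution, cells, curve,
                                          window_genes = curve$window_genes,
                                          complete_frac = 0.5,
                                          var_ratio = 2,
                                          sw_alpha = 0.01,
                                          molecules_per_cell = 150000,
                                          library_size = NULL,
                                          on_unattainable = c("error", "na")) {
  on_unattainable <- match.arg(on_unattainable)
  stopifnot(inherits(dilution, "normalized_matrix"),
            inherits(cells, "normalized_matrix"),
            inherits(curve, "control_curve"))
  rf_d <- dilution$relfreq
  x_d <- rowMeans(rf_d)
  ord_d <- order(x_d, rownames(rf_d))
  xs <- x_d[ord_d]

  # At the top edge the centred window necessarily shrinks, down to a
  # single gene, so one high-expression variance realization could veto a
  # criterion; edge positions therefore inherit the verdict of the last
  # full-width window.
  h <- (as.integer(window_genes) - 1L) %/% 2L
  mask_top <- function(ok) {
    n <- length(ok)
    if (n > h + 1L) ok[(n - h + 1L):n] <- ok[n - h]
    ok
  }

  # criterion 1: windowed fraction of genes with no zero across replicates
  complete <- rowSums(dilution$counts == 0) == 0
  frac <- .sliding_stat(as.numeric(complete[ord_d]), window_genes, mean)
  t1 <- .threshold_above_which(xs, mask_top(frac >= complete_frac))

  # criterion 2: windowed median single-cell variance > ratio x V_exp
  rf_c <- cells$relfreq
  shared <- intersect(rownames(rf_c), rownames(rf_d))
  x_c <- rowMeans(rf_c[shared, , drop = FALSE])
  v_c <- apply(rf_c[shared, , drop = FALSE], 1, var)
  ord_c <- order(x_c, shared)
  med_vc <- .sliding_stat(v_c[ord_c], window_genes, median)
  t2 <- .threshold_above_which(
    x_c[ord_c],
    mask_top(med_vc > var_ratio * lookup_control_curve(curve, x_c[ord_c])))

  # criterion 3: windowed median Shapiro-Wilk p on dilution frequencies
  sw_p <- apply(rf_d, 1, function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: clearly non-normal
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  })
  med_p <- .sliding_stat(sw_p[ord_d], window_genes, median)
  t3 <- .threshold_above_which(xs, mask_top(med_p > sw_alpha))

  # criterion 4 (diagnostic): two-segment fit of log depth vs log rank
  depth <- sort(rowMeans(dilution$normalized), decreasing = TRUE)
  depth <- depth[depth > 0]
  bp <- .two_segment_breakpoint(log10(seq_along(depth)), log10(depth))
  bp_x <- sort(xs, decreasing = TRUE)[min(bp, length(xs))]

  crit <- c(complete = t1, variance_ratio = t2, normality = t3)
  if (any(!is.finite(crit)))
    warning("criterion unattainable: ",
            paste(names(crit)[!is.finite(crit)], collapse = ", "))
  selected <- max(crit)
  if (!is.finite(selected)) {
    if (on_unattainable == "error")
      stop("no finite selected threshold: at least one criterion is never met")
    selected <- NA_real_
  }
  structure(list(criteria = crit, selected = selected,
                 breakpoint = c(rank = bp, x = bp_x),
                 equivalent_molecules = if (is.finite(selected))
                   threshold_to_molecules(selected, molecules_per_cell)$value
                 else NA_real_,
                 equivalent_reads = if (is.finite(selected) &&
                                          !is.null(library_size))
                   threshold_to_reads(selected, library_size)$value
                 else NA_real_,
                 window_genes = window_genes),
            class = "reliability_threshold")
}

#' @export
print.reliability_threshold <- function(x, ...) {
  cat("reliability_threshold (relative frequency):\n")
  for (nm in names(x$criteria))
    cat(sprintf("  %-15s %.3g\n", nm, x$criteria[[nm]]))
  cat(sprintf("  selected        %.3g\n", x$selected))
  if (is.finite(x$equivalent_molecules))
    cat(sprintf("  ~ %.3g input molecules\n", x$equivalent_molecules))
  invisible(x)
}

## Exhaustive two-segment least squares: scan all interior breakpoints,
## fit a line on each side, return the split minimizing total RSS.
.two_segment_breakpoint <- function(x, y) {
  n <- length(x)
  if (n < 6) return(NA_integer_)
  rss_line <- function(ix) {
    f <- lm.fit(cbind(1, x[ix]), y[ix])
    sum(f$residuals^2)
  }
  cand <- 3:(n - 3)
  rss <- vapply(cand, function(b) rss_line(1:b) + rss_line((b + 1):n),
                numeric(1))
  cand[which.min(rss)]
}

#' Convert a relative-frequency threshold to molecules or reads
#'
#' Multiplies the threshold by an assumed molecules-per-cell total, or by
#' a library size, returning the raw product and its nearest-integer
#' report.
#'
#' @param threshold Relative-frequency threshold (non-negative).
#' @param molecules_per_cell Assumed total mRNA molecules in a cell.
#' @return List with `value` and `rounded`.
#' @export
threshold_to_molecules <- function(threshold, molecules_per_cell = 150000) {
  stopifnot(threshold >= 0, molecules_per_cell > 0)
  v <- threshold * molecules_per_cell
  list(value = v, rounded = round(v))
}

#' @param library_size Reads in the library the threshold is expressed
#'   against.
#' @rdname threshold_to_molecules
#' @export
threshold_to_reads <- function(threshold, library_size) {
  stopifnot(threshold >= 0, library_size > 0)
  v <- threshold * library_size
  list(value = v, rounded = round(v))
}
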