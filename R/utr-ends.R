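#' Smoothed antisense-sense differential of read starts
#'
#' Computes, for one gene in one cell, a moving average of sense and
#' antisense read-start multiplicity over windows of `window` bases moved
#' by `step` bases across the analysis region (annotated 3' end +/-
#' `flank` bases, clipped to the gene start), and their differential
#' (antisense mean - sense mean). Internal positions have matched sense
#' and antisense starts under random fragmentation, so the differential
#' fluctuates around zero except near a true transcript end.
#'
#' @param track A [read_start_track()].
#' @param gene_id,cell_id Which (gene, cell) pair to smooth.
#' @param window Moving-average window in bases.
#' @param step Step between window placements in bases.
#' @param flank Analysis half-width around the annotated end, in bases.
#'
#' @return `data.frame` with columns `pos` (window midpoint), `sense`,
#'   `antisense` (window means), and `differential`. Zero rows for an
#'   empty track.
#' @export
smooth_differential <- function(track, gene_id, cell_id, window = 50,
                                step = 5, flank = 1000) {
  stopifnot(inherits(track, "read_start_track"))
  if (window < step || step < 1) stop("need window >= step >= 1")
  g <- track$gene_models[track$gene_models$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene_id")
  s <- track$starts[track$starts$gene_id == gene_id &
                      track$starts$cell_id == cell_id, , drop = FALSE]
  empty <- data.frame(pos = integer(), sense = numeric(),
                      antisense = numeric(), differential = numeric())
  if (nrow(s) == 0) return(empty)

  lo <- max(g$start, g$annotated_end - flank)
  hi <- g$annotated_end + flank
  .smooth_diff(s, lo, hi, window, step)
}

## Core smoothing on a per-(gene, cell) starts subset over [lo, hi].
.smooth_diff <- function(s, lo, hi, window, step) {
  len <- hi - lo + window  # pad so windows ending at hi are complete
  mult <- function(orient) {
    sel <- s$orientation == orient & s$pos >= lo & s$pos < lo + len
    v <- numeric(len)
    if (any(sel)) {
      agg <- rowsum(as.numeric(s$count[sel]), s$pos[sel] - lo + 1L)
      v[as.integer(rownames(agg))] <- agg[, 1]
    }
    v
  }
  se <- mult("sense")
  an <- mult("antisense")
  win_starts <- seq(1L, len - window + 1L, by = step)
  wsum <- function(v) {
    cs <- c(0, cumsum(v))
    (cs[win_starts + window] - cs[win_starts]) / window
  }
  sm_s <- wsum(se)
  sm_a <- wsum(an)
  keep <- (lo + win_starts - 1L) <= hi
  data.frame(pos = lo + win_starts[keep] - 1L + window %/% 2L,
             sense = sm_s[keep], antisense = sm_a[keep],
             differential = sm_a[keep] - sm_s[keep])
}

#' Call candidate 3' UTR end positions from a smoothed differential
#'
#' Local maxima of the positive differential are ranked by height within
#' the gene's analysis region; peaks at or above the `1 - top_fraction`
#' height percentile of positive differential values, and whose raw
#' antisense read-start depth within the window at the apex reaches
#' `min_depth`, become candidate end positions. Nearby maxima within one
#' window width are merged, keeping the highest (ties resolved toward
#' the most 3' position).
#'
#' @param differential Output of [smooth_differential()].
#' @param top_fraction Retained upper fraction of peak heights.
#' @param min_depth Minimum raw antisense starts in the apex window.
#' @param window Window size used for smoothing (for the depth gate and
#'   peak merging).
#'
#' @return Integer vector of candidate end positions (window midpoints),
#'   possibly empty.
#' @export
call_end_candidates <- function(differential, top_fraction = 0.02,
                                min_depth = 10, window = 50) {
  if (nrow(differential) == 0) return(integer(0))
  d <- differential$differential
  pos <- differential$pos
  if (all(d <= 0)) return(integer(0))
  n <- length(d)
  is_max <- d > 0 &
    d >= c(-Inf, d[-n]) &
    d >= c(d[-1], -Inf)
  thr <- quantile(d[d > 0], probs = 1 - top_fraction, names = FALSE)
  depth_ok <- differential$antisense * window >= min_depth
  cand <- which(is_max & d >= thr & depth_ok)
  if (length(cand) == 0) return(integer(0))
  # merge apexes within one window width; keep highest, ties -> most 3'
  ord <- cand[order(pos[cand])]
  groups <- cumsum(c(1, diff(pos[ord]) > window))
  out <- vapply(split(ord, groups), function(ix) {
    best <- ix[d[ix] == max(d[ix])]
    pos[max(best)]
  }, numeric(1))
  as.integer(sort(unname(out)))
}

#' Pairwise overlap of two cells' 3' end sets
#'
#' For each end in A, a match is scored if B has an end within
#' `tolerance` bases, and vice versa; the overlap is the mean of the two
#' match fractions. Symmetric, with `d(A, A) = 1`.
#'
#' @param ends_a,ends_b Integer vectors of end positions.
#' @param tolerance Match tolerance in bases.
#' @return Overlap in \code{[0, 1]}, or `NA` if either list is empty.
#' @export
pairwise_overlap <- function(ends_a, ends_b, tolerance = 200) {
  if (length(ends_a) == 0 || length(ends_b) == 0) return(NA_real_)
  match_frac <- function(x, y)
    mean(vapply(x, function(p) any(abs(y - p) <= tolerance), logical(1)))
  (match_frac(ends_a, ends_b) + match_frac(ends_b, ends_a)) / 2
}

#' Per-gene 3' end profile across cells and cell types
#'
#' Calls candidate ends for every (gene, cell), pools them into reference
#' peaks (single-linkage clusters with gaps larger than `tolerance`
#' separating peaks; the reference position is the cluster median), and
#' tabulates, per cell type, the fraction of that type's expressing cells
#' possessing each peak (an end within `tolerance` of the reference). A
#' cell is expressing if it has any read start for the gene; cell types
#' with fewer than `min_cells` expressing cells are dropped from the
#' fraction table for that gene.
#'
#' @param track A [read_start_track()].
#' @param window,step,flank Smoothing parameters
#'   ([smooth_differential()]).
#' @param top_fraction,min_depth Peak-calling parameters
#'   ([call_end_candidates()]).
#' @param tolerance Match tolerance in bases.
#' @param min_cells Minimum expressing cells for a cell type to count.
#'
#' @return An object of class `utr_end_profile`: list with `fractions`
#'   (`data.frame`: `gene_id`, `end_position`, `cell_type`, `fraction`),
#'   `cell_ends` (per-cell candidate ends), and `expressing` (expressing
#'   cell counts per gene and type).
#' @export
utr_end_profile <- function(track, window = 50, step = 5, flank = 1000,
                            top_fraction = 0.02, min_depth = 10,
                            tolerance = 200, min_cells = 5) {
  stopifnot(inherits(track, "read_start_track"))
  genes <- track$gene_models$gene_id
  cell_ends <- list()
  frac_rows <- list()
  expr_rows <- list()
  starts_by_gene <- split(track$starts,
                          factor(track$starts$gene_id, levels = genes))

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gm <- track$gene_models[gi, ]
    gs <- starts_by_gene[[g]]
    expr_cells <- unique(gs$cell_id)
    types <- track$cells$cell_type[match(expr_cells, track$cells$cell_id)]
    type_counts <- table(types)
    kept_types <- names(type_counts)[type_counts >= min_cells]
    expr_rows[[g]] <- data.frame(gene_id = g,
                                 cell_type = names(type_counts),
                                 n_expressing = as.integer(type_counts))
    lo <- max(gm$start, gm$annotated_end - flank)
    hi <- gm$annotated_end + flank
    gs_by_cell <- split(gs, factor(gs$cell_id, levels = expr_cells))
    ends_by_cell <- lapply(gs_by_cell, function(sub) {
      diffs <- .smooth_diff(sub, lo, hi, window, step)
      call_end_candidates(diffs, top_fraction = top_fraction,
                          min_depth = min_depth, window = window)
    })
    cell_ends[[g]] <- ends_by_cell
    pooled <- sort(unlist(ends_by_cell, use.names = FALSE))
    if (length(pooled) == 0 || length(kept_types) == 0) next
    cl <- cumsum(c(1, diff(pooled) > tolerance))
    refs <- vapply(split(pooled, cl), median, numeric(1))
    for (ref in refs) {
      for (ty in kept_types) {
        tcells <- expr_cells[types == ty]
        has <- vapply(tcells, function(cc) {
          e <- ends_by_cell[[cc]]
          length(e) > 0 && any(abs(e - ref) <= tolerance)
        }, logical(1))
        frac_rows[[length(frac_rows) + 1L]] <-
          data.frame(gene_id = g, end_position = ref, cell_type = ty,
                     fraction = mean(has))
      }
    }
  }

  fractions <- if (length(frac_rows)) do.call(rbind, frac_rows) else
    data.frame(gene_id = character(), end_position = numeric(),
               cell_type = character(), fraction = numeric())
  rownames(fractions) <- NULL
  structure(list(fractions = fractions,
                 cell_ends = cell_ends,
                 expressing = do.call(rbind, expr_rows),
                 min_cells = min_cells),
            class = "utr_end_profile")
}

#' Classify genes by cross-cell-type coherence of 3' end usage
#'
#' Using the fraction table of a [utr_end_profile()], a gene is
#' `consistent` when every identified end reaches at least `coherent_min`
#' in every retained cell type (and at least `min_types` types are
#' retained); `variable` when every end stays below `incoherent_max` in
#' every retained type; `cell_type_specific` when some end is coherent
#' (`>= coherent_min`) in at least one type but absent or less coherent
#' in at least one other, and the gene is not consistent; otherwise
#' `unclassified` (including genes with no called ends or fewer than
#' `min_types` retained types).
#'
#' @param profile A [utr_end_profile()].
#' @param coherent_min Coherence fraction defining a shared end.
#' @param incoherent_max Upper bound defining variable usage.
#' @param min_types Minimum retained cell types.
#'
#' @return `data.frame` with `gene_id` and `class`.
#' @export
classify_utr_genes <- function(profile, coherent_min = 0.8,
                               incoherent_max = 0.6, min_types = 2) {
  stopifnot(inherits(profile, "utr_end_profile"))
  genes <- names(profile$cell_ends)
  cls <- vapply(genes, function(g) {
    ft <- profile$fractions[profile$fractions$gene_id == g, , drop = FALSE]
    if (nrow(ft) == 0) return("unclassified")
    types <- unique(ft$cell_type)
    if (length(types) < min_types) return("unclassified")
    # complete the end x type grid; a type lacking an end has fraction 0
    wide <- matrix(0, nrow = length(unique(ft$end_position)),
                   ncol = length(types),
                   dimnames = list(NULL, types))
    ends <- sort(unique(ft$end_position))
    wide[cbind(match(ft$end_position, ends), match(ft$cell_type, types))] <-
      ft$fraction
    if (all(wide >= coherent_min)) return("consistent")
    if (all(wide < incoherent_max)) return("variable")
    specific <- any(apply(wide, 1, function(r)
      any(r >= coherent_min) && any(r < coherent_min)))
    if (specific) return("cell_type_specific")
    "unclassified"
  }, character(1))
  data.frame(gene_id = genes, class = unname(cls))
}
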