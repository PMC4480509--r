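#' Strand-resolved read-start tracks
#'
#' A `read_start_track` stores, per gene and cell, the genomic positions
#' (0-based) of read starts together with their orientation relative to
#' the gene (`"sense"` or `"antisense"`) and a multiplicity count. Around
#' any internal transcript position random fragmentation produces equal
#' numbers of sense and antisense read starts in expectation; a genuine
#' 3' transcript end produces an excess of antisense starts, which is the
#' signal the UTR-end caller exploits.
#'
#' @param starts `data.frame` with columns `gene_id`, `cell_id`, `pos`,
#'   `orientation`, `count`.
#' @param gene_models `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, and optionally `annotated_end` (defaults
#'   to `end`). Coordinates 0-based.
#' @param cells `data.frame` with columns `cell_id`, `cell_type`.
#' @return An object of class `read_start_track`.
#' @export
read_start_track <- function(starts, gene_models, cells) {
  stopifnot(all(c("gene_id", "cell_id", "pos", "orientation", "count") %in%
                  names(starts)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(gene_models)),
            all(c("cell_id", "cell_type") %in% names(cells)))
  if (is.null(gene_models$annotated_end))
    gene_models$annotated_end <- gene_models$end
  if (!all(starts$orientation %in% c("sense", "antisense")))
    stop("orientation must be 'sense' or 'antisense'")
  if (any(starts$count < 0)) stop("counts must be non-negative")
  structure(list(starts = starts, gene_models = gene_models, cells = cells),
            class = "read_start_track")
}

#' @export
print.read_start_track <- function(x, ...) {
  cat(sprintf("read_start_track: %d genes, %d cells, %d start records\n",
              nrow(x$gene_models), nrow(x$cells), nrow(x$starts)))
  invisible(x)
}

#' Simulate per-cell read-start tracks with planted 3' ends
#'
#' Random fragmentation places breakpoints uniformly along the expressed
#' transcript; every breakpoint contributes one sense and one antisense
#' read start at the same position, so the smoothed antisense-sense
#' differential is centred on zero at internal positions. Each planted 3'
#' end adds a Poisson number of extra antisense starts at the end
#' position (with small positional jitter), creating the peak the caller
#' should recover. A cell that does not express a gene contributes no
#' rows for it.
#'
#' @param spec A [synthetic_spec()]; supplies the seed.
#' @param gene_models Gene table as in [read_start_track()].
#' @param cells Cell table (`cell_id`, `cell_type`).
#' @param planted_ends `data.frame` with columns `gene_id`, `position`,
#'   and optionally `cell_type` and/or `cell_id` (`NA` = applies to all).
#'   Positions must lie within the gene span.
#' @param frag_depth Expected fragmentation breakpoints per expressed
#'   gene per cell.
#' @param end_reads Expected excess antisense starts per planted end per
#'   cell.
#' @param end_jitter_sd Positional jitter (bp) of planted end reads.
#' @param expressed_prob Probability that a cell expresses a gene.
#'
#' @return A [read_start_track()].
#' @export
simulate_read_starts <- function(spec, gene_models, cells, planted_ends,
                                 frag_depth = 200, end_reads = 30,
                                 end_jitter_sd = 3, expressed_prob = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(gene_models$annotated_end))
    gene_models$annotated_end <- gene_models$end
  if (nrow(planted_ends)) {
    if (is.null(planted_ends$cell_type)) planted_ends$cell_type <- NA
    if (is.null(planted_ends$cell_id)) planted_ends$cell_id <- NA
    gi <- match(planted_ends$gene_id, gene_models$gene_id)
    if (anyNA(gi)) stop("planted end for unknown gene")
    bad <- planted_ends$position < gene_models$start[gi] |
      planted_ends$position > gene_models$end[gi]
    if (any(bad))
      stop(sprintf("planted end position outside gene span for %s",
                   paste(unique(planted_ends$gene_id[bad]), collapse = ", ")))
  }

  pe_by_gene <- if (nrow(planted_ends))
    split(planted_ends, planted_ends$gene_id) else list()

  # accumulate plain vectors; one data.frame at the end
  acc_gene <- list(); acc_cell <- list(); acc_pos <- list()
  acc_orient <- list(); acc_cnt <- list(); k <- 0L
  push <- function(gene, cell, pos, orient) {
    if (length(pos) == 0) return(invisible())
    tb <- tabulate_positions(pos)
    k <<- k + 1L
    acc_gene[[k]] <<- rep(gene, length(tb$pos))
    acc_cell[[k]] <<- rep(cell, length(tb$pos))
    acc_pos[[k]] <<- tb$pos
    acc_orient[[k]] <<- rep(orient, length(tb$pos))
    acc_cnt[[k]] <<- tb$count
  }
  tabulate_positions <- function(pos) {
    agg <- rowsum(rep(1L, length(pos)), pos)
    list(pos = as.integer(rownames(agg)), count = as.integer(agg[, 1]))
  }

  .with_seed(.stream_seed(spec$seed, "read_starts"), {
    for (i in seq_len(nrow(gene_models))) {
      g <- gene_models[i, ]
      pe_g <- pe_by_gene[[g$gene_id]]
      for (j in seq_len(nrow(cells))) {
        if (runif(1) >= expressed_prob) next
        cell_id <- cells$cell_id[j]
        cell_type <- cells$cell_type[j]
        pe <- if (is.null(pe_g)) NULL else
          pe_g[(is.na(pe_g$cell_type) | pe_g$cell_type == cell_type) &
                 (is.na(pe_g$cell_id) | pe_g$cell_id == cell_id), ,
               drop = FALSE]
        has_ends <- !is.null(pe) && nrow(pe) > 0
        tx_end <- if (has_ends) max(pe$position) else g$annotated_end
        nfrag <- rpois(1, frag_depth)
        if (nfrag > 0) {
          bp <- g$start + floor(runif(nfrag) * max(1, tx_end - g$start))
          push(g$gene_id, cell_id, bp, "sense")
          push(g$gene_id, cell_id, bp, "antisense")
        }
        if (has_ends) {
          kk <- rpois(nrow(pe), end_reads)
          epos <- round(rnorm(sum(kk), rep(pe$position, kk), end_jitter_sd))
          push(g$gene_id, cell_id, pmax(g$start, epos), "antisense")
        }
      }
    }
  })
  starts <- if (k > 0)
    data.frame(gene_id = unlist(acc_gene), cell_id = unlist(acc_cell),
               pos = unlist(acc_pos), orientation = unlist(acc_orient),
               count = unlist(acc_cnt))
  else
    data.frame(gene_id = character(), cell_id = character(),
               pos = integer(), orientation = character(), count = integer())
  read_start_track(starts, gene_models, cells)
}

#' Write / read a read-start track as 6-column BED
#'
#' One row per (position, orientation): `chrom`, `start`, `start + 1`,
#' `gene_id:cell_id`, `count`, `strand`. The genomic strand encodes
#' orientation: sense read starts carry the gene's strand, antisense
#' starts the opposite. Coordinates are 0-based half-open.
#'
#' @param track A [read_start_track()].
#' @param path Output BED path.
#' @export
write_read_starts_bed <- function(track, path) {
  stopifnot(inherits(track, "read_start_track"))
  s <- track$starts
  gm <- track$gene_models[match(s$gene_id, track$gene_models$gene_id), ]
  strand <- ifelse(s$orientation == "sense", gm$strand,
                   ifelse(gm$strand == "+", "-", "+"))
  bed <- data.frame(chrom = gm$chrom, start = s$pos, end = s$pos + 1L,
                    name = paste(s$gene_id, s$cell_id, sep = ":"),
                    score = s$count, strand = strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @param gene_models,cells Tables as in [read_start_track()]; needed to
#'   resolve orientation and cell types when reading.
#' @rdname write_read_starts_bed
#' @export
read_read_starts_bed <- function(path, gene_models, cells) {
  bed <- read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  parts <- strsplit(bed$name, ":", fixed = TRUE)
  gene_id <- vapply(parts, `[`, character(1), 1)
  cell_id <- vapply(parts, `[`, character(1), 2)
  gstrand <- gene_models$strand[match(gene_id, gene_models$gene_id)]
  starts <- data.frame(gene_id = gene_id, cell_id = cell_id,
                       pos = bed$start,
                       orientation = ifelse(bed$strand == gstrand,
                                            "sense", "antisense"),
                       count = bed$score)
  read_start_track(starts, gene_models, cells)
}
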