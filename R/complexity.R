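#' Expressed and private gene counts per sample
#'
#' An expressed gene has at least one read in the sample; a private gene
#' has at least one read in that sample and none in any other sample.
#'
#' @param x A [count_matrix()].
#' @return `data.frame` with `sample_id`, `expressed`, `private`.
#' @export
expressed_and_private_genes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  pos <- x$counts >= 1
  n_samples_with <- rowSums(pos)
  data.frame(sample_id = colnames(x$counts),
             expressed = colSums(pos),
             private = colSums(pos & n_samples_with == 1),
             row.names = NULL)
}

#' Number of top genes covering half of a sample's reads
#'
#' The smallest k such that the k largest gene counts sum to at least
#' half the sample total. Genes are taken in descending count order with
#' gene id as the stable secondary order.
#'
#' @param x A [count_matrix()].
#' @param sample Sample id.
#' @param fraction Read fraction to cover (default one half).
#' @return Integer k.
#' @export
genes_covering_half_reads <- function(x, sample, fraction = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts[, sample]
  total <- sum(counts)
  if (total == 0) stop(sprintf("sample %s has zero total reads", sample))
  ord <- order(-counts, rownames(x$counts))
  cum <- cumsum(counts[ord])
  as.integer(which(cum >= fraction * total)[1])
}

#' Cell-size-corrected expressed-gene counts
#'
#' Large cells hold more RNA, inflating detection sensitivity. For each
#' sample in `large_cell_samples` the detection threshold is raised to
#' `factor` times that sample's minimum non-zero relative frequency;
#' corrected expressed genes are those at or above the threshold. Other
#' samples keep their ordinary expressed count.
#'
#' @param nm A `normalized_matrix`.
#' @param large_cell_samples Character vector of sample ids to correct.
#' @param factor Size ratio; must be at least 1.
#' @return `data.frame` with `sample_id`, `expressed`,
#'   `corrected_expressed`.
#' @export
size_corrected_expressed <- function(nm, large_cell_samples, factor = 8) {
  stopifnot(inherits(nm, "normalized_matrix"), factor >= 1)
  rf <- nm$relfreq
  out <- data.frame(sample_id = colnames(rf),
                    expressed = colSums(rf > 0),
                    corrected_expressed = colSums(rf > 0))
  for (s in large_cell_samples) {
    v <- rf[, s]
    nz <- v[v > 0]
    if (length(nz) == 0)
      stop(sprintf("sample %s has no non-zero gene", s))
    thr <- factor * min(nz)
    out$corrected_expressed[out$sample_id == s] <- sum(v >= thr)
  }
  out
}

#' Partition a genome into exonic, intronic, flanking and intergenic
#'
#' Any base covered by an exon of any supplied annotation source is
#' exonic; bases internal to a transcribed unit but not exonic are
#' intronic; bases within `flank_bp` upstream or downstream of a
#' transcribed unit (and not already labelled) are flanking; everything
#' else is intergenic. Precedence is exonic > intronic > flanking >
#' intergenic, applied by set subtraction. Coordinates are 0-based
#' half-open.
#'
#' @param exons `data.frame` of exon intervals: `chrom`, `start`, `end`,
#'   `gene_id`, `strand`.
#' @param flank_bp Flank width in base pairs.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the furthest flank end per chromosome.
#' @return A `GenomicRanges::GRanges` whose `label` metadata column
#'   partitions each chromosome.
#' @export
build_region_annotation <- function(exons, flank_bp = 5000,
                                    chrom_lengths = NULL) {
  req <- c("chrom", "start", "end", "gene_id", "strand")
  if (!all(req %in% names(exons)))
    stop("exons must have columns ", paste(req, collapse = ", "))
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stop("malformed exon intervals (need 0 <= start < end)")

  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start + 1, exons$end))
  exonic <- GenomicRanges::reduce(gr)
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  spans <- data.frame(
    chrom = vapply(by_gene, function(ix) exons$chrom[ix[1]], character(1)),
    start = vapply(by_gene, function(ix) min(exons$start[ix]), numeric(1)),
    end = vapply(by_gene, function(ix) max(exons$end[ix]), numeric(1)))
  tx <- GenomicRanges::reduce(
    GenomicRanges::GRanges(spans$chrom,
                           IRanges::IRanges(spans$start + 1, spans$end)))
  intronic <- GenomicRanges::setdiff(tx, exonic)
  fl <- c(GenomicRanges::flank(tx, flank_bp, start = TRUE),
          GenomicRanges::flank(tx, flank_bp, start = FALSE))
  fl <- GenomicRanges::restrict(fl, start = 1L)
  flanking <- GenomicRanges::setdiff(GenomicRanges::reduce(fl),
                                     GenomicRanges::union(tx, exonic))

  chroms <- unique(exons$chrom)
  if (is.null(chrom_lengths)) {
    ends <- tapply(exons$end + flank_bp, exons$chrom, max)
    chrom_lengths <- setNames(as.numeric(ends), names(ends))
  }
  genome <- GenomicRanges::GRanges(chroms,
                                   IRanges::IRanges(1, chrom_lengths[chroms]))
  labelled <- GenomicRanges::union(GenomicRanges::union(exonic, intronic),
                                   flanking)
  intergenic <- GenomicRanges::setdiff(genome, labelled)

  pieces <- list(exonic = exonic, intronic = intronic,
                 flanking = flanking, intergenic = intergenic)
  out <- do.call(c, unname(lapply(names(pieces), function(lb) {
    p <- pieces[[lb]]
    if (length(p)) p$label <- lb
    p
  })))
  sort(out)
}

#' Assign reads to genomic region labels
#'
#' Reads (0-based half-open intervals) are assigned with intersection
#' non-empty semantics and precedence exonic > intronic > flanking >
#' intergenic: a read overlapping any exonic base is exonic, and so on.
#'
#' @param reads `data.frame` with `chrom`, `start`, `end` and `sample_id`.
#' @param annotation Output of [build_region_annotation()].
#' @return `data.frame` of per-sample fractions over the four labels
#'   (rows sum to 1).
#' @export
assign_read_regions <- function(reads, annotation) {
  stopifnot(all(c("chrom", "start", "end", "sample_id") %in% names(reads)))
  rg <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start + 1, reads$end))
  label <- rep(NA_character_, length(rg))
  for (lb in c("exonic", "intronic", "flanking", "intergenic")) {
    sub <- annotation[annotation$label == lb]
    hit <- IRanges::overlapsAny(rg, sub)
    label[is.na(label) & hit] <- lb
  }
  label[is.na(label)] <- "intergenic"
  tab <- table(reads$sample_id, factor(label, levels = c("exonic", "intronic",
                                                         "flanking",
                                                         "intergenic")))
  frac <- prop.table(tab, 1)
  out <- as.data.frame.matrix(frac)
  out <- cbind(sample_id = rownames(out), out)
  rownames(out) <- NULL
  out
}
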