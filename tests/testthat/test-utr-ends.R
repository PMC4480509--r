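# Minimal one-gene fixtures for the smoothing and calling layers.
utr_gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 0,
                       end = 3000, strand = "+", annotated_end = 3000)
utr_cells <- data.frame(cell_id = c("c1", "c2"), cell_type = c("A", "A"))

track_from_starts <- function(pos, orientation, count = 1, cell = "c1") {
  read_start_track(data.frame(gene_id = "g1", cell_id = cell, pos = pos,
                              orientation = orientation, count = count),
                   utr_gene, utr_cells)
}

test_that("matched sense/antisense starts give an identically zero differential", {
  pos <- seq(2100, 2900, by = 7)
  tr <- track_from_starts(c(pos, pos), rep(c("sense", "antisense"),
                                           each = length(pos)))
  d <- smooth_differential(tr, "g1", "c1")
  expect_true(all(d$differential == 0))
  expect_gt(max(d$sense), 0)
})

test_that("window 1 / step 1 smoothing is the identity", {
  tr <- track_from_starts(c(2500, 2500, 2600), c("antisense", "antisense",
                                                 "sense"),
                          count = c(3, 4, 2))
  d <- smooth_differential(tr, "g1", "c1", window = 1, step = 1)
  expect_equal(d$differential[d$pos == 2500], 7)
  expect_equal(d$differential[d$pos == 2600], -2)
  expect_true(all(d$differential[!d$pos %in% c(2500, 2600)] == 0))
})

test_that("a point source smooths to a plateau of height count/window", {
  tr <- track_from_starts(2500, "antisense", count = 10)
  d <- smooth_differential(tr, "g1", "c1", window = 50, step = 5)
  expect_equal(max(d$differential), 10 / 50)
  covered <- d$pos[d$differential > 0]
  # windows covering position 2500: midpoints within half a window
  expect_true(all(abs(covered - 2500) <= 25))
  # empty track gives an empty differential
  tr0 <- read_start_track(
    data.frame(gene_id = character(), cell_id = character(), pos = integer(),
               orientation = character(), count = integer()),
    utr_gene, utr_cells)
  expect_equal(nrow(smooth_differential(tr0, "g1", "c1")), 0)
})

test_that("smoothing is linear in the track", {
  set.seed(2)
  p1 <- sample(2000:3000, 40, replace = TRUE)
  p2 <- sample(2000:3000, 40, replace = TRUE)
  o1 <- sample(c("sense", "antisense"), 40, TRUE)
  o2 <- sample(c("sense", "antisense"), 40, TRUE)
  t1 <- track_from_starts(p1, o1)
  t2 <- track_from_starts(p2, o2)
  tsum <- track_from_starts(c(p1, p2), c(o1, o2))
  d1 <- smooth_differential(t1, "g1", "c1")
  d2 <- smooth_differential(t2, "g1", "c1")
  ds <- smooth_differential(tsum, "g1", "c1")
  expect_equal(ds$differential, d1$differential + d2$differential)
})

test_that("candidate calling gates on depth and separates distinct ends", {
  spec <- synthetic_spec(seed = 91)
  # planted end, ample depth: exactly one candidate near the end
  tr <- simulate_read_starts(spec, utr_gene, utr_cells,
                             data.frame(gene_id = "g1", position = 2600),
                             frag_depth = 150, end_reads = 50)
  d <- smooth_differential(tr, "g1", "c1")
  cand <- call_end_candidates(d)
  expect_length(cand, 1)
  expect_lt(abs(cand - 2600), 50)
  # depth gate: a 5-read end cannot reach min_depth = 10 on average
  tr2 <- simulate_read_starts(spec, utr_gene, utr_cells,
                              data.frame(gene_id = "g1", position = 2600),
                              frag_depth = 0, end_reads = 5)
  d2 <- smooth_differential(tr2, "g1", "c1")
  expect_length(call_end_candidates(d2, min_depth = 10), 0)
  # two equal ends 500 bp apart (deterministic multi-isoform fixture
  # with identical antisense excess at both): two candidates
  tr3 <- track_from_starts(c(2100, 2600), c("antisense", "antisense"),
                           count = c(30, 30))
  d3 <- smooth_differential(tr3, "g1", "c1")
  cand3 <- call_end_candidates(d3)
  expect_length(cand3, 2)
  expect_lt(abs(cand3[1] - 2100), 60)
  expect_lt(abs(cand3[2] - 2600), 60)
  # all-nonpositive differential: no candidates
  trs <- track_from_starts(2500, "sense", count = 30)
  expect_length(call_end_candidates(smooth_differential(trs, "g1", "c1")),
                0)
})

test_that("planted ends outside the gene span are rejected", {
  spec <- synthetic_spec(seed = 1)
  expect_error(simulate_read_starts(spec, utr_gene, utr_cells,
                                    data.frame(gene_id = "g1",
                                               position = 5000)),
               "outside gene span")
})

test_that("pairwise overlap follows the printed formula", {
  expect_equal(pairwise_overlap(c(100, 500), 120), 0.75)
  expect_equal(pairwise_overlap(c(100, 500), c(100, 500)), 1)
  expect_equal(pairwise_overlap(c(0, 1000), c(400, 2000)), 0)
  expect_true(is.na(pairwise_overlap(integer(0), 100)))
  # symmetry and self-overlap on random end lists
  set.seed(12)
  for (i in 1:50) {
    a <- sample(0:5000, sample(1:6, 1))
    b <- sample(0:5000, sample(1:6, 1))
    expect_equal(pairwise_overlap(a, b), pairwise_overlap(b, a))
    expect_equal(pairwise_overlap(a, a), 1)
  }
})

test_that("classification rules map fraction tables to the four labels", {
  prof <- function(fr, genes = "g1") {
    structure(list(fractions = fr,
                   cell_ends = setNames(vector("list", length(genes)), genes),
                   expressing = NULL, min_cells = 5),
              class = "utr_end_profile")
  }
  # one end at 1.0 in two types -> consistent
  f1 <- data.frame(gene_id = "g1", end_position = 100,
                   cell_type = c("A", "B"), fraction = c(1, 1))
  expect_equal(classify_utr_genes(prof(f1))$class, "consistent")
  # two ends each at 0.4 in both types -> variable
  f2 <- expand.grid(gene_id = "g1", end_position = c(100, 600),
                    cell_type = c("A", "B"))
  f2$fraction <- 0.4
  expect_equal(classify_utr_genes(prof(f2))$class, "variable")
  # end coherent in A, absent in B -> cell-type-specific
  f3 <- data.frame(gene_id = "g1", end_position = 100,
                   cell_type = c("A", "B"), fraction = c(0.9, 0))
  expect_equal(classify_utr_genes(prof(f3))$class, "cell_type_specific")
  # a single retained type cannot be classified
  f4 <- data.frame(gene_id = "g1", end_position = 100, cell_type = "A",
                   fraction = 1)
  expect_equal(classify_utr_genes(prof(f4))$class, "unclassified")
  # mixed: one end 0.7 everywhere (neither coherent nor <0.6) -> unclassified
  f5 <- data.frame(gene_id = "g1", end_position = 100,
                   cell_type = c("A", "B"), fraction = c(0.7, 0.7))
  expect_equal(classify_utr_genes(prof(f5))$class, "unclassified")
  # labels are exhaustive and exclusive over a grid of two-type tables
  fr_grid <- seq(0, 1, by = 0.25)
  for (fa in fr_grid) for (fb in fr_grid) {
    f <- data.frame(gene_id = "g1", end_position = 100,
                    cell_type = c("A", "B"), fraction = c(fa, fb))
    cls <- classify_utr_genes(prof(f))$class
    expect_true(cls %in% c("consistent", "variable", "cell_type_specific",
                           "unclassified"))
  }
})

test_that("profile round-trip recovers planted per-type structure", {
  spec <- synthetic_spec(seed = 17)
  gm <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                   start = c(0, 10000), end = c(3000, 13000), strand = "+",
                   annotated_end = c(3000, 13000))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:16),
                      cell_type = rep(c("T1", "T2"), each = 8))
  pe <- rbind(data.frame(gene_id = "gA", position = 2700, cell_type = NA,
                         cell_id = NA),
              data.frame(gene_id = "gB", position = 12300, cell_type = "T1",
                         cell_id = NA))
  tr <- simulate_read_starts(spec, gm, cells, pe, frag_depth = 200,
                             end_reads = 30)
  prof <- utr_end_profile(tr)
  cls <- classify_utr_genes(prof)
  expect_equal(cls$class[cls$gene_id == "gA"], "consistent")
  expect_equal(cls$class[cls$gene_id == "gB"], "cell_type_specific")
  # a cell with no reads leaves no rows (empty-row contract)
  tr0 <- simulate_read_starts(spec, gm[1, , drop = FALSE], cells,
                              pe[1, , drop = FALSE], frag_depth = 200,
                              end_reads = 30, expressed_prob = 0.5)
  expressed <- unique(tr0$starts$cell_id)
  expect_lt(length(expressed), 16)
})

test_that("read-start BED round-trip preserves the track", {
  spec <- synthetic_spec(seed = 3)
  gm <- data.frame(gene_id = "gA", chrom = "chr1", start = 0, end = 2000,
                   strand = "+", annotated_end = 2000)
  cells <- data.frame(cell_id = c("c1", "c2"), cell_type = "T1")
  tr <- simulate_read_starts(spec, gm, cells,
                             data.frame(gene_id = "gA", position = 1800),
                             frag_depth = 50, end_reads = 20)
  bed <- tempfile(fileext = ".bed")
  write_read_starts_bed(tr, bed)
  tr2 <- read_read_starts_bed(bed, gm, cells)
  o1 <- tr$starts[order(tr$starts$cell_id, tr$starts$pos,
                        tr$starts$orientation), ]
  o2 <- tr2$starts[order(tr2$starts$cell_id, tr2$starts$pos,
                         tr2$starts$orientation), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})
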