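# Shared fixture builders and independent brute-force oracles.

# Small count matrix with explicit values; genes g1..gn, samples s1..sm.
cm_fixture <- function(values, n_genes, n_samples, groups = NULL) {
  m <- matrix(values, nrow = n_genes, ncol = n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  meta <- data.frame(sample_id = colnames(m),
                     group = if (is.null(groups)) "x" else groups)
  count_matrix(m, meta)
}

# Hand-rolled normalized_matrix wrapper around a relative-frequency
# matrix, for tests that control rf values directly.
nm_from_relfreq <- function(rf, normalized = rf) {
  structure(list(counts = rf, size_factors = rep(1, ncol(rf)),
                 normalized = normalized, relfreq = rf,
                 sample_meta = data.frame(sample_id = colnames(rf),
                                          group = "x")),
            class = "normalized_matrix")
}

# Independent median-of-ratios implementation (loops, no vectorized
# sharing with the package code path).
size_factors_bruteforce <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- counts[keep, , drop = FALSE]
  geo <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) geo[i] <- prod(ref[i, ])^(1 / ncol(ref))
  sf <- numeric(ncol(ref))
  for (j in seq_len(ncol(ref))) sf[j] <- median(ref[, j] / geo)
  sf
}

# Independent outlier-sum implementation following the published recipe
# step by step, with explicit type-7 quartile interpolation.
outlier_sum_bruteforce <- function(values, tmin) {
  med <- sort(values)[ceiling(length(values) / 2)]
  if (length(values) %% 2 == 0) {
    sv <- sort(values)
    med <- (sv[length(values) / 2] + sv[length(values) / 2 + 1]) / 2
  }
  dev <- abs(values - med)
  sdev <- sort(dev)
  mad_v <- if (length(dev) %% 2 == 0)
    (sdev[length(dev) / 2] + sdev[length(dev) / 2 + 1]) / 2
  else sdev[ceiling(length(dev) / 2)]
  scale <- if (mad_v == 0) tmin else mad_v
  z <- (values - med) / scale
  q7 <- function(v, p) {
    sv <- sort(v)
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }
  q1 <- q7(z, 0.25); q3 <- q7(z, 0.75)
  fence <- q3 + (q3 - q1)
  sum(z[z > fence])
}

# Closed-form expected detected genes under without-replacement
# subsampling at depth d.
expected_detected <- function(counts, d) {
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, d) - lchoose(total, d)))
}
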