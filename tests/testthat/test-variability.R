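# Shared small pipeline fixture: one dilution set, curve, and cell type.
local_pipeline <- local({
  spec <- synthetic_spec(n_genes = 1500, target_depth = 2e5, seed = 19)
  dil <- compute_size_factors(simulate_dilution_counts(spec, 10))
  curve <- build_control_curve(dil, 300)
  cells <- simulate_cell_type_counts(spec, "Car")
  nc <- compute_size_factors(cells$matrix)
  thr <- evaluate_reliability_criteria(dil, nc, curve)
  list(spec = spec, dil = dil, curve = curve, cells = cells, nc = nc,
       thr = thr)
})

test_that("f-statistic is a variance ratio with the documented edge cases", {
  p <- local_pipeline
  tab <- f_statistic(p$nc, p$curve, p$thr)
  expect_true(all(tab$x >= p$thr$selected))
  expect_true(all(tab$f_stat >= 0))
  expect_equal(tab$f_stat, tab$v_total / tab$v_exp)
  # constant gene: zero variance -> F exactly 0
  rf <- matrix(rep(c(2e-3, 1e-3, 3e-3), each = 5), 3, 5, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  rf[2, ] <- rf[2, ] * (1 + c(-0.2, -0.1, 0, 0.1, 0.2))
  tab0 <- f_statistic(nm_from_relfreq(rf), p$curve, 0)
  expect_equal(tab0$f_stat[tab0$gene_id == "g1"], 0)
  expect_gt(tab0$f_stat[tab0$gene_id == "g2"], 0)
})

test_that("planted variance 9 x V_exp yields mean F near 10", {
  p <- local_pipeline
  # cells = technical replicates plus gaussian biological noise with
  # variance 9 x V_exp at each gene's expression level
  spec2 <- synthetic_spec(n_genes = 1500, target_depth = 2e5, seed = 77)
  reps <- simulate_dilution_counts(spec2, 10, n_replicates = 400)
  rf <- sweep(reps$counts, 2, colSums(reps$counts), "/")
  keep <- rowMeans(rf) >= p$thr$selected
  rf <- rf[keep, , drop = FALSE]
  vexp <- lookup_control_curve(p$curve, rowMeans(rf))
  set.seed(1)
  rf_bio <- rf + matrix(rnorm(length(rf), 0, sqrt(9 * vexp)), nrow(rf))
  tab <- f_statistic(nm_from_relfreq(rf_bio), p$curve, 0)
  # total variance = technical (~V_exp) + 9 V_exp
  expect_lt(abs(mean(tab$f_stat) - 10) / 10, 0.1)
})

test_that("null calibration: technical-only cells give median F near 1", {
  spec <- synthetic_spec(n_genes = 3000, target_depth = 2e5, seed = 23)
  all32 <- simulate_dilution_counts(spec, 10, n_replicates = 32)
  d <- count_matrix(all32$counts[, 1:12], all32$sample_meta[1:12, ])
  c20 <- count_matrix(all32$counts[, 13:32],
                      transform(all32$sample_meta[13:32, ], group = "cells"))
  nd <- compute_size_factors(d)
  nc <- compute_size_factors(c20)
  curve <- build_control_curve(nd, 500)
  thr <- suppressWarnings(
    evaluate_reliability_criteria(nd, nc, curve, on_unattainable = "na"))
  t13 <- max(thr$criteria[c("complete", "normality")])
  tab <- f_statistic(nc, curve, t13)
  expect_lt(abs(median(tab$f_stat) - 1), 0.1)
  expect_lt(mean(tab$f_stat > 10), 0.01)
})

test_that("top variable genes: order statistics, ties and nesting", {
  tab <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    x = runif(100, 1e-4, 1e-3),
                    f_stat = c(rep(5, 4), runif(96, 0, 3)))
  expect_length(top_variable_genes(tab, 0.05), 5)
  top5 <- top_variable_genes(tab, 0.05)
  expect_true(all(tab$f_stat[match(top5, tab$gene_id)] >=
                    max(tab$f_stat[!tab$gene_id %in% top5])))
  expect_setequal(top_variable_genes(tab, 1), tab$gene_id)
  expect_true(all(top_variable_genes(tab, 0.05) %in%
                    top_variable_genes(tab, 0.10)))
  expect_error(top_variable_genes(tab, 0), "fraction")
  # deterministic tie-break: equal F decided by larger x then id
  tie <- data.frame(gene_id = c("b", "a", "c"), x = c(1e-3, 2e-3, 2e-3),
                    f_stat = c(7, 7, 7))
  expect_equal(top_variable_genes(tie, 1 / 3), "a")
})

test_that("planted hypervariable genes are recovered by the top-F rule", {
  # calibration against a technical-null background: background genes
  # carry (almost) no biological dispersion, planted genes a strong
  # two-state mixture, so the selector is tested on a known contrast
  spec <- synthetic_spec(n_genes = 2000, target_depth = 2e5,
                         cell_type_sizes = c(Car = 20),
                         background_dispersion_sd = 0.05, seed = 37)
  dil <- compute_size_factors(simulate_dilution_counts(spec, 10))
  curve <- build_control_curve(dil, 400)
  sim <- simulate_cell_type_counts(spec, "Car")
  nc <- compute_size_factors(sim$matrix)
  thr <- suppressWarnings(
    evaluate_reliability_criteria(dil, nc, curve, on_unattainable = "na"))
  t13 <- max(thr$criteria[c("complete", "normality")])
  tab <- f_statistic(nc, curve, t13)
  planted <- sim$truth$gene_id[sim$truth$hypervariable]
  planted_in <- intersect(planted, tab$gene_id)
  top <- top_variable_genes(tab, length(planted_in) / nrow(tab))
  expect_gte(mean(planted_in %in% top), 0.9)
})

test_that("ancova recovers planted category effects and matches algebra", {
  set.seed(55)
  n <- 2000
  cats <- sample(c("metabolism", "ribosome", "ion_channel"), n, TRUE)
  depth <- runif(n, 1, 4)
  logf <- 0.2 + 0.15 * depth + 0.3 * (cats == "ion_channel") +
    rnorm(n, 0, 0.3)
  tabs <- list(
    A = data.frame(gene_id = sprintf("g%04d", 1:n), x = 10^-depth,
                   mean_norm = 10^depth, f_stat = 10^logf),
    B = data.frame(gene_id = sprintf("g%04d", 1:n), x = 10^-depth,
                   mean_norm = 10^depth,
                   f_stat = 10^(logf + rnorm(n, 0.1, 0.3))))
  cat_tab <- data.frame(gene_id = sprintf("g%04d", 1:n), category = cats)
  res <- category_ancova(tabs, cat_tab)
  # factor levels are alphabetical: ion_channel is the baseline, so the
  # planted +0.3 appears as metabolism - ion_channel near -0.3
  met_vs_ic <- res$contrasts[
    res$contrasts$comparison == "metabolism - ion_channel", ]
  expect_equal(nrow(met_vs_ic), 1)
  expect_lt(abs(met_vs_ic$estimate - (-0.3)), 0.05)
  expect_true(met_vs_ic$lower < -0.3 && -0.3 < met_vs_ic$upper)
  # contrasts equal the normal-equations solution on the same design
  dat <- do.call(rbind, lapply(names(tabs), function(ct)
    cbind(tabs[[ct]], cell_type = ct)))
  dat <- merge(dat, cat_tab, by = "gene_id")
  X <- model.matrix(~ category + cell_type + log10(mean_norm), dat)
  beta <- solve(t(X) %*% X, t(X) %*% log10(dat$f_stat))
  expect_equal(met_vs_ic$estimate, unname(beta["categorymetabolism", 1]),
               tolerance = 1e-8)
  expect_equal(nrow(res$contrasts), 3)
})

test_that("ancova interval coverage is near nominal under the null", {
  hits <- vapply(1:200, function(s) {
    set.seed(s + 4000)
    n <- 240
    cats <- rep(c("a", "b"), each = n / 2)
    depth <- runif(n, 1, 3)
    tab <- data.frame(gene_id = sprintf("g%03d", 1:n), x = 10^-depth,
                      mean_norm = 10^depth,
                      f_stat = 10^(0.1 * depth + rnorm(n, 0, 0.3)))
    res <- category_ancova(list(A = tab),
                           data.frame(gene_id = tab$gene_id, category = cats))
    res$contrasts$lower[1] < 0 && 0 < res$contrasts$upper[1]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("cross-species partial correlation handles the canonical cases", {
  set.seed(9)
  n <- 5000
  x <- 10^runif(n, -4.5, -2.5)
  hom <- data.frame(a = sprintf("A%04d", 1:n), b = sprintf("B%04d", 1:n))
  mk <- function(ids, f) data.frame(gene_id = ids, x = x, f_stat = f)
  # identical F independent of expression -> rho = 1
  f0 <- 10^rnorm(n, 0.5, 0.4)
  r1 <- cross_species_partial_correlation(mk(hom$a, f0), mk(hom$b, f0), hom)
  expect_equal(r1$rho, 1, tolerance = 1e-10)
  # F a shared deterministic function of expression only -> rho ~ 0
  fx <- 10^(0.5 + 0.8 * log10(x) + 0.1 * log10(x)^2)
  eps <- matrix(10^rnorm(2 * n, 0, 0.2), n)
  r2 <- cross_species_partial_correlation(mk(hom$a, fx * eps[, 1]),
                                          mk(hom$b, fx * eps[, 2]), hom)
  expect_lt(abs(r2$rho), 0.05)
  # residuals orthogonal to both covariates
  X <- cbind(log10(x), log10(x))
  expect_lt(max(abs(crossprod(cbind(1, log10(x)), r2$residuals$resid_a))),
            1e-8)
  # ambiguous homologues rejected
  bad <- rbind(hom, hom[1, ])
  expect_error(cross_species_partial_correlation(mk(hom$a, f0),
                                                 mk(hom$b, f0), bad),
               "ambiguous")
  # invariance to a constant log-scale shift of expression
  tab_shift <- mk(hom$a, f0); tab_shift$x <- tab_shift$x * 100
  r3 <- cross_species_partial_correlation(tab_shift, mk(hom$b, f0), hom)
  expect_equal(r3$rho, r1$rho, tolerance = 1e-10)
})

test_that("planted cross-species dispersion correlation is recovered", {
  spec <- synthetic_spec(n_genes = 4000, target_depth = 2e5,
                         planted_cross_species_rho = 0.5, seed = 41)
  spec_b <- synthetic_spec(n_genes = 4000, target_depth = 2e5, seed = 100044)
  ts <- simulate_two_species(spec, c(species_a = 100, species_b = 100))
  curve <- build_control_curve(compute_size_factors(
    simulate_dilution_counts(spec, 10, profile = ts$profile)), 400)
  curve_b <- build_control_curve(compute_size_factors(
    simulate_dilution_counts(spec_b, 10, profile = ts$profile)), 400)
  ta <- f_statistic(compute_size_factors(ts$species_a), curve, 6e-5)
  tb <- f_statistic(compute_size_factors(ts$species_b), curve_b, 6e-5)
  r <- cross_species_partial_correlation(ta, tb, ts$homologues)
  expect_lt(abs(r$rho - 0.5), 0.07)
  expect_lt(r$p_value, 1e-10)
})

test_that("within and between variance follow the pooled decomposition", {
  rf1 <- matrix(c(0.2, 0.3, 0.5, 0.4, 0.1, 0.5), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a1", "a2")))
  rf2 <- matrix(c(0.6, 0.2, 0.2, 0.5, 0.3, 0.2), 3, 2,
                dimnames = list(paste0("g", 1:3), c("b1", "b2")))
  res <- within_between_variance(list(A = nm_from_relfreq(rf1),
                                      B = nm_from_relfreq(rf2)))
  t1 <- asin(sqrt(rf1)); t2 <- asin(sqrt(rf2))
  expect_equal(res$within$within_variance[1], mean(apply(t1, 1, var)))
  expect_equal(res$between$between_variance[1],
               mean(apply(cbind(t1, t2), 1, var)))
  # identical populations: between comparable to within
  res2 <- within_between_variance(list(A = nm_from_relfreq(rf1),
                                       B = nm_from_relfreq(rf1)))
  expect_lt(res2$between$between_variance[1],
            2 * res2$within$within_variance[1] + 1e-12)
  # single-cell type reported missing
  res3 <- within_between_variance(
    list(A = nm_from_relfreq(rf1[, 1, drop = FALSE]),
         B = nm_from_relfreq(rf2)))
  expect_true(is.na(res3$within$within_variance[1]))
})
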