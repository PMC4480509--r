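#' Specification of a synthetic single-cell experiment
#'
#' Bundles every parameter of the simulation so that all generated inputs
#' (dilution controls, single-cell matrices, two-species data, read-start
#' tracks, annotation tables) are reproducible from one object and one
#' integer seed. Defaults emulate the study design the pipeline is built
#' for: 91 single cells across five mouse cell types, 8 + 8 rat pyramidal
#' neurons, and 30 dilution replicates of bulk RNA amplified from 10, 50
#' and 100 pg of input (12/9/9 replicates), with 10 pg corresponding to a
#' pool of 150,000 mRNA molecules and 50/100 pg scaling linearly.
#'
#' The technical noise chain is binomial molecule capture, multiplicative
#' log-normal amplification noise (mean 1), then a multinomial sequencing
#' draw at `target_depth` reads. It is the simplest chain that reproduces
#' the two qualitative facts the analysis relies on: technical variation
#' grows as gene expression and input amount fall, and dropout appears
#' below roughly tens of molecules.
#'
#' @param n_genes Number of genes to simulate.
#' @param cell_type_sizes Named integer vector, cells per cell type.
#' @param dilution_design `data.frame` with columns `input_pg` and
#'   `n_replicates`.
#' @param mean_expression_model Named numeric `c(location, scale)` of the
#'   log-normal distribution of per-gene molecule abundance (the location
#'   cancels on normalization; the scale sets the dynamic range).
#' @param capture_efficiency Fraction of molecules captured, in (0, 1].
#' @param amplification_noise_sd Standard deviation (log scale) of the
#'   multiplicative log-normal amplification noise.
#' @param target_depth Reads per sample drawn by the sequencing step.
#' @param molecules_per_cell Molecule pool equivalent to 10 pg of input.
#' @param background_dispersion_sd Log-scale SD of the small biological
#'   dispersion shared by background (non-planted) genes.
#' @param planted_hypervariable List with `fraction` of genes planted as
#'   hypervariable, `fold_change` (> 1) of the on state, and
#'   `on_probability` of a cell being in the on state.
#' @param planted_cross_species_rho Correlation in (-1, 1) of per-gene
#'   excess dispersion between the two simulated species.
#' @param dispersion_log10_location,dispersion_log10_sd Location and SD of
#'   the per-gene log10 excess-dispersion values used by
#'   [simulate_two_species()]. The location of 1 centres planted
#'   biological variance at ten times the baseline.
#' @param species_cell_counts Named vector, cells per species for
#'   [simulate_two_species()].
#' @param seed Single integer; all operation-level random streams are
#'   derived from it deterministically.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 5000,
                           cell_type_sizes = c(Adi = 13, Car = 19, Pyc = 19,
                                               Pyh = 18, Ser = 22),
                           dilution_design = data.frame(
                             input_pg = c(10, 50, 100),
                             n_replicates = c(12L, 9L, 9L)),
                           mean_expression_model = c(location = 0, scale = 2),
                           capture_efficiency = 0.3,
                           amplification_noise_sd = 0.25,
                           target_depth = 5e5,
                           molecules_per_cell = 150000,
                           background_dispersion_sd = 0.55,
                           planted_hypervariable = list(fraction = 0.05,
                                                        fold_change = 16,
                                                        on_probability = 0.2),
                           planted_cross_species_rho = 0.5,
                           dispersion_log10_location = 1,
                           dispersion_log10_sd = 0.6,
                           species_cell_counts = c(species_a = 19,
                                                   species_b = 8),
                           seed = 1L) {
  stopifnot(n_genes >= 1, target_depth > 0, molecules_per_cell > 0)
  if (capture_efficiency <= 0 || capture_efficiency > 1)
    stop("capture_efficiency must be in (0, 1]")
  if (amplification_noise_sd < 0)
    stop("amplification_noise_sd must be non-negative")
  ph <- planted_hypervariable
  if (ph$fraction < 0 || ph$fraction > 1)
    stop("planted_hypervariable$fraction must be in [0, 1]")
  if (ph$fraction > 0 && ph$fold_change <= 1)
    stop("planted_hypervariable$fold_change must exceed 1")
  if (ph$on_probability < 0 || ph$on_probability > 1)
    stop("planted_hypervariable$on_probability must be in [0, 1]")
  if (abs(planted_cross_species_rho) >= 1)
    stop("planted_cross_species_rho must lie strictly inside (-1, 1)")
  if (!all(c("input_pg", "n_replicates") %in% names(dilution_design)))
    stop("dilution_design needs columns input_pg and n_replicates")
  structure(list(
    n_genes = as.integer(n_genes),
    cell_type_sizes = cell_type_sizes,
    dilution_design = dilution_design,
    mean_expression_model = mean_expression_model,
    capture_efficiency = capture_efficiency,
    amplification_noise_sd = amplification_noise_sd,
    target_depth = target_depth,
    molecules_per_cell = molecules_per_cell,
    background_dispersion_sd = background_dispersion_sd,
    planted_hypervariable = ph,
    planted_cross_species_rho = planted_cross_species_rho,
    dispersion_log10_location = dispersion_log10_location,
    dispersion_log10_sd = dispersion_log10_sd,
    species_cell_counts = species_cell_counts,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d genes, %d cell types, seed %d\n",
              x$n_genes, length(x$cell_type_sizes), x$seed))
  invisible(x)
}

.gene_ids <- function(n) sprintf("g%05d", seq_len(n))

## Fixed bulk expression profile shared by all dilution replicates of all
## input amounts (one bulk tube, diluted).
.bulk_profile <- function(spec) {
  p <- .with_seed(.stream_seed(spec$seed, "bulk_profile"),
                  rlnorm(spec$n_genes,
                         meanlog = spec$mean_expression_model[["location"]],
                         sdlog = spec$mean_expression_model[["scale"]]))
  p / sum(p)
}

## Approximate squared technical coefficient of variation of the chain at
## relative frequency x: amplification noise + binomial capture +
## sequencing sampling. Used to scale planted biological dispersion so a
## gene's expected variance ratio is independent of expression level.
.technical_cv2 <- function(spec, x) {
  m <- x * spec$molecules_per_cell
  p <- spec$capture_efficiency
  v <- exp(spec$amplification_noise_sd^2) - 1
  v + (1 - p) / (p * m) + 1 / (spec$target_depth * x)
}

## Technical measurement chain applied to a genes x samples matrix of
## input molecule counts: binomial capture -> log-normal amplification
## (mean 1) -> multinomial read sampling at target_depth.
.technical_counts <- function(molecules, spec) {
  n <- nrow(molecules)
  m <- ncol(molecules)
  captured <- matrix(rbinom(n * m, size = as.vector(molecules),
                            prob = spec$capture_efficiency),
                     nrow = n)
  s <- spec$amplification_noise_sd
  amp <- captured * matrix(rlnorm(n * m, meanlog = -s^2 / 2, sdlog = s),
                           nrow = n)
  counts <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    if (sum(amp[, j]) > 0)
      counts[, j] <- rmultinom(1, size = spec$target_depth, prob = amp[, j])
  }
  counts
}

#' Simulate dilution-control replicates
#'
#' Replicate amplifications of one fixed bulk RNA profile diluted to the
#' requested input amount. All replicates of all input amounts share the
#' same bulk profile; the molecule pool scales linearly with `input_pg`
#' (10 pg = `molecules_per_cell` molecules). The coefficient of variation
#' across replicates therefore decreases, in expectation, with input
#' amount and with gene abundance.
#'
#' @param spec A [synthetic_spec()].
#' @param input_pg Input amount in picograms; must appear in
#'   `spec$dilution_design`.
#' @param n_replicates Optional override of the designed replicate count
#'   (used for Monte-Carlo calibration at large n).
#' @param profile Optional bulk expression profile (non-negative vector,
#'   one value per gene) to dilute instead of the spec's own bulk
#'   profile. Supplying the expression profile of the simulated tissue
#'   mirrors the study design, where the dilution controls are bulk RNA
#'   of the same tissue as the cells, and keeps the control curve's
#'   expression support matched to the cells'.
#'
#' @return A [count_matrix()] with group `"dilution"`. The attribute
#'   `"molecule_pool"` records the fixed per-gene input molecule counts.
#' @export
simulate_dilution_counts <- function(spec, input_pg, n_replicates = NULL,
                                     profile = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  des <- spec$dilution_design
  row <- which(des$input_pg == input_pg)
  if (length(row) != 1)
    stop(sprintf("input_pg = %g is not part of the dilution design", input_pg))
  nrep <- if (is.null(n_replicates)) des$n_replicates[row] else n_replicates
  if (is.null(profile)) {
    profile <- .bulk_profile(spec)
  } else {
    stopifnot(length(profile) == spec$n_genes, all(profile >= 0))
    profile <- profile / sum(profile)
  }
  pool <- round(profile * spec$molecules_per_cell * input_pg / 10)
  molecules <- matrix(pool, nrow = spec$n_genes, ncol = nrep)
  counts <- .with_seed(.stream_seed(spec$seed, paste0("dilution_", input_pg)),
                       .technical_counts(molecules, spec))
  ids <- sprintf("dil%03g_r%04d", input_pg, seq_len(nrep))
  dimnames(counts) <- list(.gene_ids(spec$n_genes), ids)
  meta <- data.frame(sample_id = ids, group = "dilution", input_pg = input_pg)
  out <- count_matrix(counts, meta)
  attr(out, "molecule_pool") <- setNames(pool, rownames(counts))
  out
}

## Ground-truth hypervariable gene flags; one draw per spec, shared by
## every cell type so labels are identical across types at a fixed seed.
.hypervariable_flags <- function(spec) {
  k <- round(spec$planted_hypervariable$fraction * spec$n_genes)
  idx <- .with_seed(.stream_seed(spec$seed, "hypervariable_genes"),
                    sample(spec$n_genes, k))
  flags <- logical(spec$n_genes)
  flags[idx] <- TRUE
  flags
}

#' Simulate single-cell count matrices with planted biological structure
#'
#' Each cell type receives its own mean expression profile. Background
#' genes vary across cells by a small log-normal biological dispersion;
#' planted hypervariable genes are two-state mixtures, multiplying the
#' off-state mean by `fold_change` with probability `on_probability` in
#' each cell. The planted gene set is drawn once per spec, so ground
#' truth is identical across cell types. Measurement noise then follows
#' the same technical chain as the dilution controls.
#'
#' @param spec A [synthetic_spec()].
#' @param cell_types Which cell types to simulate (default: all in
#'   `spec$cell_type_sizes`).
#' @param preserve_mean If `TRUE` (default), the two-state multiplier of
#'   planted genes is rescaled to unit mean, so planting inflates
#'   variance without shifting the gene's expression level; ground-truth
#'   labels then stay balanced across expression levels instead of
#'   concentrating above detection thresholds.
#'
#' @return A list with `matrix` (a [count_matrix()] whose groups are the
#'   cell types) and `truth`, a `data.frame` of per-gene ground truth:
#'   `hypervariable` flag and `true_dispersion` (the squared coefficient
#'   of variation of the biological multiplier).
#' @export
simulate_cell_type_counts <- function(spec,
                                      cell_types = names(spec$cell_type_sizes),
                                      preserve_mean = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$cell_type_sizes) == 0) stop("cell_type_sizes is empty")
  ph <- spec$planted_hypervariable
  hyper <- .hypervariable_flags(spec)
  bg <- spec$background_dispersion_sd
  n <- spec$n_genes

  all_counts <- NULL
  meta <- NULL
  for (ct in cell_types) {
    ncell <- spec$cell_type_sizes[[ct]]
    profile <- .with_seed(.stream_seed(spec$seed, paste0("type_profile_", ct)),
                          rlnorm(n, spec$mean_expression_model[["location"]],
                                 spec$mean_expression_model[["scale"]]))
    profile <- profile / sum(profile)
    counts <- .with_seed(.stream_seed(spec$seed, paste0("cells_", ct)), {
      mult <- matrix(rlnorm(n * ncell, meanlog = -bg^2 / 2, sdlog = bg),
                     nrow = n)
      if (any(hyper)) {
        on <- matrix(runif(sum(hyper) * ncell) < ph$on_probability,
                     nrow = sum(hyper))
        state <- ifelse(on, ph$fold_change, 1)
        if (preserve_mean)
          state <- state / (1 + ph$on_probability * (ph$fold_change - 1))
        mult[hyper, ] <- mult[hyper, , drop = FALSE] * state
      }
      expr <- profile * mult
      expr <- sweep(expr, 2, colSums(expr), "/")
      molecules <- round(expr * spec$molecules_per_cell)
      .technical_counts(molecules, spec)
    })
    ids <- sprintf("%s_c%03d", ct, seq_len(ncell))
    dimnames(counts) <- list(.gene_ids(n), ids)
    all_counts <- cbind(all_counts, counts)
    meta <- rbind(meta, data.frame(sample_id = ids, group = ct))
  }

  # CV^2 of the biological multiplier: log-normal background times the
  # two-state mixture for planted genes.
  cv2_bg <- exp(bg^2) - 1
  m_mix <- 1 + ph$on_probability * (ph$fold_change - 1)
  v_mix <- ph$on_probability * (1 - ph$on_probability) * (ph$fold_change - 1)^2
  cv2 <- ifelse(hyper, (1 + cv2_bg) * (1 + v_mix / m_mix^2) - 1, cv2_bg)

  list(matrix = count_matrix(all_counts, meta),
       truth = data.frame(gene_id = .gene_ids(n),
                          hypervariable = hyper,
                          true_dispersion = cv2))
}

#' Simulate homologous single-cell data for two species
#'
#' Both species share one mean expression profile (expression levels are
#' conserved), while per-gene excess biological dispersion is drawn from
#' a bivariate normal on the log10 scale with correlation
#' `planted_cross_species_rho`, independent of expression. Each gene's
#' biological squared coefficient of variation is
#' `10^(dispersion_log10_location + e)` times the model's own technical
#' squared coefficient of variation at that gene's expression level, so
#' the expected variance ratio (the F-statistic) is flat in expression
#' and the planted dispersion is exactly the quantity the partial
#' correlation targets after expression adjustment. Counts then pass
#' through the shared technical chain.
#'
#' @param spec A [synthetic_spec()].
#' @param cells_per_species Optional named vector overriding
#'   `spec$species_cell_counts`.
#' @param confound_only If `TRUE`, biological dispersion is identically
#'   zero in both species, so the variance of every gene is a
#'   deterministic function of its (shared) expression level through the
#'   technical noise model alone; any apparent cross-species similarity
#'   of variability then arises from shared expression, not biology.
#'
#' @return List with `species_a`, `species_b` (each a [count_matrix()]),
#'   `homologues` (one-to-one two-column map), `truth` holding the
#'   planted per-gene dispersions, and `profile`, the shared mean
#'   expression profile (pass it to [simulate_dilution_counts()] so the
#'   control curve covers the same expression range as the cells).
#' @export
simulate_two_species <- function(spec,
                                 cells_per_species = spec$species_cell_counts,
                                 confound_only = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rho <- spec$planted_cross_species_rho
  if (is.null(rho) || abs(rho) >= 1)
    stop("planted_cross_species_rho must be set and strictly inside (-1, 1)")
  n <- spec$n_genes
  tau <- spec$dispersion_log10_sd

  profile <- .with_seed(.stream_seed(spec$seed, "xspecies_profile"),
                        rlnorm(n, spec$mean_expression_model[["location"]],
                               spec$mean_expression_model[["scale"]]))
  profile <- profile / sum(profile)

  e <- .with_seed(.stream_seed(spec$seed, "xspecies_dispersion"), {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    cbind(a = tau * z1, b = tau * (rho * z1 + sqrt(1 - rho^2) * z2))
  })
  if (confound_only) e[] <- 0

  mats <- list()
  cv2_tech <- .technical_cv2(spec, profile)
  for (s in c("a", "b")) {
    ncell <- cells_per_species[[paste0("species_", s)]]
    cv2 <- if (confound_only) rep(0, n) else
      cv2_tech * 10^(spec$dispersion_log10_location + e[, s])
    counts <- .with_seed(.stream_seed(spec$seed, paste0("xspecies_cells_", s)), {
      # gamma expression noise (mean 1, variance cv2): the steady-state
      # distribution of bursty transcription, with tails light enough
      # that sample variances across cells estimate the planted
      # dispersion stably
      shape <- ifelse(cv2 > 0, 1 / cv2, Inf)
      mult <- matrix(1, n, ncell)
      pos <- cv2 > 0
      if (any(pos))
        mult[pos, ] <- matrix(rgamma(sum(pos) * ncell,
                                     shape = rep(shape[pos], ncell),
                                     rate = rep(shape[pos], ncell)),
                              nrow = sum(pos))
      expr <- profile * mult
      expr <- sweep(expr, 2, colSums(expr), "/")
      .technical_counts(round(expr * spec$molecules_per_cell), spec)
    })
    prefix <- toupper(s)
    ids <- sprintf("sp%s_c%03d", prefix, seq_len(ncell))
    dimnames(counts) <- list(paste0(prefix, "_", .gene_ids(n)), ids)
    mats[[s]] <- count_matrix(counts,
                              data.frame(sample_id = ids,
                                         group = paste0("species_", s)))
  }

  list(species_a = mats$a,
       species_b = mats$b,
       homologues = data.frame(species_a = paste0("A_", .gene_ids(n)),
                               species_b = paste0("B_", .gene_ids(n))),
       truth = data.frame(gene_a = paste0("A_", .gene_ids(n)),
                          gene_b = paste0("B_", .gene_ids(n)),
                          dispersion_a = e[, "a"],
                          dispersion_b = e[, "b"]),
       profile = setNames(profile, .gene_ids(n)))
}

#' Simulate per-gene annotation tables
#'
#' Produces the three annotation fixtures the downstream association
#' stages consume: RNA half-lives (log-normal, optionally associated with
#' the planted hypervariable ground truth at a configurable odds ratio of
#' being fast-decaying), functional category memberships, and binary
#' phenotype labels.
#'
#' @param spec A [synthetic_spec()].
#' @param odds_ratio Odds ratio of a hypervariable gene being drawn from
#'   the fast-decay half-life component relative to a background gene
#'   (baseline fast probability 1/3). `1` plants no association.
#'
#' @return List of data frames: `half_life` (`gene_id`,
#'   `half_life_hours`), `categories` (`gene_id`, `category`),
#'   `phenotypes` (`gene_id`, `phenotype`), and `truth` (the
#'   hypervariable flags and latent fast-decay component used for
#'   planting, emitted so tests never re-derive ground truth from the
#'   realized tables).
#' @export
simulate_annotations <- function(spec, odds_ratio = 1) {
  stopifnot(inherits(spec, "synthetic_spec"), odds_ratio > 0)
  n <- spec$n_genes
  hyper <- .hypervariable_flags(spec)
  .with_seed(.stream_seed(spec$seed, "annotations"), {
    p0 <- 1 / 3
    odds1 <- odds_ratio * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    fast <- runif(n) < ifelse(hyper, p1, p0)
    hl <- exp(rnorm(n, mean = ifelse(fast, log(2), log(10)), sd = 0.4))
    cats <- sample(c("metabolism", "ribosome", "transcription_factor",
                     "ion_channel"),
                   n, replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15))
    phen <- runif(n) < 0.3
    list(half_life = data.frame(gene_id = .gene_ids(n),
                                half_life_hours = hl),
         categories = data.frame(gene_id = .gene_ids(n), category = cats),
         phenotypes = data.frame(gene_id = .gene_ids(n), phenotype = phen),
         truth = data.frame(gene_id = .gene_ids(n), hypervariable = hyper,
                            fast_component = fast))
  })
}
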