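## Negative-binomial ribo-seq simulator. Generates endogenous gene
## counts with donor/library-batch/treatment structure (including a
## global translational suppression affecting most genes) and spike-in
## counts proportional to the designed pool concentrations, with
## injectable ratio compression, manufacturing-batch offsets and shared
## latent nuisance factors. All effect sizes are in log2 units.

#' Simulation configuration
#'
#' Defaults describe a stress-response ribo-seq study: ~2 Mio mapped
#' footprints per library, spike-ins at 2.3% of the library, 90% of
#' genes affected by treatment with mean |log2 FC| 1.6 of which 96% are
#' down-regulated, and modest donor/library-batch technical effects.
#'
#' @param n_genes number of endogenous genes.
#' @param library_size expected total endogenous counts per sample
#'   (scalar or one value per sample).
#' @param baseline_sdlog sd (natural log) of the lognormal gene
#'   abundance distribution.
#' @param dispersion_meanlog,dispersion_sdlog lognormal parameters of
#'   the per-gene NB dispersion phi (variance = mu + phi mu^2).
#' @param fraction_affected fraction of genes with a nonzero treatment
#'   effect.
#' @param effect_size_log2 mean |log2 fold change| of affected genes.
#' @param effect_sd_log2 sd of the |log2 fold change| draw.
#' @param down_fraction probability an affected gene is down-regulated.
#' @param donor_sd_log2 sd of gene-by-donor log2 effects.
#' @param batch_sd_log2 sd of feature-by-library-batch log2 effects
#'   (applies to genes and spike-ins: library preparation acts on both).
#' @param spike_capture expected spike-in share of the library.
#' @param spike_dispersion NB dispersion of spike rows (scalar or one
#'   value per oligomer).
#' @param compression intercept `a` and slope `b` of the observed
#'   log-mean vs log expected concentration: mean proportional to
#'   `exp(a + b * ln c)`; `b < 1` yields ratio compression.
#' @param manufacturing_offsets_log2 named per-manufacturing-batch log2
#'   shifts applied to spike rows (constant across samples).
#' @param n_unwanted_factors number of latent nuisance factors loading
#'   on all features (genes and spike-ins).
#' @param unwanted_factor_sd_log2 sd of per-feature factor loadings.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       library_size = 2e6,
                       baseline_sdlog = 1.8,
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       fraction_affected = 0.9,
                       effect_size_log2 = 1.6,
                       effect_sd_log2 = 0.5,
                       down_fraction = 0.96,
                       donor_sd_log2 = 0.1,
                       batch_sd_log2 = 0.1,
                       spike_capture = 0.023,
                       spike_dispersion = 0.05,
                       compression = c(a = 0, b = 1),
                       manufacturing_offsets_log2 = c(B1 = 0, B2 = 0.5),
                       n_unwanted_factors = 0L,
                       unwanted_factor_sd_log2 = 0,
                       seed = 1L) {
  stopifnot(fraction_affected >= 0, fraction_affected <= 1,
            down_fraction >= 0, down_fraction <= 1,
            donor_sd_log2 >= 0, batch_sd_log2 >= 0,
            effect_sd_log2 >= 0, unwanted_factor_sd_log2 >= 0,
            compression[["b"]] > 0, spike_capture >= 0)
  structure(as.list(environment()), class = "sim_config")
}

rnbinom_phi <- function(n, mu, phi) {
  ## NB parameterized by mean and dispersion phi; Poisson limit as
  ## phi -> 0.
  out <- numeric(n)
  tiny <- phi < 1e-12
  if (any(tiny)) out[tiny] <- stats::rpois(sum(tiny), mu[tiny])
  if (any(!tiny)) {
    out[!tiny] <- stats::rnbinom(sum(!tiny), mu = mu[!tiny],
                                 size = 1 / phi[!tiny])
  }
  out
}

## Draw the latent truth shared by the endogenous and spike generators.
## A single seed fixes everything; sub-draws happen in a fixed order.
sim_draw_truth <- function(config, design, sheet) {
  set.seed(as.integer(config$seed))
  n <- config$n_genes
  donors <- unique(sheet$donor)
  batches <- unique(sheet$library_batch)
  oligos <- design_oligomers(design)
  baseline <- stats::rnorm(n, 0, config$baseline_sdlog)
  phi <- stats::rlnorm(n, config$dispersion_meanlog, config$dispersion_sdlog)
  affected <- stats::runif(n) < config$fraction_affected
  sign <- ifelse(stats::runif(n) < config$down_fraction, -1, 1)
  magnitude <- abs(stats::rnorm(n, config$effect_size_log2,
                                config$effect_sd_log2))
  effect <- ifelse(affected, sign * magnitude, 0)
  donor_eff <- matrix(stats::rnorm(n * length(donors), 0, config$donor_sd_log2),
                      n, length(donors), dimnames = list(NULL, donors))
  batch_eff <- matrix(stats::rnorm(n * length(batches), 0, config$batch_sd_log2),
                      n, length(batches), dimnames = list(NULL, batches))
  spike_batch_eff <- matrix(
    stats::rnorm(length(oligos) * length(batches), 0, config$batch_sd_log2),
    length(oligos), length(batches), dimnames = list(oligos, batches))
  q <- config$n_unwanted_factors
  scores <- loadings_g <- loadings_s <- NULL
  if (q > 0L) {
    scores <- matrix(stats::rnorm(nrow(sheet) * q), nrow(sheet), q,
                     dimnames = list(sheet$sample_id, NULL))
    loadings_g <- matrix(stats::rnorm(n * q, 0, config$unwanted_factor_sd_log2),
                         n, q)
    loadings_s <- matrix(stats::rnorm(length(oligos) * q, 0,
                                      config$unwanted_factor_sd_log2),
                         length(oligos), q)
  }
  list(baseline = baseline, phi = phi, effect_log2 = effect,
       donor_eff = donor_eff, batch_eff = batch_eff,
       spike_batch_eff = spike_batch_eff, factor_scores = scores,
       gene_loadings = loadings_g, spike_loadings = loadings_s,
       spike_treatment_log2 = rep(0, length(oligos)))
}

sim_library_sizes <- function(config, sheet) {
  libs <- config$library_size
  if (length(libs) == 1L) libs <- rep(libs, nrow(sheet))
  stats::setNames(libs, sheet$sample_id)
}

sim_gene_mu <- function(config, sheet, truth) {
  libs <- sim_library_sizes(config, sheet)
  rel <- exp(truth$baseline)
  rel <- rel / sum(rel)
  ln2 <- log(2)
  mu <- matrix(0, config$n_genes, nrow(sheet),
               dimnames = list(sprintf("gene%04d", seq_len(config$n_genes)),
                               sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    eta <- truth$donor_eff[, sheet$donor[j]] +
      truth$batch_eff[, sheet$library_batch[j]] +
      truth$effect_log2 * (sheet$treatment[j] == "treated")
    if (!is.null(truth$factor_scores)) {
      eta <- eta + as.vector(truth$gene_loadings %*% truth$factor_scores[j, ])
    }
    mu[, j] <- libs[j] * rel * exp(ln2 * eta)
  }
  mu
}

sim_spike_mu <- function(config, design, sheet, truth, panel = NULL) {
  libs <- sim_library_sizes(config, sheet)
  oligos <- design_oligomers(design)
  conc <- expected_concentration_matrix(design)
  a <- config$compression[["a"]]
  b <- config$compression[["b"]]
  ## manufacturing batch per oligomer: from the panel if given, else
  ## the first/second half of the panel ordering.
  if (!is.null(panel)) {
    mb <- stats::setNames(panel$manufacturing_batch, panel$oligomer_id)[oligos]
  } else {
    labs <- names(config$manufacturing_offsets_log2)
    mb <- rep(labs, each = ceiling(length(oligos) / length(labs)))
    mb <- stats::setNames(mb[seq_along(oligos)], oligos)
  }
  moff <- config$manufacturing_offsets_log2[mb]
  ln2 <- log(2)
  mu <- matrix(0, length(oligos), nrow(sheet),
               dimnames = list(paste0("spike:", oligos), sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    w <- exp(a + b * log(conc[, sheet$pool[j]]))
    w <- w / sum(w)
    eta <- moff + truth$spike_batch_eff[, sheet$library_batch[j]]
    if (!is.null(truth$factor_scores)) {
      eta <- eta + as.vector(truth$spike_loadings %*% truth$factor_scores[j, ])
    }
    mu[, j] <- libs[j] * config$spike_capture * w * exp(ln2 * eta)
  }
  mu
}

#' Simulate a full ribo-seq dataset (endogenous genes + spike-ins)
#'
#' Endogenous counts are NB with mean `library_size * relative
#' abundance * 2^(donor + batch + treatment effect)`; spike counts are
#' NB with mean proportional to `exp(a + b ln c)` of the expected pool
#' concentration `c` (renormalized so spikes take up `spike_capture` of
#' the library), times manufacturing/library-batch terms. Treatment has
#' no effect on spike means by construction: pools are loaded at a
#' constant RNA mass.
#'
#' @param config a [sim_config()].
#' @param design a `pooling_design`.
#' @param sheet a sample sheet.
#' @param panel optional `oligomer_panel` providing manufacturing-batch
#'   labels.
#' @return a `ribosim` list: `counts` (integer matrix, spike rows named
#'   `spike:<id>`), `spike_flags`, `truth` (per-gene true log2 treatment
#'   effect), `factor_truth` (realized donor/batch/factor values).
#' @export
simulate_dataset <- function(config, design = default_pooling_design(),
                             sheet = default_sample_sheet(design = design),
                             panel = NULL) {
  validate_sample_sheet(sheet, design)
  truth <- sim_draw_truth(config, design, sheet)
  mu_g <- sim_gene_mu(config, sheet, truth)
  mu_s <- sim_spike_mu(config, design, sheet, truth, panel)
  phi_g <- matrix(truth$phi, nrow(mu_g), ncol(mu_g))
  phi_s <- matrix(rep_len(config$spike_dispersion, nrow(mu_s)),
                  nrow(mu_s), ncol(mu_s))
  counts_g <- matrix(rnbinom_phi(length(mu_g), as.vector(mu_g),
                                 as.vector(phi_g)),
                     nrow(mu_g), ncol(mu_g), dimnames = dimnames(mu_g))
  counts_s <- matrix(rnbinom_phi(length(mu_s), as.vector(mu_s),
                                 as.vector(phi_s)),
                     nrow(mu_s), ncol(mu_s), dimnames = dimnames(mu_s))
  counts <- rbind(counts_g, counts_s)
  ## counts stay double only in the (pathological) regime beyond the
  ## 32-bit integer range
  if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    spike_flags = c(rep(FALSE, nrow(counts_g)), rep(TRUE, nrow(counts_s))),
    truth = stats::setNames(truth$effect_log2, rownames(counts_g)),
    factor_truth = truth,
    design = design, sheet = sheet
  ), class = "ribosim")
}

#' Simulate endogenous gene counts only
#'
#' @inheritParams simulate_dataset
#' @return a `ribosim` restricted to endogenous rows.
#' @export
simulate_endogenous_counts <- function(config,
                                       design = default_pooling_design(),
                                       sheet = default_sample_sheet(design = design)) {
  sim <- simulate_dataset(config, design, sheet)
  sim$counts <- sim$counts[!sim$spike_flags, , drop = FALSE]
  sim$spike_flags <- rep(FALSE, nrow(sim$counts))
  sim
}

#' Simulate spike-in rows only
#'
#' @inheritParams simulate_dataset
#' @return a `ribosim` restricted to spike rows.
#' @export
simulate_spikein_counts <- function(config,
                                    design = default_pooling_design(),
                                    sheet = default_sample_sheet(design = design),
                                    panel = NULL) {
  sim <- simulate_dataset(config, design, sheet, panel)
  sim$counts <- sim$counts[sim$spike_flags, , drop = FALSE]
  sim$truth <- NULL
  sim$spike_flags <- rep(TRUE, nrow(sim$counts))
  sim
}

#' Thin columns of a count matrix to a requested relative depth
#'
#' Binomial thinning: each read survives independently with the
#' column's probability, emulating deliberate sequencing-depth
#' differences between libraries.
#'
#' @param counts integer matrix.
#' @param factors per-sample retention probabilities in `[0, 1]` (scalar
#'   recycled).
#' @param seed integer seed.
#' @return integer matrix of the same shape.
#' @export
apply_global_library_scaling <- function(counts, factors, seed = 1L) {
  factors <- rep_len(factors, ncol(counts))
  if (any(factors < 0) || any(factors > 1)) {
    stop("thinning factors must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    f <- factors[j]
    if (f == 1) next
    if (f == 0) { out[, j] <- 0L; next }
    out[, j] <- stats::rbinom(nrow(counts), counts[, j], f)
  }
  storage.mode(out) <- "integer"
  out
}
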