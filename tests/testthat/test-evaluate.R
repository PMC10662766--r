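design <- default_pooling_design()
sheet <- default_sample_sheet(design = design)

test_that("obs_vs_exp_regression reports ideal and shifted fits", {
  x <- rep(c(-5.13, -1.87, 1.58, 3.54), each = 12)
  reg <- obs_vs_exp_regression(x, x)
  expect_equal(reg$slope, 1, tolerance = 1e-12)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  set.seed(51)
  y <- 0.87 * x + rnorm(length(x), 0, 0.1)
  reg2 <- obs_vs_exp_regression(y, x)
  expect_lt(abs(reg2$slope - 0.87), 2 * reg2$slope_se)
  y3 <- x + 1.6 + rnorm(length(x), 0, 0.1)
  reg3 <- obs_vs_exp_regression(y3, x)
  expect_lt(abs(reg3$intercept - 1.6), 2 * reg3$intercept_se)
  expect_equal(reg3$slope, 1, tolerance = 0.05)
  # brute-force recomputation from closed forms
  expect_equal(reg2$slope, cov(x, y) / var(x), tolerance = 1e-12)
  expect_equal(reg2$intercept, mean(y) - reg2$slope * mean(x),
               tolerance = 1e-12)
  expect_error(obs_vs_exp_regression(y, rep(1, length(y))), "zero variance")
  expect_error(obs_vs_exp_regression(1:2, 1:2), "at least 3")
})

test_that("compression_by_stratum exposes an additive low-end bias", {
  # exact construction: a fixed offset added before pooling compresses
  # ratios most where the denominator concentration is lowest
  conc <- expected_concentration_matrix(design)
  rows <- expand.grid(o = rownames(conc), pa = colnames(conc),
                      pb = colnames(conc), stringsAsFactors = FALSE)
  rows <- rows[rows$pa != rows$pb, ]
  delta <- 2
  expected <- log2(conc[cbind(rows$o, rows$pa)] /
                     conc[cbind(rows$o, rows$pb)])
  observed <- log2((conc[cbind(rows$o, rows$pa)] + delta) /
                     (conc[cbind(rows$o, rows$pb)] + delta))
  denom <- conc[cbind(rows$o, rows$pb)]
  strata <- compression_by_stratum(observed, expected, denom)
  expect_equal(nrow(strata), 3L)
  expect_true(max(strata$n) - min(strata$n) <= 1)
  expect_lt(strata$slope[1], strata$slope[3])
  expect_lt(strata$slope[1], 0.9)
  # no bias: all strata recover slope 1
  flat <- compression_by_stratum(expected, expected, denom)
  expect_equal(flat$slope, rep(1, 3), tolerance = 1e-12)
})

test_that("fpr_at_cutoff counts TN rejections", {
  tests <- data.frame(truth = rep(c("TN", "TP"), each = 4),
                      p = c(0.5, 0.05, 0.2, 0.01, 0.9, 0.9, 0.9, 0.9))
  out <- fpr_at_cutoff(tests, alpha = 0.1)
  expect_equal(out$n_tests, 4L)
  expect_equal(out$n_false, 2L)
  expect_equal(out$fpr, 0.5)
  # brute-force recomputation from the raw table
  expect_equal(out$fpr, mean(tests$p[tests$truth == "TN"] < 0.1))
  tests$p <- 1
  expect_equal(fpr_at_cutoff(tests)$fpr, 0)
  tests$p <- 0
  expect_equal(fpr_at_cutoff(tests)$fpr, 1)
  expect_error(fpr_at_cutoff(tests[tests$truth == "TP", ]), "no true-negative")
})

test_that("monotonicity_check flags a swapped pool assignment", {
  cfg <- sim_config(seed = 13, n_genes = 2, library_size = 2e9,
                    baseline_sdlog = 0, fraction_affected = 0,
                    spike_dispersion = 1e-4, batch_sd_log2 = 0)
  sim <- simulate_dataset(cfg, design, sheet)
  spikes <- sim$counts[sim$spike_flags, ]
  mono <- monotonicity_check(spikes, design, sheet)
  expect_true(all(mono$monotonic))
  expect_true(all(abs(mono$rho) <= 1))
  # swap two pools of one oligomer's counts: ranking must break
  swapped <- spikes
  p1 <- sheet$pool == "P1"; p2 <- sheet$pool == "P2"
  tmp <- swapped[1, p1]
  swapped[1, p1] <- swapped[1, p2]
  swapped[1, p2] <- tmp
  mono2 <- monotonicity_check(swapped, design, sheet)
  expect_false(mono2$monotonic[1])
  expect_true(all(mono2$monotonic[-1]))
})

test_that("the correlation outlier screen is calibrated on homogeneous panels", {
  clean <- 0L
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(seed = 3000 + s, fraction_affected = 0),
                            design, sheet)
    out <- per_oligomer_correlation_outliers(sim$counts[sim$spike_flags, ],
                                             design, sheet)
    expect_true(all(out$oligomer_id %in% rownames(
      expected_concentration_matrix(design))))
    clean <- clean + (sum(out$flagged) == 0L)
  }
  # measured operating point: no flags in ~90% of homogeneous panels
  expect_gte(clean, 16L)
})

test_that("an oligomer with inflated dispersion is the one flagged", {
  hits <- 0L
  others <- integer(16)
  for (s in 1:20) {
    disp <- rep(0.05, 16); disp[4] <- 0.25  # 5x on A4
    sim <- simulate_dataset(sim_config(seed = 4000 + s,
                                       spike_dispersion = disp,
                                       fraction_affected = 0),
                            design, sheet)
    out <- per_oligomer_correlation_outliers(sim$counts[sim$spike_flags, ],
                                             design, sheet)
    hits <- hits + out$flagged[4]
    others <- others + out$flagged
  }
  # the inflated oligomer dominates the flags (measured: 13/20) and is
  # flagged more often than any well-behaved one
  expect_gte(hits, 10L)
  expect_true(all(others[-4] < hits))
  expect_error(per_oligomer_correlation_outliers(
    matrix(1, 3, 12, dimnames = list(paste0("spike:", c("A1", "A2", "A3")),
                                     sheet$sample_id)),
    design, sheet), "at least 5")
})

test_that("overlap_summary counts partitions of the union", {
  expect_equal(overlap_summary(c("1", "2", "3"), c("2", "3", "4")),
               list(a_only = 1L, shared = 2L, b_only = 1L,
                    replication_fraction = 2 / 3))
  same <- overlap_summary(letters[1:5], letters[1:5])
  expect_equal(same$a_only + same$b_only, 0L)
  expect_equal(same$replication_fraction, 1)
  disj <- overlap_summary(letters[1:3], letters[4:6])
  expect_equal(disj$shared, 0L)
  set.seed(61)
  for (i in 1:5) {
    a <- sample(letters, 10); b <- sample(letters, 8)
    s <- overlap_summary(a, b)
    expect_equal(s$a_only + s$shared + s$b_only, length(union(a, b)))
  }
})

test_that("recovery_at_relaxed_fdr measures recovery and sign agreement", {
  ref <- data.frame(q = c(0.01, 0.03, 0.5, 0.15, 0.9),
                    estimate = c(1, -2, 0.5, -1, 2),
                    row.names = paste0("g", 1:5))
  # query inside the strict discoveries: full recovery
  q1 <- data.frame(id = c("g1", "g2"), estimate = c(2, -1))
  r1 <- recovery_at_relaxed_fdr(ref, q1, relaxed_fdr = 0.05)
  expect_equal(r1$recovered_fraction, 1)
  expect_equal(r1$sign_agreement_fraction, 1)
  # empty query is reported as undefined
  r0 <- recovery_at_relaxed_fdr(ref, data.frame(id = character(0),
                                                estimate = numeric(0)))
  expect_true(is.na(r0$recovered_fraction))
  # systematic sign flips yield agreement below one half
  q2 <- data.frame(id = c("g1", "g2", "g4"), estimate = c(-1, 2, 1))
  r2 <- recovery_at_relaxed_fdr(ref, q2, relaxed_fdr = 0.2)
  expect_equal(r2$n_recovered, 3L)
  expect_lt(r2$sign_agreement_fraction, 0.5)
  expect_error(recovery_at_relaxed_fdr(ref, data.frame(id = "nope",
                                                       estimate = 1)),
               "absent")
})

test_that("subsample_robustness is reproducible and degenerates correctly", {
  sim <- simulate_dataset(sim_config(seed = 21), design, sheet)
  filt <- filter_min_count(sim$counts, sim$spike_flags)
  expc <- expected_log_conc_matrix(design, sheet)
  ctrl_ids <- rownames(filt$counts)[filt$spike_flags]
  expc <- expc[ctrl_ids, , drop = FALSE]
  # n_iter = 1, fraction = 1: identical to full-control normalization
  r1 <- subsample_robustness(filt$counts, filt$spike_flags, expc,
                             n_iter = 1, fraction = 1, k = 3, seed = 2)
  full <- factor_normalize(filt$counts, filt$spike_flags, 3)$normalized_counts
  expect_true(all(r1$cv$subsampling_cv == 0, na.rm = TRUE))
  expect_equal(r1$cv$biological_cv,
               apply(full[!filt$spike_flags, ], 1,
                     function(v) sd(v) / mean(v)),
               ignore_attr = TRUE)
  # fixed seed reproduces bit-identically
  r2 <- subsample_robustness(filt$counts, filt$spike_flags, expc,
                             n_iter = 4, fraction = 0.5, k = 3, seed = 9)
  r3 <- subsample_robustness(filt$counts, filt$spike_flags, expc,
                             n_iter = 4, fraction = 0.5, k = 3, seed = 9)
  expect_identical(r2, r3)
  expect_error(subsample_robustness(filt$counts, filt$spike_flags, expc,
                                    fraction = 0.1, k = 3), "cannot support")
})

test_that("subsampling CV sits far below biological CV under a global shift", {
  sim <- simulate_dataset(sim_config(seed = 21), design, sheet)
  filt <- filter_min_count(sim$counts, sim$spike_flags)
  expc <- expected_log_conc_matrix(design, sheet)
  expc <- expc[rownames(filt$counts)[filt$spike_flags], , drop = FALSE]
  rob <- subsample_robustness(filt$counts, filt$spike_flags, expc,
                              n_iter = 10, fraction = 0.5, k = 3, seed = 5)
  expect_lt(rob$mean_subsampling_cv, rob$mean_biological_cv)
  # measured margin in this stated world is ~3.4x (the study's data
  # showed 4.4x); assert a conservative 2x
  expect_gt(rob$mean_biological_cv / rob$mean_subsampling_cv, 2)
  expect_equal(nrow(rob$iterations), 10L)
  expect_true(all(rob$iterations$r_squared_in > 0.5))
})
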