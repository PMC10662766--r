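test_that("filter_min_count drops zero-containing genes but keeps spikes", {
  counts <- rbind(g1 = c(3, 5, 2, 8), g2 = c(0, 4, 4, 4), g3 = c(1, 1, 1, 1),
                  g4 = c(9, 9, 9, 9), g5 = c(2, 2, 2, 2),
                  `spike:A1` = c(0, 0, 7, 1))
  flags <- c(rep(FALSE, 5), TRUE)
  out <- filter_min_count(counts, flags)
  expect_equal(rownames(out$counts), c("g1", "g3", "g4", "g5", "spike:A1"))
  expect_equal(sum(out$spike_flags), 1L)
  # idempotent
  again <- filter_min_count(out$counts, out$spike_flags)
  expect_identical(again$counts, out$counts)
  # all-positive input is untouched
  pos <- counts[c(1, 4), ]
  expect_identical(filter_min_count(pos, c(FALSE, FALSE))$counts, pos)
})

test_that("log2_transform applies the pseudo-count exactly", {
  expect_equal(log2_transform(matrix(0))[1, 1], -2)
  expect_equal(log2_transform(matrix(7))[1, 1], log2(7.25))
  v <- log2_transform(matrix(0:10, nrow = 1))
  expect_true(all(diff(v[1, ]) > 0))
  expect_error(log2_transform(matrix(-1)), "nonnegative")
  expect_error(log2_transform(matrix(1), pseudocount = 0), "> 0")
})

test_that("tmm_factors handles pure-depth and identical columns", {
  m <- matrix(rpois(400, 50), 100, 4)
  expect_equal(unname(tmm_factors(cbind(m[, 1], m[, 1]))), c(1, 1))
  doubled <- cbind(m[, 1], m[, 1] * 2L)
  expect_equal(unname(tmm_factors(doubled)), c(1, 1))
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
  expect_error(tmm_factors(m, logratio_trim = 0.5), "trims")
})

test_that("tmm_factors matches the brute-force trimmed-mean oracle", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnbinom(30, mu = rlnorm(10, 4, 1.5), size = 2), 10, 3)
    if (any(colSums(m) == 0)) next
    f <- tmm_factors(m)
    lib <- colSums(m)
    f75 <- vapply(1:3, function(j) quantile(m[, j], 0.75, names = FALSE) /
                    lib[j], numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
    raw <- vapply(1:3, function(j) {
      if (j == ref) 1 else brute_tmm_pair(m[, j], m[, ref], lib[j], lib[ref])
    }, numeric(1))
    expect_equal(unname(f), raw / exp(mean(log(raw))), tolerance = 1e-12)
  }
})

test_that("tmm_factors reproduces the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(32)
  for (i in 1:10) {
    m <- matrix(rnbinom(600, mu = rlnorm(100, 4, 1.8), size = 1.5), 100, 6)
    expect_equal(unname(tmm_factors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-12)
  }
})

test_that("scale_normalize produces depth-invariant CPM", {
  m <- matrix(c(10, 20, 70, 5, 10, 35), 3, 2)
  cpm <- scale_normalize(m)
  expect_equal(cpm[, 1], c(10, 20, 70) / 100 * 1e6)
  expect_equal(cpm[, 1], cpm[, 2])  # column 2 is column 1 halved
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(scale_normalize(m2)[, 2], cpm[, 2])
  expect_error(scale_normalize(m, factors = c(1, 0)), "positive")
})

test_that("factor_normalize with k = 0 is the identity", {
  m <- matrix(rpois(60, 20), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  out <- factor_normalize(m, control_rows = 1:3, k = 0)
  expect_identical(out$normalized_counts, m)
  expect_equal(ncol(out$W), 0L)
})

test_that("factor_normalize removes a planted rank-one batch effect", {
  set.seed(41)
  n <- 60; s <- 8
  base <- matrix(rpois(n * s, exp(rnorm(n, 5, 1))), n, s)
  batch <- rep(c(0, 1), each = s / 2)
  shifted <- round(base * 2^outer(rep(1, n), batch))  # +1 log2 in batch 2
  storage.mode(shifted) <- "integer"
  rownames(shifted) <- paste0("f", 1:n)
  colnames(shifted) <- paste0("s", 1:s)
  ctrl <- 1:10
  before <- rowMeans(log(shifted[ctrl, batch == 1] + 1)) -
    rowMeans(log(shifted[ctrl, batch == 0] + 1))
  out <- factor_normalize(shifted, ctrl, k = 1)
  norm <- out$normalized_counts
  after <- rowMeans(log(norm[ctrl, batch == 1] + 1)) -
    rowMeans(log(norm[ctrl, batch == 0] + 1))
  expect_gt(abs(mean(before)), log(2) * 0.9)
  expect_lt(abs(mean(after)), 0.05)
  # W has exactly k orthogonal columns
  out2 <- factor_normalize(shifted, ctrl, k = 2)
  expect_equal(ncol(out2$W), 2L)
  expect_equal(crossprod(out2$W), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("factor_normalize validates k and controls", {
  m <- matrix(rpois(60, 20), 10, 6)
  expect_error(factor_normalize(m, 1:3, k = 4), "k must be <=")
  expect_error(factor_normalize(m, integer(0), k = 1), "nonempty")
  z <- m; z[1:3, ] <- 0L
  expect_error(factor_normalize(z, 1:3, k = 1), "all zero|rank")
})

test_that("select_k records a full trace and stops at the plateau", {
  design <- default_pooling_design()
  sheet <- default_sample_sheet(design = design)
  expc <- expected_log_conc_matrix(design, sheet)
  # controls already near-perfect at k = 0: noiseless high-depth world
  cfg <- sim_config(seed = 12, n_genes = 2, library_size = 2e9,
                    baseline_sdlog = 0, fraction_affected = 0,
                    spike_dispersion = 1e-6, batch_sd_log2 = 0,
                    manufacturing_offsets_log2 = c(B1 = 0, B2 = 0))
  sim <- simulate_dataset(cfg, design, sheet)
  sel <- select_k(sim$counts, sim$spike_flags, expc, k_max = 4)
  expect_equal(sel$chosen_k, 0L)
  expect_equal(sel$trace$k, 0:4)
  expect_true(all(diff(sel$trace$r_squared) < sel$delta))
  expect_error(select_k(sim$counts, sim$spike_flags, expc, k_max = 12),
               "k_max")
})

test_that("select_k recovers three planted unwanted factors", {
  design <- default_pooling_design()
  sheet <- default_sample_sheet(design = design)
  sheet$pool <- "P1"  # hold the pool fixed so the Latin-square signal
                      # does not masquerade as an unwanted factor
  expc <- expected_log_conc_matrix(design, sheet)
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = 300 + s, n_unwanted_factors = 3,
                      unwanted_factor_sd_log2 = 1.2, donor_sd_log2 = 0,
                      batch_sd_log2 = 0, fraction_affected = 0)
    sim <- simulate_dataset(cfg, design, sheet)
    sel <- select_k(sim$counts, sim$spike_flags, expc, k_max = 6)
    hits <- hits + (sel$chosen_k == 3L)
  }
  expect_gte(hits, 9L)
})

test_that("factor normalization preserves a global shift that TMM removes", {
  design <- default_pooling_design()
  sheet <- default_sample_sheet(design = design)
  sim <- simulate_dataset(sim_config(seed = 11), design, sheet)
  filt <- filter_min_count(sim$counts, sim$spike_flags)
  trt <- sheet$treatment == "treated"
  med_shift <- function(e) {
    stats::median(rowMeans(e[, trt]) - rowMeans(e[, !trt]))
  }
  true_med <- stats::median(sim$truth)
  e_fac <- log2_transform(
    factor_normalize(filt$counts, filt$spike_flags, 3)$normalized_counts
  )[!filt$spike_flags, ]
  e_tmm <- log2_transform(
    scale_normalize(filt$counts, tmm_factors(filt$counts))
  )[!filt$spike_flags, ]
  expect_lt(abs(med_shift(e_fac) - true_med), 0.2)
  expect_lt(abs(med_shift(e_tmm)), 0.2)
})
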