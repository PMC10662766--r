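## Evaluation framework: observed-vs-expected regressions, ratio
## compression stratification, false-positive accounting on the
## spike-in true negatives, per-oligomer monotonicity and outlier
## screens, discovery overlap summaries and control-subsampling
## robustness.

#' Regression of observed on expected log2 fold changes
#'
#' Ordinary least squares of observed on expected, with
#' deviation-from-ideal tests (slope vs 1, intercept vs 0). A slope
#' below 1 measures ratio compression; a nonzero intercept measures a
#' systematic shift of fold changes.
#'
#' @param observed_log2fc,expected_log2fc paired numeric vectors,
#'   length >= 3.
#' @return a `regression_summary` list: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `r_squared`, `n`, `p_slope_vs_1`,
#'   `p_intercept_vs_0`.
#' @export
obs_vs_exp_regression <- function(observed_log2fc, expected_log2fc) {
  stopifnot(length(observed_log2fc) == length(expected_log2fc))
  n <- length(observed_log2fc)
  if (n < 3L) stop("need at least 3 paired points")
  if (stats::var(expected_log2fc) == 0) {
    stop("expected fold changes have zero variance")
  }
  fit <- stats::lm(observed_log2fc ~ expected_log2fc)
  ## a perfect fit (summary.lm warns) is a legitimate input here
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  df <- fit$df.residual
  slope <- sm[2L, 1L]; slope_se <- sm[2L, 2L]
  intercept <- sm[1L, 1L]; intercept_se <- sm[1L, 2L]
  structure(list(
    slope = slope, intercept = intercept,
    slope_se = slope_se, intercept_se = intercept_se,
    r_squared = sfit$r.squared, n = n,
    p_slope_vs_1 = 2 * stats::pt(-abs((slope - 1) / slope_se), df),
    p_intercept_vs_0 = 2 * stats::pt(-abs(intercept / intercept_se), df)
  ), class = "regression_summary")
}

#' Ratio compression by concentration stratum
#'
#' Splits comparisons into equal-count strata by the expected
#' concentration of the denominator quantification and reports the
#' observed-vs-expected slope per stratum; progressive compression shows
#' as a smaller slope in the lowest stratum.
#'
#' @param observed_log2fc,expected_log2fc paired vectors.
#' @param denominator_conc expected concentration of each comparison's
#'   denominator.
#' @param n_strata number of equal-count strata.
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `conc_min`, `conc_max`, `slope`, `slope_se`.
#' @export
compression_by_stratum <- function(observed_log2fc, expected_log2fc,
                                   denominator_conc, n_strata = 3L) {
  stopifnot(length(observed_log2fc) == length(denominator_conc))
  grp <- ceiling(rank(denominator_conc, ties.method = "first") *
                   n_strata / length(denominator_conc))
  out <- lapply(seq_len(n_strata), function(s) {
    idx <- grp == s
    if (sum(idx) < 3L) stop("stratum ", s, " has fewer than 3 points")
    reg <- obs_vs_exp_regression(observed_log2fc[idx], expected_log2fc[idx])
    data.frame(stratum = s, n = sum(idx),
               conc_min = min(denominator_conc[idx]),
               conc_max = max(denominator_conc[idx]),
               slope = reg$slope, slope_se = reg$slope_se)
  })
  do.call(rbind, out)
}

#' False-positive fraction among true-negative comparisons
#'
#' @param spike_tests a `comparison_result`.
#' @param alpha p-value cutoff.
#' @return list: `fpr`, `n_false`, `n_tests`.
#' @export
fpr_at_cutoff <- function(spike_tests, alpha = 0.1) {
  tn <- spike_tests[spike_tests$truth == "TN", , drop = FALSE]
  if (nrow(tn) == 0L) stop("no true-negative rows present")
  n_false <- sum(tn$p < alpha)
  list(fpr = n_false / nrow(tn), n_false = n_false, n_tests = nrow(tn))
}

#' Per-oligomer monotonicity of observed counts vs expected concentration
#'
#' Spearman rank correlation of observed counts against expected
#' concentration, per oligomer. The monotonic flag is declared on
#' pool-level mean counts (absorbing replicate noise): an oligomer is
#' monotonic iff the rank correlation of its pool means with the pool
#' concentrations is exactly 1. The raw per-sample rho is also
#' reported.
#'
#' @param spike_counts matrix of spike rows (rows `spike:<id>` or bare
#'   ids) x samples.
#' @param design a `pooling_design`.
#' @param sheet the sample sheet.
#' @return data.frame: `oligomer_id`, `rho` (per-sample),
#'   `rho_pool_means`, `monotonic`.
#' @export
monotonicity_check <- function(spike_counts, design, sheet) {
  conc <- expected_concentration_matrix(design)
  ids <- sub("^spike:", "", rownames(spike_counts))
  out <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    if (!id %in% rownames(conc)) stop("unknown oligomer: ", id)
    expc <- conc[id, sheet$pool]
    if (length(unique(expc)) < 2L) {
      stop("oligomer ", id, " observed at a single expected concentration")
    }
    obs <- as.numeric(spike_counts[i, ])
    rho <- stats::cor(obs, expc, method = "spearman")
    pool_means <- tapply(obs, sheet$pool, mean)
    pool_conc <- conc[id, names(pool_means)]
    rho_pool <- stats::cor(as.numeric(pool_means), as.numeric(pool_conc),
                           method = "spearman")
    data.frame(oligomer_id = id, rho = rho, rho_pool_means = rho_pool,
               monotonic = rho_pool == 1)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag oligomers whose observed-vs-expected correlation falls below trend
#'
#' Per oligomer, the Pearson correlation between log2 observed
#' quantification and log2 expected concentration across samples is
#' Fisher z-transformed (symmetrizing the left-skewed sampling noise of
#' correlations near 1) and regressed (robust loess) on the
#' across-pool-average log2 expected concentration, adjusting for the
#' genuine decay of correlation toward the low-concentration range. An
#' oligomer is flagged when its z value falls below the lower
#' confidence bound of the trend (pointwise fit variance plus the
#' global robust residual scale) *and* sits more than 3 robust residual
#' scales below the trend — the "far below" criterion that keeps the
#' screen silent on homogeneous panels.
#'
#' @param spike_counts matrix of spike rows x samples.
#' @param design a `pooling_design`.
#' @param sheet the sample sheet.
#' @param ci confidence level of the pointwise band.
#' @param span loess span.
#' @param z_mult robust-scale multiplier of the far-below criterion.
#' @return data.frame: `oligomer_id`, `r`, `mean_log2_conc`, `fitted_z`,
#'   `lower_z`, `flagged`.
#' @export
per_oligomer_correlation_outliers <- function(spike_counts, design, sheet,
                                              ci = 0.95, span = 0.75,
                                              z_mult = 3) {
  if (nrow(spike_counts) < 5L) stop("need at least 5 oligomers")
  conc <- expected_concentration_matrix(design)
  ids <- sub("^spike:", "", rownames(spike_counts))
  r <- vapply(seq_along(ids), function(i) {
    expc <- log2(conc[ids[i], sheet$pool])
    obs <- log2_transform(matrix(spike_counts[i, ], nrow = 1))[1, ]
    stats::cor(obs, expc)
  }, numeric(1))
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  mean_conc <- log2(rowMeans(conc[ids, , drop = FALSE]))
  fit <- suppressWarnings(stats::loess(
    z ~ mean_conc, span = span, degree = 2L, family = "symmetric",
    control = stats::loess.control(surface = "direct")))
  pred <- suppressWarnings(stats::predict(fit, se = TRUE))
  res <- z - pred$fit
  scale <- 1.4826 * stats::median(abs(res))
  tcrit <- stats::qt(1 - (1 - ci) / 2, pred$df)
  lower <- pred$fit - tcrit * sqrt(pred$se.fit^2 + scale^2)
  data.frame(oligomer_id = ids, r = r, mean_log2_conc = mean_conc,
             fitted_z = pred$fit, lower_z = lower,
             flagged = z < lower & res < -z_mult * scale,
             row.names = NULL)
}

#' Overlap of two discovery sets
#'
#' @param set_a,set_b character vectors of significant feature ids.
#' @return list: `a_only`, `shared`, `b_only`, `replication_fraction`
#'   (share of `set_a` found in `set_b`).
#' @export
overlap_summary <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- length(intersect(set_a, set_b))
  list(a_only = length(setdiff(set_a, set_b)), shared = shared,
       b_only = length(setdiff(set_b, set_a)),
       replication_fraction = if (length(set_a)) shared / length(set_a)
                              else NA_real_)
}

#' Recovery of method-specific discoveries at a relaxed FDR
#'
#' For a query set of discoveries specific to one method, asks how many
#' are recovered by the reference method at a relaxed FDR, and among
#' the recovered, how many agree in effect sign.
#'
#' @param reference_results data.frame with rownames (or an `id`
#'   column), a `q` column and an `estimate` column.
#' @param query_set data.frame with an `id` column and an `estimate`
#'   column (the query method's effects), or a character vector of ids
#'   (sign agreement then unavailable).
#' @param relaxed_fdr relaxed FDR threshold in the reference.
#' @return list: `n_query`, `n_recovered`, `recovered_fraction`,
#'   `sign_agreement_fraction` (NA if signs unavailable or nothing
#'   recovered).
#' @export
recovery_at_relaxed_fdr <- function(reference_results, query_set,
                                    relaxed_fdr = 0.2) {
  ref <- as.data.frame(reference_results)
  if (!"id" %in% names(ref)) ref$id <- rownames(ref)
  if (is.character(query_set)) {
    query <- data.frame(id = query_set, estimate = NA_real_)
  } else {
    query <- as.data.frame(query_set)
  }
  if (nrow(query) == 0L) {
    return(list(n_query = 0L, n_recovered = 0L,
                recovered_fraction = NA_real_,
                sign_agreement_fraction = NA_real_))
  }
  miss <- setdiff(query$id, ref$id)
  if (length(miss)) stop("query genes absent from reference: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(query$id, ref$id)
  rec <- ref$q[idx] <= relaxed_fdr
  agree <- NA_real_
  if (any(rec) && !all(is.na(query$estimate))) {
    agree <- mean(sign(ref$estimate[idx][rec]) == sign(query$estimate[rec]))
  }
  list(n_query = nrow(query), n_recovered = sum(rec),
       recovered_fraction = mean(rec), sign_agreement_fraction = agree)
}

#' Robustness of factor normalization to control subsampling
#'
#' Repeats factor normalization `n_iter` times, each time using a
#' random subsample of the control rows as control genes, and measures
#' (i) the per-iteration regression of normalized control log2
#' quantification on expected log2 concentration for held-in and
#' held-out controls, and (ii) the per-feature coefficient of variation
#' of normalized linear-scale quantification across iterations
#' (technical CV), contrasted with the across-sample CV of the
#' full-control normalization (biological CV; computed over all
#' samples, both conditions).
#'
#' @param counts integer matrix, features x samples.
#' @param control_rows control row index (logical or integer).
#' @param expected_log_conc matrix (controls x samples) of log2 expected
#'   concentrations.
#' @param n_iter number of subsampling iterations.
#' @param fraction fraction of controls kept per iteration.
#' @param k number of unwanted factors.
#' @param seed integer seed.
#' @return a `robustness_report` list: `iterations` (per-iteration
#'   regression summaries), `cv` (per-endogenous-feature subsampling and
#'   biological CV), `mean_subsampling_cv`, `mean_biological_cv`.
#' @export
subsample_robustness <- function(counts, control_rows, expected_log_conc,
                                 n_iter = 10L, fraction = 0.5, k = 3L,
                                 seed = 1L) {
  if (is.logical(control_rows)) control_rows <- which(control_rows)
  n_ctrl <- length(control_rows)
  n_sub <- max(1L, round(fraction * n_ctrl))
  if (n_sub <= k) stop("subsample of ", n_sub,
                       " controls cannot support k = ", k, " factors")
  set.seed(as.integer(seed))
  endo <- setdiff(seq_len(nrow(counts)), control_rows)
  norm_stack <- array(NA_real_, c(length(endo), ncol(counts), n_iter))
  iters <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    sub <- sort(sample(seq_len(n_ctrl), n_sub))
    held_in <- control_rows[sub]
    held_out <- setdiff(control_rows, held_in)
    norm <- factor_normalize(counts, held_in, k)$normalized_counts
    reg_for <- function(rows, rows_idx) {
      y <- as.vector(log2_transform(norm[rows, , drop = FALSE]))
      x <- as.vector(expected_log_conc[rows_idx, , drop = FALSE])
      obs_vs_exp_regression(y, x)
    }
    rin <- reg_for(held_in, sub)
    rout <- if (length(held_out) >= 1L) {
      reg_for(held_out, setdiff(seq_len(n_ctrl), sub))
    } else NULL
    iters[[it]] <- data.frame(
      iteration = it, n_controls = n_sub,
      slope_in = rin$slope, r_squared_in = rin$r_squared,
      slope_out = if (is.null(rout)) NA_real_ else rout$slope,
      r_squared_out = if (is.null(rout)) NA_real_ else rout$r_squared)
    norm_stack[, , it] <- norm[endo, , drop = FALSE]
  }
  ## technical CV: per (feature, sample) across iterations, averaged
  ## over samples; undefined cells (mean 0) are dropped
  cv_cell <- apply(norm_stack, c(1, 2), function(v) {
    m <- mean(v)
    if (m == 0) NA_real_ else stats::sd(v) / m
  })
  sub_cv <- rowMeans(cv_cell, na.rm = TRUE)
  full <- factor_normalize(counts, control_rows, k)$normalized_counts
  bio_cv <- apply(full[endo, , drop = FALSE], 1L, function(v) {
    m <- mean(v)
    if (m == 0) NA_real_ else stats::sd(v) / m
  })
  cv <- data.frame(feature = rownames(counts)[endo],
                   subsampling_cv = sub_cv, biological_cv = bio_cv,
                   row.names = NULL)
  structure(list(iterations = do.call(rbind, iters), cv = cv,
                 mean_subsampling_cv = mean(sub_cv, na.rm = TRUE),
                 mean_biological_cv = mean(bio_cv, na.rm = TRUE)),
            class = "robustness_report")
}
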