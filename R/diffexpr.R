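## Per-feature linear modeling with empirical-Bayes moderated
## t-statistics. Expression E_j is modeled as
##   E_j = mu + beta1 T_j + beta2 B_j + beta3 C_j + eps_j
## with treatment T as the predictor and library batch B and donor C as
## covariates; per-feature residual variances are shrunk toward a prior
## estimated by the method of moments on log s^2, and the treatment
## coefficient is tested with a moderated t.

#' Design matrix for the treatment model
#'
#' Intercept + treatment indicator + library batch + donor (factor
#' coded, first donor as reference).
#'
#' @param sheet a sample sheet.
#' @return numeric design matrix with rows aligned to `sheet`.
#' @export
build_design_matrix <- function(sheet) {
  treatment <- factor(sheet$treatment, levels = c("control", "treated"))
  batch <- factor(sheet$library_batch)
  donor <- factor(sheet$donor, levels = unique(sheet$donor))
  X <- stats::model.matrix(~ treatment + batch + donor)
  rownames(X) <- sheet$sample_id
  X
}

#' Ordinary least squares fits for every feature
#'
#' @param log_expression matrix, features x samples, on the log2 scale.
#' @param design design matrix (samples x coefficients), full column
#'   rank.
#' @param coef name or index of the coefficient of interest (default:
#'   the first coefficient whose name starts with "treatment").
#' @return a `gene_fits` list: `coefficients` (features x p),
#'   `estimate` (coefficient of interest), `stdev_unscaled`, `sigma2`,
#'   `df_residual`, `coef`.
#' @export
fit_gene_models <- function(log_expression, design, coef = NULL) {
  log_expression <- as.matrix(log_expression)
  if (ncol(log_expression) != nrow(design)) {
    stop("columns of expression must align with design rows")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  d <- nrow(design) - qrX$rank
  if (d < 1L) stop("no residual degrees of freedom")
  if (is.null(coef)) {
    hit <- grep("^treatment", colnames(design))
    coef <- if (length(hit)) hit[1L] else 2L
  }
  if (is.character(coef)) coef <- match(coef, colnames(design))
  fit <- stats::lm.fit(design, t(log_expression))
  B <- t(as.matrix(fit$coefficients))           # features x p
  if (nrow(log_expression) == 1L) B <- matrix(B, 1L, ncol(design),
                                              dimnames = list(rownames(log_expression),
                                                              colnames(design)))
  res <- as.matrix(fit$residuals)               # samples x features
  sigma2 <- colSums(res^2) / d
  xtxinv <- chol2inv(qr.R(qrX))
  structure(list(coefficients = B,
                 estimate = B[, coef],
                 stdev_unscaled = sqrt(xtxinv[coef, coef]),
                 sigma2 = unname(sigma2),
                 df_residual = d,
                 coef = colnames(design)[coef]),
            class = "gene_fits")
}

## Newton solve of trigamma(y) = x, vectorized; used by the moment
## estimator of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  out <- x
  lo <- x > 1e7
  out[lo] <- 1 / sqrt(x[lo])
  hi <- x < 1e-6
  out[hi] <- 1 / x[hi]
  mid <- !lo & !hi
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

## Method-of-moments fit of the scaled inverse-chi-square prior on the
## residual variances: returns prior df d0 and prior variance s0^2.
fit_variance_prior <- function(sigma2, df) {
  ok <- sigma2 > 0
  ## fully degenerate (e.g. identical replicates everywhere): a
  ## zero-variance prior; moderated t is defined by its limits there
  if (!any(ok)) return(list(df_prior = Inf, var_prior = 0))
  z <- log(sigma2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1)
  evar <- evar - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## variances are as concordant as a single variance: infinite prior
    ## df, all posterior variances equal to the common value
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df_prior = d0, var_prior = s02)
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks each feature's residual variance toward a prior estimated by
#' the method of moments on log s^2:
#' `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`, then tests the coefficient
#' of interest with `t = estimate / (stdev_unscaled * sqrt(s2_post))`
#' on `d0 + d` degrees of freedom (two-sided p).
#'
#' @param fits a `gene_fits` object.
#' @return a `moderated_stats` data.frame with columns `estimate`, `t`,
#'   `p`, `q` (BH-adjusted) plus attributes `df_prior`, `var_prior`,
#'   `s2_post`, `df_total`.
#' @export
moderate <- function(fits) {
  stopifnot(inherits(fits, "gene_fits"))
  d <- fits$df_residual
  prior <- fit_variance_prior(fits$sigma2, d)
  d0 <- prior$df_prior
  s02 <- prior$var_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(fits$sigma2))
             else (d0 * s02 + d * fits$sigma2) / (d0 + d)
  tstat <- fits$estimate / (fits$stdev_unscaled * sqrt(s2_post))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  ## zero posterior variance: t defined by limits (0/0 -> no evidence)
  degen <- s2_post == 0
  if (any(degen)) {
    tstat[degen] <- ifelse(fits$estimate[degen] == 0, 0,
                           sign(fits$estimate[degen]) * Inf)
    p[degen] <- ifelse(fits$estimate[degen] == 0, 1, 0)
  }
  out <- data.frame(estimate = fits$estimate, t = tstat, p = p,
                    q = bh_fdr(p))
  rownames(out) <- names(fits$estimate)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  attr(out, "s2_post") <- s2_post
  attr(out, "df_total") <- df_total
  class(out) <- c("moderated_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, returned in the
#' input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return vector of adjusted values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  ranked <- pvalues[ord] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(ranked, 1)
  q
}

#' Spike-in comparison tests against the truth table
#'
#' For each truth-table row, fits the oligomer's log2 quantification on
#' the two sample groups' library-batch replicates with a treatment
#' indicator and a library-batch covariate, then moderates the residual
#' variances jointly across all rows and reports the moderated t, p and
#' BH q next to the truth label.
#'
#' @param log_expression matrix (features x samples) on the log2 scale;
#'   spike rows named `spike:<id>` (bare ids also accepted).
#' @param truth a `truth_table` from [enumerate_comparisons()].
#' @param sheet the sample sheet (provides replicate membership).
#' @return a `comparison_result` data.frame: truth columns plus
#'   `estimate`, `t`, `p`, `q`.
#' @export
test_spikein_comparisons <- function(log_expression, truth, sheet) {
  groups <- sheet_groups(sheet)
  group_samples <- function(gid) {
    g <- groups[groups$group_id == gid, ]
    sheet$sample_id[sheet$donor == g$donor & sheet$treatment == g$treatment]
  }
  rowname_for <- function(id) {
    spiked <- paste0("spike:", id)
    if (spiked %in% rownames(log_expression)) spiked
    else if (id %in% rownames(log_expression)) id
    else stop("oligomer ", id, " not found in expression matrix")
  }
  n <- nrow(truth)
  est <- sig2 <- se_unscaled <- numeric(n)
  dfres <- integer(n)
  for (i in seq_len(n)) {
    sa <- group_samples(truth$sample_a[i])   # treated side
    sb <- group_samples(truth$sample_b[i])   # control side
    if (length(sa) < 1L || length(sb) < 1L) {
      stop("truth row ", i, ": missing replicates")
    }
    cols <- c(sa, sb)
    y <- log_expression[rowname_for(truth$oligomer_id[i]), cols]
    tr <- c(rep(1, length(sa)), rep(0, length(sb)))
    bat <- factor(sheet$library_batch[match(cols, sheet$sample_id)])
    X <- if (nlevels(bat) > 1L) stats::model.matrix(~ tr + bat)
         else stats::model.matrix(~ tr)
    d <- length(y) - ncol(X)
    if (d < 1L) stop("truth row ", i, ": no residual degrees of freedom")
    fit <- stats::lm.fit(X, y)
    est[i] <- fit$coefficients[["tr"]]
    sig2[i] <- sum(fit$residuals^2) / d
    se_unscaled[i] <- sqrt(chol2inv(qr.R(fit$qr))[2L, 2L])
    dfres[i] <- d
  }
  if (length(unique(dfres)) != 1L) {
    stop("unequal residual df across comparisons; cannot moderate jointly")
  }
  fits <- structure(list(coefficients = cbind(tr = est), estimate = est,
                         stdev_unscaled = se_unscaled[1L], sigma2 = sig2,
                         df_residual = dfres[1L], coef = "tr"),
                    class = "gene_fits")
  ## per-row unscaled standard errors can differ if replicate numbers
  ## differ; rescale estimates into a common unit before moderation
  stats_tab <- if (all(se_unscaled == se_unscaled[1L])) {
    moderate(fits)
  } else {
    fits$estimate <- est / se_unscaled
    fits$stdev_unscaled <- 1
    tab <- moderate(fits)
    tab$estimate <- est
    tab
  }
  out <- cbind(as.data.frame(truth), stats_tab[, c("estimate", "t", "p", "q")])
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Transcriptome-wide differential translation scan
#'
#' Fits the treatment model to every feature, moderates variances,
#' adjusts with BH and reports the significant set at the requested
#' FDR with its up/down split.
#'
#' @param normalized_expression matrix (features x samples), log2 scale.
#' @param design design matrix from [build_design_matrix()].
#' @param fdr FDR threshold for the significant set.
#' @return a `de_result` list: `table` (data.frame with `estimate`, `t`,
#'   `p`, `q`), `significant` (ids), `n_up`, `n_down`, `fdr`.
#' @export
de_scan <- function(normalized_expression, design, fdr = 0.05) {
  fits <- fit_gene_models(normalized_expression, design)
  tab <- moderate(fits)
  sig <- rownames(tab)[tab$q <= fdr]
  structure(list(table = tab, significant = sig,
                 n_up = sum(tab[sig, "estimate"] > 0),
                 n_down = sum(tab[sig, "estimate"] < 0),
                 fdr = fdr),
            class = "de_result")
}
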