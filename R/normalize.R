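## Normalization: the two approaches compared throughout the package —
## global scaling by a weighted trimmed mean of M-values (TMM) and
## control-gene factor analysis anchored on the spike-in rows — plus the
## shared filtering/transform steps and the spike-in-anchored procedure
## for choosing the number of unwanted factors to remove.

#' Drop endogenous genes lacking coverage in any sample
#'
#' Keeps endogenous rows with at least one read in every sample; spike
#' rows are always retained regardless of zeros.
#'
#' @param counts integer matrix, features x samples.
#' @param spike_flags logical row indicator of spike-in rows.
#' @return list with filtered `counts` and matching `spike_flags`.
#' @export
filter_min_count <- function(counts, spike_flags) {
  stopifnot(length(spike_flags) == nrow(counts))
  keep <- spike_flags | apply(counts >= 1L, 1L, all)
  list(counts = counts[keep, , drop = FALSE],
       spike_flags = spike_flags[keep])
}

#' Log2 transform with a small pseudo-count
#'
#' `log2(x + pseudocount)`; the default 0.25 avoids singular values at
#' zero counts while leaving large counts essentially untouched.
#'
#' @param counts nonnegative matrix.
#' @param pseudocount positive offset.
#' @return matrix of the same shape.
#' @export
log2_transform <- function(counts, pseudocount = 0.25) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(counts < 0)) stop("counts must be nonnegative")
  log2(counts + pseudocount)
}

## 75th-percentile count-per-library-size, used to pick the TMM
## reference sample.
tmm_quantile <- function(counts, lib_size, p = 0.75) {
  vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j], p, names = FALSE) / lib_size[j]
  }, numeric(1))
}

tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim,
                            abs_expr_trim) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]
  ref <- ref[keep0]
  if (length(obs) == 0L) {
    stop("sample shares no positive features with the reference")
  }
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  ## binomial-approximation precision weights (variance of M)
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_expr_trim) + 1
  hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Per-sample scaling factors computed as the precision-weighted doubly
#' trimmed mean of log2 expression ratios (M-values) against a
#' reference sample, exponentiated and rescaled to geometric mean 1.
#' Features with a zero count in either the sample or the reference are
#' excluded; the top/bottom `logratio_trim` fraction by M and
#' `abs_expr_trim` fraction by average log abundance (A) are trimmed;
#' weights are the inverse binomial-approximation variances of M. The
#' reference is the sample whose 75th-percentile count-per-library-size
#' is closest to the mean across samples.
#'
#' @param counts nonnegative matrix, features x samples (>= 2 samples).
#' @param logratio_trim fraction trimmed on each tail of M.
#' @param abs_expr_trim fraction trimmed on each tail of A.
#' @param lib_size library sizes (default column sums).
#' @return numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_expr_trim = 0.05,
                        lib_size = colSums(counts)) {
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abs_expr_trim < 0 || abs_expr_trim >= 0.5) {
    stop("trims must lie in [0, 0.5)")
  }
  f75 <- tmm_quantile(counts, lib_size)
  if (median(f75) < 1e-20) {
    ref <- which.max(colSums(sqrt(counts)))
  } else {
    ref <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
                    logratio_trim, abs_expr_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Counts per million against effective library sizes
#'
#' @param counts nonnegative matrix.
#' @param factors per-sample scaling factors (e.g. from
#'   [tmm_factors()]); effective library size is `lib_size * factor`.
#' @param lib_size library sizes (default column sums).
#' @return matrix of CPM values.
#' @export
scale_normalize <- function(counts, factors = rep(1, ncol(counts)),
                            lib_size = colSums(counts)) {
  eff <- lib_size * factors
  if (any(eff <= 0)) stop("effective library sizes must be positive")
  t(t(counts) / eff) * 1e6
}

#' Control-gene factor-analysis normalization
#'
#' Estimates `k` unwanted-variation factors from the control (spike-in)
#' rows and removes their fitted contribution from every feature:
#' log(counts + 1) of the controls is row-centered, the first `k`
#' sample-side singular vectors form the factor score matrix `W`, every
#' feature's log counts are regressed on `W` (no intercept; `W` is
#' orthogonal to the constant by construction) and the fitted unwanted
#' component subtracted. Normalized counts are recovered by
#' exponentiating, subtracting the offset, rounding half away from zero
#' and flooring at 0. No upper-quartile pre-scaling is applied, so a
#' genuine global shift carried by the endogenous genes survives
#' normalization.
#'
#' @param counts nonnegative integer matrix, features x samples.
#' @param control_rows logical or integer index of control rows.
#' @param k number of unwanted factors to remove (`0` returns the input
#'   unchanged).
#' @param offset pseudo-count used inside the decomposition (log(x +
#'   offset)).
#' @return a `factor_norm` list: `W` (samples x k), `alpha` (k x
#'   features loadings), `k`, `normalized_counts`.
#' @export
factor_normalize <- function(counts, control_rows, k, offset = 1) {
  if (is.logical(control_rows)) control_rows <- which(control_rows)
  if (length(control_rows) == 0L) stop("controls must be nonempty")
  if (k < 0) stop("k must be >= 0")
  if (k > min(length(control_rows), ncol(counts) - 1L)) {
    stop("k must be <= min(#controls, #samples - 1)")
  }
  if (k == 0L) {
    return(structure(list(W = matrix(0, ncol(counts), 0),
                          alpha = matrix(0, 0, nrow(counts)),
                          k = 0L, normalized_counts = counts),
                     class = "factor_norm"))
  }
  if (all(counts[control_rows, ] == 0)) stop("controls are all zero")
  Y <- t(log(counts + offset))              # samples x features
  Yc <- scale(Y[, control_rows, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  if (sv$d[k] < 1e-8) stop("k = ", k, " exceeds the rank of the controls")
  W <- sv$u[, seq_len(k), drop = FALSE]
  alpha <- solve(crossprod(W), crossprod(W, Y))   # k x features
  corrected <- Y - W %*% alpha
  norm <- exp(t(corrected)) - offset
  norm <- pmax(floor(norm + 0.5), 0)
  dimnames(norm) <- dimnames(counts)
  storage.mode(norm) <- "integer"
  structure(list(W = W, alpha = alpha, k = as.integer(k),
                 normalized_counts = norm),
            class = "factor_norm")
}

#' Choose the number of unwanted factors from spike-in truth
#'
#' For `k = 0..k_max`, records the pooled R-squared between the
#' factor-corrected control log2 quantification and the known log2
#' expected concentration over all (control, sample) pairs. The trace
#' is computed on the continuous corrected values on the decomposition
#' scale (`log(count + offset)`, converted to log2), not on the rounded
#' integer extraction of [factor_normalize()], so low-count controls do
#' not inject quantization noise into the trace. The chosen `k` is the
#' smallest whose increment to `k + 1` falls below `delta` (the plateau
#' of the trace).
#'
#' @param counts nonnegative integer matrix.
#' @param control_rows control row index.
#' @param expected_log_conc matrix (controls x samples) of log2 expected
#'   concentrations, rows aligned with `control_rows`.
#' @param k_max largest k to scan (must be < number of samples).
#' @param delta plateau tolerance in R-squared units.
#' @param offset pseudo-count of the decomposition scale.
#' @return a `k_selection` list: `trace` (data.frame of k, r_squared),
#'   `chosen_k`, `delta`.
#' @export
select_k <- function(counts, control_rows, expected_log_conc, k_max = 6L,
                     delta = 0.01, offset = 1) {
  if (k_max >= ncol(counts)) stop("k_max must be < number of samples")
  if (is.logical(control_rows)) control_rows <- which(control_rows)
  stopifnot(nrow(expected_log_conc) == length(control_rows),
            ncol(expected_log_conc) == ncol(counts))
  Yc_all <- t(log(counts[control_rows, , drop = FALSE] + offset))
  sv <- svd(scale(Yc_all, center = TRUE, scale = FALSE))
  x <- as.vector(expected_log_conc)
  r2 <- vapply(0:k_max, function(k) {
    if (k == 0L) {
      corrected <- Yc_all
    } else {
      if (sv$d[k] < 1e-8) stop("k = ", k, " exceeds the rank of the controls")
      W <- sv$u[, seq_len(k), drop = FALSE]
      corrected <- Yc_all - W %*% solve(crossprod(W), crossprod(W, Yc_all))
    }
    stats::cor(as.vector(t(corrected)) / log(2), x)^2
  }, numeric(1))
  inc <- diff(r2)
  below <- which(inc < delta)
  chosen <- if (length(below)) below[1L] - 1L else k_max
  structure(list(trace = data.frame(k = 0:k_max, r_squared = r2),
                 chosen_k = as.integer(chosen), delta = delta),
            class = "k_selection")
}
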