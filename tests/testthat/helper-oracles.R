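# Independent oracles used across the suite. These deliberately take
# different code paths from the package implementations they check.

# Exhaustive enumeration of all nested secondary structures (no
# memoization, plain recursion) under the stacking-free energy model:
# -1.0 GC, -0.7 AU, -0.3 GU, minimum hairpin loop 3.
brute_mfe <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  pe <- function(x, y) {
    switch(paste0(x, y),
           GC = , CG = -1.0, AU = , UA = -0.7, GU = , UG = -0.3,
           NA_real_)
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0)
    best <- rec(i + 1L, j)
    for (l in (i + 4L):j) {
      e <- pe(b[i], b[l])
      if (!is.na(e)) best <- min(best, e + rec(i + 1L, l - 1L) + rec(l + 1L, j))
    }
    best
  }
  rec(1L, length(b))
}

# Direct recomputation of a single TMM factor from its definition,
# written naively (explicit sorting-based trim instead of ranks).
brute_tmm_pair <- function(obs, ref, n_obs, n_ref,
                           logratio_trim = 0.30, abs_expr_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * (log2(obs / n_obs) + log2(ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  ok <- is.finite(M) & is.finite(A)
  M <- M[ok]; A <- A[ok]; w <- w[ok]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_expr_trim) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# A small panel of real-looking RNA sequences used as a miRNA reference
# stand-in for profile/panel tests.
toy_mirna_set <- function(n = 25, len = 22, seed = 99) {
  set.seed(seed)
  replicate(n, paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE,
                             prob = c(0.27, 0.22, 0.27, 0.24)),
                      collapse = ""))
}
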