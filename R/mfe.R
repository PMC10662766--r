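## Built-in folding engine: a nested-secondary-structure dynamic program
## with stacking-free pair energies. Deliberately simple: deterministic,
## exhaustively testable against brute-force structure enumeration, and
## pluggable so a thermodynamic folder can replace it.

PAIR_ENERGY <- local({
  m <- matrix(NA_real_, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["G", "C"] <- m["C", "G"] <- -1.0
  m["A", "U"] <- m["U", "A"] <- -0.7
  m["G", "U"] <- m["U", "G"] <- -0.3
  m
})

## Minimum number of unpaired bases enclosed by a pair.
MIN_HAIRPIN_LOOP <- 3L

#' Minimum free energy of an RNA sequence
#'
#' Scores the best nested (pseudoknot-free) secondary structure under a
#' simple additive energy model: -1.0 kcal/mol per G:C pair, -0.7 per
#' A:U, -0.3 per G:U wobble, with a minimum hairpin loop of 3 unpaired
#' nucleotides. A value of 0 means no stabilizing structure exists. An
#' external thermodynamic folding engine can be plugged in via `engine`
#' (any function mapping a sequence string to a numeric free energy).
#'
#' @param sequence RNA string (T accepted and mapped to U).
#' @param engine `NULL` for the built-in dynamic program, or a function
#'   `function(sequence) -> numeric`.
#' @return free energy in kcal/mol, always `<= 0` for the built-in
#'   engine.
#' @examples
#' mfe("AAAAAAAAAAAA") # 0: no complementary pairs
#' mfe("GGGAAAACCC")   # a small hairpin
#' @export
mfe <- function(sequence, engine = NULL) {
  if (!is.null(engine)) return(engine(sequence))
  s <- normalize_rna(sequence)
  if (nchar(s) < 1L) stop("sequence must have length >= 1")
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n < MIN_HAIRPIN_LOOP + 2L) return(0)
  ## E[i, j]: best energy of subsequence i..j; cells default to 0
  ## (unfolded). Indexing is padded one column/row so E[l + 1, j] with
  ## l = j reads 0.
  E <- matrix(0, n + 1L, n + 1L)
  for (span in (MIN_HAIRPIN_LOOP + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      ls <- (i + MIN_HAIRPIN_LOOP + 1L):j
      ev <- PAIR_ENERGY[b[i], b[ls]]
      ok <- !is.na(ev)
      best <- E[i + 1L, j]
      if (any(ok)) {
        lsok <- ls[ok]
        v <- ev[ok] + E[cbind(i + 1L, lsok - 1L)] + E[cbind(lsok + 1L, j)]
        best <- min(best, v)
      }
      E[i, j] <- best
    }
  }
  E[1L, n]
}
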