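#' Normalize a character vector of sequences to the RNA alphabet
#'
#' Upper-cases and maps T to U. Errors on any character outside A/C/G/U
#' after mapping.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the alphabet A, C, G, U.
#' @export
normalize_rna <- function(x) {
  if (!is.character(x)) stop("sequences must be a character vector")
  out <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

#' Positional base-composition profile of a reference sequence set
#'
#' Computes, for each of the first `length` positions, the frequency of
#' each base A/C/G/U among the input sequences. The default length of 20
#' targets the 5' portion of mature miRNAs, which the spike-in core
#' sequences are designed to mimic.
#'
#' @param sequences character vector of RNA (or DNA) sequences, each at
#'   least `length` nt long.
#' @param length number of 5' positions to profile.
#' @return a `base_profile` object: a `length` x 4 matrix of
#'   probabilities with columns A, C, G, U; each row sums to 1.
#' @examples
#' build_mirna_profile(c("ACGUACGUACGUACGUACGU", "ACGAACGAACGAACGAACGA"))
#' @export
build_mirna_profile <- function(sequences, length = 20L) {
  length <- as.integer(length)
  if (length < 1L) stop("`length` must be >= 1")
  seqs <- normalize_rna(sequences)
  if (length(seqs) == 0L) stop("empty sequence set")
  if (any(nchar(seqs) < length)) {
    stop("all sequences must be at least ", length, " nt long")
  }
  mat <- do.call(rbind, strsplit(substr(seqs, 1L, length), ""))
  probs <- t(apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = RNA_BASES))
    as.numeric(tab) / length(col)
  }))
  colnames(probs) <- RNA_BASES
  rownames(probs) <- seq_len(length)
  structure(probs, class = c("base_profile", "matrix"))
}

#' Sample core sequences from a positional base profile
#'
#' Draws each position independently from the profile's per-position
#' base distribution.
#'
#' @param profile a `base_profile` from [build_mirna_profile()].
#' @param n number of core sequences to draw.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return data.frame with columns `core_id`, `seq`.
#' @export
sample_core_sequences <- function(profile, n, seed = 1L) {
  if (!inherits(profile, "base_profile")) stop("`profile` must be a base_profile")
  if (n < 0) stop("`n` must be >= 0")
  n <- as.integer(n)
  len <- nrow(profile)
  if (n == 0L) {
    return(data.frame(core_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(len), function(p) {
    sample(RNA_BASES, n, replace = TRUE, prob = profile[p, ])
  }, character(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  seqs <- apply(draws, 1L, paste0, collapse = "")
  data.frame(core_id = sprintf("core%04d", seq_len(n)), seq = seqs,
             stringsAsFactors = FALSE)
}

all_tetramers <- function() {
  g <- expand.grid(b4 = RNA_BASES, b3 = RNA_BASES, b2 = RNA_BASES,
                   b1 = RNA_BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4)
}

#' Enumerate or sample flanking tetramers around a core sequence
#'
#' Attaches 4-nt flanks to both ends of a 20-nt core, producing 28-nt
#' oligomer candidates (the length of a typical ribosome footprint).
#' With `mode = "all"` every one of the 4^8 = 65,536 distinct
#' (5' flank, 3' flank) combinations is produced.
#'
#' @param core single-row data.frame (`core_id`, `seq`) or a list with
#'   those fields.
#' @param mode `"all"` or `"sample"`.
#' @param n number of distinct pairs when `mode = "sample"`.
#' @param seed seed used when `mode = "sample"`.
#' @return data.frame with columns `core_id`, `flank5`, `flank3`,
#'   `full_seq` and an `mfe` column of `NA` (fill with
#'   [fold_candidates()]).
#' @export
enumerate_flanks <- function(core, mode = c("all", "sample"), n = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  core_seq <- normalize_rna(core$seq)
  if (nchar(core_seq) != 20L) stop("core sequence must be exactly 20 nt")
  tet <- all_tetramers()
  total <- length(tet)^2
  if (mode == "all") {
    idx <- seq_len(total)
  } else {
    if (is.null(n)) stop("`n` is required when mode = 'sample'")
    if (n > total) stop("cannot sample ", n, " distinct pairs; only ",
                        total, " exist")
    set.seed(as.integer(seed))
    idx <- sample.int(total, as.integer(n))
  }
  i5 <- ((idx - 1L) %/% length(tet)) + 1L
  i3 <- ((idx - 1L) %% length(tet)) + 1L
  flank5 <- tet[i5]
  flank3 <- tet[i3]
  data.frame(core_id = core$core_id, flank5 = flank5, flank3 = flank3,
             full_seq = paste0(flank5, core_seq, flank3),
             mfe = NA_real_, stringsAsFactors = FALSE)
}

#' Compute minimum free energies for a table of oligomer candidates
#'
#' @param candidates data.frame with a `full_seq` column.
#' @param engine folding engine; see [mfe()].
#' @return the input with its `mfe` column filled.
#' @export
fold_candidates <- function(candidates, engine = NULL) {
  candidates$mfe <- vapply(candidates$full_seq, mfe, numeric(1),
                           engine = engine, USE.NAMES = FALSE)
  candidates
}

#' Remove core sequences matched by a genome-mapping predicate
#'
#' @param cores data.frame of cores (`core_id`, `seq`).
#' @param mapper function taking a character vector of sequences and
#'   returning a logical vector: `TRUE` means the sequence maps to the
#'   genome and must be removed. [exact_match_mapper()] builds one from
#'   a reference sequence set.
#' @return the cores for which the predicate is `FALSE`, order kept.
#' @export
filter_genome_mapping <- function(cores, mapper) {
  hits <- tryCatch(mapper(cores$seq), error = function(e) {
    stop("genome-mapping predicate failed: ", conditionMessage(e))
  })
  if (!is.logical(hits) || length(hits) != nrow(cores)) {
    stop("mapper must return one logical per core sequence")
  }
  cores[!hits, , drop = FALSE]
}

#' Exact-substring genome-mapping predicate
#'
#' Flags a core if it occurs verbatim (as a substring) in any of the
#' supplied reference sequences. Stands in for a genome aligner at desk
#' scale; any predicate with the same signature can replace it.
#'
#' @param reference character vector of reference sequences.
#' @return a predicate function for [filter_genome_mapping()].
#' @export
exact_match_mapper <- function(reference) {
  reference <- normalize_rna(reference)
  function(seqs) {
    vapply(normalize_rna(seqs), function(s) {
      any(vapply(reference, function(r) grepl(s, r, fixed = TRUE),
                 logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }
}

#' Select one oligomer per core group by matching a target MFE profile
#'
#' Quantile-matches the target free-energy distribution at `k` points
#' and, for each matched target value (ascending), picks the candidate
#' whose MFE is nearest among the core groups not yet used. Ties are
#' broken lexicographically by `full_seq`. This mirrors a panel design
#' whose folding-energy spectrum resembles that of endogenous miRNAs.
#'
#' @param candidates_by_core data.frame of folded candidates (columns
#'   `core_id`, `full_seq`, `flank5`, `flank3`, `mfe`) or a list of such
#'   data.frames, one per core.
#' @param target_mfes numeric vector of target free energies (the
#'   endogenous reference distribution).
#' @param k panel size; requires at least `k` distinct core groups.
#' @param batches number of manufacturing batches the panel is split
#'   into (consecutive blocks; the default 2 mirrors ordering oligomers
#'   in two batches of 8).
#' @return an `oligomer_panel` data.frame with columns `oligomer_id`,
#'   `core_id`, `flank5`, `flank3`, `full_seq`, `mfe`,
#'   `manufacturing_batch`.
#' @export
select_by_mfe_profile <- function(candidates_by_core, target_mfes, k,
                                  batches = 2L) {
  if (is.data.frame(candidates_by_core)) {
    cand <- candidates_by_core
  } else {
    cand <- do.call(rbind, candidates_by_core)
  }
  if (any(is.na(cand$mfe))) stop("candidates must be folded first (mfe is NA)")
  if (length(target_mfes) == 0L) stop("target_mfes must be nonempty")
  groups <- unique(cand$core_id)
  if (length(groups) < k) {
    stop("need at least k = ", k, " core groups; have ", length(groups))
  }
  probs <- if (k == 1L) 0.5 else (seq_len(k) - 1) / (k - 1)
  targets <- sort(stats::quantile(target_mfes, probs = probs, names = FALSE,
                                  type = 7))
  used <- character(0)
  picked <- vector("list", k)
  for (i in seq_len(k)) {
    avail <- cand[!(cand$core_id %in% used), , drop = FALSE]
    dev <- abs(avail$mfe - targets[i])
    ## nearest candidate; ties resolved lexicographically by full_seq
    ord <- order(dev, avail$full_seq)
    best <- avail[ord[1L], , drop = FALSE]
    picked[[i]] <- best
    used <- c(used, best$core_id)
  }
  panel <- do.call(rbind, picked)
  rownames(panel) <- NULL
  panel$oligomer_id <- panel$core_id
  nb <- max(1L, as.integer(batches))
  per <- ceiling(k / nb)
  panel$manufacturing_batch <- paste0("B", ((seq_len(k) - 1L) %/% per) + 1L)
  panel <- panel[, c("oligomer_id", "core_id", "flank5", "flank3",
                     "full_seq", "mfe", "manufacturing_batch")]
  class(panel) <- c("oligomer_panel", "data.frame")
  panel
}

#' End-to-end spike-in panel design
#'
#' Profiles a miRNA reference set, samples candidate cores, removes
#' genome-mapping cores, attaches sampled flank tetramers, folds the
#' candidates and selects a panel matched to the reference MFE
#' distribution.
#'
#' @param mirna_seqs character vector of reference miRNA sequences.
#' @param n_cores number of candidate cores to draw.
#' @param panel_size number of oligomers to select.
#' @param flanks_per_core number of flank pairs sampled per core
#'   (sampling keeps desk-scale runtime; `mode = "all"` enumeration is
#'   available through [enumerate_flanks()]).
#' @param seed integer seed.
#' @param engine folding engine passed to [mfe()].
#' @param mapper optional genome-mapping predicate; `NULL` skips the
#'   filter.
#' @return an `oligomer_panel`.
#' @export
design_panel <- function(mirna_seqs, n_cores = 64L, panel_size = 16L,
                         flanks_per_core = 24L, seed = 1L, engine = NULL,
                         mapper = NULL) {
  profile <- build_mirna_profile(mirna_seqs, length = 20L)
  cores <- sample_core_sequences(profile, n_cores, seed = seed)
  if (!is.null(mapper)) cores <- filter_genome_mapping(cores, mapper)
  if (nrow(cores) < panel_size) stop("not enough cores after filtering")
  cand <- lapply(seq_len(nrow(cores)), function(i) {
    enumerate_flanks(cores[i, ], mode = "sample", n = flanks_per_core,
                     seed = seed + i)
  })
  cand <- fold_candidates(do.call(rbind, cand), engine = engine)
  targets <- vapply(normalize_rna(mirna_seqs), mfe, numeric(1),
                    engine = engine, USE.NAMES = FALSE)
  select_by_mfe_profile(cand, targets, k = panel_size)
}

#' Write an oligomer panel as FASTA
#'
#' One record per oligomer; the header carries the oligomer id plus
#' `core=`, `batch=` and `mfe=` fields.
#'
#' @param panel an `oligomer_panel`.
#' @param destination output file path.
#' @return the destination path, invisibly.
#' @export
write_panel_fasta <- function(panel, destination) {
  if (!inherits(panel, "oligomer_panel") || nrow(panel) == 0L) {
    stop("panel must be a nonempty oligomer_panel")
  }
  set <- Biostrings::RNAStringSet(panel$full_seq)
  names(set) <- sprintf("%s core=%s batch=%s mfe=%.3f", panel$oligomer_id,
                        panel$core_id, panel$manufacturing_batch, panel$mfe)
  Biostrings::writeXStringSet(set, filepath = destination)
  invisible(destination)
}

#' Read an oligomer panel written by [write_panel_fasta()]
#'
#' @param path FASTA file path.
#' @return an `oligomer_panel`.
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readRNAStringSet(path)
  hdr <- strsplit(names(set), "\\s+")
  field <- function(h, key) {
    hit <- grep(paste0("^", key, "="), h, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
  }
  seqs <- as.character(set)
  panel <- data.frame(
    oligomer_id = vapply(hdr, `[[`, character(1), 1L),
    core_id = vapply(hdr, field, character(1), "core"),
    flank5 = substr(seqs, 1L, 4L),
    flank3 = substr(seqs, 25L, 28L),
    full_seq = seqs,
    mfe = as.numeric(vapply(hdr, field, character(1), "mfe")),
    manufacturing_batch = vapply(hdr, field, character(1), "batch"),
    stringsAsFactors = FALSE
  )
  rownames(panel) <- NULL
  class(panel) <- c("oligomer_panel", "data.frame")
  panel
}
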