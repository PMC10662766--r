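## Modified-Latin-square pooling: four mixes of four oligomers at
## 8-fold within-mix increments, combined into three pools at a rotated
## permutation of the fractions 2/6/22/70%. Every oligomer therefore has
## a known relative concentration in every pool, giving analytically
## known fold changes between samples.

DEFAULT_POOL_FRACTIONS <- c(0.02, 0.06, 0.22, 0.70)

default_oligomer_ids <- function(n = 16L) {
  if (n %% 4L != 0L) stop("panel size must be divisible by 4")
  mixes <- LETTERS[seq_len(n / 4L)]
  as.vector(t(outer(mixes, seq_len(4L), paste0)))
}

panel_ids <- function(panel) {
  if (inherits(panel, "oligomer_panel")) panel$oligomer_id
  else if (is.character(panel)) panel
  else stop("`panel` must be an oligomer_panel or a character vector of ids")
}

#' Partition a panel into spike-in mixes with geometric concentration levels
#'
#' The panel is split in order into mixes A, B, C, ... of 4 oligomers
#' each; within a mix the members sit at relative levels
#' `(1, increment, increment^2, increment^3)` (8-fold increments by
#' default, as produced by 2-fold serial dilutions).
#'
#' @param panel an `oligomer_panel` or character vector of oligomer ids;
#'   length must be divisible by 4.
#' @param increment within-mix concentration ratio between consecutive
#'   members.
#' @return list of `mix` objects (fields `label`, `members`, `levels`).
#' @export
build_mixes <- function(panel, increment = 8) {
  ids <- panel_ids(panel)
  n <- length(ids)
  if (n %% 4L != 0L) stop("panel size (", n, ") must be divisible by 4")
  if (increment <= 0) stop("`increment` must be positive")
  labels <- LETTERS[seq_len(n / 4L)]
  levels <- increment^(0:3)
  mixes <- lapply(seq_along(labels), function(m) {
    members <- ids[((m - 1L) * 4L + 1L):(m * 4L)]
    structure(list(label = labels[m], members = members, levels = levels),
              class = "spike_mix")
  })
  names(mixes) <- labels
  mixes
}

#' Combine mixes into pools at rotated fraction permutations
#'
#' Pool `p` assigns mix `m` the fraction at index `(m + p) mod 4` under
#' the default cyclic rotation; any explicit rotation matrix (pools x
#' mixes, entries indexing into `fractions`) may be supplied instead.
#' Across the 3 pools every mix receives 3 distinct fraction levels, so
#' every oligomer has a known nonzero fold change between any two pools.
#'
#' @param mixes list of mixes from [build_mixes()].
#' @param fractions the 4 mixing fractions; must sum to 1.
#' @param n_pools number of pools (default 3).
#' @param rotation `"cyclic"` or an integer matrix (`n_pools` x
#'   `length(mixes)`) of 1-based indices into `fractions`.
#' @return list of `pool` objects (fields `label`, `mix_fractions`).
#' @export
build_pools <- function(mixes, fractions = DEFAULT_POOL_FRACTIONS,
                        n_pools = 3L, rotation = "cyclic") {
  if (length(mixes) != 4L) stop("expected 4 mixes")
  if (length(fractions) != 4L) stop("expected 4 fractions")
  if (abs(sum(fractions) - 1) > 1e-12) stop("fractions must sum to 1")
  mix_labels <- vapply(mixes, `[[`, character(1), "label")
  if (identical(rotation, "cyclic")) {
    rotation <- t(vapply(seq_len(n_pools), function(p) {
      ((seq_along(mixes) - 1L + (p - 1L)) %% 4L) + 1L
    }, integer(length(mixes))))
  }
  stopifnot(is.matrix(rotation), nrow(rotation) == n_pools,
            ncol(rotation) == length(mixes))
  pools <- lapply(seq_len(n_pools), function(p) {
    fr <- fractions[rotation[p, ]]
    names(fr) <- mix_labels
    structure(list(label = paste0("P", p), mix_fractions = fr),
              class = "spike_pool")
  })
  names(pools) <- vapply(pools, `[[`, character(1), "label")
  pools
}

#' Assemble a pooling design
#'
#' @param mixes from [build_mixes()].
#' @param pools from [build_pools()].
#' @return a `pooling_design` with lookup tables from oligomer id to mix
#'   label and within-mix level.
#' @export
pooling_design <- function(mixes, pools) {
  oligo_mix <- unlist(lapply(mixes, function(m) {
    stats::setNames(rep(m$label, length(m$members)), m$members)
  }))
  oligo_level <- unlist(lapply(mixes, function(m) {
    stats::setNames(m$levels, m$members)
  }))
  names(oligo_mix) <- sub("^[A-Z]+\\.", "", names(oligo_mix))
  names(oligo_level) <- names(oligo_mix)
  structure(list(mixes = mixes, pools = pools, oligo_mix = oligo_mix,
                 oligo_level = oligo_level),
            class = "pooling_design")
}

#' The default 16-oligomer, 3-pool design
#'
#' Four mixes of four oligomers at 8-fold increments, pooled at
#' fractions 2/6/22/70% under the cyclic rotation; spans a relative
#' concentration range of 1 to 17,920.
#'
#' @param panel optional `oligomer_panel` or id vector (defaults to ids
#'   A1..D4).
#' @inheritParams build_mixes
#' @inheritParams build_pools
#' @return a `pooling_design`.
#' @export
default_pooling_design <- function(panel = default_oligomer_ids(),
                                   increment = 8,
                                   fractions = DEFAULT_POOL_FRACTIONS,
                                   rotation = "cyclic") {
  mixes <- build_mixes(panel, increment = increment)
  pools <- build_pools(mixes, fractions = fractions, rotation = rotation)
  pooling_design(mixes, pools)
}

design_oligomers <- function(design) names(design$oligo_mix)
design_pools <- function(design) names(design$pools)

#' Expected relative concentration matrix
#'
#' Within-mix level times the pool's fraction for the oligomer's mix,
#' rescaled so the design-wide minimum equals 1.
#'
#' @param design a `pooling_design`.
#' @return matrix, oligomers x pools.
#' @export
expected_concentration_matrix <- function(design) {
  oligos <- design_oligomers(design)
  pools <- design_pools(design)
  conc <- vapply(pools, function(p) {
    fr <- design$pools[[p]]$mix_fractions
    fr[design$oligo_mix[oligos]] * design$oligo_level[oligos]
  }, numeric(length(oligos)))
  conc <- matrix(conc, nrow = length(oligos),
                 dimnames = list(oligos, pools))
  conc / min(conc)
}

#' Expected relative concentration of one oligomer in one pool
#'
#' @param design a `pooling_design`.
#' @param oligomer_id oligomer id.
#' @param pool_label pool label.
#' @return dimensionless relative concentration (design-wide minimum 1).
#' @export
expected_concentration <- function(design, oligomer_id, pool_label) {
  conc <- expected_concentration_matrix(design)
  if (!oligomer_id %in% rownames(conc)) stop("unknown oligomer: ", oligomer_id)
  if (!pool_label %in% colnames(conc)) stop("unknown pool: ", pool_label)
  conc[oligomer_id, pool_label]
}

#' Expected log2 fold change of an oligomer between two pools
#'
#' The within-mix level cancels, leaving the log-ratio of the two pools'
#' fractions for the oligomer's mix.
#'
#' @param design a `pooling_design`.
#' @param oligomer_id oligomer id.
#' @param pool_a,pool_b pool labels (numerator, denominator).
#' @return log2 fold change.
#' @export
expected_log2fc <- function(design, oligomer_id, pool_a, pool_b) {
  mix <- design$oligo_mix[oligomer_id]
  if (is.na(mix)) stop("unknown oligomer: ", oligomer_id)
  for (p in c(pool_a, pool_b)) {
    if (!p %in% design_pools(design)) stop("unknown pool: ", p)
  }
  fa <- design$pools[[pool_a]]$mix_fractions[[mix]]
  fb <- design$pools[[pool_b]]$mix_fractions[[mix]]
  log2(fa / fb)
}

#' Max/min ratio of expected concentrations across the whole design
#'
#' @param design a `pooling_design`.
#' @return dimensionless ratio (17,920 for the default design).
#' @export
quantitative_range <- function(design) {
  conc <- expected_concentration_matrix(design)
  max(conc) / min(conc)
}

#' Default 12-sample sheet mirroring a 3-donor, 2-condition study
#'
#' 3 donors x 2 treatments x 2 library-preparation batches (T, U).
#' Pools are rotated across donors so that each donor's control and
#' treated samples receive different pools (yielding true positives) and
#' each pool is shared by exactly one control and one treated sample
#' from different donors (yielding true negatives). Library-batch
#' replicates of the same (donor, treatment) always share a pool.
#'
#' @param donors donor labels.
#' @param design a `pooling_design` supplying the pool labels.
#' @return a `sample_sheet` data.frame with columns `sample_id`,
#'   `donor`, `treatment`, `library_batch`, `pool`.
#' @export
default_sample_sheet <- function(donors = c("505", "193", "204"),
                                 design = default_pooling_design()) {
  pools <- design_pools(design)
  if (length(pools) < length(donors)) stop("need one pool per donor")
  rows <- list()
  for (d in seq_along(donors)) {
    for (trt in c("control", "treated")) {
      ## control(donor i) -> pool i; treated(donor i) -> pool i+1 (wrapping),
      ## so control(d_i) and treated(d_{i-1}) share a pool.
      pool <- if (trt == "control") pools[d]
              else pools[(d %% length(donors)) + 1L]
      for (batch in c("T", "U")) {
        prefix <- if (trt == "control") "C" else "E"
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(prefix, donors[d], "_", batch),
          donor = donors[d], treatment = trt, library_batch = batch,
          pool = pool, stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)
  validate_sample_sheet(sheet, design)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

validate_sample_sheet <- function(sheet, design = NULL) {
  need <- c("sample_id", "donor", "treatment", "library_batch", "pool")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids")
  key <- paste(sheet$donor, sheet$treatment, sheet$library_batch)
  if (anyDuplicated(key)) {
    stop("(donor, treatment, library_batch) combinations must be unique")
  }
  if (!all(sheet$treatment %in% c("control", "treated"))) {
    stop("treatment must be 'control' or 'treated'")
  }
  if (!is.null(design) && !all(sheet$pool %in% design_pools(design))) {
    stop("sample sheet references pools absent from the design")
  }
  invisible(sheet)
}

## (donor, treatment) groups; the unit at which spike-in comparisons are
## made, with library batches as within-group replicates.
sheet_groups <- function(sheet) {
  g <- unique(sheet[, c("donor", "treatment", "pool")])
  g$group_id <- paste0(ifelse(g$treatment == "control", "C", "E"), g$donor)
  rownames(g) <- NULL
  g
}

#' Enumerate the truth table of spike-in comparisons
#'
#' True negatives: the same oligomer compared between a treated and a
#' control sample group that received the same pool (necessarily from
#' different donors under the default rotation); expected log2 fold
#' change exactly 0. True positives: same-donor treated-vs-control
#' pairs that received different pools; expected log2 fold change given
#' by the pool fraction ratio for the oligomer's mix.
#'
#' @param design a `pooling_design`.
#' @param sheet a sample sheet (see [default_sample_sheet()]).
#' @return a `truth_table` data.frame with columns `oligomer_id`,
#'   `sample_a` (treated group), `sample_b` (control group),
#'   `pool_a`, `pool_b`, `expected_log2fc`, `truth`.
#' @export
enumerate_comparisons <- function(design, sheet) {
  validate_sample_sheet(sheet, design)
  groups <- sheet_groups(sheet)
  ctrl <- groups[groups$treatment == "control", , drop = FALSE]
  trt <- groups[groups$treatment == "treated", , drop = FALSE]
  oligos <- design_oligomers(design)
  rows <- list()
  for (i in seq_len(nrow(trt))) {
    for (j in seq_len(nrow(ctrl))) {
      a <- trt[i, ]
      b <- ctrl[j, ]
      same_pool <- a$pool == b$pool
      same_donor <- a$donor == b$donor
      if (same_pool && !same_donor) {
        label <- "TN"
      } else if (!same_pool && same_donor) {
        label <- "TP"
      } else {
        if (same_pool && same_donor) {
          warning("donor ", a$donor, ": control and treated share pool ",
                  a$pool, "; no true positives derivable for this donor")
        }
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        oligomer_id = oligos,
        sample_a = a$group_id, sample_b = b$group_id,
        pool_a = a$pool, pool_b = b$pool,
        expected_log2fc = vapply(oligos, expected_log2fc, numeric(1),
                                 design = design, pool_a = a$pool,
                                 pool_b = b$pool),
        truth = label, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Expected log2 concentration for control rows in every sample
#'
#' @param design a `pooling_design`.
#' @param sheet a sample sheet.
#' @return matrix (oligomers x samples) of log2 expected relative
#'   concentration, rows named `spike:<id>`.
#' @export
expected_log_conc_matrix <- function(design, sheet) {
  conc <- expected_concentration_matrix(design)
  m <- log2(conc[, sheet$pool, drop = FALSE])
  dimnames(m) <- list(paste0("spike:", rownames(conc)), sheet$sample_id)
  m
}

#' Write / read a pooling design as JSON
#'
#' @param design a `pooling_design`.
#' @param path file path.
#' @return `path` (write) or a `pooling_design` (read).
#' @export
write_design_json <- function(design, path) {
  obj <- list(
    mixes = lapply(design$mixes, function(m) m[c("label", "members", "levels")]),
    pools = lapply(design$pools, function(p) {
      list(label = p$label, mix_fractions = as.list(p$mix_fractions))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixes <- lapply(obj$mixes, function(m) {
    structure(list(label = m$label, members = m$members,
                   levels = as.numeric(m$levels)), class = "spike_mix")
  })
  pools <- lapply(obj$pools, function(p) {
    fr <- unlist(p$mix_fractions)
    structure(list(label = p$label, mix_fractions = fr),
              class = "spike_pool")
  })
  names(mixes) <- vapply(mixes, `[[`, character(1), "label")
  names(pools) <- vapply(pools, `[[`, character(1), "label")
  pooling_design(mixes, pools)
}

#' Read / write a sample sheet CSV
#'
#' Header: `sample_id,donor,treatment,library_batch,pool`.
#'
#' @param path CSV file path.
#' @param sheet a sample sheet.
#' @return a `sample_sheet` (read) or `path` invisibly (write).
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_sample_sheet(sheet)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
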