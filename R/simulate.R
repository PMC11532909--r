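# Synthetic benchmark generation: random tryptic-like peptides, a
# transparent in-silico b/y spectrum generator, and mutated-peptide
# datasets with recorded mutation positions. Together with the mock
# engine these make the whole evaluation framework testable offline.

#' Configuration for the in-silico spectrum generator
#'
#' The generator emits singly charged b/y ions with rank-based synthetic
#' intensities — deliberately transparent rather than learned, since the
#' mutation analysis only needs the major b/y ions to be present.
#'
#' @param dropout Per-ion drop probability in `[0, 1)` (default 0.1:
#'   high-quality spectra still miss some fragments).
#' @param noise_peaks Number of uniform-m/z noise peaks per spectrum
#'   (default 10).
#' @param mz_jitter Half-width (Da) of uniform m/z noise on fragment
#'   peaks; must stay below half the 0.02 Da matching tolerance
#'   (default 0.005).
#' @param terminal_site_dropout Extra drop probability for ions at
#'   fragmentation sites within `terminal_width` of either terminus
#'   (default 0); models the missing terminal fragments behind adjacent
#'   amino-acid swaps.
#' @param terminal_width Number of terminal sites affected (default 3).
#' @return List of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(dropout = 0.1, noise_peaks = 10L,
                                mz_jitter = 0.005,
                                terminal_site_dropout = 0,
                                terminal_width = 3L) {
  stopifnot(dropout >= 0, dropout < 1,
            terminal_site_dropout >= 0, terminal_site_dropout <= 1,
            noise_peaks >= 0L, mz_jitter >= 0)
  if (mz_jitter > 0.01)
    warning("mz_jitter above half the 0.02 Da matching tolerance")
  structure(list(dropout = dropout, noise_peaks = as.integer(noise_peaks),
                 mz_jitter = mz_jitter,
                 terminal_site_dropout = terminal_site_dropout,
                 terminal_width = as.integer(terminal_width)),
            class = "spectrum_sim_config")
}

#' Predict a simple in-silico spectrum for a peptide
#'
#' Emits the singly charged b/y ions of the peptide (at most `2 * (L - 1)`
#' peaks), applies optional per-ion dropout, m/z jitter and noise peaks,
#' and sets the precursor m/z consistent with the peptide neutral mass at
#' the requested charge. Uses the current RNG state.
#'
#' @param p A `peptide` of length >= 2.
#' @param scan_id Scan identifier for the resulting spectrum.
#' @param charge Precursor charge (default 2).
#' @param config A [spectrum_sim_config()].
#' @param mass_table Mass table.
#' @return A `spectrum`.
#' @export
predict_spectrum_simple <- function(p, scan_id, charge = 2L,
                                    config = spectrum_sim_config(),
                                    mass_table = default_mass_table()) {
  stopifnot(inherits(p, "peptide"))
  if (length(p) < 2L)
    stop("cannot predict a spectrum for a peptide shorter than 2 residues")
  L <- length(p)
  ions <- enumerate_theoretical_ions(p, mass_table, charges = 1L,
                                     losses = "none")
  # rank-based intensities: y series brighter than b, mid-sequence
  # fragments brighter than terminal ones
  centrality <- 1 - abs(ions$site - (L / 2)) / L
  intensity <- 1000 * (0.25 + 0.75 * centrality) *
    ifelse(ions$series == "y", 1.5, 1) * stats::runif(nrow(ions), 0.5, 1)
  keep <- stats::runif(nrow(ions)) >= config$dropout
  if (config$terminal_site_dropout > 0) {
    terminal <- ions$site <= config$terminal_width |
      ions$site >= L - config$terminal_width
    keep <- keep & !(terminal &
      stats::runif(nrow(ions)) < config$terminal_site_dropout)
  }
  mz <- ions$mz[keep]
  if (config$mz_jitter > 0)
    mz <- mz + stats::runif(length(mz), -config$mz_jitter, config$mz_jitter)
  peaks <- data.frame(mz = mz, intensity = intensity[keep])
  if (config$noise_peaks > 0L) {
    M <- peptide_neutral_mass(p, mass_table)
    noise <- data.frame(
      mz = stats::runif(config$noise_peaks, 100, M + mass_table$proton),
      intensity = stats::runif(config$noise_peaks, 10, 150))
    peaks <- rbind(peaks, noise)
  }
  precursor_mz <- (peptide_neutral_mass(p, mass_table) +
                     charge * mass_table$proton) / charge
  new_spectrum(scan_id, precursor_mz, charge, peaks)
}

#' Random tryptic-like peptide
#'
#' @param len Peptide length.
#' @param tryptic End with K or R (default TRUE).
#' @return A `peptide`.
#' @export
random_peptide <- function(len, tryptic = TRUE) {
  aa <- sample(amino_acid_letters(), len, replace = TRUE)
  if (tryptic && len > 0L) aa[len] <- sample(c("K", "R"), 1L)
  new_peptide(aa)
}

#' Generate a synthetic fixture dataset
#'
#' `n` random tryptic-like peptides with lengths uniform on
#' `length_range`, one in-silico spectrum each, and a ground-truth table
#' keyed by scan id. Deterministic for a given seed.
#'
#' @param n Number of spectra (>= 1).
#' @param seed Integer RNG seed; `NULL` uses the current state.
#' @param length_range Inclusive peptide length range (default 7..20).
#' @param charge Precursor charge for every spectrum.
#' @param config A [spectrum_sim_config()].
#' @param mass_table Mass table.
#' @return List: `spectra` (list of `spectrum`), `truth` (data frame with
#'   `scan_id`, `peptide`, `length`).
#' @export
generate_fixture_dataset <- function(n, seed = NULL,
                                     length_range = c(7L, 20L),
                                     charge = 2L,
                                     config = spectrum_sim_config(),
                                     mass_table = default_mass_table()) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  spectra <- vector("list", n)
  peps <- character(n)
  ids <- sprintf("S%05d", seq_len(n))
  for (i in seq_len(n)) {
    p <- random_peptide(lens[i])
    peps[i] <- format_peptide(p)
    spectra[[i]] <- predict_spectrum_simple(p, ids[i], charge, config,
                                            mass_table)
  }
  list(spectra = spectra,
       truth = data.frame(scan_id = ids, peptide = peps, length = lens,
                          stringsAsFactors = FALSE))
}

#' Substitute k residues of a peptide
#'
#' Exactly `k` distinct positions are substituted; each replacement is
#' drawn uniformly from the 19 other standard residues, so the Hamming
#' distance to the input is exactly `k`. Modifications on mutated
#' positions are dropped. Isobaric substitutions (e.g. L to I) are
#' allowed and will still register as matches under the 0.1 Da rule.
#'
#' @param p A `peptide`.
#' @param k Number of substitutions, `0 <= k <= length(p)`.
#' @return A `peptide` with attribute `mutated_positions` (sorted integer
#'   positions).
#' @export
mutate_peptide <- function(p, k) {
  stopifnot(inherits(p, "peptide"))
  k <- as.integer(k)
  if (k < 0L || k > length(p))
    stop("mutation count k must be between 0 and the peptide length")
  aa <- p$aa; mod <- p$mod
  pos <- if (k > 0L) sort(sample.int(length(p), k)) else integer()
  for (i in pos) {
    aa[i] <- sample(setdiff(amino_acid_letters(), aa[i]), 1L)
    mod[i] <- NA_character_
  }
  out <- new_peptide(aa, mod)
  attr(out, "mutated_positions") <- pos
  out
}

#' Generate the mutated-peptide benchmark datasets
#'
#' One dataset per mutation count `k` in `k_range`: every input peptide
#' long enough for `k` substitutions appears once with exactly `k`
#' mutations; shorter peptides are skipped and counted. Mutated positions
#' are recorded so positional accuracy needs no re-inference.
#' Deterministic by seed.
#'
#' @param peptides Character vector of peptide strings (or list of
#'   `peptide` objects).
#' @param k_range Integer mutation counts (default 1..10).
#' @param seed Integer RNG seed; `NULL` uses the current state.
#' @param mass_table Mass table.
#' @return Named list (`"k=1"`, ...) of data frames with columns
#'   `peptide_id`, `original`, `mutated`, `positions` (comma-separated)
#'   and attribute `n_skipped`.
#' @export
generate_mutation_datasets <- function(peptides, k_range = 1:10,
                                       seed = NULL,
                                       mass_table = default_mass_table()) {
  if (!is.null(seed)) set.seed(seed)
  parsed <- if (is.character(peptides))
    lapply(peptides, parse_peptide, mass_table = mass_table) else peptides
  out <- stats::setNames(vector("list", length(k_range)),
                         paste0("k=", k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    ok <- vapply(parsed, length, integer(1)) >= k
    rows <- lapply(which(ok), function(i) {
      m <- mutate_peptide(parsed[[i]], k)
      data.frame(peptide_id = i, original = format_peptide(parsed[[i]]),
                 mutated = format_peptide(m),
                 positions = paste(attr(m, "mutated_positions"),
                                   collapse = ","),
                 stringsAsFactors = FALSE)
    })
    ds <- do.call(rbind, rows)
    rownames(ds) <- NULL
    attr(ds, "n_skipped") <- sum(!ok)
    out[[ki]] <- ds
  }
  out
}

#' Accuracy of mutated residues by position class
#'
#' For each PSM, the de novo peptide is aligned to the (mutated) ground
#' truth and a mutated position counts as recovered when the alignment
#' matches some de novo residue to it. Positions are classed as first-3,
#' middle-3 (positions `ceiling(L/2) - 1 .. ceiling(L/2) + 1`) or last-3;
#' peptides shorter than 9 residues — too short for the three classes to
#' be disjoint — are excluded and counted. Positions outside all classes
#' are ignored in the class table. When `fixed_length` is given, a
#' per-absolute-position table is also returned for peptides of exactly
#' that length.
#'
#' @param dn_psms De novo PSM data frame (`scan_id`, `peptide`).
#' @param truth Data frame with `scan_id`, `peptide` (the mutated ground
#'   truth) and `positions` (comma-separated mutated positions).
#' @param mass_table Mass table.
#' @param fixed_length Optional length for the per-position table
#'   (e.g. 15).
#' @return List: `classes` (data frame `class`, `n`, `matched`,
#'   `accuracy`), `by_position` (or `NULL`), `n_excluded_short`.
#' @export
positional_accuracy <- function(dn_psms, truth,
                                mass_table = default_mass_table(),
                                fixed_length = NULL) {
  dn_lookup <- stats::setNames(dn_psms$peptide, dn_psms$scan_id)
  class_n <- c(first3 = 0L, middle3 = 0L, last3 = 0L)
  class_m <- c(first3 = 0L, middle3 = 0L, last3 = 0L)
  pos_n <- pos_m <- NULL
  if (!is.null(fixed_length)) pos_n <- pos_m <- integer(fixed_length)
  n_short <- 0L
  for (r in seq_len(nrow(truth))) {
    scan <- truth$scan_id[r]
    if (!(scan %in% names(dn_lookup))) next
    gt <- parse_peptide(truth$peptide[r], mass_table)
    L <- length(gt)
    mut <- as.integer(strsplit(truth$positions[r], ",")[[1]])
    mut <- mut[!is.na(mut)]
    if (length(mut) == 0L) next
    dn <- parse_peptide(dn_lookup[[scan]], mass_table)
    matched_gt <- align_amino_acids(dn, gt, mass_table)$pairs$gt_pos
    if (!is.null(fixed_length) && L == fixed_length) {
      for (pp in mut) {
        pos_n[pp] <- pos_n[pp] + 1L
        pos_m[pp] <- pos_m[pp] + (pp %in% matched_gt)
      }
    }
    if (L < 9L) { n_short <- n_short + 1L; next }
    mid <- ceiling(L / 2)
    for (pp in mut) {
      cls <- if (pp <= 3L) "first3"
             else if (pp >= L - 2L) "last3"
             else if (pp >= mid - 1L && pp <= mid + 1L) "middle3"
             else NA_character_
      if (is.na(cls)) next
      class_n[cls] <- class_n[cls] + 1L
      class_m[cls] <- class_m[cls] + (pp %in% matched_gt)
    }
  }
  classes <- data.frame(class = names(class_n), n = unname(class_n),
                        matched = unname(class_m),
                        accuracy = unname(ifelse(class_n > 0,
                                                 class_m / class_n, NaN)),
                        stringsAsFactors = FALSE)
  by_position <- if (!is.null(fixed_length))
    data.frame(position = seq_len(fixed_length), n = pos_n, matched = pos_m,
               accuracy = ifelse(pos_n > 0, pos_m / pos_n, NaN))
  else NULL
  list(classes = classes, by_position = by_position,
       n_excluded_short = n_short)
}
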