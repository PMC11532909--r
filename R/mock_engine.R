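# A controllable stand-in for a de novo sequencing engine. It starts from
# the ground-truth peptide of each scan and corrupts it in ways tied to
# the spectrum evidence, so accuracy and FDR behaviour can be dialled and
# predicted in tests. The engine is origin-blind: decoy spectra are
# processed exactly like targets, through their linked target scan's
# ground truth.

#' Mock engine configuration
#'
#' @param residue_error_rate Per-residue probability of a random
#'   substitution (models plain sequencing error).
#' @param swap_rate Per-adjacent-pair probability of a transposition,
#'   independent of the spectrum.
#' @param missing_site_swap_rate Probability of swapping the two residues
#'   flanking a fragmentation site that has no matched b/y ion in the
#'   spectrum (default 0.5): without the site ion the local residue order
#'   is unobservable, which is the mechanism behind terminal swaps.
#' @param recall_rate When a reference (e.g. unmutated) peptide is
#'   supplied, the probability of recalling the reference residue instead
#'   of the ground-truth residue at positions where the two differ —
#'   a knob for training-data memorization.
#' @param score_noise_sd Standard deviation of Gaussian noise added to
#'   the score (score scale is 0-100).
#' @return List of class `mock_engine_config`.
#' @export
mock_engine_config <- function(residue_error_rate = 0.02,
                               swap_rate = 0.01,
                               missing_site_swap_rate = 0.5,
                               recall_rate = 0.35,
                               score_noise_sd = 2) {
  stopifnot(residue_error_rate >= 0, residue_error_rate <= 1,
            swap_rate >= 0, swap_rate <= 1,
            missing_site_swap_rate >= 0, missing_site_swap_rate <= 1,
            recall_rate >= 0, recall_rate <= 1, score_noise_sd >= 0)
  structure(list(residue_error_rate = residue_error_rate,
                 swap_rate = swap_rate,
                 missing_site_swap_rate = missing_site_swap_rate,
                 recall_rate = recall_rate,
                 score_noise_sd = score_noise_sd),
            class = "mock_engine_config")
}

#' Mock de novo sequencing over a set of spectra
#'
#' For every spectrum, the linked ground-truth peptide is corrupted:
#' (1) optional recall of reference residues where ground truth and
#' reference differ; (2) adjacent swaps at fragmentation sites with no
#' matched singly charged b/y ion in the spectrum; (3) independent random
#' residue substitutions; (4) independent adjacent transpositions. The
#' score is the percentage of the prediction's singly charged b/y ions
#' matched in the spectrum (0.02 Da), plus bounded Gaussian noise, clamped
#' to [0, 100]. With all rates zero and complete spectra, predictions
#' equal the ground truth and scores are maximal.
#'
#' Decoy spectra (scan id starting with `decoy_prefix`) are handled
#' identically via their target scan's ground truth; their origin is
#' recorded as `"decoy"`.
#'
#' @param spectra List of `spectrum` objects (targets and/or decoys).
#' @param truth Ground-truth data frame (`scan_id`, `peptide`) keyed by
#'   target scan id; must cover all scans.
#' @param config A [mock_engine_config()].
#' @param reference Optional named character vector (target scan id ->
#'   reference peptide string) enabling the recall mechanism.
#' @param mass_table Mass table.
#' @param tol Fragment tolerance (Da) for evidence and scoring.
#' @param decoy_prefix Decoy scan-id prefix.
#' @return PSM data frame: `scan_id`, `origin`, `peptide`, `score`.
#' @export
mock_denovo <- function(spectra, truth, config = mock_engine_config(),
                        reference = NULL,
                        mass_table = default_mass_table(), tol = 0.02,
                        decoy_prefix = "DECOY_") {
  gt_lookup <- stats::setNames(truth$peptide, truth$scan_id)
  letters20 <- amino_acid_letters()
  rows <- lapply(spectra, function(s) {
    is_decoy <- startsWith(s$scan_id, decoy_prefix)
    base <- if (is_decoy) sub(paste0("^", decoy_prefix), "", s$scan_id)
            else s$scan_id
    if (!(base %in% names(gt_lookup)))
      stop("ground truth does not cover scan id: ", base)
    gt <- parse_peptide(gt_lookup[[base]], mass_table)
    L <- length(gt)
    aa <- gt$aa
    mod <- gt$mod
    if (!is.null(reference) && base %in% names(reference) &&
        config$recall_rate > 0) {
      ref <- parse_peptide(reference[[base]], mass_table)
      if (length(ref) == L) {
        diff_pos <- which(ref$aa != aa)
        recall <- diff_pos[stats::runif(length(diff_pos)) <
                             config$recall_rate]
        aa[recall] <- ref$aa[recall]
        mod[recall] <- NA_character_
      }
    }
    if (L >= 2L) {
      gt_ions <- enumerate_theoretical_ions(gt, mass_table, charges = 1L,
                                            losses = "none")
      supported <- unique(gt_ions$site[
        match_ions(s, gt_ions, tol)$matched_pairs$ion])
      missing_sites <- setdiff(seq_len(L - 1L), supported)
      for (k in missing_sites) {
        if (stats::runif(1) < config$missing_site_swap_rate) {
          aa[c(k, k + 1L)] <- aa[c(k + 1L, k)]
          mod[c(k, k + 1L)] <- mod[c(k + 1L, k)]
        }
      }
    }
    subst <- which(stats::runif(L) < config$residue_error_rate)
    for (k in subst) {
      aa[k] <- sample(setdiff(letters20, aa[k]), 1L)
      mod[k] <- NA_character_
    }
    if (L >= 2L && config$swap_rate > 0) {
      for (k in which(stats::runif(L - 1L) < config$swap_rate)) {
        aa[c(k, k + 1L)] <- aa[c(k + 1L, k)]
        mod[c(k, k + 1L)] <- mod[c(k + 1L, k)]
      }
    }
    pred <- new_peptide(aa, mod, mass_table)
    score <- if (L >= 2L) {
      pred_ions <- enumerate_theoretical_ions(pred, mass_table,
                                              charges = 1L, losses = "none")
      100 * match_ions(s, pred_ions, tol)$matched_ion_count / nrow(pred_ions)
    } else 0
    score <- min(100, max(0, score + stats::rnorm(1, 0,
                                                  config$score_noise_sd)))
    data.frame(scan_id = s$scan_id,
               origin = if (is_decoy) "decoy" else "target",
               peptide = format_peptide(pred), score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
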