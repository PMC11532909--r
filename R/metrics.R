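# Accuracy metrics for de novo results against ground truth. All three
# dataset-level metrics are micro-averages: numerators and denominators
# are summed over PSMs first, then divided.

#' Fragment-ion matching of ground-truth and de novo peptides on a spectrum
#'
#' Enumerates the 12 theoretical ion categories for both peptides, matches
#' them against the spectrum peaks at `tol`, and reports matched-ion counts
#' plus the shared count. By default a matched-ion count is the number of
#' distinct matched *peaks* (a peak satisfying both a b and a y ion counts
#' once) and the shared count is the size of the intersection of the two
#' matched-peak sets — peak-level sharing is what the spectrum evidences.
#' `count = "ions"` instead counts theoretical ions, with an ion shared
#' when its matched peak is also matched by the other peptide.
#'
#' @param s A `spectrum`.
#' @param gt Ground-truth `peptide`.
#' @param dn De novo `peptide` (may be empty).
#' @param mass_table Mass table.
#' @param tol Fragment tolerance in Da.
#' @param count `"peaks"` (default) or `"ions"`.
#' @return List with integers `gt_matched`, `dn_matched`, `shared_matched`.
#' @export
evaluate_fragment_ions <- function(s, gt, dn,
                                   mass_table = default_mass_table(),
                                   tol = 0.02, count = c("peaks", "ions")) {
  count <- match.arg(count)
  m_gt <- match_ions(s, enumerate_theoretical_ions(gt, mass_table), tol)
  if (length(dn) == 0L) {
    gt_n <- if (count == "peaks") length(m_gt$matched_peaks) else
      m_gt$matched_ion_count
    return(list(gt_matched = gt_n, dn_matched = 0L, shared_matched = 0L))
  }
  m_dn <- match_ions(s, enumerate_theoretical_ions(dn, mass_table), tol)
  if (count == "peaks") {
    shared <- intersect(m_gt$matched_peaks, m_dn$matched_peaks)
    list(gt_matched = length(m_gt$matched_peaks),
         dn_matched = length(m_dn$matched_peaks),
         shared_matched = length(shared))
  } else {
    list(gt_matched = m_gt$matched_ion_count,
         dn_matched = m_dn$matched_ion_count,
         shared_matched = sum(m_gt$matched_pairs$peak %in%
                                m_dn$matched_peaks))
  }
}

#' Mass-based alignment of a de novo peptide against ground truth
#'
#' Simultaneous N-to-C iteration with one cursor per peptide. The cursors
#' are compared through cumulative residue masses: when the cumulative
#' masses agree within `prefix_tol` the residues are compared, counted as
#' matched when their masses differ by less than `aa_tol`, and both cursors
#' advance; otherwise only the cursor with the smaller cumulative mass
#' advances (exact ties advance both). The approximate match absorbs
#' isobaric pairs (I/L, N(Deamidation)/D, K/Q, Q(Deamidation)/E,
#' M(Oxidation)/F) that high-resolution instruments cannot separate.
#' The peptide is matched when every de novo residue matched.
#'
#' @param dn De novo `peptide` (may be empty).
#' @param gt Ground-truth `peptide`.
#' @param mass_table Mass table.
#' @param aa_tol Residue-mass tolerance in Da (strict `<`).
#' @param prefix_tol Cumulative-mass tolerance in Da (strict `<`).
#' @return List: `aa_matched` (matched de novo residues),
#'   `peptide_match` (logical), and `pairs` (data frame of matched
#'   `dn_pos`/`gt_pos` index pairs, used for positional analyses).
#' @export
align_amino_acids <- function(dn, gt, mass_table = default_mass_table(),
                              aa_tol = 0.1, prefix_tol = 0.5) {
  stopifnot(inherits(dn, "peptide"), inherits(gt, "peptide"))
  m_d <- residue_masses(dn, mass_table)
  m_g <- residue_masses(gt, mass_table)
  cum_d <- cumsum(m_d)
  cum_g <- cumsum(m_g)
  i <- 1L; j <- 1L
  dn_pos <- integer(); gt_pos <- integer()
  while (i <= length(m_d) && j <= length(m_g)) {
    if (abs(cum_d[i] - cum_g[j]) < prefix_tol) {
      if (abs(m_d[i] - m_g[j]) < aa_tol) {
        dn_pos <- c(dn_pos, i); gt_pos <- c(gt_pos, j)
      }
      i <- i + 1L; j <- j + 1L
    } else if (cum_d[i] < cum_g[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(aa_matched = length(dn_pos),
       peptide_match = length(dn) > 0L && length(dn_pos) == length(dn),
       pairs = data.frame(dn_pos = dn_pos, gt_pos = gt_pos))
}

#' Evaluate a set of de novo PSMs against ground truth
#'
#' Joins de novo predictions and ground-truth peptides on scan id, runs
#' fragment-ion matching and amino-acid alignment per PSM, and returns one
#' evaluation row per ground-truth scan. Scans where the tool produced no
#' prediction (empty peptide, or no row at all) contribute zeros to every
#' numerator and full denominators.
#'
#' @param spectra List of `spectrum` objects (or a list named by scan id).
#' @param dn_psms PSM data frame (`scan_id`, `peptide`, ...) of de novo
#'   predictions.
#' @param gt_psms PSM data frame of ground-truth peptides; every row is
#'   evaluated.
#' @param mass_table Mass table.
#' @param tol Fragment tolerance (Da).
#' @param count Matched-ion counting mode, see [evaluate_fragment_ions()].
#' @return Data frame with one row per ground-truth PSM: `scan_id`,
#'   `gt_len`, `gt_matched`, `dn_matched`, `shared_matched`,
#'   `aa_total_gt`, `aa_matched`, `peptide_match`.
#' @export
evaluate_psms <- function(spectra, dn_psms, gt_psms,
                          mass_table = default_mass_table(),
                          tol = 0.02, count = c("peaks", "ions")) {
  count <- match.arg(count)
  spec_ids <- vapply(spectra, `[[`, "", "scan_id")
  dn_lookup <- stats::setNames(dn_psms$peptide, dn_psms$scan_id)
  rows <- lapply(seq_len(nrow(gt_psms)), function(r) {
    scan <- gt_psms$scan_id[r]
    k <- match(scan, spec_ids)
    if (is.na(k)) stop("no spectrum for ground-truth scan id: ", scan)
    gt <- parse_peptide(gt_psms$peptide[r], mass_table)
    dn_txt <- if (scan %in% names(dn_lookup)) dn_lookup[[scan]] else ""
    dn <- parse_peptide(dn_txt, mass_table)
    fr <- evaluate_fragment_ions(spectra[[k]], gt, dn, mass_table, tol, count)
    al <- align_amino_acids(dn, gt, mass_table)
    data.frame(scan_id = scan, gt_len = length(gt),
               gt_matched = fr$gt_matched, dn_matched = fr$dn_matched,
               shared_matched = fr$shared_matched,
               aa_total_gt = length(gt), aa_matched = al$aa_matched,
               peptide_match = al$peptide_match,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Micro-averaged accuracy report
#'
#' Fragment-ion accuracy = sum(shared) / sum(ground-truth matched ions);
#' amino-acid accuracy = sum(matched residues) / sum(ground-truth
#' residues); peptide accuracy = matched peptides / ground-truth peptides.
#' Ratios are of summed totals, never means of per-PSM ratios.
#'
#' @param evals Evaluation data frame from [evaluate_psms()], non-empty.
#' @return Object of class `accuracy_report`: the three ratios plus the
#'   summed numerators and denominators.
#' @export
aggregate_accuracy <- function(evals) {
  if (!is.data.frame(evals) || nrow(evals) == 0L)
    stop("cannot aggregate an empty evaluation set")
  totals <- list(
    shared_matched = sum(evals$shared_matched),
    gt_matched = sum(evals$gt_matched),
    aa_matched = sum(evals$aa_matched),
    aa_total_gt = sum(evals$aa_total_gt),
    peptides_matched = sum(evals$peptide_match),
    peptides_total = nrow(evals)
  )
  structure(list(
    fragment_ion_accuracy = totals$shared_matched / totals$gt_matched,
    amino_acid_accuracy = totals$aa_matched / totals$aa_total_gt,
    peptide_accuracy = totals$peptides_matched / totals$peptides_total,
    totals = totals
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy: fragment ion %.4f  amino acid %.4f  peptide %.4f  (n=%d PSMs)\n",
    x$fragment_ion_accuracy, x$amino_acid_accuracy, x$peptide_accuracy,
    x$totals$peptides_total))
  invisible(x)
}

#' Accuracy stratified by ground-truth peptide length
#'
#' Partitions the evaluations into length bins and micro-averages within
#' each bin. Bin edges must be strictly increasing (bins cannot overlap);
#' every observed length must fall in a bin. Bins are left-open,
#' right-closed except the first, which includes its lower edge. Empty
#' bins report zero denominators and `NaN` ratios.
#'
#' @param evals Evaluation data frame with a `gt_len` column.
#' @param breaks Numeric vector of bin edges covering all observed lengths.
#' @return Data frame, one row per bin: the bin label, PSM count, the three
#'   accuracies, and the summed numerators/denominators.
#' @export
stratify_by_length <- function(evals, breaks) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("length bins must be strictly increasing (non-overlapping)")
  bins <- cut(evals$gt_len, breaks = breaks, include.lowest = TRUE)
  if (anyNA(bins))
    stop("length bins do not cover all observed peptide lengths")
  rows <- lapply(levels(bins), function(b) {
    sub <- evals[bins == b, , drop = FALSE]
    if (nrow(sub) == 0L) {
      data.frame(bin = b, n_psms = 0L, fragment_ion_accuracy = NaN,
                 amino_acid_accuracy = NaN, peptide_accuracy = NaN,
                 shared_matched = 0L, gt_matched = 0L,
                 aa_matched = 0L, aa_total_gt = 0L, peptides_matched = 0L)
    } else {
      rep <- aggregate_accuracy(sub)
      data.frame(bin = b, n_psms = nrow(sub),
                 fragment_ion_accuracy = rep$fragment_ion_accuracy,
                 amino_acid_accuracy = rep$amino_acid_accuracy,
                 peptide_accuracy = rep$peptide_accuracy,
                 shared_matched = rep$totals$shared_matched,
                 gt_matched = rep$totals$gt_matched,
                 aa_matched = rep$totals$aa_matched,
                 aa_total_gt = rep$totals$aa_total_gt,
                 peptides_matched = rep$totals$peptides_matched)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
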