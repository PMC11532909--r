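# Target-decoy competition and FDR estimation for de novo PSMs, plus the
# fragment-ion-coverage "true FDR" used to validate the estimate when
# ground truth is available.

#' Pair target and decoy PSMs by scan id
#'
#' Decoy scan ids are linked to targets by the `decoy_prefix`. Every
#' target scan yields one pair; a scan for which the tool returned no
#' decoy PSM gets an absent decoy. Decoy scans with no target counterpart
#' are an error (orphans are listed).
#'
#' @param target_psms,decoy_psms PSM data frames (`scan_id`, `peptide`,
#'   `score`).
#' @param decoy_prefix Prefix on decoy scan ids.
#' @return Data frame with one row per target scan: `scan_id`,
#'   `target_peptide`, `target_score`, `decoy_present`, `decoy_peptide`,
#'   `decoy_score`.
#' @export
pair_by_scan <- function(target_psms, decoy_psms, decoy_prefix = "DECOY_") {
  d_base <- sub(paste0("^", decoy_prefix), "", decoy_psms$scan_id)
  orphans <- setdiff(d_base, target_psms$scan_id)
  if (length(orphans) > 0L)
    stop("decoy scan(s) with no target counterpart: ",
         paste(utils::head(orphans, 10L), collapse = ", "))
  j <- match(target_psms$scan_id, d_base)
  data.frame(
    scan_id = target_psms$scan_id,
    target_peptide = target_psms$peptide,
    target_score = target_psms$score,
    decoy_present = !is.na(j),
    decoy_peptide = ifelse(is.na(j), "", decoy_psms$peptide[j]),
    decoy_score = ifelse(is.na(j), NA_real_, decoy_psms$score[j]),
    stringsAsFactors = FALSE
  )
}

#' Target-decoy competition
#'
#' `scan_specific`: per scan, the higher-scoring of the target and decoy
#' PSMs is kept (score ties go to the target). `keep_both`: both PSMs are
#' kept, so the competition space is the whole dataset and the output has
#' up to twice as many records as scans — the more stringent estimator.
#' A side with an empty peptide (no prediction) loses to a present side;
#' scans where both sides are absent are dropped and counted in the
#' `dropped_scans` attribute.
#'
#' @param pairs Data frame from [pair_by_scan()].
#' @param mode `"keep_both"` (default) or `"scan_specific"`.
#' @param decoy_prefix Prefix used to reconstruct decoy scan ids.
#' @return PSM data frame (`scan_id`, `origin`, `peptide`, `score`) with
#'   attribute `dropped_scans`.
#' @export
compete <- function(pairs, mode = c("keep_both", "scan_specific"),
                    decoy_prefix = "DECOY_") {
  mode <- match.arg(mode)
  t_empty <- !nzchar(pairs$target_peptide)
  d_empty <- !pairs$decoy_present | !nzchar(pairs$decoy_peptide)
  both_absent <- t_empty & d_empty
  t_rec <- data.frame(scan_id = pairs$scan_id, origin = "target",
                      peptide = pairs$target_peptide,
                      score = pairs$target_score, stringsAsFactors = FALSE)
  d_rec <- data.frame(scan_id = paste0(decoy_prefix, pairs$scan_id),
                      origin = "decoy", peptide = pairs$decoy_peptide,
                      score = pairs$decoy_score, stringsAsFactors = FALSE)
  if (mode == "keep_both") {
    out <- rbind(t_rec[!t_empty, ], d_rec[!d_empty, ])
  } else {
    decoy_wins <- (!d_empty & t_empty) |
      (!d_empty & !t_empty & pairs$decoy_score > pairs$target_score)
    keep_t <- !both_absent & !decoy_wins
    out <- rbind(t_rec[keep_t, ], d_rec[!both_absent & decoy_wins, ])
  }
  rownames(out) <- NULL
  attr(out, "dropped_scans") <- sum(both_absent)
  out
}

#' Estimated FDR curve from competed PSMs
#'
#' At each score cutoff `c`, with `D` decoy and `T` target PSMs scoring at
#' least `c`, the estimated FDR is `D / (D + T)` — the proportion of decoy
#' PSMs among those above the cutoff (default) — or the classical `D / T`
#' with `denominator = "targets"`. Default cutoffs are 200 evenly spaced
#' quantiles of the observed scores.
#'
#' @param psms PSM data frame with `origin` and `score`, non-empty.
#' @param cutoffs Numeric score cutoffs; `NULL` for score quantiles.
#' @param n_cutoffs Number of quantile cutoffs when `cutoffs` is `NULL`.
#' @param denominator `"all"` for D/(D+T), `"targets"` for D/T.
#' @return Data frame of class `fdr_curve`: `cutoff`, `n_target`,
#'   `n_decoy`, `n_psms_above`, `estimated_fdr`.
#' @export
estimated_fdr_curve <- function(psms, cutoffs = NULL, n_cutoffs = 200L,
                                denominator = c("all", "targets")) {
  denominator <- match.arg(denominator)
  if (!is.data.frame(psms) || nrow(psms) == 0L)
    stop("cannot estimate FDR from an empty PSM set")
  stopifnot(all(psms$origin %in% c("target", "decoy")))
  if (is.null(cutoffs))
    cutoffs <- sort(unique(stats::quantile(
      psms$score, probs = seq(0, 1, length.out = n_cutoffs), names = FALSE)))
  is_decoy <- psms$origin == "decoy"
  n_decoy <- vapply(cutoffs, function(cc)
    sum(is_decoy & psms$score >= cc), integer(1))
  n_target <- vapply(cutoffs, function(cc)
    sum(!is_decoy & psms$score >= cc), integer(1))
  total <- n_decoy + n_target
  est <- switch(denominator,
    all = ifelse(total > 0L, n_decoy / total, NA_real_),
    targets = ifelse(n_target > 0L, n_decoy / n_target, NA_real_))
  out <- data.frame(cutoff = cutoffs, n_target = n_target,
                    n_decoy = n_decoy, n_psms_above = total,
                    estimated_fdr = est)
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Classify one de novo PSM as correct by fragment-ion coverage
#'
#' Set 1 is the peaks matched by the ground-truth peptide's theoretical
#' ions; set 2 the peaks matched by the de novo peptide's. The PSM is
#' correct when set 2 covers more than `coverage` (strictly) of set 1.
#' When set 1 is empty the spectrum carries no usable fragment evidence
#' for the ground truth, and it is unreasonable to demand the sequence
#' from a de novo tool: the PSM is excluded (`NA`).
#'
#' @param s A `spectrum`.
#' @param gt Ground-truth `peptide`.
#' @param dn De novo `peptide` (may be empty).
#' @param mass_table Mass table.
#' @param coverage Required covered fraction Y (default 0.9, strict `>`).
#' @param tol Fragment tolerance in Da.
#' @return `TRUE`, `FALSE`, or `NA` when set 1 is empty.
#' @export
classify_correct <- function(s, gt, dn, mass_table = default_mass_table(),
                             coverage = 0.9, tol = 0.02) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("coverage threshold must be in (0, 1]")
  set1 <- match_ions(s, enumerate_theoretical_ions(gt, mass_table),
                     tol)$matched_peaks
  if (length(set1) == 0L) return(NA)
  if (length(dn) == 0L) return(FALSE)
  set2 <- match_ions(s, enumerate_theoretical_ions(dn, mass_table),
                     tol)$matched_peaks
  length(intersect(set1, set2)) > coverage * length(set1)
}

#' True-FDR (false peptide rate) curve
#'
#' For target PSMs with ground truth, each prediction is classified via
#' [classify_correct()]; at each cutoff the true FDR is the fraction of
#' false classifications among classified PSMs scoring at least the
#' cutoff. PSMs whose ground truth matches no peaks are excluded.
#'
#' @param psms Target PSM data frame (`scan_id`, `peptide`, `score`).
#' @param gt_table Ground-truth data frame (`scan_id`, `peptide`); must be
#'   non-empty.
#' @param spectra List of target `spectrum` objects covering the scans.
#' @param cutoffs Score cutoffs (share these with the estimated curve when
#'   validating).
#' @param mass_table Mass table.
#' @param coverage Coverage threshold Y.
#' @param tol Fragment tolerance (Da).
#' @return Data frame of class `fdr_curve`: `cutoff`, `n_psms_above`
#'   (classified PSMs at or above the cutoff), `true_fdr`; attribute
#'   `n_excluded` counts PSMs with empty set 1.
#' @export
true_fdr_curve <- function(psms, gt_table, spectra, cutoffs,
                           mass_table = default_mass_table(),
                           coverage = 0.9, tol = 0.02) {
  if (!is.data.frame(gt_table) || nrow(gt_table) == 0L)
    stop("no ground-truth rows: cannot compute a true FDR")
  spec_ids <- vapply(spectra, `[[`, "", "scan_id")
  gt_lookup <- stats::setNames(gt_table$peptide, gt_table$scan_id)
  psms <- psms[psms$scan_id %in% names(gt_lookup), , drop = FALSE]
  if (nrow(psms) == 0L)
    stop("no PSMs with ground truth: cannot compute a true FDR")
  correct <- vapply(seq_len(nrow(psms)), function(r) {
    scan <- psms$scan_id[r]
    k <- match(scan, spec_ids)
    if (is.na(k)) stop("no spectrum for scan id: ", scan)
    classify_correct(spectra[[k]],
                     parse_peptide(gt_lookup[[scan]], mass_table),
                     parse_peptide(psms$peptide[r], mass_table),
                     mass_table, coverage, tol)
  }, logical(1))
  keep <- !is.na(correct)
  scores <- psms$score[keep]
  false <- !correct[keep]
  n_above <- vapply(cutoffs, function(cc) sum(scores >= cc), integer(1))
  n_false <- vapply(cutoffs, function(cc) sum(false & scores >= cc),
                    integer(1))
  out <- data.frame(cutoff = cutoffs, n_psms_above = n_above,
                    true_fdr = ifelse(n_above > 0L, n_false / n_above,
                                      NA_real_))
  class(out) <- c("fdr_curve", "data.frame")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Validate an estimated FDR curve against the true FDR
#'
#' Joins the two curves on their (identical) cutoffs, reports the signed
#' gap (estimated - true) per cutoff, and summarizes the maximum absolute
#' gap over the low-FDR region (true FDR at most `fdr_region`). The curve
#' is labelled `"accurate"` when that maximum is within `accurate_tol`,
#' otherwise `"underestimation"` (estimate below truth at the worst
#' cutoff) or `"overestimation"`.
#'
#' @param est Curve from [estimated_fdr_curve()].
#' @param truth Curve from [true_fdr_curve()] at the same cutoffs.
#' @param fdr_region Upper bound on true FDR for the summary region.
#' @param accurate_tol Gap magnitude considered accurate.
#' @return List: `table` (cutoff, estimated, true, gap), `max_abs_gap`,
#'   `label`.
#' @export
validate_fdr <- function(est, truth, fdr_region = 0.2, accurate_tol = 0.05) {
  if (length(est$cutoff) != length(truth$cutoff) ||
      any(abs(est$cutoff - truth$cutoff) > 1e-9))
    stop("estimated and true FDR curves must share the same cutoffs")
  tab <- data.frame(cutoff = est$cutoff,
                    estimated_fdr = est$estimated_fdr,
                    true_fdr = truth$true_fdr,
                    gap = est$estimated_fdr - truth$true_fdr)
  region <- !is.na(tab$true_fdr) & !is.na(tab$estimated_fdr) &
    tab$true_fdr <= fdr_region
  if (!any(region)) {
    return(list(table = tab, max_abs_gap = NA_real_, label = "undefined"))
  }
  gaps <- tab$gap[region]
  worst <- which.max(abs(gaps))
  max_abs_gap <- abs(gaps[worst])
  label <- if (max_abs_gap <= accurate_tol) "accurate"
           else if (gaps[worst] < 0) "underestimation" else "overestimation"
  list(table = tab, max_abs_gap = max_abs_gap, label = label)
}

#' Pick the removal percentage whose estimate best tracks the truth
#'
#' @param validations Named list of [validate_fdr()] results, one per
#'   removal fraction (names are the fractions).
#' @return Data frame with one row per sweep point (`X`, `max_abs_gap`,
#'   `label`) and attribute `best` naming the minimizing X.
#' @export
best_removal_fraction <- function(validations) {
  out <- data.frame(
    X = names(validations),
    max_abs_gap = vapply(validations, `[[`, numeric(1), "max_abs_gap"),
    label = vapply(validations, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  ok <- !is.na(out$max_abs_gap)
  attr(out, "best") <- if (any(ok)) out$X[ok][which.min(out$max_abs_gap[ok])]
                       else NA_character_
  out
}

#' Number of PSMs identifiable at an FDR level
#'
#' The maximum `n_psms_above` over cutoffs whose estimated FDR is at most
#' `level`; 0 when no cutoff qualifies. Non-decreasing in `level`.
#'
#' @param curve An estimated `fdr_curve`.
#' @param level FDR level in (0, 1].
#' @return Integer PSM count.
#' @export
psms_at_fdr <- function(curve, level) {
  if (!is.numeric(level) || level <= 0 || level > 1)
    stop("FDR level must be in (0, 1]")
  ok <- !is.na(curve$estimated_fdr) & curve$estimated_fdr <= level
  if (!any(ok)) return(0L)
  max(curve$n_psms_above[ok])
}

#' Full FDR estimation-and-validation sweep
#'
#' Runs the complete validation workflow on spectra with known ground
#' truth: a de novo engine is applied to the targets once; for every
#' (strategy, removal fraction) a decoy set is generated, the engine is
#' applied to the decoys, target-decoy competition is performed, and the
#' estimated FDR curve is validated against the fragment-ion-coverage
#' true FDR. Because the true FDR is a rate among target PSMs, the
#' default estimator here is decoys/targets (`denominator = "targets"`),
#' the estimator on the same scale.
#'
#' @param spectra Target `spectrum` list.
#' @param truth Ground-truth data frame (`scan_id`, `peptide`).
#' @param denovo_fun Function `(spectra) -> PSM data frame`; applied to
#'   targets and to each decoy set (origin-blind engines only).
#' @param Xs Removal fractions to sweep.
#' @param strategies Removal strategies to sweep.
#' @param mode Competition mode for the estimated curve.
#' @param denominator Estimator denominator, see [estimated_fdr_curve()].
#' @param seed Optional RNG seed set once before the sweep.
#' @param mass_table,coverage,tol,fdr_region Passed to the curve
#'   functions.
#' @return List: `truth_curve`, `sweep` (data frame from
#'   [best_removal_fraction()] with a `strategy` column and attribute
#'   `best`), `validations` (named list of [validate_fdr()] results),
#'   `curves` (named list of estimated curves).
#' @export
fdr_calibration_sweep <- function(spectra, truth, denovo_fun,
                                  Xs = seq(0.1, 0.9, by = 0.1),
                                  strategies = c("random", "intensity_mass"),
                                  mode = "keep_both",
                                  denominator = "targets",
                                  seed = NULL,
                                  mass_table = default_mass_table(),
                                  coverage = 0.9, tol = 0.02,
                                  fdr_region = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  t_psms <- denovo_fun(spectra)
  cutoffs <- sort(unique(stats::quantile(
    t_psms$score, probs = seq(0, 1, length.out = 200), names = FALSE)))
  truth_curve <- true_fdr_curve(t_psms, truth, spectra, cutoffs,
                                mass_table, coverage, tol)
  validations <- list()
  curves <- list()
  strat_of <- character()
  for (strat in strategies) {
    for (X in Xs) {
      key <- sprintf("%s_%d", strat, round(X * 100))
      dec <- generate_decoy_dataset(spectra, strategy = strat, X = X,
                                    mass_table = mass_table)
      d_psms <- denovo_fun(dec$decoys)
      comp <- compete(pair_by_scan(t_psms, d_psms), mode = mode)
      est <- estimated_fdr_curve(comp, cutoffs = cutoffs,
                                 denominator = denominator)
      curves[[key]] <- est
      validations[[key]] <- validate_fdr(est, truth_curve,
                                         fdr_region = fdr_region)
      strat_of[key] <- strat
    }
  }
  sweep <- best_removal_fraction(validations)
  sweep$strategy <- unname(strat_of[sweep$X])
  list(truth_curve = truth_curve, sweep = sweep,
       validations = validations, curves = curves)
}
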