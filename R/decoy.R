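# Decoy spectrum generation. A decoy keeps its target's precursor line and
# exact peak count: a fraction of peaks is removed and replaced by "noise"
# peaks that are real peaks pooled from the whole dataset, so target and
# decoy peaks share one distribution.

#' Pool all peaks of a dataset
#'
#' @param spectra Non-empty list of `spectrum` objects.
#' @return Data frame (`mz`, `intensity`) with one row per peak across all
#'   spectra; order-independent content.
#' @export
build_peak_pool <- function(spectra) {
  if (length(spectra) == 0L) stop("cannot build a peak pool from no spectra")
  pool <- do.call(rbind, lapply(spectra, function(s) s$peaks))
  rownames(pool) <- NULL
  if (nrow(pool) == 0L) stop("spectra contain no peaks to pool")
  pool
}

#' Random-removal decoy for one spectrum
#'
#' Removes `round(X * n)` of the spectrum's `n` peaks uniformly without
#' replacement (halves round away from zero) and injects the same number
#' of noise peaks sampled with replacement from the dataset-wide pool, so
#' the decoy has exactly `n` peaks. Precursor m/z and charge are copied
#' verbatim; the scan id and title get `scan_prefix`. Uses the current R
#' RNG state; seed at the dataset level for determinism.
#'
#' @param s Target `spectrum`.
#' @param X Removal fraction in `[0, 1]`.
#' @param pool Peak pool from [build_peak_pool()] over the full target set.
#' @param scan_prefix Prefix linking the decoy to its target scan id.
#' @return A decoy `spectrum`.
#' @export
make_decoy_random <- function(s, X, pool, scan_prefix = "DECOY_") {
  stopifnot(inherits(s, "spectrum"))
  if (!is.numeric(X) || X < 0 || X > 1)
    stop("removal fraction X must be in [0, 1]")
  n <- nrow(s$peaks)
  k <- min(as.integer(round_half_away(X * n)), n)
  keep_idx <- if (k == 0L) seq_len(n) else sort(sample.int(n, n - k))
  noise <- pool[sample.int(nrow(pool), k, replace = TRUE), , drop = FALSE]
  peaks <- rbind(s$peaks[keep_idx, , drop = FALSE], noise)
  new_spectrum(paste0(scan_prefix, s$scan_id), s$precursor_mz,
               s$precursor_charge, peaks,
               title = paste0(scan_prefix, s$title))
}

#' Expected removal count from the precursor mass
#'
#' Estimates the peptide length as `L = round(M / avg_residue_mass)`
#' (minimum 1), the expected number of theoretical b/y ions as
#' `N_ions = (L - 1) * 2`, and the removal count as
#' `round(N_ions * X)`; halves round away from zero. Callers cap the
#' result at the spectrum's peak count.
#'
#' @param M Peptide neutral mass in Da (> 0).
#' @param X Removal fraction in `[0, 1]`.
#' @param avg_residue_mass Average residue mass in Da (default 123, the
#'   approximate average of the standard amino acids).
#' @return Integer number of peaks to remove.
#' @examples
#' estimate_removal_count(1230, 0.5)  # L = 10, N_ions = 18 -> 9
#' @export
estimate_removal_count <- function(M, X, avg_residue_mass = 123) {
  if (!is.numeric(M) || M <= 0) stop("peptide mass M must be positive")
  if (!is.numeric(X) || X < 0 || X > 1)
    stop("removal fraction X must be in [0, 1]")
  L <- max(1L, as.integer(round_half_away(M / avg_residue_mass)))
  n_ions <- (L - 1L) * 2L
  as.integer(round_half_away(n_ions * X))
}

#' Intensity/peptide-mass decoys for a whole dataset
#'
#' Two-phase construction. Phase 1: for every target spectrum the removal
#' count is derived from its precursor neutral mass via
#' [estimate_removal_count()] (capped at the peak count) and the top-count
#' highest-intensity peaks are removed (intensity ties break toward lower
#' m/z); all removed peaks are pooled. Phase 2: each spectrum receives the
#' same number of noise peaks, sampled with replacement from the
#' removed-peak pool, so per-spectrum peak counts are preserved.
#'
#' @param spectra List of target `spectrum` objects.
#' @param X Removal fraction in `[0, 1]`.
#' @param mass_table Mass table (for the precursor neutral mass).
#' @param avg_residue_mass Average residue mass (Da).
#' @param scan_prefix Decoy scan-id prefix.
#' @return List of decoy spectra, same order as input, with attribute
#'   `removed_pool` (the phase-1 pool).
#' @export
make_decoy_intensity <- function(spectra, X,
                                 mass_table = default_mass_table(),
                                 avg_residue_mass = 123,
                                 scan_prefix = "DECOY_") {
  if (!is.numeric(X) || X < 0 || X > 1)
    stop("removal fraction X must be in [0, 1]")
  kept <- vector("list", length(spectra))
  removed <- vector("list", length(spectra))
  counts <- integer(length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    M <- precursor_neutral_mass(s$precursor_mz, s$precursor_charge, mass_table)
    k <- min(estimate_removal_count(M, X, avg_residue_mass), nrow(s$peaks))
    counts[i] <- k
    ord <- order(-s$peaks$intensity, s$peaks$mz)
    removed[[i]] <- s$peaks[ord[seq_len(k)], , drop = FALSE]
    kept[[i]] <- s$peaks[setdiff(seq_len(nrow(s$peaks)), ord[seq_len(k)]), ,
                         drop = FALSE]
  }
  pool <- do.call(rbind, removed)
  rownames(pool) <- NULL
  if (nrow(pool) == 0L)
    warning("removal count is 0 for every spectrum; decoys equal targets")
  decoys <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    noise <- if (counts[i] > 0L)
      pool[sample.int(nrow(pool), counts[i], replace = TRUE), , drop = FALSE]
    else pool[0L, , drop = FALSE]
    decoys[[i]] <- new_spectrum(paste0(scan_prefix, s$scan_id),
                                s$precursor_mz, s$precursor_charge,
                                rbind(kept[[i]], noise),
                                title = paste0(scan_prefix, s$title))
  }
  attr(decoys, "removed_pool") <- pool
  decoys
}

#' Generate a full decoy dataset
#'
#' One decoy per target spectrum, same order, under either removal
#' strategy. Deterministic for a given `(spectra, config, seed)`.
#'
#' @param spectra List of target `spectrum` objects.
#' @param strategy `"random"` or `"intensity_mass"`.
#' @param X Removal fraction in `[0, 1]`.
#' @param seed Integer RNG seed (recorded in the summary); `NULL` uses the
#'   current RNG state.
#' @param scan_prefix Decoy scan-id prefix.
#' @param mass_table Mass table (intensity/mass strategy only).
#' @param avg_residue_mass Average residue mass in Da.
#' @return List with elements `decoys` (list of spectra) and `summary`
#'   (strategy, X, seed, spectrum count, pool size, removed-peak total).
#' @export
generate_decoy_dataset <- function(spectra,
                                   strategy = c("random", "intensity_mass"),
                                   X, seed = NULL, scan_prefix = "DECOY_",
                                   mass_table = default_mass_table(),
                                   avg_residue_mass = 123) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  if (strategy == "random") {
    pool <- build_peak_pool(spectra)
    decoys <- lapply(spectra, function(s)
      make_decoy_random(s, X, pool, scan_prefix))
    pool_size <- nrow(pool)
    removed_total <- sum(vapply(spectra, function(s)
      min(as.integer(round_half_away(X * nrow(s$peaks))), nrow(s$peaks)),
      integer(1)))
  } else {
    decoys <- make_decoy_intensity(spectra, X, mass_table, avg_residue_mass,
                                   scan_prefix)
    pool_size <- nrow(attr(decoys, "removed_pool"))
    removed_total <- pool_size
  }
  list(decoys = decoys,
       summary = list(strategy = strategy, removal_fraction = X,
                      seed = seed, n_spectra = length(spectra),
                      pool_size = pool_size, removed_total = removed_total,
                      scan_prefix = scan_prefix))
}
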