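# Theoretical fragment ions and peak matching. Twelve ion categories are
# enumerated per fragmentation site: b and y series, each plain or with an
# H2O or NH3 neutral loss, at charge 1 and charge 2.

#' Precursor neutral mass from m/z and charge
#'
#' M = mz * z - z * proton.
#'
#' @param precursor_mz Precursor m/z (Da).
#' @param z Positive integer charge.
#' @param mass_table Mass table supplying the proton mass.
#' @return Neutral peptide mass in Da.
#' @examples
#' precursor_neutral_mass(100.0, 1)  # 98.99272
#' @export
precursor_neutral_mass <- function(precursor_mz, z,
                                   mass_table = default_mass_table()) {
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("charge z must be a positive integer")
  precursor_mz * z - z * mass_table$proton
}

#' Enumerate the 12 theoretical fragment-ion categories of a peptide
#'
#' For each fragmentation site k = 1..L-1 the b fragment holds residues
#' 1..k and the y fragment the last L-k residues (plus water). Each site
#' yields 12 ions: series b/y, neutral loss none/H2O/NH3, charge 1/2, with
#' m/z = (neutral fragment + z * proton) / z. A peptide of length L gives
#' exactly 12 * (L - 1) ions; a single residue gives none. Modifications
#' contribute their delta to whichever fragment contains the modified
#' residue.
#'
#' @param p A `peptide` of length >= 1.
#' @param mass_table Mass table.
#' @param charges Fragment charges to emit (default `c(1, 2)`; charge-2
#'   ions are enumerated regardless of the precursor charge).
#' @param losses Neutral losses to emit, subset of
#'   `c("none", "H2O", "NH3")`.
#' @return Data frame with columns `series`, `loss`, `charge`, `site`,
#'   `mz`, ordered by site within category.
#' @export
enumerate_theoretical_ions <- function(p, mass_table = default_mass_table(),
                                       charges = c(1L, 2L),
                                       losses = c("none", "H2O", "NH3")) {
  stopifnot(inherits(p, "peptide"), length(p) >= 1L)
  losses <- match.arg(losses, several.ok = TRUE)
  L <- length(p)
  empty <- data.frame(series = character(), loss = character(),
                      charge = integer(), site = integer(), mz = numeric())
  if (L < 2L) return(empty)
  r <- residue_masses(p, mass_table)
  pre <- cumsum(r)                       # b_k neutral fragment, k = 1..L-1
  suf <- rev(cumsum(rev(r)))             # sum of residues k..L
  sites <- seq_len(L - 1L)
  b_neutral <- pre[sites]
  y_neutral <- suf[sites + 1L] + mass_table$water
  loss_delta <- c(none = 0, H2O = mass_table$water, NH3 = mass_table$ammonia)
  grid <- expand.grid(site = sites, charge = as.integer(charges),
                      loss = losses, series = c("b", "y"),
                      stringsAsFactors = FALSE)
  neutral <- ifelse(grid$series == "b", b_neutral[grid$site],
                    y_neutral[grid$site]) - loss_delta[grid$loss]
  mz <- (neutral + grid$charge * mass_table$proton) / grid$charge
  out <- data.frame(series = grid$series, loss = grid$loss,
                    charge = grid$charge, site = grid$site, mz = mz)
  rownames(out) <- NULL
  out
}

#' Match theoretical ions against spectrum peaks
#'
#' Each theoretical ion is paired with its nearest peak when the mass
#' difference is at most `tol` (inclusive; 0.02 Da by default). Matching is
#' many-ions-to-one-peak: one ion contributes at most one pair, but several
#' ions may match the same peak. Equidistant candidates break toward the
#' lower-m/z peak. The result does not depend on the ion enumeration order.
#'
#' @param s A `spectrum` (peaks sorted by m/z).
#' @param ions Data frame from [enumerate_theoretical_ions()] (only the
#'   `mz` column is required).
#' @param tol Tolerance in Da, non-negative.
#' @return List of class `ion_match`: `matched_pairs` (data frame with
#'   `ion` and `peak` indices), `matched_peaks` (sorted unique peak
#'   indices), `matched_ion_count` (number of ions with a match).
#' @export
match_ions <- function(s, ions, tol = 0.02) {
  stopifnot(inherits(s, "spectrum"))
  if (!is.numeric(tol) || tol < 0) stop("tolerance must be non-negative")
  pk <- s$peaks$mz
  n_ion <- nrow(ions)
  if (n_ion == 0L || length(pk) == 0L) {
    return(structure(list(
      matched_pairs = data.frame(ion = integer(), peak = integer()),
      matched_peaks = integer(), matched_ion_count = 0L),
      class = "ion_match"))
  }
  idx <- findInterval(ions$mz, pk)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(pk))
  d_lo <- ifelse(idx >= 1L, abs(ions$mz - pk[lo]), Inf)
  d_hi <- ifelse(idx < length(pk), abs(ions$mz - pk[hi]), Inf)
  nearest <- ifelse(d_lo <= d_hi, lo, hi)     # tie -> lower-m/z peak
  dist <- pmin(d_lo, d_hi)
  hit <- dist <= tol + 1e-9                   # inclusive at the boundary
  pairs <- data.frame(ion = which(hit), peak = nearest[hit])
  structure(list(matched_pairs = pairs,
                 matched_peaks = sort(unique(pairs$peak)),
                 matched_ion_count = nrow(pairs)),
            class = "ion_match")
}
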