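# Independent oracles and small builders shared across tests.

# Brute force: every (ion, peak) pair tested against |dm| <= tol.
# Returns the set of ion indices with at least one peak within tolerance.
brute_force_matched_ions <- function(s, ions, tol = 0.02) {
  which(vapply(ions$mz, function(m)
    any(abs(m - s$peaks$mz) <= tol + 1e-9), logical(1)))
}

# Dynamic-programming oracle for the amino-acid alignment: the maximum
# number of matched (dn, gt) residue pairs over all monotone cursor
# paths, a pair being matchable when both the inclusive cumulative masses
# (< prefix_tol) and the residue masses (< aa_tol) agree.
dp_max_aa_matches <- function(dn, gt, mt = default_mass_table(),
                              aa_tol = 0.1, prefix_tol = 0.5) {
  m_d <- residue_masses(dn, mt); m_g <- residue_masses(gt, mt)
  cum_d <- cumsum(m_d); cum_g <- cumsum(m_g)
  nd <- length(m_d); ng <- length(m_g)
  dp <- matrix(0L, nd + 1L, ng + 1L)
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      credit <- (abs(cum_d[i] - cum_g[j]) < prefix_tol) &&
        (abs(m_d[i] - m_g[j]) < aa_tol)
      dp[i + 1L, j + 1L] <- max(dp[i, j + 1L], dp[i + 1L, j],
                                dp[i, j] + as.integer(credit))
    }
  }
  dp[nd + 1L, ng + 1L]
}

# A spectrum whose peaks sit exactly at chosen m/z values.
spectrum_at <- function(mz, scan_id = "T1", precursor_mz = 500,
                        charge = 2L, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  new_spectrum(scan_id, precursor_mz, charge,
               data.frame(mz = mz, intensity = intensity))
}

# Random spectrum with peaks uniform over an m/z range.
random_spectrum <- function(n_peaks, scan_id = "R1", mz_range = c(100, 1500)) {
  spectrum_at(sort(stats::runif(n_peaks, mz_range[1], mz_range[2])),
              scan_id = scan_id,
              intensity = stats::runif(n_peaks, 1, 1000))
}

# All strings of lengths 1..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- character()
  cur <- ""
  for (len in seq_len(max_len)) {
    cur <- as.vector(outer(if (len == 1L) "" else prev, alphabet, paste0))
    prev <- cur
    out <- c(out, cur)
  }
  out
}
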