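# Monoisotopic residue masses, frozen at 5 decimals. The same values are
# shipped as a plain-text resource (inst/extdata/monoisotopic_masses.tsv)
# so that the numbers used at run time can be audited bit-exactly.
.RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Modification registry: label -> monoisotopic mass delta (Da).
.MOD_DELTAS <- c(
  Carbamidomethylation = 57.02146,
  Oxidation            = 15.99491,
  Deamidation          = 0.98402
)

.PROTON_MASS  <- 1.007276
.WATER_MASS   <- 18.010565
.AMMONIA_MASS <- 17.026549

#' The 20 standard amino acid letters
#'
#' @return Character vector of one-letter codes, in mass-table order.
#' @export
amino_acid_letters <- function() names(.RESIDUE_MASSES)

#' Default monoisotopic mass table
#'
#' Residue masses for the 20 standard amino acids, mass deltas for the
#' registered modifications (Carbamidomethylation, Oxidation, Deamidation),
#' and the proton, water and ammonia masses used for fragment and precursor
#' mass arithmetic. All values are monoisotopic: the framework targets
#' high-resolution data, where fragment ions are matched at 0.02 Da.
#'
#' @param residues Named numeric vector of residue masses (Da).
#' @param modifications Named numeric vector of modification deltas (Da).
#' @return An object of class `mass_table`: a list with elements
#'   `residues`, `modifications`, `proton`, `water`, `ammonia`.
#' @examples
#' mt <- default_mass_table()
#' mt$residues[["G"]]
#' @export
default_mass_table <- function(residues = .RESIDUE_MASSES,
                               modifications = .MOD_DELTAS) {
  mt <- structure(
    list(residues = residues, modifications = modifications,
         proton = .PROTON_MASS, water = .WATER_MASS, ammonia = .AMMONIA_MASS),
    class = "mass_table"
  )
  validate_mass_table(mt)
  mt
}

validate_mass_table <- function(mt) {
  stopifnot(inherits(mt, "mass_table"))
  missing <- setdiff(names(.RESIDUE_MASSES), names(mt$residues))
  if (length(missing) > 0L)
    stop("mass table is missing standard residues: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(mt$residues)) || any(mt$residues <= 0))
    stop("all residue masses must be positive and finite")
  if (any(!is.finite(mt$modifications)))
    stop("all modification deltas must be finite")
  invisible(mt)
}

#' Read a mass table from its plain-text resources
#'
#' Reads the residue-mass and modification-delta TSV files shipped with the
#' package (or any files in the same two-column format) and builds a
#' `mass_table`. Exists so audits can confirm that the frozen in-code table
#' and the shipped text resource agree.
#'
#' @param residue_file,modification_file Paths to tab-separated files with
#'   columns `letter`/`label` and `mass_da`. Defaults to the packaged files.
#' @return A `mass_table`.
#' @export
read_mass_table <- function(
    residue_file = system.file("extdata", "monoisotopic_masses.tsv",
                               package = "denovoeval"),
    modification_file = system.file("extdata", "modification_deltas.tsv",
                                    package = "denovoeval")) {
  res <- utils::read.delim(residue_file, stringsAsFactors = FALSE)
  mod <- utils::read.delim(modification_file, stringsAsFactors = FALSE)
  default_mass_table(
    residues = stats::setNames(res$mass_da, res$letter),
    modifications = stats::setNames(mod$mass_da, mod$label)
  )
}

# Nearest integer, halves away from zero. R's round() uses banker's
# rounding; decoy peak-count arithmetic needs a frozen deterministic rule.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
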