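# Peptide sequences: ordered residues with optional modification labels.
# Stored as parallel vectors (aa, mod) under S3 class "peptide"; mod is
# NA_character_ for an unmodified residue.

#' Construct a peptide sequence object
#'
#' @param aa Character vector of one-letter amino acid codes.
#' @param mod Character vector of modification labels (NA for none),
#'   same length as `aa`.
#' @param mass_table Mass table used to validate letters and labels.
#' @return An object of class `peptide`.
#' @export
new_peptide <- function(aa = character(),
                        mod = rep(NA_character_, length(aa)),
                        mass_table = default_mass_table()) {
  stopifnot(length(aa) == length(mod))
  bad_aa <- setdiff(aa, names(mass_table$residues))
  if (length(bad_aa) > 0L)
    stop("unknown amino acid letter(s): ", paste(unique(bad_aa), collapse = ", "))
  bad_mod <- setdiff(mod[!is.na(mod)], names(mass_table$modifications))
  if (length(bad_mod) > 0L)
    stop("unknown modification label(s): ", paste(unique(bad_mod), collapse = ", "))
  structure(list(aa = as.character(aa), mod = as.character(mod)),
            class = "peptide")
}

#' @export
length.peptide <- function(x) length(x$aa)

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", if (length(x) == 0L) "(empty)" else format_peptide(x),
      " [", length(x), " residues]\n", sep = "")
  invisible(x)
}

#' @export
as.character.peptide <- function(x, ...) format_peptide(x)

#' Parse a peptide string into a peptide object
#'
#' Accepts the Letter(ModName) dialect, e.g.
#' `"PEPTC(Carbamidomethylation)IDE"` or `"M(Oxidation)K"`. Unknown letters
#' or modification labels are rejected with an error naming the offending
#' token. The empty string (or NA) parses to the empty peptide, which
#' represents "the tool returned no prediction".
#'
#' @param text Peptide string.
#' @param mass_table Mass table whose residue letters and modification
#'   registry define what is valid.
#' @return A `peptide` object.
#' @examples
#' parse_peptide("M(Oxidation)K")
#' @export
parse_peptide <- function(text, mass_table = default_mass_table()) {
  if (length(text) != 1L) stop("parse_peptide() takes a single string")
  if (is.na(text) || !nzchar(text)) return(new_peptide(mass_table = mass_table))
  m <- gregexpr("[A-Z](\\([^()]*\\))?", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (paste(tokens, collapse = "") != text) {
    # reconstruct what was not consumed to name the offending token
    consumed <- paste(tokens, collapse = "")
    stop("cannot parse peptide string near: ",
         substr(text, nchar(consumed) + 1L, nchar(consumed) + 8L))
  }
  aa <- substr(tokens, 1L, 1L)
  mod <- ifelse(nchar(tokens) > 1L,
                substr(tokens, 3L, nchar(tokens) - 1L), NA_character_)
  new_peptide(aa, mod, mass_table = mass_table)
}

#' Format a peptide object back to its string form
#'
#' Inverse of [parse_peptide()]: `parse_peptide(format_peptide(p))`
#' reproduces `p` exactly.
#'
#' @param p A `peptide`.
#' @return A single string in Letter(ModName) notation.
#' @export
format_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  paste(ifelse(is.na(p$mod), p$aa, paste0(p$aa, "(", p$mod, ")")),
        collapse = "")
}

#' Convert mass-delta peptide notation to the Letter(ModName) dialect
#'
#' Some de novo tools report modifications as mass deltas, e.g.
#' `"C+57.02IDE"` or `"M(+15.99)K"`. Each delta is matched against the
#' modification registry within `tol` Da and replaced by its label.
#'
#' @param text Peptide string with `+/-delta` annotations.
#' @param mass_table Mass table providing the registry.
#' @param tol Maximum |delta - registry delta| (Da) for a match.
#' @return A string in Letter(ModName) notation.
#' @examples
#' convert_mass_delta_notation("C+57.02K")
#' @export
convert_mass_delta_notation <- function(text, mass_table = default_mass_table(),
                                        tol = 0.01) {
  pat <- "\\(?([+-][0-9]+\\.?[0-9]*)\\)?"
  m <- gregexpr(pat, text)
  deltas <- regmatches(text, m)[[1]]
  if (length(deltas) == 0L) return(text)
  labels <- vapply(deltas, function(d) {
    val <- as.numeric(gsub("[()]", "", d))
    diffs <- abs(mass_table$modifications - val)
    if (min(diffs) > tol)
      stop("no registered modification within ", tol, " Da of ", d)
    paste0("(", names(mass_table$modifications)[which.min(diffs)], ")")
  }, character(1))
  regmatches(text, m) <- list(labels)
  text
}

#' Per-residue masses of a peptide
#'
#' Residue monoisotopic mass plus the delta of any attached modification.
#'
#' @param p A `peptide`.
#' @param mass_table Mass table.
#' @return Numeric vector, one mass (Da) per residue.
#' @export
residue_masses <- function(p, mass_table = default_mass_table()) {
  stopifnot(inherits(p, "peptide"))
  if (length(p) == 0L) return(numeric())
  base <- unname(mass_table$residues[p$aa])
  delta <- ifelse(is.na(p$mod), 0, unname(mass_table$modifications[p$mod]))
  base + ifelse(is.na(delta), 0, delta)
}

#' Neutral (uncharged) mass of a peptide
#'
#' Sum of residue masses, modification deltas and one water.
#' The empty peptide has the mass of water.
#'
#' @inheritParams residue_masses
#' @return Mass in Da.
#' @examples
#' peptide_neutral_mass(parse_peptide("G"))  # 75.03202
#' @export
peptide_neutral_mass <- function(p, mass_table = default_mass_table()) {
  sum(residue_masses(p, mass_table)) + mass_table$water
}

# Cumulative N-terminal masses, residue i inclusive.
prefix_masses <- function(p, mass_table = default_mass_table()) {
  cumsum(residue_masses(p, mass_table))
}
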