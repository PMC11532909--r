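# Mascot Generic Format (MGF) reading and writing, plus the spectrum
# container. A spectrum is one MS/MS scan: identifiers, the precursor
# (m/z, charge) pair, and a peak table sorted ascending by m/z.

#' Construct a spectrum object
#'
#' @param scan_id Text scan identifier (unique within a file).
#' @param precursor_mz Precursor m/z (Da).
#' @param precursor_charge Positive integer precursor charge.
#' @param peaks Data frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0). Re-sorted ascending by m/z.
#' @param title Optional TITLE text; defaults to the scan id.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(scan_id, precursor_mz, precursor_charge, peaks,
                         title = scan_id) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0)) stop("peak m/z values must be strictly positive")
  if (any(peaks$intensity < 0)) stop("peak intensities must be non-negative")
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive")
  precursor_charge <- as.integer(precursor_charge)
  if (is.na(precursor_charge) || precursor_charge < 1L)
    stop("precursor_charge must be a positive integer")
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(scan_id = as.character(scan_id), title = as.character(title),
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge, peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> scan=%s  precursor %.4f m/z (%d+)  %d peaks\n",
              x$scan_id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE and
#' optional SCANS keys. The scan id is taken from SCANS when present,
#' otherwise from TITLE. Charge is accepted as `2+` or `2`. Peaks are
#' sorted ascending by m/z; zero-intensity peaks are retained.
#'
#' @param path Path to an MGF file.
#' @return List of `spectrum` objects, in file order.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_key <- grepl("^[A-Z]+=", block)
    keys <- block[is_key]
    kv <- sub("=.*$", "", keys)
    vv <- sub("^[A-Z]+=", "", keys)
    get1 <- function(key) if (key %in% kv) vv[match(key, kv)] else NA_character_
    pepmass <- get1("PEPMASS")
    if (is.na(pepmass))
      stop("malformed MGF block ", b, ": missing PEPMASS")
    precursor_mz <- suppressWarnings(as.numeric(strsplit(trimws(pepmass),
                                                         "[ \t]+")[[1]][1]))
    if (is.na(precursor_mz))
      stop("malformed MGF block ", b, ": non-numeric PEPMASS")
    charge_txt <- get1("CHARGE")
    charge <- if (is.na(charge_txt)) 1L else
      as.integer(sub("\\+$", "", trimws(charge_txt)))
    if (is.na(charge))
      stop("malformed MGF block ", b, ": cannot parse CHARGE '", charge_txt, "'")
    title <- get1("TITLE")
    scans <- get1("SCANS")
    scan_id <- if (!is.na(scans)) scans else title
    if (is.na(scan_id))
      stop("malformed MGF block ", b, ": neither SCANS nor TITLE present")
    peak_lines <- block[!is_key]
    if (length(peak_lines) > 0L) {
      parts <- strsplit(trimws(peak_lines), "[ \t]+")
      if (any(lengths(parts) < 2L))
        stop("malformed MGF block ", b, ": peak line with fewer than 2 fields")
      mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
      intensity <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
      if (anyNA(mz) || anyNA(intensity))
        stop("malformed MGF block ", b, ": non-numeric peak line")
      peaks <- data.frame(mz = mz, intensity = intensity)
    } else {
      peaks <- data.frame(mz = numeric(), intensity = numeric())
    }
    spectra[[b]] <- new_spectrum(scan_id, precursor_mz, charge, peaks,
                                 title = if (is.na(title)) scan_id else title)
  }
  ids <- vapply(spectra, `[[`, "", "scan_id")
  if (anyDuplicated(ids))
    stop("duplicate scan id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  spectra
}

#' Write spectra to an MGF file
#'
#' One BEGIN IONS block per spectrum, in list order. Peak values are
#' printed with 5 decimals, so a read/write round trip preserves them to
#' that precision. An optional `scan_prefix` (e.g. `"DECOY_"`) is
#' prepended to each SCANS and TITLE value, preserving linkage between a
#' decoy block and its target scan id.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output file path.
#' @param scan_prefix Optional prefix for scan ids (default none).
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, scan_prefix = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum"))
    id <- if (is.null(scan_prefix)) s$scan_id else paste0(scan_prefix, s$scan_id)
    title <- if (is.null(scan_prefix)) s$title else paste0(scan_prefix, s$title)
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%.5f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      paste0("SCANS=", id),
      if (nrow(s$peaks) > 0L)
        sprintf("%.5f %.5f", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}
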