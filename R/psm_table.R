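# Delimited PSM tables: one row per peptide-spectrum match from a de novo
# tool or a database-search ground truth. Column names vary across tools,
# so the reader takes an explicit column map.

#' Read a delimited PSM table
#'
#' Reads a tab- or comma-delimited table with a header and returns a
#' normalized PSM data frame with columns `scan_id`, `origin`
#' (`"target"`/`"decoy"`), `peptide` (string, possibly empty when the tool
#' returned no prediction) and `score`. Rows with an empty peptide cell are
#' retained, never dropped: abstentions count against a tool. Origin is
#' taken from `origin_column` when mapped, otherwise inferred from the scan
#' id prefix.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping the required fields to
#'   column names in the file; must name `scan_id`, `peptide`, `score`.
#' @param origin_column Optional column holding `target`/`decoy` directly.
#' @param decoy_prefix Scan-id prefix marking decoy spectra.
#' @param sep Field separator; `NULL` (default) picks tab when the header
#'   contains one, else comma.
#' @return Data frame with columns `scan_id`, `origin`, `peptide`, `score`.
#' @export
read_psm_table <- function(path,
                           column_map = c(scan_id = "scan_id",
                                          peptide = "peptide",
                                          score = "score"),
                           origin_column = NULL,
                           decoy_prefix = "DECOY_",
                           sep = NULL) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  required <- c("scan_id", "peptide", "score")
  if (!all(required %in% names(column_map)))
    stop("column_map must name: ", paste(required, collapse = ", "))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  missing <- setdiff(unname(column_map), names(raw))
  if (!is.null(origin_column) && !(origin_column %in% names(raw)))
    missing <- c(missing, origin_column)
  if (length(missing) > 0L)
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing, collapse = ", "))
  scan_id <- as.character(raw[[column_map[["scan_id"]]]])
  peptide <- as.character(raw[[column_map[["peptide"]]]])
  peptide[is.na(peptide)] <- ""
  origin <- if (!is.null(origin_column)) {
    o <- tolower(as.character(raw[[origin_column]]))
    if (!all(o %in% c("target", "decoy")))
      stop("origin column must contain only 'target'/'decoy'")
    o
  } else {
    ifelse(startsWith(scan_id, decoy_prefix), "decoy", "target")
  }
  data.frame(scan_id = scan_id, origin = origin, peptide = peptide,
             score = as.numeric(raw[[column_map[["score"]]]]),
             stringsAsFactors = FALSE)
}

#' Write a PSM data frame as tab-delimited text
#'
#' @param psms Data frame with at least `scan_id`, `peptide`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
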