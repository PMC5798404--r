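#' Tree codes of the fourteen partitions
#'
#' @return character vector `A`-`D`, `E`-`H`, `Q`, `R`, `W`-`Z`.
#' @export
partition_codes <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "Q", "R", "W", "X", "Y", "Z")
}

#' Read a clade-support spreadsheet (TSV)
#'
#' The file has one row per named clade and one column per tree code; the
#' first column is the clade identifier and an optional `taxa` column lists
#' the clade's taxa separated by `;`. Cells are either blank (clade absent
#' from that tree's set, or below the 50% reporting threshold -- the two
#' are deliberately not distinguished) or a bootstrap percentage in
#' `[50, 100]`.
#'
#' @param path TSV file path.
#' @param allowed_codes permitted tree-code columns (default the fourteen
#'   partition codes); any other code column is an error.
#' @return a [clade_support_matrix()] whose `bp` entries are `NA` where the
#'   file is blank.
#' @export
read_support_table <- function(path, allowed_codes = partition_codes()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("support table needs a clade column and >=1 tree column")
  cn <- colnames(df)
  id_col <- cn[1]
  taxa_col <- intersect(c("taxa", "Taxa"), cn)
  code_cols <- setdiff(cn, c(id_col, taxa_col))
  unknown <- setdiff(code_cols, allowed_codes)
  if (length(unknown) > 0L)
    stop("unknown tree code column(s): ", paste(unknown, collapse = ", "))
  bp <- matrix(NA_real_, nrow(df), length(code_cols),
               dimnames = list(df[[id_col]], code_cols))
  for (cc in code_cols) {
    raw <- trimws(df[[cc]])
    has <- nzchar(raw) & !is.na(raw)
    vals <- suppressWarnings(as.numeric(raw[has]))
    if (any(is.na(vals)))
      stop("non-numeric support cell in column ", cc)
    if (any(vals < 50 | vals > 100))
      stop("support value outside [50, 100] in column ", cc, ": ",
           paste(vals[vals < 50 | vals > 100], collapse = ", "),
           " (the table reports BP >= 50 only)")
    bp[has, cc] <- vals
  }
  entries <- if (length(taxa_col) == 1L)
    lapply(strsplit(df[[taxa_col]], ";"), function(x) sort(trimws(x)))
  else
    vector("list", nrow(df))
  names(entries) <- df[[id_col]]
  clade_support_matrix(entries = entries, bp = bp)
}

#' Write a clade-support matrix as TSV
#'
#' Mirrors the layout read by [read_support_table()]: one row per clade,
#' one column per tree code, blanks where support is below the reporting
#' threshold or the clade is absent.
#'
#' @param matrix a [clade_support_matrix()].
#' @param path output file path.
#' @param threshold reporting threshold (default the matrix's own, 50).
#' @return `path`, invisibly.
#' @export
write_support_table <- function(matrix, path, threshold = matrix$threshold) {
  bp <- matrix$bp
  rep_bp <- ifelse(!is.na(bp) & bp >= threshold, formatC(bp, format = "g"), "")
  df <- data.frame(clade_id = rownames(bp),
                   taxa = vapply(matrix$entries, function(e)
                     if (is.null(e)) "" else paste(e, collapse = ";"),
                     character(1)),
                   rep_bp, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
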