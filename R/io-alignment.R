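#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and relaxed PHYLIP (sequential; taxon labels run
#' to the first whitespace, so labels longer than the strict 10 characters
#' are fine). Taxon order is preserved as in the file.
#'
#' @param path file path.
#' @param dialect `"fasta"` or `"phylip_relaxed"` (default: guessed from the
#'   first character, `>` meaning FASTA).
#' @return a [raw_alignment()].
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "phylip_relaxed")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (startsWith(trimws(first), ">")) "fasta" else "phylip_relaxed"
  }
  if (dialect == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
    seqs <- stats::setNames(seqs, sub("[[:space:]].*$", "", names(seqs)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("not a PHYLIP alignment: ", path)
    hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
    if (length(hdr) != 2L || any(is.na(hdr)))
      stop("malformed PHYLIP header in ", path)
    ntax <- hdr[1]; ncols <- hdr[2]
    body <- lines[-1]
    if (length(body) != ntax)
      stop("PHYLIP body has ", length(body), " rows, header declares ", ntax)
    labs <- sub("[[:space:]].*$", "", trimws(body))
    seqstr <- gsub("[[:space:]]", "",
                   sub("^[^[:space:]]+[[:space:]]+", "", trimws(body)))
    lens <- nchar(seqstr)
    if (any(lens != ncols)) {
      bad <- labs[lens != ncols]
      stop("row length differs from declared ", ncols, " columns for: ",
           paste(bad, collapse = ", "))
    }
    seqs <- stats::setNames(seqstr, labs)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment in ", path, ": ",
         paste(names(seqs)[lens != lens[1]], collapse = ", "))
  raw_alignment(seqs)
}

#' Write a multiple sequence alignment
#'
#' @param aln a [raw_alignment()] or [partitioned_alignment()].
#' @param path output file path.
#' @param dialect `"fasta"` or `"phylip_relaxed"`.
#' @return `path`, invisibly. `read_alignment(write_alignment(a))` is the
#'   identity for both dialects.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "phylip_relaxed")) {
  dialect <- match.arg(dialect)
  seqs <- alignment_strings(aln)
  if (length(seqs) == 0L) stop("refusing to write an empty alignment")
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "fasta") {
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      writeLines(seqs[[i]], con)
    }
  } else {
    writeLines(sprintf("%d %d", length(seqs), nchar(seqs[[1]])), con)
    writeLines(sprintf("%s  %s", names(seqs), unname(seqs)), con)
  }
  invisible(path)
}
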