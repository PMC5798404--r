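#' Alignment containers
#'
#' A `raw_alignment` is a taxa x columns character matrix (one nucleotide or
#' gap per cell, uppercase) with unique rownames giving the taxon labels.
#' A `partitioned_alignment` wraps a `raw_alignment` together with per-column
#' metadata (source locus, codon position, original column index) and,
#' optionally, one of the fourteen partition codes.
#'
#' The gap symbol is `-` only; `N` and IUPAC ambiguity codes are residues,
#' not gaps. Distance and selection code handle ambiguity separately by
#' pairwise deletion.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix with one residue per cell and taxon rownames.
#' @return `raw_alignment`: a character matrix of class `raw_alignment`.
#' @examples
#' a <- raw_alignment(c(t1 = "ACGT", t2 = "A-GT"))
#' n_columns(a)
#' @export
raw_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m)) && nrow(m) > 0L)
      stop("alignment matrix must have taxon rownames")
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != lens[1L]]
      stop("ragged alignment: rows differ in length for taxa: ",
           paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    if (lens[1L] == 0L) m <- matrix(character(0), nrow = length(seqs), ncol = 0L)
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  m[] <- toupper(m)
  class(m) <- c("raw_alignment", class(m))
  m
}

#' @rdname raw_alignment
#' @param x an alignment object.
#' @export
n_columns <- function(x) {
  if (inherits(x, "partitioned_alignment")) ncol(x$aln) else ncol(x)
}

#' @rdname raw_alignment
#' @export
taxa_of <- function(x) {
  if (inherits(x, "partitioned_alignment")) rownames(x$aln) else rownames(x)
}

#' Convert an alignment to per-taxon strings
#' @param x a `raw_alignment` or `partitioned_alignment`.
#' @return named character vector of sequence strings.
#' @export
alignment_strings <- function(x) {
  m <- if (inherits(x, "partitioned_alignment")) x$aln else x
  out <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) out <- stats::setNames(rep("", nrow(m)), rownames(m))
  out
}

#' Construct a partitioned alignment
#'
#' @param aln a `raw_alignment`.
#' @param meta data.frame with one row per column and columns `locus`
#'   (character; `"noncoding"` for non-CDS columns), `codon_pos` (integer 1:3
#'   or `NA` for non-codon columns) and `original_index` (strictly increasing
#'   integer giving each column's index in the source matrix).
#' @param code optional partition code (one of A-D, E-H, Q, R, W-Z).
#' @return an object of class `partitioned_alignment`.
#' @export
partitioned_alignment <- function(aln, meta = NULL, code = NULL) {
  if (!inherits(aln, "raw_alignment")) aln <- raw_alignment(aln)
  if (is.null(meta)) {
    meta <- data.frame(locus = rep("noncoding", ncol(aln)),
                       codon_pos = rep(NA_integer_, ncol(aln)),
                       original_index = seq_len(ncol(aln)))
  }
  stopifnot(nrow(meta) == ncol(aln))
  if (is.unsorted(meta$original_index, strictly = TRUE) && nrow(meta) > 1L)
    stop("column metadata original_index must be strictly increasing")
  structure(list(aln = aln, meta = meta, code = code),
            class = "partitioned_alignment")
}

#' @export
print.raw_alignment <- function(x, ...) {
  cat(sprintf("raw_alignment: %d taxa x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("partitioned_alignment%s: %d taxa x %d columns (%d loci)\n",
              if (is.null(x$code)) "" else paste0(" [", x$code, "]"),
              nrow(x$aln), ncol(x$aln), length(unique(x$meta$locus))))
  invisible(x)
}
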