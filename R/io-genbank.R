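#' Annotated genome container
#'
#' One taxon's plastome sequence plus located features. Coordinates are
#' 0-based half-open `[start, end)` on the forward strand; GenBank input
#' (1-based closed) is converted on read. Compound (`join`) locations become
#' multiple intervals in transcript order.
#'
#' @param taxon_id taxon label.
#' @param residues nucleotide string (A, C, G, T, N and IUPAC ambiguity
#'   codes).
#' @param features list of features, each a list with `name`, `kind`
#'   (`"CDS"`, `"intron"` or `"other"`), `intervals` (matrix or list of
#'   `c(start, end)` 0-based half-open pairs) and `strand` (`"+"` or `"-"`).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(taxon_id, residues, features = list()) {
  residues <- toupper(residues)
  len <- nchar(residues)
  if (len == 0L) stop("zero-length sequence for ", taxon_id)
  feats <- lapply(features, function(f) {
    if (is.null(f$name) || !nzchar(f$name)) stop("feature with empty name")
    iv <- f$intervals
    if (is.list(iv)) iv <- do.call(rbind, iv)
    iv <- matrix(as.numeric(iv), ncol = 2)
    if (any(iv[, 1] < 0) || any(iv[, 1] >= iv[, 2]) || any(iv[, 2] > len))
      stop("feature '", f$name, "': interval outside [0, ", len,
           ") or empty")
    list(name = f$name,
         kind = if (is.null(f$kind)) "other" else f$kind,
         intervals = iv,
         strand = if (is.null(f$strand)) "+" else f$strand)
  })
  structure(list(taxon_id = taxon_id, residues = residues,
                 features = feats, length = len),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d bp, %d features\n",
              x$taxon_id, x$length, length(x$features)))
  invisible(x)
}

## Convert one GenBank location string (1-based closed) into a 0-based
## half-open interval matrix plus a strand flag. Handles join(...),
## complement(...) and complement(join(...)).
.parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    } else {
      se <- rep(as.numeric(p), 2)
    }
    if (any(is.na(se))) stop("unparseable location part: ", p)
    c(se[1] - 1, se[2])  # 1-based closed -> 0-based half-open
  }, numeric(2)))
  dimnames(iv) <- NULL
  list(intervals = iv, strand = strand)
}

#' Read a GenBank flat file into an `annotated_genome`
#'
#' A minimal parser for single-record GenBank flat files: the LOCUS name (or
#' ORGANISM, if present) becomes the taxon label; `CDS`, `intron` and `exon`
#' features are retained with their `/gene` (or `/product`) qualifier as the
#' feature name; the ORIGIN block supplies the sequence. 1-based closed
#' coordinates are converted to 0-based half-open; minus-strand features
#' keep a strand flag.
#'
#' @param path file path.
#' @return an [annotated_genome()].
#' @export
read_annotated_genome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)
  locus_line <- grep("^LOCUS", lines)
  if (length(locus_line) == 0L)
    stop("malformed GenBank record: no LOCUS line in ", path)
  taxon <- strsplit(trimws(sub("^LOCUS", "", lines[locus_line[1]])),
                    "[[:space:]]+")[[1]][1]
  org_line <- grep("^[[:space:]]+ORGANISM", lines)
  if (length(org_line) > 0L) {
    org <- trimws(sub("^[[:space:]]+ORGANISM", "", lines[org_line[1]]))
    if (nzchar(org)) taxon <- gsub(" ", "_", org)
  }
  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(origin_start) == 0L)
    stop("malformed GenBank record: no ORIGIN block (truncated file?), line ",
         length(lines))
  seq_lines <- lines[(origin_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(residues) == 0L) stop("zero-length sequence in ", path)
  features <- list()
  if (length(feat_start) > 0L) {
    fl <- lines[(feat_start[1] + 1L):(origin_start[1] - 1L)]
    ## feature keys start at column 6; qualifiers/continuations at column 22
    key_idx <- grep("^ {5}[A-Za-z]", fl)
    for (j in seq_along(key_idx)) {
      i0 <- key_idx[j]
      i1 <- if (j < length(key_idx)) key_idx[j + 1] - 1L else length(fl)
      block <- fl[i0:i1]
      key <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]][1]
      if (!key %in% c("CDS", "intron", "exon")) next
      ## location may continue over lines until the first qualifier
      qual_at <- grep("^[[:space:]]+/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(c(sub("^[[:space:]]*[A-Za-z'_0-9-]+[[:space:]]+", "",
                         block[1]),
                     trimws(block[seq_len(loc_end)][-1])), collapse = "")
      parsed <- tryCatch(.parse_gb_location(loc), error = function(e)
        stop("malformed location for ", key, " near line ",
             feat_start[1] + i0, ": ", conditionMessage(e)))
      gene <- sub('.*?/gene="([^"]*)".*', "\\1",
                  paste(block, collapse = " "))
      if (identical(gene, paste(block, collapse = " ")))
        gene <- sub('.*?/product="([^"]*)".*', "\\1",
                    paste(block, collapse = " "))
      if (identical(gene, paste(block, collapse = " "))) gene <- key
      kind <- if (key == "CDS") "CDS" else if (key == "intron") "intron"
              else "other"
      features[[length(features) + 1L]] <-
        list(name = gene, kind = kind, intervals = parsed$intervals,
             strand = parsed$strand)
    }
  }
  annotated_genome(taxon, residues, features)
}

#' Write an `annotated_genome` as a GenBank-like flat file
#'
#' Emits LOCUS, FEATURES (CDS/intron/exon with `/gene` qualifiers, 1-based
#' closed coordinates, `join`/`complement` as needed) and ORIGIN blocks so
#' that [read_annotated_genome()] round-trips the record.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_genome <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   PLN",
                     genome$taxon_id, genome$length), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in genome$features) {
    iv <- f$intervals
    segs <- sprintf("%d..%d", as.integer(iv[, 1] + 1), as.integer(iv[, 2]))
    loc <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")")
           else segs
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    key <- switch(f$kind, CDS = "CDS", intron = "intron", "exon")
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$residues)
  starts <- seq(1L, nchar(s), 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
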