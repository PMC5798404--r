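## Partition construction: CDS/noncoding extraction from annotated genomes,
## locus concatenation with codon metadata, gap-column stripping, selected-
## codon masking, and the fixed 14-partition derivation graph.

.revcomp <- function(s) {
  chartr("ACGTRYKMBVDHNacgtrykmbvdhn",
         "TGCAYRMKVBHDNtgcayrmkvbhdn",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## 0-based half-open intervals <-> IRanges (1-based closed)
.as_iranges <- function(iv) {
  IRanges::IRanges(start = as.integer(iv[, 1] + 1), end = as.integer(iv[, 2]))
}

.from_iranges <- function(ir) {
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Extract distinct CDS loci from an annotated genome
#'
#' One sequence per distinct CDS name: when a locus is annotated more than
#' once (the duplicated inverted-repeat copies), only the first occurrence
#' by genomic coordinate is kept. Compound intervals are concatenated in
#' transcript order; minus-strand features are reverse-complemented. A
#' trailing stop codon is retained in the sequence but flagged; a CDS whose
#' extracted length is not divisible by 3 is flagged unusable for codon
#' analysis, with a warning.
#'
#' @param genome an [annotated_genome()].
#' @return data.frame with columns `locus`, `sequence`, `usable`
#'   (frame-intact), `has_terminal_stop`.
#' @export
extract_cds_loci <- function(genome) {
  cds <- Filter(function(f) f$kind == "CDS", genome$features)
  if (length(cds) == 0L) stop("genome '", genome$taxon_id, "' has no CDS features")
  starts <- vapply(cds, function(f) min(f$intervals[, 1]), numeric(1))
  cds <- cds[order(starts)]
  seen <- character(0)
  rows <- list()
  for (f in cds) {
    if (f$name %in% seen) next  # IR duplicate: keep first copy by coordinate
    seen <- c(seen, f$name)
    segs <- apply(f$intervals, 1L, function(iv)
      substr(genome$residues, iv[1] + 1, iv[2]))
    s <- paste(segs, collapse = "")
    if (f$strand == "-") s <- .revcomp(s)
    usable <- nchar(s) %% 3L == 0L
    if (!usable)
      warning("CDS '", f$name, "' in ", genome$taxon_id, " has length ",
              nchar(s), " not divisible by 3; flagged unusable")
    term_stop <- usable && nchar(s) >= 3L &&
      .is_stop(substr(s, nchar(s) - 2L, nchar(s)))
    rows[[length(rows) + 1L]] <-
      data.frame(locus = f$name, sequence = s, usable = usable,
                 has_terminal_stop = term_stop, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Concatenated noncoding sequence of a genome
#'
#' Every base not covered by any CDS feature (coverage union; a base inside
#' any CDS is coding), concatenated in genomic order. Satisfies
#' `nchar(coding union) + nchar(noncoding) == genome length`.
#'
#' @param genome an [annotated_genome()].
#' @return nucleotide string (possibly empty).
#' @export
extract_noncoding <- function(genome) {
  cds <- Filter(function(f) f$kind == "CDS", genome$features)
  if (length(cds) == 0L) return(genome$residues)
  cov <- IRanges::reduce(do.call(c, lapply(cds, function(f)
    .as_iranges(f$intervals))))
  gap <- IRanges::setdiff(IRanges::IRanges(1L, genome$length), cov)
  if (length(gap) == 0L) return("")
  iv <- .from_iranges(gap)
  paste(apply(iv, 1L, function(x)
    substr(genome$residues, x[1] + 1, x[2])), collapse = "")
}

#' Extract the three-gene locus sets (rbcL, ndhF, matK, trnK intron)
#'
#' For each genome the rbcL, ndhF and matK CDSs are extracted, plus the
#' trnK intron, defined as the region between the two trnK exon features
#' with the embedded matK CDS excised (so coding columns are not
#' duplicated). A genome lacking one of the loci gets an all-missing entry
#' for it, with a warning.
#'
#' @param genomes list of [annotated_genome()] objects.
#' @return named list of four locus sets, each a list with `locus`,
#'   `sequences` (named character vector; `NA` when missing) and `is_cds`.
#' @export
build_three_gene_set <- function(genomes) {
  loci <- c("rbcL", "ndhF", "matK", "trnK_intron")
  out <- lapply(loci, function(l)
    list(locus = l,
         sequences = stats::setNames(rep(NA_character_, length(genomes)),
                                     vapply(genomes, `[[`, "", "taxon_id")),
         is_cds = l != "trnK_intron"))
  names(out) <- loci
  for (g in genomes) {
    cds <- tryCatch(extract_cds_loci(g), error = function(e) NULL)
    for (l in c("rbcL", "ndhF", "matK")) {
      hit <- cds[cds$locus == l, , drop = FALSE]
      if (!is.null(cds) && nrow(hit) == 1L) {
        out[[l]]$sequences[g$taxon_id] <- hit$sequence[1]
      } else {
        warning("genome ", g$taxon_id, " lacks locus ", l)
      }
    }
    trnk <- Filter(function(f) f$name == "trnK", g$features)
    matk <- Filter(function(f) f$kind == "CDS" && f$name == "matK", g$features)
    if (length(trnk) >= 1L) {
      ivs <- do.call(rbind, lapply(trnk, function(f) f$intervals))
      if (nrow(ivs) >= 2L) {
        ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
        intron <- matrix(c(ivs[1, 2], ivs[nrow(ivs), 1]), ncol = 2)
        if (intron[1, 1] < intron[1, 2]) {
          keep <- IRanges::setdiff(.as_iranges(intron),
                                   if (length(matk))
                                     IRanges::reduce(do.call(c, lapply(matk,
                                       function(f) .as_iranges(f$intervals))))
                                   else IRanges::IRanges())
          iv <- .from_iranges(keep)
          out$trnK_intron$sequences[g$taxon_id] <-
            paste(apply(iv, 1L, function(x)
              substr(g$residues, x[1] + 1, x[2])), collapse = "")
        }
      }
    }
    if (is.na(out$trnK_intron$sequences[g$taxon_id]))
      warning("genome ", g$taxon_id, " lacks a usable trnK intron")
  }
  out
}

## 0-based half-open pieces of the trnK intron with matK excised; exposed
## for interval-arithmetic testing.
trnk_intron_intervals <- function(exon_intervals, matk_intervals) {
  ivs <- exon_intervals[order(exon_intervals[, 1]), , drop = FALSE]
  intron <- matrix(c(ivs[1, 2], ivs[nrow(ivs), 1]), ncol = 2)
  keep <- IRanges::setdiff(.as_iranges(intron),
                           IRanges::reduce(.as_iranges(matk_intervals)))
  .from_iranges(keep)
}

#' Concatenate aligned loci into a partitioned supermatrix
#'
#' Columns are ordered by input locus order. Column metadata records the
#' source locus, the codon position (cycling 1, 2, 3 within each CDS locus)
#' and a running original column index. All inputs must share one taxon
#' set; a mismatch is an error listing the symmetric difference. When every
#' row of a CDS locus ends in a stop codon (or a fully gapped codon), that
#' terminal codon's columns carry no codon-position metadata, so masking
#' arithmetic never touches the stop.
#'
#' @param aligned_loci named list of [raw_alignment()] objects (names are
#'   locus labels).
#' @param is_cds logical vector parallel to `aligned_loci`; by default a
#'   locus is treated as coding unless its name contains `noncoding`,
#'   `spacer` or `intron`.
#' @return a [partitioned_alignment()].
#' @export
concatenate_loci <- function(aligned_loci,
                             is_cds = !grepl("noncoding|spacer|intron",
                                             names(aligned_loci))) {
  stopifnot(length(aligned_loci) >= 1L, !is.null(names(aligned_loci)))
  taxa <- rownames(aligned_loci[[1]])
  for (i in seq_along(aligned_loci)) {
    ti <- rownames(aligned_loci[[i]])
    if (!setequal(ti, taxa)) {
      stop("taxon set mismatch at locus '", names(aligned_loci)[i],
           "': only-in-first {", paste(setdiff(taxa, ti), collapse = ","),
           "}, only-in-this {", paste(setdiff(ti, taxa), collapse = ","), "}")
    }
  }
  mats <- lapply(aligned_loci, function(a) a[taxa, , drop = FALSE])
  big <- do.call(cbind, mats)
  metas <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    nc <- ncol(mats[[i]])
    cp <- rep(NA_integer_, nc)
    if (is_cds[i] && nc > 0L) {
      if (nc %% 3L != 0L) {
        warning("CDS locus '", names(aligned_loci)[i], "' has ", nc,
                " columns (not a multiple of 3); codon positions omitted")
      } else {
        cp <- rep(1:3, nc / 3L)
        last <- (nc - 2L):nc
        last_cods <- apply(mats[[i]][, last, drop = FALSE], 1L, paste,
                           collapse = "")
        is_term <- vapply(last_cods, function(cd) {
          if (cd == "---") return(TRUE)
          !grepl("[^ACGT]", cd) && .is_stop(cd)
        }, logical(1))
        if (all(is_term)) cp[last] <- NA_integer_
      }
    }
    metas[[i]] <- data.frame(locus = rep(names(aligned_loci)[i], nc),
                             codon_pos = cp,
                             original_index = rep(NA_integer_, nc))
  }
  meta <- do.call(rbind, metas)
  meta$original_index <- seq_len(nrow(meta))
  m <- raw_alignment(big)
  partitioned_alignment(m, meta)
}

#' Remove every column containing an alignment gap
#'
#' Keeps exactly the columns in which no row holds `-`; column order is
#' preserved, column metadata is subset accordingly, and the operation is
#' idempotent. `N` and ambiguity codes are residues, not gaps.
#'
#' @param x a [raw_alignment()] or [partitioned_alignment()].
#' @return same type as the input (possibly with 0 columns).
#' @export
strip_gapped_columns <- function(x) {
  if (inherits(x, "partitioned_alignment")) {
    keep <- colSums(x$aln == "-") == 0L
    out <- x
    out$aln <- x$aln[, keep, drop = FALSE]
    class(out$aln) <- class(x$aln)
    out$meta <- x$meta[keep, , drop = FALSE]
    rownames(out$meta) <- NULL
    return(out)
  }
  keep <- colSums(x == "-") == 0L
  out <- x[, keep, drop = FALSE]
  class(out) <- class(x)
  out
}

## Column indices (within the full matrix) of codon k (0-based) of `locus`,
## defined on the columns whose codon-position metadata cycles 1,2,3.
.codon_columns <- function(meta, locus) {
  idx <- which(meta$locus == locus & !is.na(meta$codon_pos))
  if (length(idx) %% 3L != 0L)
    stop("locus '", locus, "' codon metadata is not a whole number of codons")
  matrix(idx, nrow = 3L)  # one column per codon
}

#' Delete positively selected codons from a partitioned alignment
#'
#' For each `(locus, codon index)` pair the three columns of that codon are
#' removed; noncoding columns are untouched. Codon indices are 0-based
#' within each locus's codon frame (the convention of external site lists,
#' e.g. imported episodic-selection output, and of
#' [site_selection_scan()]).
#'
#' @param aln a [partitioned_alignment()].
#' @param sites named list mapping locus to an integer vector of 0-based
#'   codon indices; loci absent from the alignment are ignored only if
#'   their site set is empty.
#' @return a [partitioned_alignment()] with
#'   `n_columns = input - 3 * (number of masked codons present)`.
#' @export
mask_selected_codons <- function(aln, sites) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  if (length(sites) == 0L) return(aln)
  drop_cols <- integer(0)
  for (locus in names(sites)) {
    idxs <- sites[[locus]]
    if (length(idxs) == 0L) next
    if (!locus %in% aln$meta$locus)
      stop("locus '", locus, "' not present in alignment")
    cc <- .codon_columns(aln$meta, locus)
    ncod <- ncol(cc)
    bad <- idxs[idxs < 0L | idxs >= ncod]
    if (length(bad) > 0L)
      stop("codon index out of range for locus '", locus, "': ",
           paste(bad, collapse = ","), " (locus has ", ncod, " codons)")
    drop_cols <- c(drop_cols, as.vector(cc[, idxs + 1L]))
  }
  if (length(drop_cols) == 0L) return(aln)
  keep <- setdiff(seq_len(ncol(aln$aln)), drop_cols)
  out <- aln
  out$aln <- aln$aln[, keep, drop = FALSE]
  class(out$aln) <- class(aln$aln)
  out$meta <- aln$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' The fourteen partition definitions
#'
#' @return data.frame with columns `code`, `region_set` (`three_gene`,
#'   `coding`, `noncoding`, `complete`), `strip_gaps`,
#'   `remove_positive_sites` (always `FALSE` for the noncoding rows, where
#'   it is inapplicable).
#' @export
partition_specs <- function() {
  data.frame(
    code = partition_codes(),
    region_set = c(rep("three_gene", 4), rep("coding", 4),
                   rep("noncoding", 2), rep("complete", 4)),
    strip_gaps = c(FALSE, TRUE, FALSE, TRUE,
                   FALSE, TRUE, FALSE, TRUE,
                   FALSE, TRUE,
                   FALSE, TRUE, FALSE, TRUE),
    remove_positive_sites = c(FALSE, FALSE, TRUE, TRUE,
                              FALSE, FALSE, TRUE, TRUE,
                              FALSE, FALSE,
                              FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Build the full fourteen-partition suite
#'
#' Applies the fixed derivation graph to the four base (gapped,
#' unmasked) region alignments: `B = strip(A)`, `C = mask(A)`,
#' `D = strip(C)`; `F = strip(E)`, `G = mask(E)`, `H = strip(G)`;
#' `R = strip(Q)`; `X = strip(W)`, `Y = mask(W)`, `Z = strip(Y)`.
#' Masking is applied to the gapped matrix first, then gaps are stripped
#' (the order matters and is fixed).
#'
#' @param regions named list with elements `three_gene`, `coding`,
#'   `noncoding`, `complete`, each a [partitioned_alignment()] of the
#'   gapped, unmasked region supermatrix (these become partitions A, E, Q
#'   and W).
#' @param sites named list mapping CDS locus to 0-based positively selected
#'   codon indices (as from [site_selection_scan()] or an imported site
#'   list); empty list makes C == A, G == E and Y == W.
#' @return named list of fourteen [partitioned_alignment()] objects, codes
#'   A-Z as in [partition_specs()].
#' @export
build_partition_suite <- function(regions, sites = list()) {
  need <- c("three_gene", "coding", "noncoding", "complete")
  miss <- setdiff(need, names(regions))
  if (length(miss) > 0L)
    stop("missing base alignment(s): ", paste(miss, collapse = ", "))
  mask_present <- function(aln) {
    here <- intersect(names(sites), unique(aln$meta$locus))
    mask_selected_codons(aln, sites[here])
  }
  out <- list()
  out$A <- regions$three_gene
  out$B <- strip_gapped_columns(out$A)
  out$C <- mask_present(out$A)
  out$D <- strip_gapped_columns(out$C)
  out$E <- regions$coding
  out$F <- strip_gapped_columns(out$E)
  out$G <- mask_present(out$E)
  out$H <- strip_gapped_columns(out$G)
  out$Q <- regions$noncoding
  out$R <- strip_gapped_columns(out$Q)
  out$W <- regions$complete
  out$X <- strip_gapped_columns(out$W)
  out$Y <- mask_present(out$W)
  out$Z <- strip_gapped_columns(out$Y)
  for (code in names(out)) out[[code]]$code <- code
  out[partition_codes()]
}

#' Tabulate matrix lengths before and after gap stripping
#'
#' Convenience check of deposited alignment files against published matrix
#' lengths: reads each file, strips gapped columns, and reports both
#' widths.
#'
#' @param paths named character vector (or list of alignments) of gapped
#'   matrices.
#' @param dialect passed to [read_alignment()].
#' @return data.frame with `name`, `n_taxa`, `n_columns`,
#'   `n_columns_stripped`.
#' @export
verify_partition_lengths <- function(paths, dialect = "auto") {
  rows <- lapply(names(paths), function(nm) {
    a <- paths[[nm]]
    if (is.character(a)) a <- read_alignment(a, dialect)
    data.frame(name = nm, n_taxa = nrow(a), n_columns = ncol(a),
               n_columns_stripped = ncol(strip_gapped_columns(a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
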