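## Nei-Gojobori (1986) counting machinery: expected synonymous/nonsynonymous
## site counts per codon, pathway-averaged difference counts per codon pair,
## Jukes-Cantor corrected dN/dS, and the codon-based Z-test of selection.

.BASES <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  .codon_env$code
}

.translate_codon <- function(codon) {
  aa <- .genetic_code()[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

.is_stop <- function(codon) {
  aa <- .translate_codon(codon)
  !is.na(aa) & aa == "*"
}

.sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

.is_countable_codon <- function(codon) {
  ok <- nchar(codon) == 3L &
    !grepl("[^ACGT]", codon)
  ok & !ifelse(ok, .is_stop(codon), FALSE)
}

#' Expected synonymous and nonsynonymous sites of a codon
#'
#' Nei-Gojobori site counting: at each of the three codon positions the
#' fraction of the three possible single-nucleotide changes that are
#' synonymous is the synonymous site count for that position; changes that
#' create a stop codon are excluded from the denominator at that position.
#' Counts sum to 3 for every sense codon.
#'
#' @param codon a 3-character string over A, C, G, T; not a stop codon.
#' @return list with elements `S` and `N` (nonnegative reals, `S + N == 3`).
#' @examples
#' codon_site_counts("TTT")  # S = 1/3
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!.is_countable_codon(codon))
    stop("codon_site_counts requires a sense codon over ACGT, got '", codon, "'")
  nt <- strsplit(codon, "")[[1]]
  S <- 0
  for (pos in 1:3) {
    alt <- .BASES[.BASES != nt[pos]]
    neigh <- vapply(alt, function(b) {
      x <- nt; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    keep <- !.is_stop(neigh)
    if (!any(keep)) next  # position uncountable: all neighbors are stops
    syn <- .translate_codon(neigh[keep]) == .translate_codon(codon)
    S <- S + sum(syn) / sum(keep)
  }
  list(S = S, N = 3 - S)
}

.site_count_table <- function() {
  if (is.null(.codon_env$sites)) {
    cods <- .sense_codons()
    S <- vapply(cods, function(cd) codon_site_counts(cd)$S, numeric(1))
    .codon_env$sites <- data.frame(codon = cods, S = S, N = 3 - S)
    rownames(.codon_env$sites) <- cods
  }
  .codon_env$sites
}

## Pathway-averaged observed synonymous (sd) and nonsynonymous (nd)
## differences between two codons. All k! orderings of the k differing
## positions are enumerated; orderings passing through a stop codon are
## dropped; if every ordering is blocked the stop-passing paths are used
## (never occurs between sense codons differing at <3 positions via
## standard-code geometry, but guarded). sd + nd equals the number of
## differing positions whenever at least one path survives.
.codon_path_diffs <- function(c1, c2) {
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(n1 != n2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
           p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
    })
  step_counts <- function(order, allow_stops) {
    cur <- n1; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- n2[pos]
      ncod <- paste(nxt, collapse = "")
      if (!allow_stops && .is_stop(ncod)) return(NULL)
      if (.translate_codon(paste(cur, collapse = "")) == .translate_codon(ncod))
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, step_counts, allow_stops = FALSE))
  if (length(res) == 0L)
    res <- lapply(perms, step_counts, allow_stops = TRUE)
  cm <- do.call(rbind, res)
  c(sd = mean(cm[, "sd"]), nd = mean(cm[, "nd"]))
}

.path_diff_table <- function() {
  if (is.null(.codon_env$paths)) {
    .codon_env$paths <- new.env(parent = emptyenv())
  }
  .codon_env$paths
}

.codon_diffs_cached <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  tab <- .path_diff_table()
  v <- tab[[key]]
  if (is.null(v)) {
    v <- .codon_path_diffs(c1, c2)
    tab[[key]] <- v
  }
  v
}

.split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

.jc_correct <- function(p, what = "proportion") {
  if (p >= 0.75)
    stop("saturation: ", what, " = ", format(p), " >= 3/4; Jukes-Cantor ",
         "correction undefined")
  -0.75 * log(1 - (4 / 3) * p)
}

## Per-codon contributions for one sequence pair. Returns a matrix with one
## row per codon: S, N (mean of the two codons' site counts), sd, nd;
## uncountable codons (gap/ambiguity/stop in either sequence) are NA rows.
.pair_codon_contrib <- function(cod1, cod2) {
  stopifnot(length(cod1) == length(cod2))
  st <- .site_count_table()
  ok <- .is_countable_codon(cod1) & .is_countable_codon(cod2)
  out <- matrix(NA_real_, nrow = length(cod1), ncol = 4,
                dimnames = list(NULL, c("S", "N", "sd", "nd")))
  if (any(ok)) {
    S <- (st[cod1[ok], "S"] + st[cod2[ok], "S"]) / 2
    dif <- t(mapply(.codon_diffs_cached, cod1[ok], cod2[ok]))
    out[ok, "S"] <- S
    out[ok, "N"] <- 3 - S
    out[ok, "sd"] <- dif[, 1]
    out[ok, "nd"] <- dif[, 2]
  }
  out
}

#' Pairwise dN and dS by the Nei-Gojobori method
#'
#' Observed synonymous and nonsynonymous differences are averaged over all
#' equally weighted mutational pathways (paths through stop codons excluded);
#' expected site counts are averaged between the two sequences; proportions
#' are Jukes-Cantor corrected, `d = -(3/4) log(1 - (4/3) p)`, separately for
#' the synonymous and nonsynonymous classes. Codons containing a gap,
#' ambiguity code or stop in either sequence are excluded pairwise. The
#' function is symmetric in its arguments.
#'
#' @param seq1,seq2 in-frame nucleotide strings of equal length divisible by 3.
#' @return list with elements `dN`, `dS`, and the underlying counts
#'   (`sd`, `nd`, `S`, `N`, `n_codons` used).
#' @examples
#' pairwise_dn_ds("TTTGGGAAA", "TTCGGGAAA")$dS  # one synonymous change
#' @export
pairwise_dn_ds <- function(seq1, seq2) {
  cod1 <- .split_codons(seq1)
  cod2 <- .split_codons(seq2)
  if (length(cod1) != length(cod2)) stop("sequences differ in codon count")
  contrib <- .pair_codon_contrib(cod1, cod2)
  ok <- !is.na(contrib[, "S"])
  if (!any(ok)) stop("no countable codons in pair")
  S <- sum(contrib[ok, "S"]); N <- sum(contrib[ok, "N"])
  sd <- sum(contrib[ok, "sd"]); nd <- sum(contrib[ok, "nd"])
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  list(dN = .jc_correct(pN, "pN"), dS = .jc_correct(pS, "pS"),
       sd = sd, nd = nd, S = S, N = N, n_codons = sum(ok))
}

## Mean dN and dS over all sequence pairs from precomputed per-pair,
## per-codon contribution arrays, restricted to codon indices `idx`
## (with repetition, for the site bootstrap). Saturated proportions are
## clamped just below 3/4 during bootstrap variance estimation.
.mean_dnds <- function(Smat, Nmat, sdmat, ndmat, idx, clamp = FALSE) {
  Ssum <- rowSums(Smat[, idx, drop = FALSE], na.rm = TRUE)
  Nsum <- rowSums(Nmat[, idx, drop = FALSE], na.rm = TRUE)
  sds <- rowSums(sdmat[, idx, drop = FALSE], na.rm = TRUE)
  nds <- rowSums(ndmat[, idx, drop = FALSE], na.rm = TRUE)
  pS <- ifelse(Ssum > 0, sds / Ssum, 0)
  pN <- ifelse(Nsum > 0, nds / Nsum, 0)
  ## saturated pairs carry no usable distance: exclude them pairwise (the
  ## same rule applies to the point estimate and to bootstrap replicates)
  keep <- pS < 0.75 & pN < 0.75
  if (!any(keep)) {
    if (clamp) return(c(dN = NA_real_, dS = NA_real_))
    stop("all sequence pairs saturated (p >= 3/4)")
  }
  pS <- pS[keep]; pN <- pN[keep]
  dS <- -0.75 * log(1 - (4 / 3) * pS)
  dN <- -0.75 * log(1 - (4 / 3) * pN)
  c(dN = mean(dN), dS = mean(dS))
}

#' Codon-based Z-test of selection for one locus
#'
#' Computes mean pairwise dN and dS over all sequence pairs of an in-frame
#' codon alignment and tests the one-tailed hypothesis of purifying
#' (`dS > dN`) or positive (`dN > dS`) selection with
#' `Z = (dS - dN) / sqrt(Var(dS) + Var(dN))` (sign flipped for the positive
#' alternative). Variances are estimated by a seeded bootstrap over codon
#' sites: codons are resampled with replacement and the mean pairwise dN and
#' dS recomputed for each pseudo-replicate.
#'
#' All-identical alignments return verdict `"neutral"` with `p = 1`
#' (variances are zero). Saturated pairs (`pS` or `pN >= 3/4`, where the
#' Jukes-Cantor correction is undefined) are excluded pairwise; fewer than
#' two usable sequences, or saturation in every pair, returns verdict
#' `"undetermined"` with `p = NA`.
#'
#' @param aln a `raw_alignment` (or `partitioned_alignment`) of in-frame
#'   codon sequences; pass through [prepare_codon_alignment()] first if stop
#'   codons may be present.
#' @param alternative `"purifying"` or `"positive"`.
#' @param alpha significance level for the verdict (default 0.05).
#' @param nboot bootstrap pseudo-replicates for the variance (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param locus locus label carried into the result.
#' @return object of class `selection_result`: list with `locus`, `dN`, `dS`,
#'   `Z`, `p`, `verdict`, `n_codons`.
#' @export
locus_z_test <- function(aln, alternative = c("purifying", "positive"),
                         alpha = 0.05, nboot = 1000, seed = 1,
                         locus = "locus") {
  alternative <- match.arg(alternative)
  m <- if (inherits(aln, "partitioned_alignment")) aln$aln else aln
  if (!is.matrix(m)) m <- raw_alignment(m)
  res <- structure(list(locus = locus, dN = NA_real_, dS = NA_real_,
                        Z = NA_real_, p = NA_real_, verdict = "undetermined",
                        positive_sites = integer(0),
                        n_codons = ncol(m) %/% 3L),
                   class = "selection_result")
  if (nrow(m) < 2L) return(res)
  seqs <- alignment_strings(m)
  codons <- lapply(seqs, .split_codons)
  nc <- length(codons[[1]])
  pairs <- utils::combn(length(seqs), 2L)
  npair <- ncol(pairs)
  Smat <- matrix(NA_real_, npair, nc); Nmat <- Smat
  sdmat <- Smat; ndmat <- Smat
  for (k in seq_len(npair)) {
    contrib <- .pair_codon_contrib(codons[[pairs[1, k]]], codons[[pairs[2, k]]])
    Smat[k, ] <- contrib[, "S"]; Nmat[k, ] <- contrib[, "N"]
    sdmat[k, ] <- contrib[, "sd"]; ndmat[k, ] <- contrib[, "nd"]
  }
  ## drop pairs with no countable codons, then saturated pairs (pairwise
  ## exclusion; the locus is undetermined only if nothing remains)
  Ssum <- rowSums(Smat, na.rm = TRUE); Nsum <- rowSums(Nmat, na.rm = TRUE)
  pS <- ifelse(Ssum > 0, rowSums(sdmat, na.rm = TRUE) / Ssum, 0)
  pN <- ifelse(Nsum > 0, rowSums(ndmat, na.rm = TRUE) / Nsum, 0)
  usable <- rowSums(!is.na(Smat)) > 0 & pS < 0.75 & pN < 0.75
  if (!any(usable)) return(res)
  Smat <- Smat[usable, , drop = FALSE]; Nmat <- Nmat[usable, , drop = FALSE]
  sdmat <- sdmat[usable, , drop = FALSE]; ndmat <- ndmat[usable, , drop = FALSE]
  point <- .mean_dnds(Smat, Nmat, sdmat, ndmat, seq_len(nc))
  res$dN <- point[["dN"]]; res$dS <- point[["dS"]]
  if (sum(sdmat, na.rm = TRUE) == 0 && sum(ndmat, na.rm = TRUE) == 0) {
    res$Z <- 0; res$p <- 1; res$verdict <- "neutral"
    return(res)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot <- matrix(NA_real_, nboot, 2)
  for (b in seq_len(nboot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    boot[b, ] <- .mean_dnds(Smat, Nmat, sdmat, ndmat, idx, clamp = TRUE)
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  if (nrow(boot) < 2L) return(res)
  v <- stats::var(boot[, 1]) + stats::var(boot[, 2])
  if (!is.finite(v) || v <= 0) {
    res$Z <- 0; res$p <- 1; res$verdict <- "neutral"
    return(res)
  }
  z <- (point[["dS"]] - point[["dN"]]) / sqrt(v)
  if (alternative == "positive") z <- -z
  res$Z <- z
  res$p <- stats::pnorm(z, lower.tail = FALSE)
  res$verdict <- if (res$p < alpha) alternative else "neutral"
  res
}

#' Replace stop codons with gaps in a codon alignment
#'
#' Internal and terminal in-frame stop codons are replaced by `---` so that
#' downstream counting treats them as missing. Rows whose reading frame is
#' violated (in-frame stops beyond the terminal one) keep their non-stop
#' codons, with a warning; if more than half the rows contain internal stop
#' codons the frame itself is deemed wrong and an error is raised.
#'
#' @param aln a `raw_alignment` or `partitioned_alignment`; columns must be a
#'   multiple of 3.
#' @return same type as the input, stop codons gapped.
#' @export
prepare_codon_alignment <- function(aln) {
  part <- inherits(aln, "partitioned_alignment")
  m <- if (part) aln$aln else aln
  if (!is.matrix(m)) m <- raw_alignment(m)
  if (ncol(m) %% 3L != 0L) stop("alignment width not divisible by 3")
  nstop_internal <- 0L
  nrows_internal <- 0L
  ncod <- ncol(m) %/% 3L
  for (i in seq_len(nrow(m))) {
    cods <- .split_codons(paste(m[i, ], collapse = ""))
    stops <- which(nchar(gsub("[^ACGT]", "", cods)) == 3L & .is_stop(cods))
    if (length(stops) > 0L) {
      internal <- stops[stops < ncod]
      if (length(internal) > 0L) {
        nrows_internal <- nrows_internal + 1L
        nstop_internal <- nstop_internal + length(internal)
      }
      for (s in stops) m[i, (3L * s - 2L):(3L * s)] <- "-"
    }
  }
  if (nrows_internal > nrow(m) / 2)
    stop("reading frame untranslatable in more than half the rows (",
         nrows_internal, "/", nrow(m), " rows with internal stop codons)")
  if (nrows_internal > 0L)
    warning(nstop_internal, " internal stop codon(s) in ", nrows_internal,
            " row(s) replaced with gaps")
  if (part) { aln$aln <- m; aln } else m
}

#' Summarize per-locus selection results
#'
#' @param results list of `selection_result` objects (with `positive_sites`
#'   filled in, e.g. by [site_selection_scan()]).
#' @return data.frame with columns `locus`, `n_codons`, `n_positive`,
#'   `proportion_positive`, `verdict`, sorted by proportion descending.
#' @export
selection_summary <- function(results) {
  if (length(results) == 0L)
    return(data.frame(locus = character(0), n_codons = integer(0),
                      n_positive = integer(0),
                      proportion_positive = numeric(0),
                      verdict = character(0)))
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(locus = r$locus, n_codons = r$n_codons,
               n_positive = length(r$positive_sites),
               proportion_positive =
                 if (r$n_codons > 0) length(r$positive_sites) / r$n_codons else 0,
               verdict = r$verdict, stringsAsFactors = FALSE)
  }))
  df[order(-df$proportion_positive, df$locus), , drop = FALSE]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: dN=%.4g dS=%.4g Z=%.3g p=%.3g %s (%d positive sites / %d codons)\n",
              x$locus, x$dN, x$dS, x$Z, x$p, x$verdict,
              length(x$positive_sites), x$n_codons))
  invisible(x)
}

## Save/restore the global RNG state so seeded internals do not perturb the
## caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
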