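## Plastome-like data simulator with full ground truth: a known tree,
## coding loci under a codon process with a configurable fraction of
## positively selected sites, noncoding spacers under GTR+Gamma with an
## indel process (so true gap columns are known), and per-taxon
## annotations delimiting coding vs noncoding regions.

#' Simulator configuration
#'
#' Defaults are the study conditions used throughout the test suite: 32
#' taxa on a Yule tree of expected root-to-tip depth 0.8 substitutions per
#' site (deep-divergence regime, chosen so that individual codon sites
#' accumulate enough substitutions for counting-based per-site tests to
#' have power), six 300-codon coding loci with 5% of codons positively
#' selected (omega 5) against a purifying background (omega 0.2), and
#' AT-rich noncoding spacers under GTR+Gamma with indels.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param tree_model `"yule"` or `"fixed_newick"` (then supply `newick`).
#' @param newick Newick string when `tree_model = "fixed_newick"`.
#' @param tree_height expected root-to-tip substitutions per site.
#' @param n_cds_loci number of coding loci (>= 3; the first three are named
#'   rbcL, ndhF and matK so the three-gene partition is exercised).
#' @param codons_per_locus codons per coding locus.
#' @param omega_background,omega_selected dN/dS of background / selected
#'   codons.
#' @param selected_fraction fraction of codons per locus under positive
#'   selection.
#' @param noncoding_length total noncoding bases at the root, split evenly
#'   across spacers.
#' @param gtr_rates six exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freqs equilibrium base frequencies (A, C, G, T).
#' @param gamma_shape shape of the (4-category discrete) Gamma rate mix.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_length_mean mean indel tract length (geometric).
#' @param ir_duplicate annotate a duplicated inverted-repeat copy of one
#'   CDS in each genome (exercises IR de-duplication).
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 32, tree_model = "yule", newick = NULL,
                       tree_height = 0.8, n_cds_loci = 6,
                       codons_per_locus = 300, omega_background = 0.2,
                       omega_selected = 5, selected_fraction = 0.05,
                       noncoding_length = 2100,
                       gtr_rates = c(1, 2, 1, 1, 2, 1),
                       base_freqs = c(0.31, 0.18, 0.17, 0.34),
                       gamma_shape = 0.8, indel_rate = 0.05,
                       indel_length_mean = 3, ir_duplicate = TRUE,
                       seed = 1) {
  stopifnot(selected_fraction >= 0, selected_fraction <= 1,
            all(gtr_rates > 0), all(base_freqs > 0),
            omega_background > 0, omega_selected > 0)
  base_freqs <- base_freqs / sum(base_freqs)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the species tree
#'
#' A Yule (pure-birth) tree with `n_taxa` leaves, rescaled so the mean
#' root-to-tip path length equals `tree_height`; or the fixed Newick
#' supplied in the config. Reproducible by seed.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override (default: the config's).
#' @return rooted binary `phylo` tree.
#' @export
simulate_tree <- function(config, seed = config$seed) {
  if (config$n_taxa < 3) stop("n_taxa must be >= 3")
  if (identical(config$tree_model, "fixed_newick")) {
    phy <- ape::read.tree(text = config$newick)
    return(phy)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phy <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
  phy$tip.label <- sprintf("t%02d", seq_len(config$n_taxa))
  depths <- ape::node.depth.edgelength(phy)[seq_len(config$n_taxa)]
  md <- mean(depths)
  phy$edge.length <- if (md > 0) phy$edge.length * config$tree_height / md
                     else phy$edge.length * 0
  phy
}

## --- codon process -------------------------------------------------------

## Gillespie-style codon evolution along one branch. Nucleotide change
## proposals arrive at rate 1 per nucleotide site (3 per codon) per unit
## branch length; proposals creating stop codons are rejected; synonymous
## proposals are accepted with probability min(1, 1/omega) and
## nonsynonymous ones with probability min(1, omega), so the accepted
## nonsynonymous/synonymous rate ratio is omega at every site.
.evolve_codons <- function(codons, omega, t) {
  if (t <= 0) return(codons)
  nev <- stats::rpois(length(codons), 3 * t)
  hot <- which(nev > 0L)
  p_syn <- pmin(1, 1 / omega)
  p_non <- pmin(1, omega)
  for (s in hot) {
    cur <- codons[s]
    for (e in seq_len(nev[s])) {
      pos <- sample.int(3L, 1L)
      nt <- strsplit(cur, "")[[1]]
      nt[pos] <- sample(.BASES[.BASES != nt[pos]], 1L)
      cand <- paste(nt, collapse = "")
      if (.is_stop(cand)) next
      syn <- .translate_codon(cand) == .translate_codon(cur)
      acc <- if (syn) p_syn[s] else p_non[s]
      if (stats::runif(1) < acc) cur <- cand
    }
    codons[s] <- cur
  }
  codons
}

#' Simulate one coding locus on a tree
#'
#' Per-codon continuous-time process (see the package vignette): stop
#' codons are excluded from the state space, there are no indels in coding
#' loci, and a `selected_fraction` of codons evolve with
#' `omega_selected`, the rest with `omega_background`. The truth records
#' which codons are selected.
#'
#' @param tree rooted `phylo` tree.
#' @param config a [sim_config()].
#' @param locus_id label carried into the result.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `aln` (a gap-free in-frame [raw_alignment()]),
#'   `selected_sites` (0-based codon indices) and `locus`.
#' @export
simulate_coding_locus <- function(tree, config, locus_id = "locus",
                                  seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  ncod <- config$codons_per_locus
  sense <- .sense_codons()
  n_sel <- round(config$selected_fraction * ncod)
  sel <- if (n_sel > 0) sort(sample.int(ncod, n_sel)) else integer(0)
  omega <- rep(config$omega_background, ncod)
  omega[sel] <- config$omega_selected
  root <- sample(sense, ncod, replace = TRUE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- vector("list", nnode)
  states[[ntip + 1L]] <- root
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (k in rev(seq_len(nrow(edge)))) {  # preorder
    par <- edge[k, 1]; child <- edge[k, 2]
    states[[child]] <- .evolve_codons(states[[par]], omega, elen[k])
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(states[[i]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  list(aln = raw_alignment(seqs), selected_sites = sel - 1L,
       locus = locus_id)
}

## --- GTR + Gamma + indel noncoding process -------------------------------

.gtr_eigen <- function(rates, freqs) {
  R <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  R["A", "C"] <- rates[1]; R["A", "G"] <- rates[2]; R["A", "T"] <- rates[3]
  R["C", "G"] <- rates[4]; R["C", "T"] <- rates[5]; R["G", "T"] <- rates[6]
  R <- R + t(R)
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))       # mean rate; scale to 1 sub/site/unit
  Q <- Q / mu
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = es$values,
       right = diag(1 / sp) %*% es$vectors,
       left = t(es$vectors) %*% diag(sp))
}

.gtr_pmat <- function(eig, t) {
  P <- eig$right %*% diag(exp(eig$values * t)) %*% eig$left
  P[P < 0] <- 0
  P / rowSums(P)
}

.discrete_gamma_rates <- function(shape, k = 4) {
  q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  q / mean(q)
}

## Evolve one lineage segment: substitutions by category-wise transition
## matrices, then indels. A lineage is a data.frame(key, base, cat) of
## present residues ordered by key.
.evolve_noncoding_branch <- function(lin, t, eig, cat_rates, freqs,
                                     indel_rate, indel_mean) {
  if (t > 0 && nrow(lin) > 0) {
    for (ci in seq_along(cat_rates)) {
      idx <- which(lin$cat == ci)
      if (length(idx) == 0L) next
      P <- .gtr_pmat(eig, t * cat_rates[ci])
      for (b in 1:4) {
        ib <- idx[lin$base[idx] == b]
        if (length(ib) > 0L)
          lin$base[ib] <- sample.int(4L, length(ib), replace = TRUE,
                                     prob = P[b, ])
      }
    }
    nind <- stats::rpois(1, indel_rate * t * nrow(lin))
    for (e in seq_len(nind)) {
      if (nrow(lin) == 0L) break
      len <- stats::rgeom(1, 1 / indel_mean) + 1L
      if (stats::runif(1) < 0.5) {     # deletion
        start <- sample.int(nrow(lin), 1L)
        drop <- start:min(nrow(lin), start + len - 1L)
        lin <- lin[-drop, , drop = FALSE]
      } else {                          # insertion
        at <- sample.int(nrow(lin) + 1L, 1L) - 1L  # after residue `at`
        k1 <- if (at == 0L) min(lin$key) - 1 else lin$key[at]
        k2 <- if (at == nrow(lin)) max(lin$key) + 1 else lin$key[at + 1L]
        keys <- sort(stats::runif(len, k1, k2))
        ins <- data.frame(key = keys,
                          base = sample.int(4L, len, replace = TRUE,
                                            prob = freqs),
                          cat = sample.int(length(cat_rates), len,
                                           replace = TRUE))
        lin <- rbind(lin[seq_len(at), , drop = FALSE], ins,
                     lin[seq(at + 1L, length.out = nrow(lin) - at), ,
                         drop = FALSE])
      }
    }
  }
  lin
}

#' Simulate a noncoding region with indels and known gap columns
#'
#' GTR+Gamma substitutions (4-category discrete Gamma) with a Poisson
#' indel process on branches (geometric tract lengths, insertions and
#' deletions equally likely). The emitted alignment is the true homology
#' alignment, so the set of gap-containing columns is exact ground truth.
#' `indel_rate = 0` gives a gap-free alignment.
#'
#' @param tree rooted `phylo` tree.
#' @param config a [sim_config()].
#' @param length root sequence length (default
#'   `config$noncoding_length`).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `aln` (true-homology [raw_alignment()] including `-`)
#'   and `gap_columns` (1-based indices of columns containing a gap).
#' @export
simulate_noncoding_region <- function(tree, config,
                                      length = config$noncoding_length,
                                      seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  stopifnot(config$indel_rate >= 0)
  eig <- .gtr_eigen(config$gtr_rates, config$base_freqs)
  cat_rates <- .discrete_gamma_rates(config$gamma_shape)
  root <- data.frame(
    key = as.numeric(seq_len(length)),
    base = sample.int(4L, length, replace = TRUE, prob = config$base_freqs),
    cat = sample.int(4L, length, replace = TRUE))
  ntip <- base::length(tree$tip.label)
  lineages <- vector("list", ntip + tree$Nnode)
  lineages[[ntip + 1L]] <- root
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge; elen <- post$edge.length
  for (k in rev(seq_len(nrow(edge)))) {
    lineages[[edge[k, 2]]] <- .evolve_noncoding_branch(
      lineages[[edge[k, 1]]], elen[k], eig, cat_rates, config$base_freqs,
      config$indel_rate, config$indel_length_mean)
  }
  leaf_lins <- lineages[seq_len(ntip)]
  all_keys <- sort(unique(unlist(lapply(leaf_lins, `[[`, "key"))))
  m <- matrix("-", nrow = ntip, ncol = base::length(all_keys),
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) {
    pos <- match(leaf_lins[[i]]$key, all_keys)
    m[i, pos] <- .BASES[leaf_lins[[i]]$base]
  }
  aln <- raw_alignment(m)
  gap_columns <- which(colSums(aln == "-") > 0L)
  list(aln = aln, gap_columns = gap_columns)
}

## --- whole-plastome assembly ---------------------------------------------

.degap <- function(s) gsub("-", "", s)

#' Assemble synthetic plastomes with full ground truth
#'
#' Simulates a tree, coding loci and noncoding spacers, concatenates them
#' into per-taxon genome records with CDS/exon annotations at true
#' per-taxon coordinates, and emits the four pre-made region alignments
#' (`three_gene`, `coding`, `noncoding`, `complete`) consistent with the
#' concatenation, plus a complete truth bundle.
#'
#' Genome layout per taxon: `spacer0, trnK-exon1, intronA, matK, intronB,
#' trnK-exon2, spacer1, rbcL, spacer2, ndhF, spacer3, cds04, ...` and,
#' when `ir_duplicate` is set, a duplicated annotated copy of ndhF near
#' the end (emulating an inverted-repeat copy; excluded, as a duplicate,
#' from the region alignments). Coding loci carry no indels; spacers,
#' introns and trnK exons evolve with indels, so every gap column in the
#' region alignments is true indel ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `genomes` (list of [annotated_genome()]),
#'   `regions` (named list of four [partitioned_alignment()] bases),
#'   `truth` (list: `selected_sites` per locus (0-based),
#'   `gap_columns` per region, `locus_alignments`).
#' @export
assemble_synthetic_plastomes <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  if (config$n_cds_loci < 3) stop("n_cds_loci must be >= 3")
  tree <- simulate_tree(config, seed = sample.int(2^30, 1))
  taxa <- tree$tip.label
  locus_names <- c("matK", "rbcL", "ndhF",
                   if (config$n_cds_loci > 3)
                     sprintf("cds%02d", 4:config$n_cds_loci))
  loci <- lapply(locus_names, function(nm)
    simulate_coding_locus(tree, config, locus_id = nm))
  names(loci) <- locus_names
  n_spacer <- config$n_cds_loci + 1L
  spacer_len <- max(50L, round(config$noncoding_length / (n_spacer + 3)))
  sim_nc <- function(len, indel = TRUE) {
    cfg <- config
    if (!indel) cfg$indel_rate <- 0
    simulate_noncoding_region(tree, cfg, length = len)
  }
  spacers <- lapply(seq_len(n_spacer), function(i) sim_nc(spacer_len))
  names(spacers) <- sprintf("spacer%02d", seq_len(n_spacer) - 1L)
  intronA <- sim_nc(spacer_len)
  intronB <- sim_nc(spacer_len)
  exon1 <- sim_nc(30L, indel = FALSE)
  exon2 <- sim_nc(30L, indel = FALSE)

  ## genomic order of pieces: name, alignment, role
  pieces <- list(
    list(name = "spacer00", aln = spacers[[1]]$aln, role = "noncoding"),
    list(name = "trnK_exon1", aln = exon1$aln, role = "trnK_exon"),
    list(name = "trnK_intronA", aln = intronA$aln, role = "trnK_intron"),
    list(name = "matK", aln = loci$matK$aln, role = "cds"),
    list(name = "trnK_intronB", aln = intronB$aln, role = "trnK_intron"),
    list(name = "trnK_exon2", aln = exon2$aln, role = "trnK_exon"))
  rest <- setdiff(locus_names, "matK")
  for (i in seq_along(rest)) {
    pieces[[length(pieces) + 1L]] <-
      list(name = names(spacers)[i + 1L], aln = spacers[[i + 1L]]$aln,
           role = "noncoding")
    pieces[[length(pieces) + 1L]] <-
      list(name = rest[i], aln = loci[[rest[i]]]$aln, role = "cds")
  }
  last_spacer <- spacers[[n_spacer]]
  ## genomes: degapped concatenation + features at true coordinates
  genomes <- vector("list", length(taxa))
  names(genomes) <- taxa
  for (tx in taxa) {
    seq_parts <- character(0)
    feats <- list()
    offset <- 0L
    add_piece <- function(nm, role, s) {
      len <- nchar(s)
      if (len > 0L) {
        if (role == "cds")
          feats[[length(feats) + 1L]] <<-
            list(name = nm, kind = "CDS",
                 intervals = matrix(c(offset, offset + len), ncol = 2),
                 strand = "+")
        if (role == "trnK_exon")
          feats[[length(feats) + 1L]] <<-
            list(name = "trnK", kind = "other",
                 intervals = matrix(c(offset, offset + len), ncol = 2),
                 strand = "+")
      }
      seq_parts <<- c(seq_parts, s)
      offset <<- offset + len
    }
    for (p in pieces)
      add_piece(p$name, p$role, .degap(alignment_strings(p$aln)[[tx]]))
    if (isTRUE(config$ir_duplicate))
      add_piece("ndhF", "cds", .degap(alignment_strings(loci$ndhF$aln)[[tx]]))
    add_piece("spacer_last", "noncoding",
              .degap(alignment_strings(last_spacer$aln)[[tx]]))
    genomes[[tx]] <- annotated_genome(tx, paste(seq_parts, collapse = ""),
                                      feats)
  }
  ## region alignments (independently "aligned" region sets)
  noncoding_pieces <- Filter(function(p) p$role != "cds", pieces)
  noncoding_pieces[[length(noncoding_pieces) + 1L]] <-
    list(name = "spacer_last", aln = last_spacer$aln, role = "noncoding")
  nc_list <- stats::setNames(lapply(noncoding_pieces, `[[`, "aln"),
                             paste0("noncoding_",
                                    vapply(noncoding_pieces, `[[`, "", "name")))
  cds_order <- vapply(Filter(function(p) p$role == "cds", pieces), `[[`, "",
                      "name")
  coding_list <- stats::setNames(lapply(cds_order, function(nm) loci[[nm]]$aln),
                                 cds_order)
  complete_pieces <- c(pieces,
                       list(list(name = "spacer_last", aln = last_spacer$aln,
                                 role = "noncoding")))
  complete_list <- stats::setNames(
    lapply(complete_pieces, `[[`, "aln"),
    vapply(complete_pieces, function(p)
      if (p$role == "cds") p$name else paste0("noncoding_", p$name),
      character(1)))
  three_gene_list <- list(
    rbcL = loci$rbcL$aln, ndhF = loci$ndhF$aln, matK = loci$matK$aln,
    noncoding_trnK_intron = raw_alignment(cbind(intronA$aln, intronB$aln)))
  regions <- list(
    three_gene = concatenate_loci(three_gene_list),
    coding = concatenate_loci(coding_list),
    noncoding = concatenate_loci(nc_list),
    complete = concatenate_loci(complete_list))
  selected <- lapply(loci, `[[`, "selected_sites")
  truth <- list(
    selected_sites = selected,
    gap_columns = lapply(regions, function(r)
      which(colSums(r$aln == "-") > 0L)),
    locus_alignments = lapply(loci, `[[`, "aln"))
  list(tree = tree, genomes = genomes, regions = regions, truth = truth,
       config = config)
}
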