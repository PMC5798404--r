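## SLAC-style per-site positive-selection scan: ancestral codon states by
## Fitch parsimony on a given tree, observed synonymous/nonsynonymous changes
## summed over edges, and a one-tailed binomial test of the nonsynonymous
## fraction against the site's expected nonsynonymous site fraction.

## Fitch parsimony for one site over arbitrary discrete states.
## `leaf_states` is a list (indexed by leaf number) of character vectors of
## admissible states (length 0 = missing -> treated as uninformative).
## Returns character vector of assigned states for all nodes (leaves first,
## then internals, ape numbering); ties broken by uniform RNG draw.
.fitch_site <- function(phy, leaf_states) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  post <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- leaf_states[[i]]
  children <- split(post$edge[, 2], post$edge[, 1])
  edge <- post$edge
  ## process edges in postorder: when all children of a node are done the
  ## node itself can be computed; postorder edge ordering guarantees this.
  done <- c(rep(TRUE, nt), rep(FALSE, nn))
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1]
    if (done[parent]) next
    kids <- children[[as.character(parent)]]
    if (any(!done[kids])) next
    kid_sets <- Filter(length, sets[kids])
    if (length(kid_sets) == 0L) {
      sets[[parent]] <- character(0)
    } else {
      s <- Reduce(intersect, kid_sets)
      if (length(s) == 0L) s <- Reduce(union, kid_sets)
      sets[[parent]] <- s
    }
    done[parent] <- TRUE
  }
  ## top-down assignment in preorder
  assign_state <- character(nt + nn)
  root <- nt + 1L
  pick <- function(s) if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
  rs <- sets[[root]]
  assign_state[root] <- if (length(rs) == 0L) NA_character_ else pick(rs)
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    parent <- pre[k, 1]; child <- pre[k, 2]
    s <- sets[[child]]
    ps <- assign_state[parent]
    if (length(s) == 0L) {
      assign_state[child] <- ps  # missing data inherit the parent state
    } else if (!is.na(ps) && ps %in% s) {
      assign_state[child] <- ps
    } else {
      assign_state[child] <- pick(s)
    }
  }
  assign_state
}

#' Per-site scan for positively selected codons
#'
#' A counting-based (SLAC-style) scan: ancestral codon states are
#' reconstructed by Fitch parsimony on the supplied tree; for each codon
#' site the observed synonymous (`sd`) and nonsynonymous (`nd`) changes are
#' summed over tree edges (pathway-averaged for multi-nucleotide codon
#' changes); the expected nonsynonymous fraction `pN = N / (S + N)` is taken
#' from the site's observed codon composition; and a one-tailed binomial
#' test asks whether the nonsynonymous fraction of the `m = sd + nd`
#' observed changes exceeds `pN`. Sites with `p < alpha` are flagged.
#' Deterministic given tree, alignment and seed (the seed only breaks
#' parsimony ties). Invariant sites are never flagged.
#'
#' @param aln in-frame codon alignment (`raw_alignment` or
#'   `partitioned_alignment`); run [prepare_codon_alignment()] first if stop
#'   codons may be present.
#' @param tree a `phylo` tree whose tip labels equal the alignment taxa.
#' @param alpha per-site significance level (no multiple-testing correction,
#'   mirroring per-site episodic-selection usage).
#' @param seed integer seed for parsimony tie-breaking.
#' @return list with `sites` (ordered integer vector of flagged codon
#'   indices, 0-based, matching the convention of the sites table consumed
#'   by [mask_selected_codons()]) and `stats` (data.frame: `codon_index`,
#'   `sd`, `nd`, `m`, `p`, `flagged`).
#' @export
site_selection_scan <- function(aln, tree, alpha = 0.05, seed = 1) {
  m <- if (inherits(aln, "partitioned_alignment")) aln$aln else aln
  if (!is.matrix(m)) m <- raw_alignment(m)
  if (ncol(m) %% 3L != 0L) stop("alignment width violates the codon frame")
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!setequal(tree$tip.label, rownames(m)))
    stop("tree leaf set does not equal the alignment taxon set")
  phy <- tree
  if (!ape::is.binary.phylo(phy)) phy <- ape::multi2di(phy, random = FALSE)
  ncod <- ncol(m) %/% 3L
  ord <- match(phy$tip.label, rownames(m))
  st <- .site_count_table()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- data.frame(codon_index = seq_len(ncod) - 1L,
                    sd = 0, nd = 0, m = 0L, p = 1, flagged = FALSE)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (s in seq_len(ncod)) {
    cols <- (3L * s - 2L):(3L * s)
    cods <- apply(m[ord, cols, drop = FALSE], 1L, paste, collapse = "")
    countable <- .is_countable_codon(cods)
    if (sum(countable) < 2L) next
    if (length(unique(cods[countable])) == 1L) next  # invariant site
    leaf_states <- lapply(seq_along(cods), function(i)
      if (countable[i]) cods[i] else character(0))
    states <- .fitch_site(phy, leaf_states)
    sd <- 0; nd <- 0
    for (k in seq_len(nrow(edge))) {
      a <- states[edge[k, 1]]; b <- states[edge[k, 2]]
      if (is.na(a) || is.na(b) || a == b) next
      d <- .codon_diffs_cached(a, b)
      sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
    }
    mtot <- as.integer(round(sd + nd))
    if (mtot == 0L) next
    pN <- mean(st[cods[countable], "N"]) / 3
    kmin <- as.integer(ceiling(nd - 1e-9))
    p <- stats::pbinom(kmin - 1L, mtot, pN, lower.tail = FALSE)
    out$sd[s] <- sd; out$nd[s] <- nd; out$m[s] <- mtot; out$p[s] <- p
    out$flagged[s] <- (p < alpha) && nd > 0
  }
  list(sites = out$codon_index[out$flagged], stats = out)
}
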