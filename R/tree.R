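## Desk-scale tree inference: Jukes-Cantor distances, neighbor-joining,
## nonparametric bootstrap, bipartition-frequency support mapping, and
## outgroup rooting. The engine is deliberately inference-agnostic plumbing:
## externally inferred trees (e.g. ML trees with support labels) can be
## imported with read_tree() and used everywhere a built tree is.

#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns with a gap or ambiguity code in either sequence are excluded
#' (pairwise deletion); `d = -(3/4) log(1 - (4/3) p)` with `p` the mismatch
#' proportion over the remaining columns.
#'
#' @param seq1,seq2 equal-length aligned strings (or character vectors).
#' @return nonnegative distance.
#' @export
jc_distance <- function(seq1, seq2) {
  a <- if (length(seq1) == 1L) strsplit(toupper(seq1), "")[[1]] else toupper(seq1)
  b <- if (length(seq2) == 1L) strsplit(toupper(seq2), "")[[1]] else toupper(seq2)
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% .BASES & b %in% .BASES
  if (!any(ok)) stop("zero comparable columns after pairwise deletion")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75)
    stop("saturation: mismatch proportion ", format(p), " >= 3/4")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param aln a [raw_alignment()] or [partitioned_alignment()].
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
jc_distance_matrix <- function(aln) {
  m <- if (inherits(aln, "partitioned_alignment")) aln$aln else aln
  n <- nrow(m)
  ## comparable-column and match counts via 0/1 cross-products (fast path)
  ok <- matrix(as.numeric(m %in% .BASES), nrow = n)
  comp <- tcrossprod(ok)
  match_ct <- matrix(0, n, n)
  for (b in .BASES) {
    ind <- matrix(as.numeric(m == b), nrow = n)
    match_ct <- match_ct + tcrossprod(ind)
  }
  offdiag <- row(comp) != col(comp)
  if (any(comp[offdiag] == 0)) {
    bad <- which(comp == 0 & offdiag, arr.ind = TRUE)[1, ]
    stop("zero comparable columns between ", rownames(m)[bad[1]], " and ",
         rownames(m)[bad[2]])
  }
  p <- 1 - match_ct / comp
  if (any(p[offdiag] >= 0.75)) {
    bad <- which(p >= 0.75 & offdiag, arr.ind = TRUE)[1, ]
    stop("saturation between ", rownames(m)[bad[1]], " and ",
         rownames(m)[bad[2]])
  }
  d <- -0.75 * log(1 - (4 / 3) * p)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (on an additive matrix the
#' generating topology and branch lengths are recovered exactly). Negative
#' estimated branch lengths are clamped to zero, with the deficit added to
#' the sister edge so path lengths are preserved where possible.
#'
#' @param D symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3L) stop("neighbor-joining needs at least 3 taxa")
  phy <- ape::nj(as.matrix(D))
  neg <- which(phy$edge.length < 0)
  for (k in neg) {
    parent <- phy$edge[k, 1]
    sibs <- setdiff(which(phy$edge[, 1] == parent), k)
    deficit <- -phy$edge.length[k]
    phy$edge.length[k] <- 0
    if (length(sibs) > 0L)
      phy$edge.length[sibs[1]] <- phy$edge.length[sibs[1]] + deficit
  }
  phy
}

#' Bootstrap replicate trees
#'
#' Resamples alignment columns with replacement (same width), then runs
#' [jc_distance_matrix()] + [nj_tree()] on each pseudo-replicate.
#' Reproducible given the seed.
#'
#' @param aln a [raw_alignment()] or [partitioned_alignment()].
#' @param n number of replicates (>= 1).
#' @param seed integer seed.
#' @return list of `phylo` trees of length `n`.
#' @export
bootstrap_trees <- function(aln, n = 200, seed = 1) {
  m <- if (inherits(aln, "partitioned_alignment")) aln$aln else aln
  if (ncol(m) == 0L) stop("cannot bootstrap an alignment with 0 columns")
  if (n < 1L) stop("n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n), function(b) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- m[, idx, drop = FALSE]
    class(rep_aln) <- class(m)
    nj_tree(jc_distance_matrix(rep_aln))
  })
}

## Canonical split keys of a tree: each nontrivial bipartition is keyed by
## the sorted taxa of the side NOT containing the alphabetically first leaf
## label, so rooted and unrooted representations of the same split agree.
.canonical_splits <- function(phy, all_taxa = sort(phy$tip.label)) {
  ref <- all_taxa[1]
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  keys <- character(0)
  for (cl in pp) {
    taxa <- sort(phy$tip.label[cl])
    if (length(taxa) == ntip) next
    side <- if (ref %in% taxa) sort(setdiff(all_taxa, taxa)) else taxa
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

.subset_key <- function(taxa, all_taxa) {
  ref <- sort(all_taxa)[1]
  taxa <- sort(taxa)
  side <- if (ref %in% taxa) sort(setdiff(all_taxa, taxa)) else taxa
  paste(side, collapse = "|")
}

## TRUE when a taxon subset induces a trivial bipartition (a pendant edge
## or the full leaf set); trivial splits are present in every tree.
.split_trivial <- function(taxa, all_taxa) {
  k <- length(intersect(taxa, all_taxa))
  k <= 1L || k >= length(all_taxa) - 1L
}

## Percentage of replicate split-key sets containing the subset's split.
.split_frequency <- function(rep_keys, taxa, all_taxa) {
  if (.split_trivial(taxa, all_taxa)) return(100)
  key <- .subset_key(taxa, all_taxa)
  100 * mean(vapply(rep_keys, function(k) key %in% k, logical(1)))
}

#' Bootstrap frequency of an arbitrary taxon subset
#'
#' The percentage of replicate trees containing the bipartition induced by
#' `taxa` (on the unrooted leaf set), so clades absent from a best tree
#' still receive a bootstrap percentage.
#'
#' @param replicates list of `phylo` trees over one leaf set.
#' @param taxa character vector, a proper subset of the leaf set.
#' @return percentage in `[0, 100]`.
#' @export
clade_support_query <- function(replicates, taxa) {
  all_taxa <- sort(replicates[[1]]$tip.label)
  rep_keys <- lapply(replicates, .canonical_splits, all_taxa = all_taxa)
  .split_frequency(rep_keys, taxa, all_taxa)
}

#' Map bootstrap support onto a best tree
#'
#' Support of each clade of the rooted best tree is the percentage of
#' replicates containing the corresponding bipartition (bipartition
#' identity on the unrooted leaf set).
#'
#' @param best a rooted `phylo` tree.
#' @param replicates list of `phylo` trees on the identical leaf set.
#' @return object of class `supported_tree`: list with `tree` (the best
#'   tree with `$node.label` support), `support` (named numeric, keys are
#'   `|`-joined sorted clade taxa), `clades` (named list of taxon subsets),
#'   `replicates` and `n_replicates`.
#' @export
map_support <- function(best, replicates) {
  all_taxa <- sort(best$tip.label)
  for (tr in replicates)
    if (!setequal(tr$tip.label, all_taxa))
      stop("replicate leaf set differs from the best tree's")
  rep_keys <- lapply(replicates, .canonical_splits, all_taxa = all_taxa)
  ntip <- length(best$tip.label)
  nn <- best$Nnode
  support <- numeric(0)
  clades <- list()
  node_label <- rep("", nn)
  for (node in (ntip + 1L):(ntip + nn)) {
    taxa <- sort(best$tip.label[.tips_under(best, node)])
    if (length(taxa) == ntip) next
    bp <- .split_frequency(rep_keys, taxa, all_taxa)
    ckey <- paste(taxa, collapse = "|")
    support[ckey] <- bp
    clades[[ckey]] <- taxa
    node_label[node - ntip] <- formatC(round(bp), format = "d")
  }
  tree <- best
  tree$node.label <- node_label
  structure(list(tree = tree, support = support, clades = clades,
                 replicates = replicates, n_replicates = length(replicates)),
            class = "supported_tree")
}

.tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, phy = phy))
}

#' Root a tree on the branch separating an outgroup
#'
#' Places the root on the edge separating `outgroup` from the remaining
#' taxa; if no single edge induces that split the outgroup is not
#' monophyletic and an error is raised. A single-leaf outgroup always
#' succeeds.
#'
#' @param tree a `phylo` tree.
#' @param outgroup character vector, proper nonempty subset of the leaves.
#' @return rooted `phylo` tree.
#' @export
root_tree <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (length(outgroup) == 0L || !all(outgroup %in% tips) ||
      length(outgroup) >= length(tips))
    stop("outgroup must be a proper nonempty subset of the leaf set")
  if (length(outgroup) > 1L) {
    key <- .subset_key(outgroup, sort(tips))
    if (!key %in% .canonical_splits(tree, sort(tips)))
      stop("outgroup not monophyletic: no single edge separates {",
           paste(outgroup, collapse = ","), "} from the rest")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("supported_tree: %d leaves, %d clades, %d bootstrap replicates\n",
              length(x$tree$tip.label), length(x$clades), x$n_replicates))
  invisible(x)
}

#' Build a rooted, supported tree from an alignment
#'
#' Convenience wrapper: JC distances, neighbor-joining, `n` bootstrap
#' replicates, outgroup rooting, support mapping.
#'
#' @param aln alignment.
#' @param outgroup outgroup taxa for rooting.
#' @param n_bootstrap replicate count (default 200).
#' @param seed integer seed.
#' @return a `supported_tree`.
#' @export
infer_supported_tree <- function(aln, outgroup, n_bootstrap = 200, seed = 1) {
  best <- nj_tree(jc_distance_matrix(aln))
  reps <- bootstrap_trees(aln, n = n_bootstrap, seed = seed)
  rooted <- root_tree(best, outgroup)
  map_support(rooted, reps)
}
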