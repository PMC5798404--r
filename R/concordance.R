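## Cross-tree concordance: clade extraction and naming, clade x tree
## support matrices, per-tree summaries, pairwise comparisons, support
## categories, and conflicting-clade detection.

#' Extract the clades of a rooted supported tree
#'
#' One entry per internal edge below the root: the subtended taxon subset
#' and its bootstrap percentage. Single-leaf clades and the full leaf set
#' are excluded. A binary rooted tree with `n` leaves yields `n - 2`
#' clades.
#'
#' @param st a `supported_tree` (see [map_support()]) or a rooted `phylo`
#'   tree with numeric `$node.label` support.
#' @return named list of clades; names are `|`-joined sorted taxon subsets,
#'   values are lists with `taxa` and `bp` (`NA` when no support label).
#' @export
extract_clades <- function(st) {
  if (inherits(st, "supported_tree")) {
    phy <- st$tree
    sup <- st$support
  } else {
    phy <- st
    sup <- NULL
  }
  ntip <- length(phy$tip.label)
  ## a basal trifurcation is the conventional Newick encoding of an
  ## unrooted tree; a basal polytomy of >3 children is treated as a rooted
  ## star
  if (sum(phy$edge[, 1] == ntip + 1L) == 3L)
    stop("extract_clades requires a rooted tree")
  out <- list()
  labels <- phy$node.label
  for (node in (ntip + 1L):(ntip + phy$Nnode)) {
    taxa <- sort(phy$tip.label[.tips_under(phy, node)])
    if (length(taxa) < 2L || length(taxa) == ntip) next
    key <- paste(taxa, collapse = "|")
    bp <- if (!is.null(sup)) unname(sup[key])
          else if (!is.null(labels))
            suppressWarnings(as.numeric(labels[node - ntip]))
          else NA_real_
    out[[key]] <- list(taxa = taxa, bp = bp)
  }
  out
}

## Preorder-ordered clade keys of a rooted tree (deterministic numbering).
.clades_preorder <- function(phy) {
  ntip <- length(phy$tip.label)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  pre_nodes <- c(ntip + 1L, rev(edge[, 2]))
  keys <- character(0)
  for (node in pre_nodes) {
    if (node <= ntip) next
    taxa <- sort(phy$tip.label[.tips_under(phy, node)])
    if (length(taxa) < 2L || length(taxa) == ntip) next
    keys <- c(keys, paste(taxa, collapse = "|"))
  }
  unique(keys)
}

#' Build a clade registry from a reference tree and other trees
#'
#' Clades of the reference tree are numbered first, in a deterministic
#' preorder traversal; clades found in non-reference trees but not yet
#' registered are appended in tree-code order, preorder within each tree.
#' All trees must share one leaf set.
#'
#' @param reference a `supported_tree` (the reference partition's tree).
#' @param others named list of `supported_tree`s, names are tree codes.
#' @param reference_code code of the reference tree (default `"X"`).
#' @return object of class `clade_registry`: list with `entries` (named
#'   list clade_id -> sorted taxon subset; ids are `1..k` as character),
#'   `origin` (clade_id -> tree code where first named) and
#'   `reference_code`.
#' @export
build_registry <- function(reference, others = list(), reference_code = "X") {
  ref_phy <- reference$tree
  leafset <- sort(ref_phy$tip.label)
  entries <- list()
  origin <- character(0)
  add_tree <- function(phy, code, entries, origin) {
    if (!setequal(sort(phy$tip.label), leafset))
      stop("leaf-set mismatch for tree ", code)
    for (key in .clades_preorder(phy)) {
      if (!key %in% vapply(entries, paste, "", collapse = "|")) {
        id <- as.character(length(entries) + 1L)
        entries[[id]] <- strsplit(key, "\\|")[[1]]
        origin[id] <- code
      }
    }
    list(entries = entries, origin = origin)
  }
  st <- add_tree(ref_phy, reference_code, entries, origin)
  for (code in names(others)) {
    st <- add_tree(others[[code]]$tree, code, st$entries, st$origin)
  }
  structure(list(entries = st$entries, origin = st$origin,
                 reference_code = reference_code),
            class = "clade_registry")
}

#' Clade-support matrix container
#'
#' @param entries named list clade_id -> sorted taxon subset (entries may
#'   be `NULL` when only ids are known, e.g. from a support spreadsheet).
#' @param bp numeric matrix, clades x tree codes, `NA` meaning absent /
#'   below threshold.
#' @param registry optional [build_registry()] result the matrix was built
#'   from.
#' @param threshold reporting threshold (default 50).
#' @return object of class `clade_support_matrix`.
#' @export
clade_support_matrix <- function(entries, bp, registry = NULL, threshold = 50) {
  stopifnot(is.matrix(bp), nrow(bp) == length(entries))
  if (any(bp[!is.na(bp)] < 0 | bp[!is.na(bp)] > 100))
    stop("bootstrap percentages must lie in [0, 100]")
  structure(list(entries = entries, bp = bp, registry = registry,
                 threshold = threshold, codes = colnames(bp)),
            class = "clade_support_matrix")
}

#' @export
print.clade_support_matrix <- function(x, ...) {
  cat(sprintf("clade_support_matrix: %d clades x %d trees (threshold %g)\n",
              nrow(x$bp), ncol(x$bp), x$threshold))
  invisible(x)
}

#' Fill a clade x tree support matrix
#'
#' For every registry clade and every tree: when the tree carries its
#' bootstrap replicate set, the clade's bipartition frequency is computed
#' (so clades absent from the best topology still get a value); otherwise
#' only clades present in the best topology get their mapped support and
#' all others are `NA` (absent). Exact values are retained internally;
#' reporting masks values below the threshold (see
#' [write_support_table()]).
#'
#' @param registry a [build_registry()] result.
#' @param trees named list of `supported_tree`s (names are tree codes).
#' @return a [clade_support_matrix()].
#' @export
support_matrix <- function(registry, trees) {
  ids <- names(registry$entries)
  codes <- names(trees)
  bp <- matrix(NA_real_, length(ids), length(codes),
               dimnames = list(ids, codes))
  for (code in codes) {
    st <- trees[[code]]
    if (!is.null(st$replicates) && length(st$replicates) > 0L) {
      all_taxa <- sort(st$tree$tip.label)
      rep_keys <- lapply(st$replicates, .canonical_splits,
                         all_taxa = all_taxa)
      for (id in ids)
        bp[id, code] <- .split_frequency(rep_keys, registry$entries[[id]],
                                         all_taxa)
    } else {
      for (id in ids) {
        ckey <- paste(registry$entries[[id]], collapse = "|")
        if (ckey %in% names(st$support)) bp[id, code] <- st$support[[ckey]]
      }
    }
  }
  clade_support_matrix(registry$entries, bp, registry = registry)
}

.reported <- function(mat) {
  ## reported semantics: values below the threshold count as absent
  ifelse(!is.na(mat$bp) & mat$bp >= mat$threshold, mat$bp, NA_real_)
}

#' Per-tree summary of reported clade support
#'
#' @param matrix a [clade_support_matrix()].
#' @return data.frame with one row per tree code: `code`, `n_clades_ge50`
#'   (clades at or above the reporting threshold), `mean_bp_ge50`,
#'   `n_max_support` (clades at 100).
#' @export
tree_summary <- function(matrix) {
  bp <- .reported(matrix)
  rows <- lapply(colnames(bp), function(code) {
    v <- bp[, code]
    v <- v[!is.na(v)]
    data.frame(code = code, n_clades_ge50 = length(v),
               mean_bp_ge50 = if (length(v)) mean(v) else 0,
               n_max_support = sum(v == 100), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise comparison of clade support between two trees
#'
#' Computes the comparison statistics of the partitioned-tree framework on
#' the reported (>= threshold) support values: shared-clade counts,
#' maximal-support counts, clades reported in exactly one tree (and how
#' many of those reach 70), the range / mean / absolute mean of support
#' differences over shared clades (sign convention `BP(code2) -
#' BP(code1)`), counts of identical, increased and decreased support, plus
#' counts of shared clades higher in each tree (and of those, >= 10 points
#' higher) and of clades >= 70 in one tree but below threshold in the
#' other.
#'
#' @param matrix a [clade_support_matrix()].
#' @param code1,code2 tree codes present in the matrix.
#' @return object of class `pairwise_comparison` (a list of the statistics
#'   above).
#' @export
compare_pair <- function(matrix, code1, code2) {
  if (!code1 %in% colnames(matrix$bp)) stop("unknown tree code: ", code1)
  if (!code2 %in% colnames(matrix$bp)) stop("unknown tree code: ", code2)
  bp <- .reported(matrix)
  b1 <- bp[, code1]; b2 <- bp[, code2]
  shared <- !is.na(b1) & !is.na(b2)
  only1 <- !is.na(b1) & is.na(b2)
  only2 <- is.na(b1) & !is.na(b2)
  d <- b2[shared] - b1[shared]
  structure(list(
    codes = c(code1, code2),
    n_shared_ge50 = sum(shared),
    n_shared_100 = sum(b1[shared] == 100 & b2[shared] == 100),
    n_only1_ge50 = sum(only1),
    n_only1_ge70 = sum(only1 & b1 >= 70, na.rm = TRUE),
    n_only2_ge50 = sum(only2),
    n_only2_ge70 = sum(only2 & b2 >= 70, na.rm = TRUE),
    diff_range = if (length(d)) range(d) else c(NA_real_, NA_real_),
    mean_diff = if (length(d)) mean(d) else NA_real_,
    sd_diff = if (length(d) > 1) stats::sd(d) else NA_real_,
    mean_abs_diff = if (length(d)) mean(abs(d)) else NA_real_,
    sd_abs_diff = if (length(d) > 1) stats::sd(abs(d)) else NA_real_,
    n_identical = sum(d == 0),
    n_increased = sum(d > 0),
    n_decreased = sum(d < 0),
    n_higher1 = sum(d < 0),
    n_higher1_ge10 = sum(d <= -10),
    n_higher2 = sum(d > 0),
    n_higher2_ge10 = sum(d >= 10)
  ), class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("pairwise_comparison %s vs %s: %d shared (>=50), %d at 100, mean diff %+0.2f\n",
              x$codes[1], x$codes[2], x$n_shared_ge50, x$n_shared_100,
              x$mean_diff))
  invisible(x)
}

#' Support category of a bootstrap percentage
#'
#' `<50` unsupported; `50-70` weak; `71-90` moderate; `91-100` strong
#' (integer boundaries inclusive, matching the convention of reporting
#' integer bootstrap percentages).
#'
#' @param bp numeric vector in `[0, 100]`.
#' @return character vector over
#'   `{"unsupported", "weak", "moderate", "strong"}`.
#' @export
support_category <- function(bp) {
  if (any(is.na(bp)) || any(bp < 0 | bp > 100))
    stop("bootstrap percentage outside [0, 100]")
  out <- character(length(bp))
  out[bp < 50] <- "unsupported"
  out[bp >= 50 & bp <= 70] <- "weak"
  out[bp > 70 & bp <= 90] <- "moderate"
  out[bp > 90] <- "strong"
  out
}

## Two clades on a common leaf set conflict iff their taxon sets overlap
## and neither contains the other.
.clades_conflict <- function(a, b) {
  ov <- length(intersect(a, b)) > 0L
  ov && !all(a %in% b) && !all(b %in% a)
}

#' Detect conflicting clades across trees
#'
#' Qualifying clades reach `BP >= threshold` in at least `min_trees` trees
#' (reported semantics). Two qualifying clades conflict when their taxon
#' sets overlap and neither is a subset of the other (on a common leaf set
#' this is bipartition incompatibility). The report lists the connected
#' components of the conflict graph, with each clade's supporting trees
#' and support range.
#'
#' @param matrix a [clade_support_matrix()] whose entries carry taxon
#'   subsets.
#' @param threshold conflict support threshold (default 70).
#' @param min_trees minimum number of trees reaching the threshold
#'   (default 1: a clade strongly supported in a single tree can conflict).
#' @return object of class `conflict_report`: list with `groups` (list of
#'   clade-id character vectors, each pairwise incompatible within the
#'   group's conflict graph component) and `clades` (data.frame:
#'   `clade_id`, `trees`, `bp_min`, `bp_max`).
#' @export
detect_conflicts <- function(matrix, threshold = 70, min_trees = 1) {
  bp <- .reported(matrix)
  entries <- matrix$entries
  if (any(vapply(entries, is.null, logical(1))))
    stop("conflict detection needs clade taxon sets in the matrix entries")
  qual <- which(rowSums(!is.na(bp) & bp >= threshold) >= min_trees)
  ids <- rownames(bp)[qual]
  n <- length(ids)
  adj <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (.clades_conflict(entries[[ids[i]]], entries[[ids[j]]])) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  seen <- rep(FALSE, n)
  groups <- list()
  for (i in seq_len(n)) {
    if (seen[i] || length(adj[[i]]) == 0L) next
    comp <- integer(0)
    stack <- i
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    groups[[length(groups) + 1L]] <- ids[sort(comp)]
  }
  member_ids <- unique(unlist(groups))
  clades <- if (length(member_ids)) {
    do.call(rbind, lapply(member_ids, function(id) {
      v <- bp[id, ]
      sup <- !is.na(v) & v >= threshold
      data.frame(clade_id = id,
                 trees = paste(colnames(bp)[sup], collapse = ","),
                 bp_min = min(v[sup]), bp_max = max(v[sup]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(clade_id = character(0), trees = character(0),
               bp_min = numeric(0), bp_max = numeric(0))
  }
  structure(list(groups = groups, clades = clades, threshold = threshold),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf("conflict_report: %d conflict group(s) at threshold %g\n",
              length(x$groups), x$threshold))
  invisible(x)
}

#' Whole-matrix clade bookkeeping statistics
#'
#' Recomputes, from a clade x tree support matrix, the headline clade
#' counts of a partitioned-tree study: clades reported in at least one
#' tree, clades maximally supported in one / all of a designated tree
#' group, reference-tree clade count, per-tree count and mean ranges, and
#' clades confined to single trees.
#'
#' @param matrix a [clade_support_matrix()].
#' @param plastome_codes tree codes of the genome-scale group (default
#'   `E`-`H`, `Q`, `R`, `W`-`Z` intersected with the matrix's codes).
#' @param reference_code the reference tree code (default `"X"`).
#' @return list of named counts and ranges.
#' @export
clade_matrix_stats <- function(matrix,
                               plastome_codes =
                                 intersect(c("E", "F", "G", "H", "Q", "R",
                                             "W", "X", "Y", "Z"),
                                           colnames(matrix$bp)),
                               reference_code = "X") {
  bp <- .reported(matrix)
  pl <- bp[, plastome_codes, drop = FALSE]
  ts <- tree_summary(matrix)
  list(
    n_clades_reported = sum(rowSums(!is.na(bp)) > 0),
    n_max_all_trees = sum(rowSums(!is.na(bp) & bp == 100) == ncol(bp)),
    n_max_any_plastome = sum(rowSums(!is.na(pl) & pl == 100) > 0),
    n_max_all_plastome = sum(rowSums(!is.na(pl) & pl == 100) == ncol(pl)),
    n_reference = if (reference_code %in% colnames(bp))
      sum(!is.na(bp[, reference_code])) else NA_integer_,
    n_reported_any_plastome = sum(rowSums(!is.na(pl)) > 0),
    n_single_plastome = sum(rowSums(!is.na(pl)) == 1),
    per_tree_counts = stats::setNames(ts$n_clades_ge50, ts$code),
    per_tree_means = stats::setNames(ts$mean_bp_ge50, ts$code)
  )
}
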