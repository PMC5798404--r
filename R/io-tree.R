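#' Read a Newick tree with bootstrap support labels
#'
#' Internal-node labels that parse as numbers are interpreted as bootstrap
#' percentages (RAxML-style); missing labels mean "support absent", not
#' zero. Support values outside `[0, 100]` are an error.
#'
#' @param path Newick file path.
#' @return a `phylo` object; numeric support values, where present, are
#'   kept in `$node.label` (as read) and also in `$edge.support`, a numeric
#'   vector parallel to the edge matrix with `NA` on terminal edges and on
#'   internal edges lacking a label.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (length(gregexpr("\\(", txt)[[1]]) != length(gregexpr("\\)", txt)[[1]]))
    stop("unbalanced parentheses in Newick file ", path)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("cannot parse Newick in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(phy)) stop("cannot parse Newick in ", path)
  .attach_edge_support(phy)
}

.attach_edge_support <- function(phy) {
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    lab_present <- nzchar(phy$node.label) & !is.na(sup)
    if (any(lab_present & (sup < 0 | sup > 100)))
      stop("support label outside [0, 100]: ",
           paste(sup[lab_present & (sup < 0 | sup > 100)], collapse = ", "))
    ntip <- length(phy$tip.label)
    es <- rep(NA_real_, nrow(phy$edge))
    internal <- phy$edge[, 2] > ntip
    node_idx <- phy$edge[internal, 2] - ntip
    vals <- ifelse(lab_present, sup, NA_real_)
    es[internal] <- vals[node_idx]
    phy$edge.support <- es
  } else {
    phy$edge.support <- rep(NA_real_, nrow(phy$edge))
  }
  phy
}

#' Write a tree as Newick with integer support labels
#'
#' Numeric node support (from `$node.label`) is rounded to integers for
#' display, matching the convention of reporting integer bootstrap
#' percentages; branch lengths are preserved.
#'
#' @param tree a `phylo` object (optionally with `$node.label` support).
#' @param path output file path.
#' @param digits digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, digits = 10) {
  phy <- tree
  phy$edge.support <- NULL
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    phy$node.label <- ifelse(is.na(sup), phy$node.label,
                             formatC(round(sup), format = "d"))
  }
  ape::write.tree(phy, file = path, digits = digits)
  invisible(path)
}
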