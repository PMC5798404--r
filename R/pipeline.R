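#' Pipeline configuration
#'
#' @param mode `"simulate"` (build everything from [sim_config()]),
#'   or `"alignments"` (consume pre-aligned region files; supply
#'   `region_paths`, and either `tree_paths` for imported trees or let the
#'   built-in engine run).
#' @param sim a [sim_config()] (simulate mode).
#' @param region_paths named character vector (`three_gene`, `coding`,
#'   `noncoding`, `complete`) of alignment files (alignments mode).
#' @param tree_paths optional named character vector (codes -> Newick
#'   files) of externally inferred trees with support labels.
#' @param codes partition codes to build (subset of the fourteen).
#' @param alpha per-site selection significance level.
#' @param n_bootstrap bootstrap replicates per tree.
#' @param outgroup outgroup taxa for rooting (simulate mode default: the
#'   first taxon).
#' @param conflict_threshold BP threshold for conflict detection.
#' @param reference_code reference tree code for clade naming.
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "alignments"),
                            sim = sim_config(), region_paths = NULL,
                            tree_paths = NULL, codes = partition_codes(),
                            alpha = 0.05, n_bootstrap = 100,
                            outgroup = NULL, conflict_threshold = 70,
                            reference_code = "X", out_dir = tempfile("run"),
                            seed = 1) {
  mode <- match.arg(mode)
  bad <- setdiff(codes, partition_codes())
  if (length(bad) > 0L)
    stop("invalid partition code(s) requested: ", paste(bad, collapse = ", "))
  if (!reference_code %in% codes)
    stop("reference code ", reference_code, " not among requested codes")
  structure(as.list(environment()), class = "pipeline_config")
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
}

#' Run the full partition / selection / tree / concordance pipeline
#'
#' Stages: obtain the four region alignments (simulated with ground truth,
#' or read from files); scan CDS loci for selection and positively
#' selected codons; build the requested partitions along the fixed
#' derivation graph; infer a bootstrapped tree per partition (or import
#' external trees); register clades against the reference tree; and emit
#' the support matrix, per-tree summaries, all requested pairwise
#' comparisons and the conflict report. Rerunning with the same config and
#' seed reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory objects: `partitions`,
#'   `selection`, `sites`, `trees`, `registry`, `matrix`, `summary`,
#'   `pairwise`, `conflicts`, plus `out_dir` with the written files
#'   (manifest.tsv, sites.tsv, selection_summary.tsv, trees/<code>.nwk,
#'   matrix.tsv, tree_summary.tsv, pairwise.tsv, conflicts.tsv, run.log).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "trees"), showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logcon))
  .log_line(logcon, "init", sprintf("mode=%s seed=%d", config$mode,
                                    config$seed))
  ## stage 1: regions
  if (config$mode == "simulate") {
    sim <- config$sim
    sim$seed <- config$seed
    bundle <- assemble_synthetic_plastomes(sim)
    regions <- bundle$regions
    truth <- bundle$truth
    true_tree <- bundle$tree
    write_tree(true_tree, file.path(config$out_dir, "true_tree.nwk"))
  } else {
    need <- c("three_gene", "coding", "noncoding", "complete")
    if (!all(need %in% names(config$region_paths)))
      stop("stage regions: region_paths must name ",
           paste(need, collapse = ", "))
    regions <- lapply(config$region_paths[need], function(p)
      partitioned_alignment(read_alignment(p)))
    truth <- NULL
    true_tree <- NULL
  }
  .log_line(logcon, "regions", sprintf("widths: %s",
    paste(sprintf("%s=%d", names(regions),
                  vapply(regions, n_columns, 0L)), collapse = " ")))
  ## stage 2: selection scan on CDS loci of the coding region
  coding <- regions$coding
  cds_loci <- setdiff(unique(coding$meta$locus[!is.na(coding$meta$codon_pos)]),
                      "noncoding")
  guide_tree <- if (!is.null(true_tree)) true_tree else
    nj_tree(jc_distance_matrix(strip_gapped_columns(coding)))
  selection <- list()
  sites <- list()
  for (locus in cds_loci) {
    cols <- which(coding$meta$locus == locus)
    sub <- coding$aln[, cols, drop = FALSE]
    class(sub) <- class(coding$aln)
    sub <- prepare_codon_alignment(sub)
    zt <- locus_z_test(sub, "purifying", alpha = config$alpha,
                       seed = config$seed, locus = locus)
    scan <- site_selection_scan(sub, guide_tree, alpha = config$alpha,
                                seed = config$seed)
    zt$positive_sites <- scan$sites
    selection[[locus]] <- zt
    sites[[locus]] <- scan$sites
    .log_line(logcon, "selection",
              sprintf("%s: verdict=%s p=%.3g positive=%d", locus,
                      zt$verdict, zt$p, length(scan$sites)))
  }
  sites_df <- do.call(rbind, lapply(names(sites), function(l)
    if (length(sites[[l]]) > 0L)
      data.frame(locus = l, codon_index = sites[[l]]) else NULL))
  if (is.null(sites_df))
    sites_df <- data.frame(locus = character(0), codon_index = integer(0))
  utils::write.table(sites_df, file.path(config$out_dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(selection_summary(selection),
                     file.path(config$out_dir, "selection_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ## stage 3: partitions
  suite <- build_partition_suite(regions, sites)
  suite <- suite[config$codes]
  manifest <- data.frame(
    code = names(suite),
    n_taxa = vapply(suite, function(p) nrow(p$aln), 0L),
    n_columns = vapply(suite, n_columns, 0L),
    derivation = c(A = "three_gene", B = "strip(A)", C = "mask(A)",
                   D = "strip(C)", E = "coding", F = "strip(E)",
                   G = "mask(E)", H = "strip(G)", Q = "noncoding",
                   R = "strip(Q)", W = "complete", X = "strip(W)",
                   Y = "mask(W)", Z = "strip(Y)")[names(suite)])
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(logcon, "partition", paste(manifest$code, manifest$n_columns,
                                       sep = "=", collapse = " "))
  ## stage 4: trees
  outgroup <- config$outgroup
  if (is.null(outgroup)) outgroup <- taxa_of(regions$complete)[1]
  trees <- list()
  for (code in names(suite)) {
    if (!is.null(config$tree_paths) && code %in% names(config$tree_paths)) {
      phy <- read_tree(config$tree_paths[[code]])
      rooted <- root_tree(phy, outgroup)
      sup <- extract_clades(rooted)
      st <- structure(list(tree = rooted,
                           support = stats::setNames(
                             vapply(sup, function(x)
                               if (is.null(x$bp) || is.na(x$bp)) NA_real_
                               else x$bp, 0),
                             names(sup)),
                           clades = lapply(sup, `[[`, "taxa"),
                           replicates = NULL, n_replicates = 0L),
                      class = "supported_tree")
    } else {
      st <- infer_supported_tree(suite[[code]], outgroup,
                                 n_bootstrap = config$n_bootstrap,
                                 seed = config$seed + match(code,
                                                            partition_codes()))
    }
    trees[[code]] <- st
    write_tree(st$tree, file.path(config$out_dir, "trees",
                                  paste0(code, ".nwk")))
    .log_line(logcon, "tree", sprintf("%s: %d clades", code,
                                      length(st$clades)))
  }
  ## stage 5: concordance
  ref <- trees[[config$reference_code]]
  registry <- build_registry(ref, trees[setdiff(names(trees),
                                                config$reference_code)],
                             reference_code = config$reference_code)
  mat <- support_matrix(registry, trees)
  write_support_table(mat, file.path(config$out_dir, "matrix.tsv"))
  ts <- tree_summary(mat)
  utils::write.table(ts, file.path(config$out_dir, "tree_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pair_specs <- list(c("A", "C"), c("B", "D"), c("E", "G"), c("F", "H"),
                     c("W", "Y"), c("X", "Z"), c("A", "B"), c("C", "D"),
                     c("E", "F"), c("G", "H"), c("Q", "R"), c("W", "X"),
                     c("Y", "Z"), c("A", "E"), c("B", "F"), c("C", "G"),
                     c("D", "H"))
  pair_specs <- Filter(function(p) all(p %in% names(trees)), pair_specs)
  pairwise <- lapply(pair_specs, function(p) compare_pair(mat, p[1], p[2]))
  names(pairwise) <- vapply(pair_specs, paste, "", collapse = "_")
  pw_df <- do.call(rbind, lapply(pairwise, function(x)
    data.frame(pair = paste(x$codes, collapse = " vs "),
               n_shared_ge50 = x$n_shared_ge50, n_shared_100 = x$n_shared_100,
               mean_diff = x$mean_diff, mean_abs_diff = x$mean_abs_diff,
               n_identical = x$n_identical, n_increased = x$n_increased,
               n_decreased = x$n_decreased)))
  utils::write.table(pw_df, file.path(config$out_dir, "pairwise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conflicts <- detect_conflicts(mat, threshold = config$conflict_threshold)
  utils::write.table(conflicts$clades,
                     file.path(config$out_dir, "conflicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(logcon, "concord",
            sprintf("%d registered clades, %d conflict groups",
                    length(registry$entries), length(conflicts$groups)))
  invisible(list(partitions = suite, selection = selection, sites = sites,
                 trees = trees, registry = registry, matrix = mat,
                 summary = ts, pairwise = pairwise, conflicts = conflicts,
                 truth = truth, true_tree = true_tree,
                 out_dir = config$out_dir))
}
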