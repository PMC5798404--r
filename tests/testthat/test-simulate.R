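test_that("tree simulation is seeded, sized and height-scaled", {
  cfg <- sim_config(n_taxa = 8, tree_height = 0.5, seed = 4)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_length(t1$tip.label, 8L)
  expect_equal(t1$Nnode, 7L)
  depths <- ape::node.depth.edgelength(t1)[1:8]
  expect_equal(mean(depths), 0.5, tolerance = 1e-12)
  t0 <- simulate_tree(sim_config(n_taxa = 5, tree_height = 0, seed = 1))
  expect_true(all(t0$edge.length == 0))
  expect_error(simulate_tree(structure(list(n_taxa = 2, tree_model = "yule",
                                            seed = 1),
                                       class = "sim_config")), ">= 3")
})

test_that("coding simulation respects omega regimes and zero branches", {
  cfg <- sim_config(n_taxa = 6, codons_per_locus = 50, tree_height = 0,
                    seed = 2)
  tr <- simulate_tree(cfg)
  set.seed(10)
  loc <- simulate_coding_locus(tr, cfg, "L")
  s <- alignment_strings(loc$aln)
  expect_true(all(s == s[[1]]))  # zero-length branches: identical leaves
  expect_length(loc$selected_sites, round(0.05 * 50))
  ## omega_background = 0-ish forbids nonsynonymous change off selected sites
  cfg2 <- sim_config(n_taxa = 6, codons_per_locus = 60, tree_height = 0.3,
                     omega_background = 1e-9, selected_fraction = 0,
                     seed = 3)
  tr2 <- simulate_tree(cfg2)
  set.seed(11)
  loc2 <- simulate_coding_locus(tr2, cfg2, "L")
  m <- loc2$aln
  aas <- apply(m, 1, function(row) {
    paste(vapply(seq(1, ncol(m), 3), function(j)
      seqinr::translate(row[j:(j + 2)]), ""), collapse = "")
  })
  expect_true(all(aas == aas[[1]]))  # protein invariant
  ## no stops anywhere (excluded from the state space)
  expect_false(any(grepl("\\*", aas)))
})

test_that("noncoding simulation tracks exact gap-column ground truth", {
  cfg0 <- sim_config(n_taxa = 6, indel_rate = 0, seed = 5)
  tr <- simulate_tree(cfg0)
  set.seed(20)
  nc0 <- simulate_noncoding_region(tr, cfg0, length = 500)
  expect_length(nc0$gap_columns, 0L)
  expect_identical(strip_gapped_columns(nc0$aln), nc0$aln)
  cfg1 <- sim_config(n_taxa = 6, indel_rate = 0.1, seed = 5)
  set.seed(21)
  nc1 <- simulate_noncoding_region(tr, cfg1, length = 500)
  expect_gt(length(nc1$gap_columns), 0L)
  stripped <- strip_gapped_columns(nc1$aln)
  expect_equal(ncol(stripped), ncol(nc1$aln) - length(nc1$gap_columns))
  ## stripped alignment contains no truth gap column and all others
  kept <- setdiff(seq_len(ncol(nc1$aln)), nc1$gap_columns)
  expect_identical(unclass(stripped)[, , drop = FALSE],
                   unclass(nc1$aln)[, kept, drop = FALSE])
})

test_that("long-run pairwise distances track path lengths on the tree", {
  cfg <- sim_config(n_taxa = 6, tree_height = 0.15, indel_rate = 0,
                    gamma_shape = 1000, gtr_rates = rep(1, 6),
                    base_freqs = rep(0.25, 4), seed = 8)
  tr <- simulate_tree(cfg)
  set.seed(30)
  nc <- simulate_noncoding_region(tr, cfg, length = 40000)
  D <- jc_distance_matrix(nc$aln)
  path <- cophenetic(tr)[rownames(D), colnames(D)]
  off <- upper.tri(D)
  expect_true(all(abs(D[off] - path[off]) / pmax(path[off], 1e-9) < 0.10))
})

test_that("assembled plastomes are consistent with their ground truth", {
  suppressWarnings(bundle <- assemble_synthetic_plastomes(
    sim_config(n_taxa = 6, n_cds_loci = 4, codons_per_locus = 40,
               noncoding_length = 600, seed = 13)))
  expect_length(bundle$genomes, 6L)
  ## extraction round-trip: CDS extraction recovers the simulated loci,
  ## including IR de-duplication of the duplicated copy
  for (tx in names(bundle$genomes)) {
    cds <- extract_cds_loci(bundle$genomes[[tx]])
    for (locus in names(bundle$truth$locus_alignments)) {
      want <- gsub("-", "",
                   alignment_strings(bundle$truth$locus_alignments[[locus]])[[tx]])
      expect_identical(cds$sequence[cds$locus == locus], want)
    }
  }
  ## per-taxon conservation: coding-union + noncoding = genome length
  for (tx in names(bundle$genomes)) {
    g <- bundle$genomes[[tx]]
    cds_feats <- Filter(function(f) f$kind == "CDS", g$features)
    cov <- sum(vapply(cds_feats, function(f)
      sum(f$intervals[, 2] - f$intervals[, 1]), 0))  # features don't overlap
    expect_equal(cov + nchar(extract_noncoding(g)), g$length)
  }
  ## region gap truth: every gap column in the emitted regions is recorded
  for (rg in names(bundle$regions)) {
    aln <- bundle$regions[[rg]]$aln
    expect_identical(which(colSums(aln == "-") > 0L),
                     bundle$truth$gap_columns[[rg]])
  }
  ## partition suite over the synthetic regions has the 14 codes
  suite <- build_partition_suite(bundle$regions, list())
  expect_setequal(names(suite), partition_codes())
})

test_that("same-tree partitions do not conflict; different trees do", {
  same_conflicts <- function(seed, different) {
    cfg <- sim_config(n_taxa = 10, tree_height = 0.3, indel_rate = 0,
                      seed = seed)
    tr1 <- simulate_tree(cfg, seed = seed)
    tr2 <- if (different) simulate_tree(cfg, seed = seed + 500) else tr1
    set.seed(seed + 100)
    a1 <- simulate_noncoding_region(tr1, cfg, length = 4000)$aln
    a2 <- simulate_noncoding_region(tr2, cfg, length = 4000)$aln
    og <- tr1$tip.label[1]
    st1 <- infer_supported_tree(a1, og, n_bootstrap = 60, seed = seed)
    st2 <- infer_supported_tree(a2, og, n_bootstrap = 60, seed = seed + 1)
    reg <- build_registry(st1, list(K = st2), reference_code = "X")
    mat <- support_matrix(reg, list(X = st1, K = st2))
    length(detect_conflicts(mat, threshold = 70)$groups)
  }
  seeds <- 1:8
  same <- vapply(seeds, same_conflicts, 0L, different = FALSE)
  diff <- vapply(seeds, same_conflicts, 0L, different = TRUE)
  expect_gte(sum(same == 0), 7)   # concordant partitions: almost never conflict
  expect_gte(sum(diff >= 1), 7)   # discordant histories: almost always conflict
})
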