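mk_supported <- function(newick, bps = NULL) {
  phy <- ape::read.tree(text = newick)
  clades <- extract_clades(phy)
  keys <- names(clades)
  sup <- if (is.null(bps)) setNames(rep(100, length(keys)), keys)
         else setNames(bps[seq_along(keys)], keys)
  structure(list(tree = phy, support = sup,
                 clades = lapply(clades, `[[`, "taxa"),
                 replicates = NULL, n_replicates = 0L),
            class = "supported_tree")
}

test_that("clade extraction yields n-2 clades on binary rooted trees", {
  cl <- extract_clades(ape::read.tree(text = "((A,B),(C,D));"))
  expect_setequal(names(cl), c("A|B", "C|D"))
  cat5 <- extract_clades(ape::read.tree(text = "(A,(B,(C,(D,E))));"))
  expect_setequal(names(cat5), c("D|E", "C|D|E", "B|C|D|E"))
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    phy <- ape::rtree(n, rooted = TRUE)
    expect_length(extract_clades(phy), n - 2L)
  }
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_length(extract_clades(star), 0L)
  expect_error(extract_clades(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("the registry numbers reference clades first, novel clades after", {
  ref <- mk_supported("((A,B),((C,D),E));")
  other <- mk_supported("(((A,B),C),(D,E));")
  reg <- build_registry(ref, list(K = other), reference_code = "X")
  ## reference clades all named with origin X, novel ones with origin K
  ref_keys <- vapply(extract_clades(ref$tree), function(x)
    paste(x$taxa, collapse = "|"), "")
  reg_keys <- vapply(reg$entries, paste, "", collapse = "|")
  expect_setequal(unname(reg_keys[reg$origin == "X"]), unname(ref_keys))
  expect_setequal(
    unname(reg_keys[reg$origin == "K"]),
    unname(setdiff(vapply(extract_clades(other$tree), function(x)
      paste(x$taxa, collapse = "|"), ""), ref_keys)))
  ## shared + novel = union size
  expect_length(reg$entries,
                length(union(reg_keys[reg$origin == "X"],
                             vapply(extract_clades(other$tree), function(x)
                               paste(x$taxa, collapse = "|"), ""))))
  ## identical trees add nothing; numbering is deterministic
  reg2 <- build_registry(ref, list(K = ref))
  expect_length(reg2$entries, length(ref_keys))
  reg3 <- build_registry(ref, list(K = other))
  expect_identical(reg3$entries, reg$entries)
  mismatch <- mk_supported("((A,B),(C,Z));")
  expect_error(build_registry(ref, list(K = mismatch)), "leaf-set mismatch")
})

test_that("the support matrix equals brute-force per-tree clade lookup", {
  trees <- list(X = mk_supported("((A,B),((C,D),E));", c(90, 80, 70)),
                W = mk_supported("((A,B),((C,E),D));", c(95, 60, 99)),
                R = mk_supported("(((A,B),C),(D,E));", c(88, 77, 66)))
  reg <- build_registry(trees$X, trees[c("W", "R")])
  mat <- support_matrix(reg, trees)
  for (id in names(reg$entries)) {
    key <- paste(reg$entries[[id]], collapse = "|")
    for (code in names(trees)) {
      want <- if (key %in% names(trees[[code]]$support))
        unname(trees[[code]]$support[[key]]) else NA_real_
      expect_identical(unname(mat$bp[id, code]), want)
    }
  }
})

test_that("per-tree summaries use the >=50 reporting semantics", {
  bp <- matrix(c(100, 100, 50, 40), ncol = 1,
               dimnames = list(paste0("c", 1:4), "X"))
  m <- clade_support_matrix(vector("list", 4), bp)
  s <- tree_summary(m)
  expect_equal(s$n_clades_ge50, 3L)
  expect_equal(s$mean_bp_ge50, mean(c(100, 100, 50)), tolerance = 1e-12)
  expect_equal(s$n_max_support, 2L)
  ## all below threshold: zeros
  m0 <- clade_support_matrix(vector("list", 2),
                             matrix(c(40, NA), ncol = 1,
                                    dimnames = list(c("a", "b"), "X")))
  s0 <- tree_summary(m0)
  expect_equal(s0$n_clades_ge50, 0L)
  expect_equal(s0$mean_bp_ge50, 0)
})

test_that("pairwise comparisons compute the shared/only bookkeeping", {
  bp <- matrix(c(90, 100, 60,
                 100, 100, NA), ncol = 2,
               dimnames = list(c("c1", "c2", "c3"), c("T1", "T2")))
  m <- clade_support_matrix(vector("list", 3), bp)
  cmp <- compare_pair(m, "T1", "T2")
  expect_equal(cmp$n_shared_ge50, 2L)
  expect_equal(cmp$n_shared_100, 1L)
  expect_equal(cmp$n_only1_ge50, 1L)
  expect_equal(cmp$n_only2_ge50, 0L)
  expect_equal(cmp$mean_diff, 5)
  expect_equal(cmp$n_identical + cmp$n_increased + cmp$n_decreased,
               cmp$n_shared_ge50)
  ## identical columns: all differences zero
  bp2 <- cbind(T1 = c(90, 100), T2 = c(90, 100))
  rownames(bp2) <- c("c1", "c2")
  cmp2 <- compare_pair(clade_support_matrix(vector("list", 2), bp2),
                       "T1", "T2")
  expect_equal(cmp2$n_shared_ge50, 2L)
  expect_equal(cmp2$n_identical, 2L)
  expect_equal(cmp2$n_increased + cmp2$n_decreased, 0L)
  expect_error(compare_pair(m, "T1", "nope"), "unknown tree code")
})

test_that("the bookkeeping identity holds on random support matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    bp <- matrix(sample(c(NA, 30, 50:100), 2 * n, replace = TRUE), ncol = 2,
                 dimnames = list(paste0("c", 1:n), c("U", "V")))
    cmp <- compare_pair(clade_support_matrix(vector("list", n), bp),
                        "U", "V")
    expect_equal(cmp$n_identical + cmp$n_increased + cmp$n_decreased,
                 cmp$n_shared_ge50)
    expect_true(all(is.na(cmp$diff_range)) ||
                  all(cmp$diff_range >= -100 & cmp$diff_range <= 100))
  }
})

test_that("support categories map the published boundaries", {
  expect_equal(support_category(c(0, 49, 50, 70, 71, 90, 91, 100)),
               c("unsupported", "unsupported", "weak", "weak", "moderate",
                 "moderate", "strong", "strong"))
  expect_error(support_category(101), "outside")
  expect_error(support_category(-1), "outside")
})

test_that("conflict detection matches the overlap-without-nesting rule", {
  entries <- list(g1 = c("A", "B", "C"), g2 = c("B", "C", "D"),
                  g3 = c("A", "B"), g4 = c("D", "E"))
  ## only g1 and g2 reach the conflict threshold; g3 (nested in g1) and g4
  ## stay below it
  bp <- matrix(c(90, NA, 60, NA, NA, 85, NA, 60), ncol = 2,
               dimnames = list(names(entries), c("T1", "T2")))
  m <- clade_support_matrix(entries, bp)
  rep70 <- detect_conflicts(m, threshold = 70)
  ## {A,B,C}@90 vs {B,C,D}@85: exactly one conflict group of two
  expect_length(rep70$groups, 1L)
  expect_setequal(rep70$groups[[1]], c("g1", "g2"))
  ## nesting ({A,B} in {A,B,C}) and disjointness ({D,E}) are compatible
  expect_false("g3" %in% unlist(rep70$groups))
  expect_false("g4" %in% unlist(rep70$groups))
})

test_that("conflict components agree with the brute-force oracle", {
  for (seed in 1:60) {
    set.seed(seed)
    n_leaves <- sample(4:8, 1)
    entries <- random_clade_set(n_leaves, sample(3:8, 1), seed)
    names(entries) <- paste0("c", seq_along(entries))
    n_trees <- sample(2:3, 1)
    bp <- matrix(sample(c(NA, 55, 72, 95, 100), length(entries) * n_trees,
                        replace = TRUE),
                 ncol = n_trees,
                 dimnames = list(names(entries),
                                 LETTERS[seq_len(n_trees)]))
    m <- clade_support_matrix(entries, bp)
    got <- detect_conflicts(m, threshold = 70)
    qual <- names(entries)[rowSums(!is.na(bp) & bp >= 70) >= 1]
    want <- conflict_groups_oracle(entries, qual)
    norm <- function(gs) sort(vapply(gs, function(g)
      paste(sort(g), collapse = ","), ""))
    expect_identical(norm(got$groups), norm(want))
  }
})

test_that("compatible clade sets assemble into a single tree", {
  ## clades of one tree are pairwise non-conflicting
  for (seed in 1:10) {
    set.seed(seed)
    phy <- ape::rtree(sample(5:9, 1), rooted = TRUE)
    cl <- extract_clades(phy)
    entries <- lapply(cl, `[[`, "taxa")
    names(entries) <- paste0("c", seq_along(entries))
    bp <- matrix(100, length(entries), 1,
                 dimnames = list(names(entries), "X"))
    rep <- detect_conflicts(clade_support_matrix(entries, bp))
    expect_length(rep$groups, 0L)
  }
})

test_that("matrix-wide statistics recompute the headline clade counts", {
  codes <- c("A", "B", "E", "Q", "X")
  set.seed(33)
  n <- 40
  bp <- matrix(sample(c(NA, 55, 80, 100), n * length(codes), replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)),
               ncol = length(codes), dimnames = list(paste0("c", 1:n), codes))
  m <- clade_support_matrix(vector("list", n), bp)
  st <- clade_matrix_stats(m, plastome_codes = c("E", "Q", "X"),
                           reference_code = "X")
  ## independent brute-force recomputation from the raw matrix
  rep_bp <- ifelse(!is.na(bp) & bp >= 50, bp, NA)
  pl <- rep_bp[, c("E", "Q", "X")]
  expect_equal(st$n_clades_reported, sum(rowSums(!is.na(rep_bp)) > 0))
  expect_equal(st$n_max_any_plastome, sum(apply(pl, 1, function(v)
    any(!is.na(v) & v == 100))))
  expect_equal(st$n_max_all_plastome, sum(apply(pl, 1, function(v)
    all(!is.na(v) & v == 100))))
  expect_equal(st$n_reference, sum(!is.na(rep_bp[, "X"])))
  expect_equal(unname(st$per_tree_counts["B"]),
               sum(!is.na(rep_bp[, "B"])))
})
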