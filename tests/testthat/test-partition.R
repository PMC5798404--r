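test_that("CDS extraction de-duplicates IR copies and handles strand", {
  set.seed(5)
  res <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  ## force a known minus-strand CDS: forward substring CAT -> extracted ATG
  res <- paste0(substr(res, 1, 99), "CAT", substr(res, 103, 200))
  g <- annotated_genome("t1", res, list(
    list(name = "ndhB", kind = "CDS",
         intervals = matrix(c(10, 40), ncol = 2), strand = "+"),
    list(name = "psbA", kind = "CDS",
         intervals = matrix(c(99, 102), ncol = 2), strand = "-"),
    list(name = "ndhB", kind = "CDS",  # IR duplicate, later coordinate
         intervals = matrix(c(150, 180), ncol = 2), strand = "+")))
  cds <- extract_cds_loci(g)
  expect_equal(sum(cds$locus == "ndhB"), 1L)
  expect_equal(cds$sequence[cds$locus == "ndhB"], substr(res, 11, 40))
  expect_equal(cds$sequence[cds$locus == "psbA"], "ATG")
  ## frame violation flagged unusable
  g2 <- annotated_genome("t2", res, list(
    list(name = "orfX", kind = "CDS",
         intervals = matrix(c(0, 10), ncol = 2), strand = "+")))
  expect_warning(cds2 <- extract_cds_loci(g2), "not divisible by 3")
  expect_false(cds2$usable[1])
})

test_that("noncoding extraction is the complement of CDS coverage union", {
  g <- toy_genome()  # 100 bp, CDS [10,40)
  expect_equal(nchar(extract_noncoding(g)), 70L)
  ## overlapping CDS features: union coverage 50 -> noncoding 50
  g2 <- annotated_genome("t", g$residues, list(
    list(name = "a", kind = "CDS", intervals = matrix(c(10, 40), ncol = 2),
         strand = "+"),
    list(name = "b", kind = "CDS", intervals = matrix(c(30, 60), ncol = 2),
         strand = "+")))
  expect_equal(nchar(extract_noncoding(g2)), 50L)
  ## full coverage -> empty string
  g3 <- annotated_genome("t", g$residues, list(
    list(name = "a", kind = "CDS", intervals = matrix(c(0, 100), ncol = 2),
         strand = "+")))
  expect_equal(extract_noncoding(g3), "")
})

test_that("per-taxon base conservation holds on random annotated genomes", {
  for (seed in 1:10) {
    set.seed(seed)
    len <- sample(100:300, 1)
    res <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    nfeat <- sample(1:5, 1)
    feats <- lapply(seq_len(nfeat), function(i) {
      s <- sample(0:(len - 10), 1)
      list(name = paste0("g", i), kind = "CDS",
           intervals = matrix(c(s, min(len, s + sample(5:60, 1))), ncol = 2),
           strand = sample(c("+", "-"), 1))
    })
    g <- annotated_genome("t", res, feats)
    iv <- do.call(rbind, lapply(feats, `[[`, "intervals"))
    covered <- unique(unlist(apply(iv, 1, function(x) seq(x[1], x[2] - 1))))
    expect_equal(length(covered) + nchar(extract_noncoding(g)), len)
  }
})

test_that("trnK intron is the inter-exon region with matK excised", {
  iv <- plastconcord:::trnk_intron_intervals(
    matrix(c(0, 30, 400, 430), ncol = 2, byrow = TRUE),
    matrix(c(100, 300), ncol = 2))
  expect_equal(unname(iv), matrix(c(30, 100, 300, 400), ncol = 2,
                                  byrow = TRUE))
  set.seed(9)
  res <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  mk_genome <- function(with_ndhF) {
    feats <- list(
      list(name = "trnK", kind = "other",
           intervals = matrix(c(0, 30), ncol = 2), strand = "+"),
      list(name = "matK", kind = "CDS",
           intervals = matrix(c(100, 301), ncol = 2), strand = "+"),
      list(name = "trnK", kind = "other",
           intervals = matrix(c(400, 430), ncol = 2), strand = "+"),
      list(name = "rbcL", kind = "CDS",
           intervals = matrix(c(431, 461), ncol = 2), strand = "+"))
    if (with_ndhF)
      feats <- c(feats, list(list(name = "ndhF", kind = "CDS",
                                  intervals = matrix(c(461, 491), ncol = 2),
                                  strand = "+")))
    annotated_genome(paste0("t", with_ndhF), res, feats)
  }
  suppressWarnings({
    full <- build_three_gene_set(list(mk_genome(TRUE)))
    partial <- build_three_gene_set(list(mk_genome(FALSE)))
  })
  expect_equal(nchar(full$trnK_intron$sequences[[1]]),
               (100 - 30) + (400 - 301))
  expect_false(is.na(full$ndhF$sequences[[1]]))
  expect_true(is.na(partial$ndhF$sequences[[1]]))
  expect_false(is.na(partial$rbcL$sequences[[1]]))
})

test_that("locus concatenation builds faithful codon and index metadata", {
  a <- raw_alignment(c(x = "ATGAAA", y = "ATGAAG"))
  b <- raw_alignment(c(x = "ATGGGGAAA", y = "ATGGGAAAA"))
  cat2 <- concatenate_loci(list(lA = a, lB = b))
  expect_equal(n_columns(cat2), 15L)
  expect_equal(cat2$meta$codon_pos, rep(1:3, 5))
  expect_equal(cat2$meta$locus, rep(c("lA", "lB"), c(6, 9)))
  expect_equal(cat2$meta$original_index, 1:15)
  ## single locus: identity apart from metadata
  one <- concatenate_loci(list(lA = a))
  expect_identical(unclass(one$aln)[, ], unclass(a)[, ])
  ## taxon mismatch errors with the symmetric difference
  c2 <- raw_alignment(c(x = "AAA", z = "CCC"))
  expect_error(concatenate_loci(list(lA = a, lB = c2)), "y.*z|z.*y")
})

test_that("gap stripping keeps exactly the gap-free columns and is idempotent", {
  a <- raw_alignment(c(x = "A-CG", y = "ATCG", z = "AT-G"))
  s <- strip_gapped_columns(a)
  expect_equal(unname(alignment_strings(s)), rep("AG", 3))
  expect_identical(strip_gapped_columns(s), s)
  ## gap-free alignment unchanged
  b <- random_alignment(5, 30, gap_prob = 0, seed = 2)
  expect_identical(strip_gapped_columns(b), b)
  ## brute-force per-column oracle on random gapped alignments
  for (seed in 1:10) {
    r <- random_alignment(4, 50, gap_prob = 0.1, seed = seed)
    keep <- which(vapply(seq_len(ncol(r)), function(j)
      !any(r[, j] == "-"), logical(1)))
    expect_identical(unclass(strip_gapped_columns(r))[, , drop = FALSE],
                     unclass(r)[, keep, drop = FALSE])
  }
})

test_that("metadata survives stripping as a faithful index map", {
  r <- random_alignment(4, 60, gap_prob = 0.1, seed = 11)
  pa <- partitioned_alignment(r)
  s <- strip_gapped_columns(pa)
  for (j in seq_len(n_columns(s)))
    expect_identical(s$aln[, j], r[, s$meta$original_index[j]])
})

test_that("codon masking deletes whole codons and validates indices", {
  a <- raw_alignment(c(x = strrep("ATG", 10), y = strrep("ATA", 10)))
  b <- raw_alignment(c(x = strrep("CCC", 10), y = strrep("CCA", 10)))
  pa <- concatenate_loci(list(lA = a, lB = b))
  m1 <- mask_selected_codons(pa, list(lA = 3L))
  expect_equal(sum(m1$meta$locus == "lA"), 27L)
  m2 <- mask_selected_codons(pa, list(lA = 3L, lB = 7L))
  expect_equal(n_columns(m2), 54L)
  expect_identical(mask_selected_codons(pa, list()), pa)
  expect_error(mask_selected_codons(pa, list(lA = 10L)), "out of range")
  ## masked columns are exactly the codon's three columns (deletion oracle)
  dropped <- setdiff(pa$meta$original_index, m1$meta$original_index)
  expect_equal(dropped, 10:12)  # codon 3 (0-based) of locus lA
})

test_that("the fourteen-partition suite follows the fixed derivation graph", {
  suppressWarnings(bundle <- assemble_synthetic_plastomes(
    sim_config(n_taxa = 6, n_cds_loci = 3, codons_per_locus = 30,
               noncoding_length = 400, seed = 21)))
  sites <- list(rbcL = c(0L, 5L), matK = 2L)
  suite <- build_partition_suite(bundle$regions, sites)
  expect_setequal(names(suite), partition_codes())
  for (code in partition_codes())
    expect_equal(suite[[code]]$code, code)
  ## derivation identities
  expect_identical(suite$B$aln, strip_gapped_columns(suite$A)$aln)
  expect_identical(suite$D$aln, strip_gapped_columns(suite$C)$aln)
  expect_identical(suite$R$aln, strip_gapped_columns(suite$Q)$aln)
  expect_identical(suite$X$aln, strip_gapped_columns(suite$W)$aln)
  ## monotone lengths
  specs <- partition_specs()
  for (i in seq_len(nrow(specs))) {
    code <- specs$code[i]
    base <- switch(specs$region_set[i], three_gene = "A", coding = "E",
                   noncoding = "Q", complete = "W")
    expect_lte(n_columns(suite[[code]]), n_columns(suite[[base]]))
  }
  ## masked suites drop 3 columns per masked codon present
  expect_equal(n_columns(suite$A) - n_columns(suite$C), 9L)
  ## empty site map: C == A, G == E, Y == W
  suite0 <- build_partition_suite(bundle$regions, list())
  expect_identical(suite0$C$aln, suite0$A$aln)
  expect_identical(suite0$G$aln, suite0$E$aln)
  expect_identical(suite0$Y$aln, suite0$W$aln)
  ## missing base alignment errors
  expect_error(build_partition_suite(bundle$regions[-1], sites), "missing")
})

test_that("mask-then-strip (the fixed order) differs from strip-then-mask", {
  ## a gapped codon makes the two orders diverge
  a <- raw_alignment(c(x = "ATG---AAA", y = "ATGCCCAAA"))
  pa <- concatenate_loci(list(lA = a))
  mask_strip <- strip_gapped_columns(mask_selected_codons(pa, list(lA = 2L)))
  expect_equal(n_columns(mask_strip), 3L)  # codon 2 masked, gap codon stripped
  strip_first <- strip_gapped_columns(pa)
  expect_equal(n_columns(strip_first), 6L)
})
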