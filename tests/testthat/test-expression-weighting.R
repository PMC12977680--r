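# expression_weighting: size factors, normalization, weighted usage,
# max-normalization.

test_that("median-of-ratios size factors match hand-computed values", {
  # identical columns: perfect symmetry
  m <- matrix(c(3, 8, 5, 3, 8, 5), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(median_of_ratios_size_factors(m)), c(1, 1))

  # every row's ratio to its geometric mean is identical, so the median
  # equals it: s = (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(2, 8, 5, 4, 16, 10), ncol = 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(median_of_ratios_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # doubling column 2 shifts every row's geometric mean by sqrt(2), so the
  # estimates move to (s1 / sqrt(2), s2 * sqrt(2))
  m3 <- m2
  m3[, 2] <- m2[, 2] * 2
  sf2 <- median_of_ratios_size_factors(m2)
  sf3 <- median_of_ratios_size_factors(m3)
  expect_equal(unname(sf3), unname(sf2) * c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("size factors need a reference row unless the fallback is enabled", {
  m <- matrix(c(0, 5, 3, 0), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(median_of_ratios_size_factors(m), "pseudo-reference")
  expect_silent(median_of_ratios_size_factors(m, max_zero_rows = 1))
  expect_error(median_of_ratios_size_factors(matrix(1:3, ncol = 1)),
               "2 columns")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  spec <- sim_spec(n_genes = 200, length_range = c(50, 100), depth = 500,
                   size_factors = c(0.7, 1.3, 2.0), seed = 21)
  counts <- generate_counts(generate_catalog(spec))
  ours <- median_of_ratios_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # DESeq2 takes the median in log space; with an even number of reference
  # rows the two middle ratios are interpolated geometrically rather than
  # arithmetically, so agreement is to ~1e-4, not machine precision
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("normalize_counts divides by size factors and is idempotent", {
  m <- matrix(c(4, 8, 2, 6), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  same <- normalize_counts(m, size_factors = c(1, 1))
  expect_equal(unclass(same)[, ], m[, ])

  halved <- normalize_counts(m, size_factors = c(2, 1))
  expect_equal(unname(halved[, 1]), c(2, 4))
  expect_equal(unname(halved[, 2]), c(2, 6))

  once <- normalize_counts(estimate_size_factors(m))
  expect_equal(normalize_counts(once), once)
  expect_equal(unname(attr(once, "size_factors")), c(1, 1))

  expect_error(normalize_counts(m), "size factors unset")
  expect_equal(normalize_counts(m, pre_normalized = TRUE)[, ], m[, ])
})

test_that("weighted usage multiplies normalized counts by CDS frequency", {
  cat <- make_catalog("ATGACTTAA", genes = "g1")
  m <- matrix(c(10, 3), ncol = 2, dimnames = list("g1", c("t1", "t2")))
  u <- weighted_codon_usage(cat, m, "t1")
  expect_s3_class(u, "tissue_usage")
  expect_equal(unname(u$raw_usage["ACT"]), 10)
  expect_equal(sum(u$raw_usage), 10)
  expect_equal(u$n_genes_used, 1L)

  # symmetry: equal counts, disjoint single-codon CDS
  cat2 <- make_catalog(c("ATGACTTAA", "ATGGGTTAA"), genes = c("g1", "g2"))
  m2 <- matrix(c(5, 5), ncol = 1, dimnames = list(c("g1", "g2"), "t1"))
  u2 <- weighted_codon_usage(cat2, m2, "t1")
  expect_equal(unname(u2$raw_usage["ACT"]), unname(u2$raw_usage["GGT"]))

  expect_error(weighted_codon_usage(cat, m, "nope"), "tissue column")
})

test_that("weighted usage matches a brute-force gene x codon double loop", {
  set.seed(31)
  n <- 20
  seqs <- vapply(seq_len(n), function(i) random_cds(sample(20, 1) + 5), "")
  cat <- make_catalog(seqs)
  m <- matrix(rpois(n * 2, 50), ncol = 2,
              dimnames = list(cat$gene_id, c("t1", "t2")))
  storage.mode(m) <- "double"
  u <- weighted_codon_usage(cat, m, "t2")

  expected <- stats::setNames(numeric(64), codons())
  for (g in seq_len(n)) {
    o <- naive_elongator_count(seqs[g])
    for (cod in codons()) {
      expected[cod] <- expected[cod] + m[g, "t2"] * o$counts[[cod]] / o$total
    }
  }
  expect_equal(as.numeric(u$raw_usage), unname(expected), tolerance = 1e-12)
})

test_that("weighted usage resolves ids, skips unmatched rows, honours lists", {
  cat <- make_catalog(c("ATGACTTAA", "ATGGGTTAA"), genes = c("g1", "g2"))
  m <- matrix(c(5, 7, 9), ncol = 1,
              dimnames = list(c("g1.t1", "g2", "ghost"), "t1"))

  expect_message(u <- weighted_codon_usage(cat, m, "t1"), "skipped")
  expect_equal(u$n_genes_used, 2L)
  expect_equal(u$n_skipped, 1L)
  expect_equal(unname(u$raw_usage["ACT"]), 5)   # via transcript id
  expect_equal(unname(u$raw_usage["GGT"]), 7)

  u2 <- suppressMessages(
    weighted_codon_usage(cat, m, "t1", gene_list = "g2"))
  expect_equal(u2$n_genes_used, 1L)
  expect_equal(sum(u2$raw_usage), 7)

  ghost_only <- m["ghost", , drop = FALSE]
  expect_error(suppressMessages(weighted_codon_usage(cat, ghost_only, "t1")),
               "zero genes")

  # id_map translates foreign row ids
  map <- data.frame(transcript_id = "row1", gene_id = "g1")
  m3 <- matrix(4, dimnames = list("row1", "t1"))
  u3 <- weighted_codon_usage(cat, m3, "t1", id_map = map)
  expect_equal(unname(u3$raw_usage["ACT"]), 4)
})

test_that("transcript-level rows of one gene are summed", {
  cat <- make_catalog("ATGACTTAA", genes = "g1")
  m <- matrix(c(3, 4), ncol = 1, dimnames = list(c("g1.t1", "g1"), "t1"))
  u <- weighted_codon_usage(cat, m, "t1")
  expect_equal(u$n_genes_used, 1L)
  expect_equal(unname(u$raw_usage["ACT"]), 7)
})

test_that("usage is linear over disjoint gene sets and permutation-invariant", {
  set.seed(41)
  seqs <- vapply(1:10, function(i) random_cds(30), "")
  cat <- make_catalog(seqs)
  m <- matrix(rpois(10, 100), ncol = 1, dimnames = list(cat$gene_id, "t1"))
  storage.mode(m) <- "double"
  setA <- cat$gene_id[1:4]
  setB <- cat$gene_id[5:10]
  uA <- weighted_codon_usage(cat, m, "t1", gene_list = setA)
  uB <- weighted_codon_usage(cat, m, "t1", gene_list = setB)
  uAll <- weighted_codon_usage(cat, m, "t1")
  expect_equal(unclass(uAll$raw_usage),
               unclass(uA$raw_usage) + unclass(uB$raw_usage),
               tolerance = 1e-12)

  perm <- sample(nrow(m))
  m_perm <- m[perm, , drop = FALSE]
  u_perm <- weighted_codon_usage(cat, m_perm, "t1")
  expect_equal(unclass(u_perm$raw_usage), unclass(uAll$raw_usage),
               tolerance = 1e-12)
})

test_that("equal-count usage tracks mean frequency, not aggregate frequency,
           when lengths differ", {
  # one short ACT-pure CDS, one long GGT-pure CDS
  cat <- make_catalog(c("ATGACTTAA", paste0("ATG", strrep("GGT", 20), "TAA")),
                      genes = c("g1", "g2"))
  m <- matrix(c(1, 1), ncol = 1, dimnames = list(c("g1", "g2"), "t1"))
  u <- weighted_codon_usage(cat, m, "t1")
  agg <- aggregate_genome_usage(cat)
  # per-gene mean: ACT and GGT weigh equally; aggregate: GGT dominates
  expect_equal(unname(u$raw_usage["ACT"]), unname(u$raw_usage["GGT"]))
  expect_lt(as.numeric(agg$profile["ACT"]), as.numeric(agg$profile["GGT"]))
})

test_that("max-normalization peaks at exactly 1 and is scale-invariant", {
  p <- codon_profile(c(ACT = 0, ACC = 5, GGT = 10), kind = "WEIGHTED_USAGE")
  s <- max_normalize_usage(p)
  expect_equal(unname(s[c("ACT", "ACC", "GGT")]), c(0, 0.5, 1.0))
  expect_identical(max(s), 1)

  p2 <- codon_profile(unclass(p) * 37.5, kind = "WEIGHTED_USAGE")
  expect_equal(unclass(max_normalize_usage(p2)), unclass(s))

  zero <- codon_profile(numeric(64), kind = "WEIGHTED_USAGE")
  expect_warning(sz <- max_normalize_usage(zero), "all-zero")
  expect_true(all(sz == 0))

  cat <- make_catalog("ATGACTTAA", genes = "g1")
  m <- matrix(2, dimnames = list("g1", "t1"))
  u <- max_normalize_usage(weighted_codon_usage(cat, m, "t1"))
  expect_equal(attr(u$scaled_usage, "kind"), "MAX_NORMALIZED")
  expect_identical(max(u$scaled_usage), 1)
})
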