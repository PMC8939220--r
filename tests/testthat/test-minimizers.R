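test_that("minimizers agree with window-enumeration oracle", {
  expect_equal(minimizers("ACGTAC", MinimizerScheme(6)), "ACGTAC") # m = k
  expect_equal(minimizers("AAAAA", MinimizerScheme(2)), "AA")
  sch <- MinimizerScheme(3, seed = 42)
  expect_equal(minimizers("ACGTAC", sch),
               oracle_minimizer("ACGTAC", 3, 42))
  set.seed(7)
  for (seed in c(0L, 42L, 987654L)) {
    sch <- MinimizerScheme(5, seed)
    kmersv <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
            collapse = ""), character(1))
    got <- minimizers(kmersv, sch)
    want <- vapply(kmersv, oracle_minimizer, character(1), m = 5, seed = seed)
    expect_identical(got, unname(want))
    # a minimizer is always a substring of its k-mer
    expect_true(all(mapply(grepl, got, kmersv, fixed = TRUE)))
  }
  expect_error(minimizers("ACG", MinimizerScheme(5)), "exceeds")
})

test_that("bucketCounts matches a brute-force grouping oracle", {
  tab <- random_table_manual(800, 11, c(1L, 1L, 1L, 2L, 3L, 9L), seed = 3)
  for (delta in c(0L, 1L)) {
    sch <- MinimizerScheme(5, seed = 17)
    bk <- bucketCounts(tab, sch, delta = delta)
    want <- oracle_buckets(kmers(tab), counts(tab), 5, 17)
    expect_setequal(bk$minimizer, names(want))
    o <- match(bk$minimizer, names(want))
    expect_equal(bk$size, lengths(want)[o], ignore_attr = TRUE)
    expect_equal(bk$min, vapply(want, min, integer(1))[o],
                 ignore_attr = TRUE)
    expect_equal(bk$max, vapply(want, max, integer(1))[o],
                 ignore_attr = TRUE)
    expect_equal(bk$ambiguous,
                 vapply(want, function(v) max(v) - min(v) > delta,
                        logical(1))[o],
                 ignore_attr = TRUE)
  }
  # cardinality bounds: |M_m(K)| <= |K| and <= 4^m
  sch2 <- MinimizerScheme(2, seed = 1)
  bk2 <- bucketCounts(tab, sch2)
  expect_lte(nrow(bk2), length(tab))
  expect_lte(nrow(bk2), 4^2)
})

test_that("single-key and constant tables give unambiguous buckets", {
  one <- KmerCountTable("ACGTACG", 7L)
  bk <- bucketCounts(one, MinimizerScheme(4), delta = 0)
  expect_equal(nrow(bk), 1L)
  expect_false(bk$ambiguous)
  expect_equal(bk$min, bk$max)

  const <- random_table_manual(300, 9, 5L, seed = 8)
  bk <- bucketCounts(const, MinimizerScheme(4, 3), delta = 0)
  expect_false(any(bk$ambiguous))
})

test_that("bucketMajority returns the exact mode with smallest-value ties", {
  mj <- kcsf:::.bucket_majority_cpp(c("AC", "AC", "AC"), c(1L, 1L, 2L))
  expect_equal(mj$majority, 1L)
  mj <- kcsf:::.bucket_majority_cpp("GG", 5L)
  expect_equal(mj$majority, 5L)
  mj <- kcsf:::.bucket_majority_cpp(c("TT", "TT"), c(2L, 1L)) # tie
  expect_equal(mj$majority, 1L)

  tab <- random_table_manual(600, 9, c(1L, 2L, 3L), seed = 12)
  sch <- MinimizerScheme(4, seed = 5)
  got <- bucketMajority(tab, sch)
  want <- vapply(oracle_buckets(kmers(tab), counts(tab), 4, 5), oracle_mode,
                 integer(1))
  expect_identical(got[names(want)], want)
})
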