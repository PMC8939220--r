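test_that("CSF round-trips exactly across sizes, skews and seeds", {
  cases <- list(
    list(n = 1, values = 5L),
    list(n = 37, values = c(1L, 2L)),
    list(n = 1000, values = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L)),
    list(n = 20000, values = 1:40))
  for (cs in cases) {
    tab <- random_table_manual(cs$n, 13, cs$values, seed = cs$n)
    for (seed in c(1L, 99L)) {
      csf <- buildCSF(kmers(tab), counts(tab), seed = seed)
      expect_identical(csfQuery(csf, kmers(tab)), counts(tab))
    }
  }
})

test_that("single-valued input needs no payload bits", {
  tab <- random_table_manual(500, 11, 7L, seed = 1)
  csf <- buildCSF(kmers(tab), counts(tab), seed = 1)
  expect_identical(csfQuery(csf, kmers(tab)), counts(tab))
  expect_equal(unname(structureBits(csf)["csf"]), 0)
})

test_that("queries on unbuilt keys return a symbol without crashing", {
  tab <- random_table_manual(2000, 13, c(2L, 5L, 9L), seed = 2)
  csf <- buildCSF(kmers(tab), counts(tab), seed = 3)
  set.seed(4)
  foreign <- setdiff(kcsf:::.ids_to_kmers(sample(4^13, 3000) - 1, 13L),
                     kmers(tab))
  got <- csfQuery(csf, foreign)
  expect_true(all(got %in% c(2L, 5L, 9L)))
})

test_that("builds are deterministic and independent of input order", {
  tab <- random_table_manual(3000, 12, c(1L, 1L, 2L, 3L), seed = 5)
  a <- buildCSF(kmers(tab), counts(tab), seed = 11)
  o <- sample(length(tab))
  b <- buildCSF(kmers(tab)[o], counts(tab)[o], seed = 11)
  expect_identical(serialize(a, NULL, version = 3L),
                   serialize(b, NULL, version = 3L))
  expect_identical(csfQuery(a, kmers(tab)), csfQuery(b, kmers(tab)))
})

test_that("payload respects the gamma space envelope", {
  tab <- random_table_manual(20000, 13, c(rep(1L, 90), rep(2L, 7),
                                          rep(3L, 3)), seed = 6)
  csf <- buildCSF(kmers(tab), counts(tab), gamma = 1.10, seed = 7)
  code <- csf@code
  lens <- code@lengths[match(counts(tab), code@symbols)]
  payload <- unname(structureBits(csf)["csf"])
  # per-chunk ceil() and retry widening add at most a few bits per chunk
  expect_lte(payload, 1.10 * sum(lens) * 1.05 + 64 * csf@nChunks)
  expect_identical(csfQuery(csf, kmers(tab)), counts(tab))
})

test_that("duplicate keys are rejected", {
  expect_error(buildCSF(c("ACGT", "ACGT"), c(1L, 2L)), "duplicate")
})

test_that("solveGF2 solves random systems and reports inconsistency", {
  # empty system: the zero assignment
  expect_identical(solveGF2(list(), logical(0), 5), rep(FALSE, 5))
  # single equation over three positions XORs to 1
  s <- solveGF2(list(c(1, 4, 8)), TRUE, 8)
  expect_true(xor(xor(s[1], s[4]), s[8]))
  # inconsistent pair
  expect_null(solveGF2(list(c(1, 2), c(1, 2)), c(TRUE, FALSE), 4))

  set.seed(31)
  for (rep in 1:100) {
    nv <- sample(5:40, 1)
    planted <- sample(c(TRUE, FALSE), nv, replace = TRUE)
    eqs <- replicate(sample(3:30, 1),
                     sample.int(nv, sample(1:3, 1)), simplify = FALSE)
    rhs <- vapply(eqs, function(p) Reduce(xor, planted[p]), logical(1))
    sol <- solveGF2(eqs, rhs, nv)
    expect_false(is.null(sol))
    # substitution oracle: the returned assignment satisfies every equation
    for (i in seq_along(eqs))
      expect_identical(Reduce(xor, sol[eqs[[i]]]), rhs[[i]])
  }
})
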