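test_that("a large delta resolves everything at layer 1", {
  tab <- random_table_manual(2000, 13, c(1L, 2L, 3L, 4L), seed = 1)
  spread <- max(counts(tab)) - min(counts(tab))
  amb <- buildAMB(tab, minimizerLengths = 7, delta = spread, seed = 1)
  expect_null(amb@residual)
  got <- ambQuery(amb, kmers(tab))
  expect_true(all(abs(got - counts(tab)) <= spread))
})

test_that("constant tables leave an empty residual and exact answers", {
  tab <- random_table_manual(1500, 13, 4L, seed = 2)
  amb <- buildAMB(tab, minimizerLengths = c(7, 9), delta = 0, seed = 2)
  expect_null(amb@residual)
  expect_identical(ambQuery(amb, kmers(tab)), counts(tab))
})

test_that("AMB layer membership matches a brute-force bucketing oracle", {
  tab <- random_table_manual(5000, 13, c(1L, 1L, 1L, 2L, 3L), seed = 3)
  amb <- buildAMB(tab, minimizerLengths = c(7, 9), delta = 0, seed = 4)

  keys <- kmers(tab)
  cnts <- counts(tab)
  surv <- seq_along(keys)
  for (i in seq_along(amb@layers)) {
    sch <- MinimizerScheme(amb@minimizerLengths[i], amb@layerSeeds[i])
    mins <- minimizers(keys[surv], sch)
    groups <- split(seq_along(surv), mins)
    gval <- vapply(groups, function(ix) {
      v <- cnts[surv][ix]
      if (max(v) - min(v) > 0L) 0L else min(v)
    }, integer(1))
    # stored bucket table answers the oracle's representative per bucket
    expect_identical(bcsfQuery(amb@layers[[i]], names(gval)),
                     unname(gval))
    ambNames <- names(gval)[gval == 0L]
    surv <- surv[mins %in% ambNames]
  }
  if (length(surv)) {
    expect_false(is.null(amb@residual))
    expect_equal(amb@residual@nKeys, length(surv))
    expect_identical(bcsfQuery(amb@residual, keys[surv]), cnts[surv])
  } else {
    expect_null(amb@residual)
  }
  expect_identical(ambQuery(amb, keys), cnts)
})

test_that("AMB is exact at delta = 0 and delta-bounded otherwise", {
  tab <- powerlawTable(8000, exponent = 1.5, maxCount = 40, k = 13, seed = 5)
  exact <- buildAMB(tab, minimizerLengths = c(7, 9), delta = 0, seed = 6)
  expect_identical(ambQuery(exact, kmers(tab)), counts(tab))

  resid <- numeric(0)
  for (delta in c(1L, 2L, 5L)) {
    approx <- buildAMB(tab, minimizerLengths = c(7, 9), delta = delta,
                       seed = 6)
    got <- ambQuery(approx, kmers(tab))
    expect_true(all(abs(got - counts(tab)) <= delta))
    resid <- c(resid, if (is.null(approx@residual)) 0
               else approx@residual@nKeys)
  }
  expect_true(all(diff(resid) <= 0)) # residual shrinks as delta grows
})

test_that("layer survivor sets shrink monotonically", {
  tab <- powerlawTable(6000, exponent = 1.3, maxCount = 60, k = 13, seed = 7)
  amb <- buildAMB(tab, minimizerLengths = c(6, 8, 10), delta = 0, seed = 8)
  surv <- kmers(tab)
  sizes <- length(surv) # |K_0|, |K_1|, ... via the stored bucket tables
  for (i in seq_along(amb@layers)) {
    sch <- MinimizerScheme(amb@minimizerLengths[i], amb@layerSeeds[i])
    surv <- surv[bcsfQuery(amb@layers[[i]], minimizers(surv, sch)) == 0L]
    sizes <- c(sizes, length(surv))
  }
  expect_true(all(diff(sizes) <= 0))
  expect_lt(sizes[length(sizes)], sizes[1]) # the cascade makes progress
  resid <- if (is.null(amb@residual)) 0 else amb@residual@nKeys
  expect_equal(resid, sizes[length(sizes)])
})

test_that("FIL stores a constant table as one representative layer", {
  tab <- random_table_manual(1200, 13, 9L, seed = 9)
  fil <- buildFIL(tab, minimizerLengths = 7, seed = 9)
  expect_identical(filQuery(fil, kmers(tab)), counts(tab))
  # corrections are the all-zero constant
  expect_equal(fil@corrections@alpha, 1)
  expect_equal(fil@corrections@v0, 0L)
})

test_that("FIL telescoping identity reconstructs f for 1 and 2 layers", {
  tab <- powerlawTable(7000, exponent = 1.4, maxCount = 30, k = 13,
                       seed = 10)
  for (ml in list(7L, c(7L, 9L))) {
    fil <- buildFIL(tab, minimizerLengths = ml, seed = 11)
    acc <- integer(length(tab))
    for (i in seq_along(fil@layers)) {
      sch <- MinimizerScheme(fil@minimizerLengths[i], fil@layerSeeds[i])
      acc <- acc + bcsfQuery(fil@layers[[i]], minimizers(kmers(tab), sch))
    }
    h <- zigzagDecode(bcsfQuery(fil@corrections, kmers(tab)))
    expect_identical(acc + h, counts(tab))          # g1 + g2 + h = f
    expect_identical(filQuery(fil, kmers(tab)), counts(tab))
  }
})

test_that("bucket majority drives corrections: values {4,4,7} give g = 4", {
  mj <- kcsf:::.bucket_majority_cpp(rep("ACGTA", 3), c(4L, 4L, 7L))
  expect_equal(mj$majority, 4L)
  expect_equal(c(4L, 4L, 7L) - mj$majority[mj$group], c(0L, 0L, 3L))
})

test_that("AMB at delta 0 and FIL agree (both exact), any seed", {
  tab <- powerlawTable(3000, exponent = 2, maxCount = 12, k = 13, seed = 12)
  for (seed in c(1L, 202L)) {
    amb <- buildAMB(tab, minimizerLengths = c(8, 10), delta = 0, seed = seed)
    fil <- buildFIL(tab, minimizerLengths = c(8, 10), seed = seed)
    expect_identical(ambQuery(amb, kmers(tab)), filQuery(fil, kmers(tab)))
  }
})

test_that("invalid layer specifications are rejected", {
  tab <- random_table_manual(100, 13, c(1L, 2L), seed = 13)
  expect_error(buildAMB(tab, minimizerLengths = c(9, 7)), "increasing")
  expect_error(buildFIL(tab, minimizerLengths = c(7, 7)), "increasing")
  expect_error(buildAMB(tab, minimizerLengths = 14), "\\[1, k\\]")
  expect_error(buildAMB(tab, minimizerLengths = 7, delta = -1), ">= 0")
})
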