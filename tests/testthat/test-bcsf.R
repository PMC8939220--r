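test_that("the fitted CSF cost envelope evaluates as printed", {
  expect_equal(estimateCsfCost(0), 1.16)
  expect_equal(estimateCsfCost(1), 1.56)
  expect_equal(estimateCsfCost(2), 2.4)   # branches agree at the kink
  expect_equal(estimateCsfCost(1.999999), 2.4, tolerance = 1e-4)
  expect_equal(estimateCsfCost(3), 3.5)
  expect_error(estimateCsfCost(-0.1), ">= 0")
})

test_that("epsilon0 is the analytic minimizer of the space objective", {
  # equal costs: the Bloom stage pays off exactly above alpha = 0.59
  expect_equal(round(bloomAlphaThreshold(1.44, 1.44), 2), 0.59)
  expect_false(optimalEpsilon(0.5, cBf = 1, cCsf = 1)$useBloom)
  expect_equal(optimalEpsilon(0.5, cBf = 1, cCsf = 1)$epsilon0,
               log2(exp(1)), tolerance = 1e-12)
  opt <- optimalEpsilon(0.97, cBf = 1.44, cCsf = 1.16)
  expect_true(opt$useBloom)
  expect_equal(opt$epsilon0, 0.0554, tolerance = 1e-2)

  set.seed(41)
  for (rep in 1:60) {
    alpha <- stats::runif(1, 0.02, 0.999)
    cBf <- stats::runif(1, 0.5, 3)
    cCsf <- stats::runif(1, 1, 6)
    opt <- optimalEpsilon(alpha, cBf, cCsf)
    objective <- function(eps)
      (cBf / cCsf) * ((1 - alpha) / alpha) * log2(1 / eps) + eps
    expect_equal(opt$useBloom,
                 alpha > bloomAlphaThreshold(cBf, cCsf))
    if (opt$useBloom) {
      m <- stats::optimize(objective, c(1e-9, 1 - 1e-9), tol = 1e-10)
      expect_equal(m$minimum, opt$epsilon0, tolerance = 1e-6)
      expect_lt(objective(opt$epsilon0), 1) # space is actually saved
    }
  }
})

test_that("single-valued tables collapse to a constant structure", {
  tab <- random_table_manual(400, 11, 3L, seed = 1)
  b <- buildBCSF(tab, seed = 1)
  expect_null(b@bloom)
  expect_null(b@csf)
  expect_equal(b@alpha, 1)
  expect_identical(bcsfQuery(b, kmers(tab)), counts(tab))
})

test_that("below the threshold a plain CSF is used, above it a Bloom stage", {
  even <- random_table_manual(5000, 13, c(1L, 2L), seed = 2) # alpha ~ 0.5
  b <- buildBCSF(even, seed = 3)
  expect_null(b@bloom)
  expect_identical(bcsfQuery(b, kmers(even)), counts(even))

  skew <- dominantTable(20000, alpha = 0.97, v0 = 1, k = 13, seed = 4)
  b2 <- buildBCSF(skew, seed = 5)
  expect_false(is.null(b2@bloom))
  expect_equal(b2@epsilon,
               optimalEpsilon(b2@alpha, 1.44, estimateCsfCost(b2@h0))$epsilon0)
  expect_identical(bcsfQuery(b2, kmers(skew)), counts(skew))
})

test_that("Bloom false positives never corrupt answers (defining property)", {
  for (seed in 1:3) {
    tab <- dominantTable(8000, alpha = 0.9, v0 = 1, k = 12, seed = seed)
    b <- buildBCSF(tab, seed = seed, useBloom = "always")
    expect_false(is.null(b@bloom))
    expect_identical(bcsfQuery(b, kmers(tab)), counts(tab))
  }
})

test_that("the Bloom stage saves measured space on a skewed table", {
  tab <- dominantTable(30000, alpha = 0.95, v0 = 1, k = 13, seed = 6)
  withB <- buildBCSF(tab, seed = 7)
  noB <- buildBCSF(tab, seed = 7, useBloom = "never")
  expect_false(is.null(withB@bloom))
  pay <- function(x) sum(structureBits(x)[c("bloom", "csf", "codeTable")])
  expect_lt(pay(withB), pay(noB))
})

test_that("the measured cost model is accepted and still exact", {
  tab <- dominantTable(5000, alpha = 0.8, v0 = 2, k = 12, seed = 8)
  b <- buildBCSF(tab, seed = 9, costModel = "measured")
  expect_identical(bcsfQuery(b, kmers(tab)), counts(tab))
})
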