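#' Per-key CSF cost as a function of entropy
#'
#' The fitted cost envelope of the practical CSF implementation:
#' \code{0.22*H0^2 + 0.18*H0 + 1.16} bits per key for H0 < 2 and
#' \code{1.1*H0 + 0.2} otherwise (the branches agree at the kink H0 = 2).
#' The constant floor above 1 bit/key for H0 near 0 is precisely the
#' deficiency the Bloom enhancement removes.
#'
#' @param h0 zero-order empirical entropy in bits (>= 0).
#' @return estimated bits per key.
#' @examples
#' estimateCsfCost(0)   # 1.16
#' estimateCsfCost(2)   # 2.4
#' @export
estimateCsfCost <- function(h0) {
  if (any(is.na(h0)) || any(h0 < 0)) stop("h0 must be >= 0")
  ifelse(h0 < 2, 0.22 * h0^2 + 0.18 * h0 + 1.16, 1.1 * h0 + 0.2)
}

#' Optimal Bloom false-positive rate for a BCSF
#'
#' Minimizes the total-space objective
#' \code{(cBf/cCsf) * ((1-alpha)/alpha) * log2(1/eps) + eps} over
#' \code{eps}, giving the closed-form minimizer
#' \code{eps0 = (cBf/cCsf) * ((1-alpha)/alpha) * log2(e)}. A Bloom filter
#' saves space exactly when \code{eps0 < 1}, equivalently when
#' \code{alpha > bloomAlphaThreshold(cBf, cCsf)}.
#'
#' @param alpha dominant-value fraction, in (0, 1].
#' @param cBf Bloom cost coefficient in bits per key per log2(1/eps);
#'   1.44 (= log2 e) for a standard filter.
#' @param cCsf CSF cost in bits per key (>= 1 for the fitted envelope).
#' @return list with \code{epsilon0} and logical \code{useBloom}.
#' @examples
#' optimalEpsilon(0.97, cBf = 1.44, cCsf = 1.16)
#' @export
optimalEpsilon <- function(alpha, cBf = 1.44, cCsf) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
  eps0 <- (cBf / cCsf) * ((1 - alpha) / alpha) * log2(exp(1))
  list(epsilon0 = eps0, useBloom = eps0 < 1)
}

#' @rdname optimalEpsilon
#' @return \code{bloomAlphaThreshold}: the dominant fraction above which a
#'   Bloom filter saves space,
#'   \code{cBf*log2(e) / (cCsf + cBf*log2(e))} (0.59 for cBf = cCsf).
#' @examples
#' round(bloomAlphaThreshold(1.44, 1.44), 2)  # 0.59
#' @export
bloomAlphaThreshold <- function(cBf = 1.44, cCsf = cBf) {
  cBf * log2(exp(1)) / (cCsf + cBf * log2(exp(1)))
}

#' Build a Bloom-enhanced compressed static function
#'
#' Computes the value histogram, entropy H0, dominant value v0 and its
#' fraction alpha; estimates the per-key CSF cost; and decides
#' analytically (see [optimalEpsilon()]) whether fronting the CSF with a
#' Bloom filter over the non-dominant keys saves space. When it does, the
#' filter is built at the optimal false-positive rate and the CSF covers
#' all filter positives, with the dominant keys that are false positives
#' stored at their true value v0 -- so no Bloom error can ever surface, and
#' every built key is answered exactly.
#'
#' @param x a [KmerCountTable-class], or a character vector of keys.
#' @param values integer values (ignored when \code{x} is a table).
#' @param seed build seed; all internal seeds derive from it.
#' @param costModel \code{"fitted"} (default) uses the fitted envelope of
#'   [estimateCsfCost()]; \code{"measured"} uses this implementation's own
#'   expected payload, gamma times the mean codeword length.
#' @param useBloom \code{"auto"} (decide from alpha), \code{"never"}
#'   (plain CSF), or \code{"always"} (force the filter when alpha < 1).
#' @param cBf Bloom cost coefficient (default 1.44).
#' @inheritParams buildCSF
#' @return a [BCSF-class].
#' @examples
#' tab <- dominantTable(2000, alpha = 0.95, v0 = 1, k = 13, seed = 7)
#' b <- buildBCSF(tab, seed = 1)
#' all(bcsfQuery(b, kmers(tab)) == counts(tab))
#' @export
buildBCSF <- function(x, values = NULL, seed = 1L,
                      costModel = c("fitted", "measured"),
                      useBloom = c("auto", "never", "always"), cBf = 1.44,
                      gamma = 1.10, chunkTarget = 8192L, maxLen = 32L) {
  costModel <- match.arg(costModel)
  useBloom <- match.arg(useBloom)
  if (is(x, "KmerCountTable")) {
    keys <- x@kmer
    values <- x@count
  } else {
    keys <- as.character(x)
    values <- as.integer(values)
  }
  if (!length(keys)) stop("BCSF input must be non-empty")
  if (length(values) != length(keys)) stop("keys/values length mismatch")
  seed <- as.integer(seed)

  hist <- table(values)
  h0 <- entropyH0(hist)
  vals <- as.integer(names(hist))
  imax <- which(hist == max(hist))
  v0 <- min(vals[imax]) # modal ties broken toward the smaller value
  alpha <- as.numeric(hist[[as.character(v0)]]) / length(keys)

  cCsf <- switch(costModel,
    fitted = estimateCsfCost(h0),
    measured = {
      code <- buildCode(hist, maxLen = maxLen)
      gamma * sum(code@lengths[match(vals, code@symbols)] *
                    as.numeric(hist)) / length(keys)
    })
  opt <- optimalEpsilon(alpha, cBf = cBf, cCsf = cCsf)
  wantBloom <- switch(useBloom, auto = opt$useBloom, never = FALSE,
                      always = TRUE)

  if (alpha == 1) {
    # single-valued table: the whole structure is the constant v0
    return(new("BCSF", v0 = v0, bloom = NULL, csf = NULL,
               epsilon = NA_real_, alpha = 1, h0 = 0, cCsf = cCsf,
               cBf = cBf, nKeys = length(keys), seed = seed))
  }
  if (!wantBloom) {
    csf <- buildCSF(keys, values, gamma = gamma, chunkTarget = chunkTarget,
                    seed = .derive_seed(seed, 2L), maxLen = maxLen)
    return(new("BCSF", v0 = v0, bloom = NULL, csf = csf,
               epsilon = NA_real_, alpha = alpha, h0 = h0, cCsf = cCsf,
               cBf = cBf, nKeys = length(keys), seed = seed))
  }
  eps <- max(opt$epsilon0, 1e-9) # guard the eps -> 0 degenerate limit
  dom <- values == v0
  bloom <- buildBloom(keys[!dom], eps, seed = .derive_seed(seed, 1L))
  fp <- keys[dom][bloomQuery(bloom, keys[dom])]
  csf <- buildCSF(c(keys[!dom], fp),
                  c(values[!dom], rep(v0, length(fp))),
                  gamma = gamma, chunkTarget = chunkTarget,
                  seed = .derive_seed(seed, 2L), maxLen = maxLen)
  new("BCSF", v0 = v0, bloom = bloom, csf = csf, epsilon = eps,
      alpha = alpha, h0 = h0, cCsf = cCsf, cBf = cBf, nKeys = length(keys),
      seed = seed)
}

#' @rdname buildBCSF
#' @param structure a built [BCSF-class].
#' @param keys character vector of k-mers from the build key set.
#' @return \code{bcsfQuery}: the exact stored value for every built key
#'   (Bloom-negative keys answer v0 directly; positives are resolved by
#'   the CSF, which stores v0 for false positives).
#' @export
bcsfQuery <- function(structure, keys) {
  stopifnot(is(structure, "BCSF"))
  keys <- as.character(keys)
  if (is.null(structure@bloom)) {
    if (is.null(structure@csf))
      return(rep(structure@v0, length(keys)))
    return(csfQuery(structure@csf, keys))
  }
  out <- rep(structure@v0, length(keys))
  pos <- bloomQuery(structure@bloom, keys)
  if (any(pos)) out[pos] <- csfQuery(structure@csf, keys[pos])
  out
}

setMethod("show", "BCSF", function(object) {
  b <- structureBits(object)
  cat(sprintf(
    "BCSF: %s keys, v0 = %d (alpha %.3f, H0 %.3f), %s, %.3f bits/key\n",
    format(object@nKeys, big.mark = ","), object@v0, object@alpha,
    object@h0,
    if (is.null(object@bloom)) {
      if (is.null(object@csf)) "constant" else "no Bloom stage"
    } else sprintf("Bloom eps %.3g", object@epsilon),
    b[["total"]] / object@nKeys))
})

#' @rdname structureBits
#' @export
setMethod("structureBits", "BCSF", function(x) {
  bloom <- if (is.null(x@bloom)) 0 else x@bloom@mBits
  csf <- 0
  codeTable <- 0
  if (!is.null(x@csf)) {
    cb <- structureBits(x@csf)
    csf <- cb[["csf"]]
    codeTable <- cb[["codeTable"]]
  }
  total <- 8 * length(serialize(x, NULL, version = 3L))
  c(bloom = bloom, csf = csf, codeTable = codeTable,
    metadata = total - bloom - csf - codeTable, total = total)
})

#' @rdname queryCount
#' @export
setMethod("queryCount", "BCSF", function(x, keys) bcsfQuery(x, keys))
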