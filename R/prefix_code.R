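#' Build a canonical length-limited prefix code
#'
#' Computes optimal length-limited codeword lengths for the observed value
#' alphabet by the package-merge algorithm (the coin collector's problem
#' over denominations 2^-1 .. 2^-maxLen), then assigns canonical codewords
#' ordered by (length, symbol). The average codeword length under the
#' build histogram lies in [H0, H0 + 1) whenever maxLen is not binding,
#' and the decode tables are reconstructible from symbols and lengths
#' alone.
#'
#' @param histogram frequencies per value: a named numeric vector or
#'   \code{table} whose names are the (integer) symbols.
#' @param maxLen global codeword length cap in bits (default 32, which
#'   bounds the window width retrieved per CSF query). Must satisfy
#'   \code{2^maxLen >= number of symbols}.
#' @return a [PrefixCode-class].
#' @examples
#' code <- buildCode(c(`1` = 2, `2` = 1, `3` = 1))
#' codeLengths(code)   # 1, 2, 2
#' @export
buildCode <- function(histogram, maxLen = 32L) {
  histogram <- unclass(histogram)
  if (is.null(names(histogram)) || !length(histogram))
    stop("histogram must be a non-empty named vector (names = symbols)")
  symbols <- as.integer(names(histogram))
  if (anyNA(symbols)) stop("histogram names must be integer symbols")
  freq <- as.numeric(histogram)
  if (any(freq <= 0)) stop("all frequencies must be positive")
  maxLen <- as.integer(maxLen)
  n <- length(symbols)
  if (n > 1L && maxLen < ceiling(log2(n)))
    stop(sprintf("maxLen = %d cannot satisfy Kraft for %d symbols (need >= %d)",
                 maxLen, n, ceiling(log2(n))))
  lengths <- if (n == 1L) 0L else .package_merge(freq, maxLen)
  .canonical_code(symbols, lengths)
}

#' @rdname buildCode
#' @param code a [PrefixCode-class].
#' @return \code{codeLengths}: integer codeword lengths named by symbol.
#' @export
codeLengths <- function(code) {
  stopifnot(is(code, "PrefixCode"))
  setNames(code@lengths, code@symbols)
}

# Optimal length-limited lengths via package-merge. Returns lengths in the
# order of `freq`.
.package_merge <- function(freq, maxLen) {
  n <- length(freq)
  ord <- order(freq)
  leafW <- freq[ord]
  leafC <- as.list(ord)
  itemsW <- leafW # denomination 2^-maxLen upward
  itemsC <- leafC
  for (lev in seq_len(maxLen - 1L)) {
    np <- length(itemsW) %/% 2L
    if (np > 0L) {
      i1 <- 2L * seq_len(np) - 1L
      pW <- itemsW[i1] + itemsW[i1 + 1L]
      pC <- lapply(seq_len(np), function(i)
        c(itemsC[[2L * i - 1L]], itemsC[[2L * i]]))
    } else {
      pW <- numeric()
      pC <- list()
    }
    itemsW <- c(leafW, pW)
    itemsC <- c(leafC, pC)
    o <- order(itemsW)
    itemsW <- itemsW[o]
    itemsC <- itemsC[o]
  }
  need <- 2L * n - 2L
  if (length(itemsW) < need)
    stop("maxLen too small: package-merge cannot collect enough items")
  len <- integer(n)
  for (i in seq_len(need))
    for (s in itemsC[[i]]) len[s] <- len[s] + 1L
  len
}

# Canonical codeword assignment from (symbol, length) pairs.
.canonical_code <- function(symbols, lengths) {
  o <- order(lengths, symbols)
  symbols <- symbols[o]
  lengths <- as.integer(lengths[o])
  n <- length(symbols)
  maxLen <- max(lengths, 0L)
  codes <- numeric(n)
  if (n > 1L) {
    code <- 0
    for (i in seq_len(n)) {
      if (i > 1L) code <- (code + 1) * 2^(lengths[i] - lengths[i - 1L])
      codes[i] <- code
    }
  }
  lenCount <- integer(maxLen + 1L)
  lenFirst <- numeric(maxLen + 1L)
  lenOffset <- integer(maxLen + 1L)
  if (n > 1L) {
    for (l in seq_len(maxLen)) {
      idx <- which(lengths == l)
      lenCount[l + 1L] <- length(idx)
      if (length(idx)) {
        lenFirst[l + 1L] <- codes[idx[1L]]
        lenOffset[l + 1L] <- idx[1L] - 1L
      }
    }
  }
  new("PrefixCode", symbols = symbols, lengths = lengths, codes = codes,
      maxLen = as.integer(maxLen), lenCount = lenCount, lenFirst = lenFirst,
      lenOffset = lenOffset)
}

setMethod("show", "PrefixCode", function(object)
  cat(sprintf("PrefixCode: %d symbols, codeword lengths %d..%d bits\n",
              length(object@symbols), min(object@lengths),
              max(object@lengths))))

#' Encode and decode single values
#'
#' Instantaneous (prefix-free) coding: \code{decodeValue} reads exactly the
#' codeword's length in bits and ignores anything after it, so streams may
#' be zero-padded.
#'
#' @param code a [PrefixCode-class].
#' @param value a symbol of the code alphabet (encoding an unseen value is
#'   an error).
#' @param bits integer vector of 0/1 bits (MSB of the codeword first).
#' @return \code{encodeValue}: the codeword as an integer 0/1 vector
#'   (length 0 for a single-symbol code); \code{decodeValue}: the decoded
#'   symbol.
#' @examples
#' code <- buildCode(c(`1` = 5, `2` = 3, `7` = 1))
#' decodeValue(code, encodeValue(code, 7))
#' @export
encodeValue <- function(code, value) {
  stopifnot(is(code, "PrefixCode"))
  i <- match(as.integer(value), code@symbols)
  if (is.na(i)) stop("value ", value, " is not in the code alphabet")
  l <- code@lengths[i]
  if (l == 0L) return(integer(0))
  as.integer(floor(code@codes[i] / 2^((l - 1L):0)) %% 2)
}

#' @rdname encodeValue
#' @export
decodeValue <- function(code, bits) {
  stopifnot(is(code, "PrefixCode"))
  if (length(code@symbols) == 1L) return(code@symbols[1L])
  acc <- 0
  for (l in seq_len(code@maxLen)) {
    if (l > length(bits))
      stop("bit stream exhausted before a codeword was recognized")
    acc <- acc * 2 + bits[l]
    cnt <- code@lenCount[l + 1L]
    if (cnt > 0L) {
      d <- acc - code@lenFirst[l + 1L]
      if (d >= 0 && d < cnt)
        return(code@symbols[code@lenOffset[l + 1L] + d + 1L])
    }
  }
  stop("no codeword recognized within maxLen bits")
}

#' Zigzag mapping between signed and unsigned integers
#'
#' The bijection 0 -> 0, -1 -> 1, 1 -> 2, -2 -> 3, ... used to store the
#' (possibly negative) FIL correction terms in a non-negative code
#' alphabet while keeping 0 -- the majority correction -- mapped to 0.
#'
#' @param v integer vector (signed for encode, non-negative for decode).
#' @return integer vector of the same length.
#' @examples
#' zigzagDecode(zigzagEncode(-3L))  # -3
#' @export
zigzagEncode <- function(v) {
  v <- as.integer(v)
  ifelse(v >= 0L, 2L * v, -2L * v - 1L)
}

#' @rdname zigzagEncode
#' @export
zigzagDecode <- function(v) {
  v <- as.integer(v)
  if (any(v < 0L)) stop("zigzag-coded values must be non-negative")
  ifelse(v %% 2L == 0L, v %/% 2L, -((v + 1L) %/% 2L))
}

#' @rdname structureBits
#' @export
setMethod("structureBits", "PrefixCode", function(x) {
  codeTable <- 8 * length(serialize(list(x@symbols, x@lengths), NULL,
                                    version = 3L))
  total <- 8 * length(serialize(x, NULL, version = 3L))
  c(codeTable = codeTable, metadata = total - codeTable, total = total)
})
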