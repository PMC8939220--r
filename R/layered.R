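#' Build an AMB index (ambiguity-marked minimizer cascade)
#'
#' Per layer i, the surviving k-mers are bucketed by their length-m_i
#' minimizer. A bucket is ambiguous iff its count spread exceeds
#' \code{delta}; unambiguous buckets store the bucket minimum (the unique
#' value when delta = 0), ambiguous buckets store the reserved marker 0,
#' and their k-mers cascade to the next layer. K-mers still unresolved
#' after the last layer are stored exactly in a terminal k-mer-keyed BCSF.
#' Every bucket table and the residual are BCSFs.
#'
#' @param table a [KmerCountTable-class].
#' @param minimizerLengths strictly increasing minimizer lengths, all
#'   <= k.
#' @param delta maximum absolute error (0 = exact answers).
#' @param seed build seed; per-layer minimizer-order seeds and all
#'   structure seeds derive from it deterministically.
#' @inheritParams buildCSF
#' @return an [AMBIndex-class].
#' @examples
#' tab <- countKmers(randomGenome(5e4, repeatFraction = 0.1, seed = 4),
#'                   k = 15)
#' amb <- buildAMB(tab, minimizerLengths = 11, seed = 1)
#' all(ambQuery(amb, kmers(tab)) == counts(tab))
#' @export
buildAMB <- function(table, minimizerLengths, delta = 0L, seed = 1L,
                     gamma = 1.10, chunkTarget = 8192L) {
  stopifnot(is(table, "KmerCountTable"))
  ml <- .check_layer_lengths(minimizerLengths, table@k)
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 0L)
    stop("delta must be a single integer >= 0")
  seed <- as.integer(seed)
  keys <- table@kmer
  cnts <- table@count
  layerSeeds <- vapply(seq_along(ml), function(i) .derive_seed(seed, 10L + i),
                       integer(1))
  layers <- vector("list", 0L)
  usedLengths <- integer(0)
  surv <- seq_along(keys)
  for (i in seq_along(ml)) {
    if (!length(surv)) break # earlier layers resolved everything
    mins <- .minimizers_cpp(keys[surv], ml[i], layerSeeds[i])
    st <- .bucket_stats_cpp(mins, cnts[surv])
    amb <- (st$max - st$min) > delta
    bucketValue <- ifelse(amb, 0L, st$min)
    layers[[length(layers) + 1L]] <-
      buildBCSF(st$minimizer, bucketValue,
                seed = .derive_seed(seed, 100L + i), gamma = gamma,
                chunkTarget = chunkTarget)
    usedLengths <- c(usedLengths, ml[i])
    surv <- surv[amb[st$group]]
  }
  residual <- if (length(surv))
    buildBCSF(keys[surv], cnts[surv], seed = .derive_seed(seed, 999L),
              gamma = gamma, chunkTarget = chunkTarget)
  else NULL
  new("AMBIndex", k = table@k, delta = delta,
      minimizerLengths = usedLengths,
      layerSeeds = layerSeeds[seq_along(usedLengths)], layers = layers,
      residual = residual, nKeys = length(keys), seed = seed)
}

#' @rdname buildAMB
#' @param x a built [AMBIndex-class].
#' @param keys k-mers from the build key set.
#' @return \code{ambQuery}: integer counts; exact for delta = 0, within
#'   +/- delta otherwise (the answer is the minimum of the resolving
#'   bucket). Layers are walked in order and the first non-zero bucket
#'   value wins, so unambiguous layer-1 k-mers never touch deeper stages.
#' @export
ambQuery <- function(x, keys) {
  stopifnot(is(x, "AMBIndex"))
  keys <- as.character(keys)
  out <- integer(length(keys))
  remaining <- seq_along(keys)
  for (i in seq_along(x@layers)) {
    if (!length(remaining)) break
    mins <- .minimizers_cpp(keys[remaining], x@minimizerLengths[i],
                            x@layerSeeds[i])
    v <- bcsfQuery(x@layers[[i]], mins)
    hit <- v != 0L
    out[remaining[hit]] <- v[hit]
    remaining <- remaining[!hit]
  }
  if (length(remaining)) {
    # only non-built keys can get here with a NULL residual; any answer
    # is permitted for them (static-function contract)
    out[remaining] <- if (is.null(x@residual)) 0L
                      else bcsfQuery(x@residual, keys[remaining])
  }
  out
}

#' Build a FIL index (majority-representative cascade)
#'
#' Starting from the full table as residual f0, each layer buckets all
#' k-mers by their length-m_i minimizer and stores the per-bucket exact
#' majority g_i of the current residual values (ties toward the smallest
#' value); the residual telescopes as
#' \code{f_i(q) = f_(i-1)(q) - g_i(minimizer_i(q))}. The final residuals
#' h = f_l -- mostly 0 by the majority rule -- are zigzag-coded and stored
#' in a terminal k-mer-keyed BCSF, whose Bloom filter (if any) therefore
#' holds exactly the k-mers with a non-zero correction.
#'
#' @inheritParams buildAMB
#' @return a [FILIndex-class].
#' @examples
#' tab <- powerlawTable(2000, exponent = 2.2, maxCount = 30, k = 15,
#'                      seed = 5)
#' fil <- buildFIL(tab, minimizerLengths = c(9, 11), seed = 1)
#' all(filQuery(fil, kmers(tab)) == counts(tab))
#' @export
buildFIL <- function(table, minimizerLengths, seed = 1L, gamma = 1.10,
                     chunkTarget = 8192L) {
  stopifnot(is(table, "KmerCountTable"))
  ml <- .check_layer_lengths(minimizerLengths, table@k)
  seed <- as.integer(seed)
  keys <- table@kmer
  resid <- table@count
  layerSeeds <- vapply(seq_along(ml), function(i) .derive_seed(seed, 20L + i),
                       integer(1))
  layers <- vector("list", length(ml))
  for (i in seq_along(ml)) {
    mins <- .minimizers_cpp(keys, ml[i], layerSeeds[i])
    mj <- .bucket_majority_cpp(mins, resid)
    layers[[i]] <- buildBCSF(mj$minimizer, mj$majority,
                             seed = .derive_seed(seed, 200L + i),
                             gamma = gamma, chunkTarget = chunkTarget)
    resid <- resid - mj$majority[mj$group]
  }
  corrections <- buildBCSF(keys, zigzagEncode(resid),
                           seed = .derive_seed(seed, 998L), gamma = gamma,
                           chunkTarget = chunkTarget)
  new("FILIndex", k = table@k, minimizerLengths = ml,
      layerSeeds = layerSeeds, layers = layers, corrections = corrections,
      nKeys = length(keys), seed = seed)
}

#' @rdname buildFIL
#' @param x a built [FILIndex-class].
#' @param keys k-mers from the build key set.
#' @return \code{filQuery}: exact integer counts, reconstructed as the sum
#'   of all layer representatives along the k-mer's minimizers plus its
#'   correction (every layer is visited on every query).
#' @export
filQuery <- function(x, keys) {
  stopifnot(is(x, "FILIndex"))
  keys <- as.character(keys)
  acc <- integer(length(keys))
  for (i in seq_along(x@layers)) {
    mins <- .minimizers_cpp(keys, x@minimizerLengths[i], x@layerSeeds[i])
    acc <- acc + bcsfQuery(x@layers[[i]], mins)
  }
  acc + zigzagDecode(bcsfQuery(x@corrections, keys))
}

#' @rdname queryCount
#' @export
setMethod("queryCount", "AMBIndex", function(x, keys) ambQuery(x, keys))

#' @rdname queryCount
#' @export
setMethod("queryCount", "FILIndex", function(x, keys) filQuery(x, keys))

setMethod("show", "AMBIndex", function(object) {
  b <- structureBits(object)
  res <- if (is.null(object@residual)) 0 else object@residual@nKeys
  cat(sprintf(
    "AMBIndex: %s %d-mers, delta = %d, layers m = %s, residual %s keys, %.3f bits/key\n",
    format(object@nKeys, big.mark = ","), object@k, object@delta,
    paste(object@minimizerLengths, collapse = ","),
    format(res, big.mark = ","), b[["total"]] / object@nKeys))
})

setMethod("show", "FILIndex", function(object) {
  b <- structureBits(object)
  cat(sprintf(
    "FILIndex: %s %d-mers, layers m = %s, %.3f bits/key\n",
    format(object@nKeys, big.mark = ","), object@k,
    paste(object@minimizerLengths, collapse = ","),
    b[["total"]] / object@nKeys))
})

#' @rdname structureBits
#' @export
setMethod("structureBits", "AMBIndex", function(x) {
  parts <- lapply(x@layers, structureBits)
  if (!is.null(x@residual)) parts <- c(parts, list(structureBits(x@residual)))
  .sum_component_bits(parts, x)
})

#' @rdname structureBits
#' @export
setMethod("structureBits", "FILIndex", function(x) {
  parts <- lapply(c(x@layers, list(x@corrections)), structureBits)
  .sum_component_bits(parts, x)
})

.sum_component_bits <- function(parts, whole) {
  get0n <- function(p, nm) if (nm %in% names(p)) p[[nm]] else 0
  bloom <- sum(vapply(parts, get0n, numeric(1), "bloom"))
  csf <- sum(vapply(parts, get0n, numeric(1), "csf"))
  codeTable <- sum(vapply(parts, get0n, numeric(1), "codeTable"))
  total <- 8 * length(serialize(whole, NULL, version = 3L))
  c(bloom = bloom, csf = csf, codeTable = codeTable,
    metadata = total - bloom - csf - codeTable, total = total)
}

.check_layer_lengths <- function(minimizerLengths, k) {
  ml <- as.integer(minimizerLengths)
  if (!length(ml) || anyNA(ml))
    stop("minimizerLengths must be a non-empty integer vector")
  if (any(diff(ml) <= 0))
    stop("minimizerLengths must be strictly increasing")
  if (any(ml < 1L) || any(ml > k))
    stop("minimizerLengths must lie in [1, k]")
  ml
}
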