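#' Save and load index structures
#'
#' A self-describing, checksummed binary container. Layout: magic bytes
#' "KCSF", a little-endian format version, an 8-byte scheme tag (CSF,
#' BCSF, AMB, FIL or BLOOM), and a fixed-width section table (16-byte
#' name, 8-byte length, 8-byte CRC-32) followed by the section payloads.
#' The \code{meta} section carries scheme, k, layer lengths, delta and all
#' seeds; the \code{payload} section carries the structure itself. The
#' reported file size equals the header plus the declared section
#' lengths, and \code{loadIndex(saveIndex(x))} answers every query
#' identically to \code{x}.
#'
#' Errors are signalled with distinct condition classes:
#' \code{kcsfFormatError} (bad magic), \code{kcsfVersionError},
#' \code{kcsfTruncationError} and \code{kcsfChecksumError}, all
#' inheriting from \code{kcsfError}.
#'
#' @param x a [CSF-class], [BCSF-class], [AMBIndex-class],
#'   [FILIndex-class] or [BloomFilter-class].
#' @param path file path.
#' @return \code{saveIndex}: the path, invisibly; \code{loadIndex}: the
#'   restored structure.
#' @examples
#' tab <- powerlawTable(300, exponent = 2, maxCount = 9, k = 11, seed = 1)
#' idx <- buildBCSF(tab, seed = 1)
#' f <- tempfile(fileext = ".kcsf")
#' saveIndex(idx, f)
#' identical(queryCount(loadIndex(f), kmers(tab)),
#'           queryCount(idx, kmers(tab)))
#' @export
saveIndex <- function(x, path) {
  tag <- .scheme_tag(x)
  meta <- serialize(.index_meta(x, tag), NULL, version = 3L)
  payload <- serialize(x, NULL, version = 3L)
  sections <- list(meta = meta, payload = payload)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KCSF"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  tagRaw <- raw(8L)
  tagBytes <- charToRaw(tag)
  tagRaw[seq_along(tagBytes)] <- tagBytes
  writeBin(tagRaw, con)
  writeBin(length(sections), con, size = 4L, endian = "little")
  for (nm in names(sections)) {
    nameRaw <- raw(16L)
    nb <- charToRaw(nm)
    nameRaw[seq_along(nb)] <- nb
    writeBin(nameRaw, con)
    writeBin(as.numeric(length(sections[[nm]])), con, size = 8L,
             endian = "little")
    writeBin(.crc32_cpp(sections[[nm]]), con, size = 8L, endian = "little")
  }
  for (nm in names(sections)) writeBin(sections[[nm]], con)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(rawToChar(magic), "KCSF"))
    .kcsf_stop("kcsfFormatError", "not a kcsf container (bad magic bytes)")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(version, 1L))
    .kcsf_stop("kcsfVersionError",
               sprintf("unsupported container version %s", version))
  tag <- .raw_string(readBin(con, "raw", 8L))
  nsect <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(nsect) || is.na(nsect) || nsect < 1L || nsect > 64L)
    .kcsf_stop("kcsfTruncationError", "corrupt section table")
  names <- character(nsect)
  lens <- numeric(nsect)
  crcs <- numeric(nsect)
  for (i in seq_len(nsect)) {
    nameRaw <- readBin(con, "raw", 16L)
    lenV <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
    crcV <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
    if (length(nameRaw) < 16L || !length(lenV) || !length(crcV))
      .kcsf_stop("kcsfTruncationError", "truncated section table")
    names[i] <- .raw_string(nameRaw)
    lens[i] <- lenV
    crcs[i] <- crcV
  }
  headerBytes <- 4 + 4 + 8 + 4 + nsect * 32
  if (!is.na(size) && size != headerBytes + sum(lens))
    .kcsf_stop("kcsfTruncationError",
               sprintf("file size %d does not match header + declared sections (%d)",
                       size, headerBytes + sum(lens)))
  sections <- list()
  for (i in seq_len(nsect)) {
    data <- readBin(con, "raw", lens[i])
    if (length(data) < lens[i])
      .kcsf_stop("kcsfTruncationError",
                 sprintf("section '%s' truncated", names[i]))
    if (.crc32_cpp(data) != crcs[i])
      .kcsf_stop("kcsfChecksumError",
                 sprintf("checksum mismatch in section '%s'", names[i]))
    sections[[names[i]]] <- data
  }
  if (is.null(sections$payload))
    .kcsf_stop("kcsfFormatError", "container has no payload section")
  x <- unserialize(sections$payload)
  if (!identical(.scheme_tag(x), tag))
    .kcsf_stop("kcsfFormatError",
               sprintf("scheme tag '%s' does not match payload class '%s'",
                       tag, class(x)[1L]))
  validObject(x, complete = FALSE)
  x
}

.scheme_tag <- function(x) {
  if (is(x, "CSF")) return("CSF")
  if (is(x, "BCSF")) return("BCSF")
  if (is(x, "AMBIndex")) return("AMB")
  if (is(x, "FILIndex")) return("FIL")
  if (is(x, "BloomFilter")) return("BLOOM")
  stop("cannot serialize objects of class ", class(x)[1L])
}

.index_meta <- function(x, tag) {
  m <- list(scheme = tag, package = "kcsf", formatVersion = 1L)
  if (is(x, "AMBIndex"))
    m <- c(m, list(k = x@k, minimizerLengths = x@minimizerLengths,
                   delta = x@delta, seed = x@seed,
                   layerSeeds = x@layerSeeds))
  if (is(x, "FILIndex"))
    m <- c(m, list(k = x@k, minimizerLengths = x@minimizerLengths,
                   seed = x@seed, layerSeeds = x@layerSeeds))
  if (is(x, "CSF")) m <- c(m, list(seed = x@seed, gamma = x@gamma))
  if (is(x, "BCSF")) m <- c(m, list(seed = x@seed, epsilon = x@epsilon))
  if (is(x, "BloomFilter")) m <- c(m, list(seed = x@seed))
  m
}

# decode a zero-padded fixed-width name field
.raw_string <- function(r) rawToChar(r[r != as.raw(0L)])

.kcsf_stop <- function(class, message) {
  stop(structure(class = c(class, "kcsfError", "error", "condition"),
                 list(message = message, call = sys.call(-1L))))
}
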