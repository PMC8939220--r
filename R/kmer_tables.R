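#' Construct a k-mer count table
#'
#' Low-level constructor; most users will obtain tables from
#' [countKmers()], [readCountTable()] or the synthetic generators.
#'
#' @param kmer character vector of distinct k-mers (A/C/G/T, common length).
#' @param count integer counts, all >= 1.
#' @return a validated [KmerCountTable-class].
#' @examples
#' KmerCountTable(c("ACG", "CGT"), c(2L, 1L))
#' @export
KmerCountTable <- function(kmer, count) {
  new("KmerCountTable", kmer = as.character(kmer),
      count = as.integer(count),
      k = if (length(kmer)) nchar(kmer[[1L]])[[1L]] else NA_integer_)
}

#' @rdname kmers
#' @export
setMethod("kmers", "KmerCountTable", function(x) x@kmer)

#' @rdname kmers
#' @export
setMethod("counts", "KmerCountTable", function(x) x@count)

#' @rdname kmers
#' @export
setMethod("kmerLength", "KmerCountTable", function(x) x@k)

#' @rdname kmers
#' @export
setMethod("totalCount", "KmerCountTable", function(x) sum(as.numeric(x@count)))

setMethod("show", "KmerCountTable", function(object) {
  cat(sprintf("KmerCountTable: %d distinct %d-mers, total count %s\n",
              length(object@kmer), object@k,
              format(totalCount(object), big.mark = ",")))
  n <- min(5L, length(object@kmer))
  for (i in seq_len(n))
    cat(sprintf("  %s\t%d\n", object@kmer[i], object@count[i]))
  if (length(object@kmer) > n) cat("  ...\n")
})

#' @export
setMethod("length", "KmerCountTable", function(x) length(x@kmer))

#' Count canonical k-mers in DNA sequences
#'
#' Slides a window of length \code{k} over every sequence and counts each
#' k-mer, by default after canonicalization (the lexicographic minimum of
#' the k-mer and its reverse complement, the convention of standard k-mer
#' counters). Windows containing \code{N} are skipped entirely; lowercase
#' input is accepted; any other character is rejected.
#'
#' @param sequences character vector of DNA sequences, a
#'   \code{Biostrings::DNAStringSet}, or a path readable by
#'   [readSequences()].
#' @param k k-mer length, 1..31 (so a k-mer packs into one 64-bit word;
#'   longer k-mers, e.g. KMC dumps at k = 32, are rejected).
#' @param canonical count canonical k-mers (default) or forward strand only.
#' @return a [KmerCountTable-class], keys in lexicographic order.
#' @examples
#' countKmers("AAAA", k = 3)          # {AAA: 2}
#' countKmers("ACGT", k = 4)          # own reverse complement
#' @export
countKmers <- function(sequences, k, canonical = TRUE) {
  sequences <- .as_sequences(sequences)
  k <- .check_k(k)
  res <- .count_kmers_cpp(sequences, k, isTRUE(canonical))
  new("KmerCountTable", kmer = res$kmer, count = res$count, k = k)
}

#' Document frequency of k-mers across genomes
#'
#' Counts, for each distinct canonical k-mer, the number of genomes
#' (documents) it occurs in; all counts lie in [1, number of genomes].
#'
#' @param genomes list of sequence collections (each a character vector,
#'   \code{DNAStringSet}, or file path), one element per genome.
#' @inheritParams countKmers
#' @return a [KmerCountTable-class] of document frequencies.
#' @examples
#' documentFrequency(list("ACGTT", "ACGTT"), k = 5)
#' @export
documentFrequency <- function(genomes, k, canonical = TRUE) {
  if (!is.list(genomes)) genomes <- list(genomes)
  if (length(genomes) < 1L) stop("at least one genome is required")
  genomes <- lapply(genomes, .as_sequences)
  k <- .check_k(k)
  res <- .document_frequency_cpp(genomes, k, isTRUE(canonical))
  new("KmerCountTable", kmer = res$kmer, count = res$count, k = k)
}

#' Read and write two-column count-table dumps
#'
#' The TSV dump format of common k-mer counters: one record per line,
#' \code{<KMER>\\t<COUNT>}. \code{readCountTable} infers k from the first
#' record and enforces it (with a line number in every parse error);
#' \code{writeCountTable} is its inverse, so write-then-read is the
#' identity up to key order.
#'
#' @param path file path (plain or gzip for reading).
#' @return a [KmerCountTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeCountTable(countKmers("ACGTACGA", k = 5), f)
#' readCountTable(f)
#' @export
readCountTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty count table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected '<KMER>\\t<COUNT>', got %s",
                 bad[1L], dQuote(lines[bad[1L]])))
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  cnt <- suppressWarnings(as.integer(m[, 2L]))
  bad <- which(is.na(cnt) | m[, 2L] != as.character(cnt))
  if (length(bad))
    stop(sprintf("line %d: count %s is not a decimal integer",
                 bad[1L], dQuote(m[bad[1L], 2L])))
  bad <- which(cnt < 1L)
  if (length(bad))
    stop(sprintf("line %d: count must be >= 1 (value 0 is reserved)",
                 bad[1L]))
  k <- nchar(m[1L, 1L])
  bad <- which(nchar(m[, 1L]) != k)
  if (length(bad))
    stop(sprintf("line %d: k-mer length %d differs from inferred k = %d",
                 bad[1L], nchar(m[bad[1L], 1L]), k))
  new("KmerCountTable", kmer = m[, 1L], count = cnt, k = as.integer(k))
}

#' @rdname readCountTable
#' @param table a [KmerCountTable-class] to write.
#' @export
writeCountTable <- function(table, path) {
  stopifnot(is(table, "KmerCountTable"))
  writeLines(paste0(table@kmer, "\t", table@count), path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} (plain or gzip;
#' format chosen from the file extension) returning plain character
#' sequences.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @return named character vector of sequences.
#' @export
readSequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A,C,G,T.
#' @return character vector of reverse complements.
#' @examples
#' reverseComplement("ACGTT")
#' @export
reverseComplement <- function(x) .revcomp_cpp(as.character(x))

## ---- internal helpers -----------------------------------------------------

.as_sequences <- function(sequences) {
  if (is(sequences, "XStringSet")) return(as.character(sequences))
  if (is.character(sequences) && length(sequences) == 1L &&
      !grepl("^[ACGTNacgtn]*$", sequences) && file.exists(sequences))
    return(readSequences(sequences))
  if (!is.character(sequences) || !length(sequences))
    stop("sequences must be a non-empty character vector, DNAStringSet or file path")
  sequences
}

.check_k <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single integer >= 1")
  if (k > 31L)
    stop("k must be <= 31 so a k-mer packs into one 64-bit word (k = ", k,
         " requested)")
  k
}

.valid_windows <- function(sequences, k)
  .count_windows_cpp(.as_sequences(sequences), .check_k(k))
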