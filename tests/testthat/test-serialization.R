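make_fixture_indexes <- function() {
  tab <- powerlawTable(5000, exponent = 1.6, maxCount = 25, k = 13,
                       seed = 31)
  list(table = tab, indexes = list(
    csf = buildCSF(kmers(tab), counts(tab), seed = 1),
    bcsf = buildBCSF(tab, seed = 1),
    amb = buildAMB(tab, minimizerLengths = c(7, 9), delta = 1, seed = 1),
    fil = buildFIL(tab, minimizerLengths = 7, seed = 1)))
}

test_that("every scheme survives a save/load round trip", {
  fx <- make_fixture_indexes()
  for (nm in names(fx$indexes)) {
    x <- fx$indexes[[nm]]
    f <- tempfile(fileext = ".kcsf")
    saveIndex(x, f)
    y <- loadIndex(f)
    expect_identical(queryCount(y, kmers(fx$table)),
                     queryCount(x, kmers(fx$table)), label = nm)
  }
  bf <- buildBloom(kmers(fx$table)[1:50], 0.1, seed = 2)
  f <- tempfile()
  saveIndex(bf, f)
  expect_identical(bloomQuery(loadIndex(f), kmers(fx$table)),
                   bloomQuery(bf, kmers(fx$table)))
})

test_that("the declared section lengths account for the whole file", {
  fx <- make_fixture_indexes()
  f <- tempfile(fileext = ".kcsf")
  saveIndex(fx$indexes$bcsf, f)
  con <- file(f, "rb")
  on.exit(close(con))
  expect_identical(rawToChar(readBin(con, "raw", 4L)), "KCSF")
  expect_identical(readBin(con, "integer", 1L, size = 4L,
                           endian = "little"), 1L)
  tag <- readBin(con, "raw", 8L)
  expect_identical(rawToChar(tag[tag != as.raw(0)]), "BCSF")
  nsect <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  lens <- numeric(nsect)
  for (i in seq_len(nsect)) {
    readBin(con, "raw", 16L)
    lens[i] <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
    readBin(con, "numeric", 1L, size = 8L, endian = "little")
  }
  header <- 4 + 4 + 8 + 4 + nsect * 32
  expect_equal(file.size(f), header + sum(lens))
})

test_that("corruption and format errors raise distinct condition classes", {
  fx <- make_fixture_indexes()
  f <- tempfile(fileext = ".kcsf")
  saveIndex(fx$indexes$csf, f)

  # flip one payload byte: checksum failure, never a silent wrong answer
  bytes <- readBin(f, "raw", file.size(f))
  pos <- length(bytes) - 5L
  bytes[pos] <- xor(bytes[pos], as.raw(0xFF))
  writeBin(bytes, f)
  expect_error(loadIndex(f), class = "kcsfChecksumError")

  # truncation
  writeBin(readBin(f, "raw", file.size(f))[1:100], f)
  expect_error(loadIndex(f), class = "kcsfTruncationError")

  # bad magic
  writeBin(charToRaw("NOPE"), f)
  expect_error(loadIndex(f), class = "kcsfFormatError")

  # bad version
  saveIndex(fx$indexes$csf, f)
  bytes <- readBin(f, "raw", file.size(f))
  bytes[5] <- as.raw(9)
  writeBin(bytes, f)
  expect_error(loadIndex(f), class = "kcsfVersionError")
})

test_that("the command-line interface drives count/build/query/stats", {
  cli <- system.file("cli", "kcsf.R", package = "kcsf")
  expect_true(nzchar(cli))
  dir <- tempfile()
  dir.create(dir)
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">g", randomGenome(20000, 0.05, 500L, seed = 12)), fa)
  tsv <- file.path(dir, "counts.tsv")
  idx <- file.path(dir, "index.kcsf")

  run <- function(...) system2("Rscript", c(cli, ...), stdout = TRUE,
                               stderr = FALSE)
  run("count", "--fasta", fa, "--k", "13", "-o", tsv)
  tab <- readCountTable(tsv)
  expect_gt(length(tab), 10000)

  run("build", "--counts", tsv, "--scheme", "amb", "--minimizers", "9,11",
      "--seed", "5", "-o", idx)
  qk <- file.path(dir, "keys.txt")
  writeLines(kmers(tab)[1:200], qk)
  out <- run("query", "--index", idx, "--kmers", qk)
  parsed <- read.table(text = out, sep = "\t")
  expect_identical(as.integer(parsed$V2), counts(tab)[1:200])

  stats <- run("stats", "--counts", tsv, "--index", idx)
  expect_true(any(grepl("h0", stats)))
  sug <- run("suggest", "--genome-size", "1048576", "--k", "15")
  expect_true(any(grepl("candidates", sug)))
})
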