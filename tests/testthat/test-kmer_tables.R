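test_that("countKmers counts canonical k-mers of simple sequences", {
  tab <- countKmers("AAAA", k = 3)
  expect_equal(setNames(counts(tab), kmers(tab)), c(AAA = 2L))
  tab <- countKmers("ACGT", k = 4)
  expect_equal(setNames(counts(tab), kmers(tab)), c(ACGT = 1L))
  # forward-strand mode keeps both strands distinct
  fw <- countKmers(c("AAAT", "ATTT"), k = 4, canonical = FALSE)
  expect_setequal(kmers(fw), c("AAAT", "ATTT"))
  ca <- countKmers(c("AAAT", "ATTT"), k = 4, canonical = TRUE)
  expect_equal(setNames(counts(ca), kmers(ca)), c(AAAT = 2L))
})

test_that("count conservation and canonicalization invariances hold", {
  set.seed(11)
  seqs <- c(
    replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 200,
                              replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                       collapse = "")),
    "ACGTACGTAC")
  for (k in c(3L, 7L)) {
    tab <- countKmers(seqs, k)
    expect_identical(totalCount(tab), as.numeric(oracle_window_count(seqs, k)))
    # counting the reverse complement of every sequence gives the same table
    rc <- countKmers(reverseComplement(seqs), k)
    expect_identical(setNames(counts(tab), kmers(tab)),
                     setNames(counts(rc), kmers(rc)))
  }
})

test_that("countKmers rejects invalid input", {
  expect_error(countKmers(character(0), k = 3), "non-empty")
  expect_error(countKmers("ACGT", k = 0), ">= 1")
  expect_error(countKmers("ACGT", k = 32), "64-bit")
  expect_error(countKmers("ACGU", k = 2), "invalid character")
  expect_error(countKmers(c("ACG", "GT"), k = 5), "shorter than k")
  expect_error(countKmers("ANNGA", k = 3), "shorter than k|contain N")
})

test_that("documentFrequency counts genomes containing each k-mer", {
  df <- documentFrequency(list("ACGTT", "ACGTT"), k = 5)
  expect_equal(counts(df), 2L)
  expect_equal(kmers(df), min("ACGTT", reverseComplement("ACGTT")))
  df1 <- documentFrequency(list("AAAAA"), k = 5)
  expect_equal(setNames(counts(df1), kmers(df1)), c(AAAAA = 1L))

  # three genomes sharing a seeded 1 kb segment: brute-force per-genome
  # membership oracle
  set.seed(42)
  shared <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  genomes <- lapply(1:3, function(i) {
    own <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
    paste0(own, shared)
  })
  k <- 15L
  df <- documentFrequency(genomes, k)
  perGenome <- lapply(genomes, function(g) kmers(countKmers(g, k)))
  expected <- table(unlist(perGenome))
  expect_identical(setNames(counts(df), kmers(df)),
                   setNames(as.integer(expected)[match(kmers(df),
                                                       names(expected))],
                            kmers(df)))
  expect_true(all(counts(df) <= 3L))
  sharedKmers <- kmers(countKmers(shared, k))
  expect_true(all(counts(df)[match(sharedKmers, kmers(df))] == 3L))
})

test_that("count-table TSV round trips and parse errors carry line numbers", {
  f <- tempfile(fileext = ".tsv")
  writeLines("AAA\t2", f)
  tab <- readCountTable(f)
  expect_equal(setNames(counts(tab), kmers(tab)), c(AAA = 2L))

  big <- random_table_manual(1000, 9, 1:50, seed = 5)
  writeCountTable(big, f)
  back <- readCountTable(f)
  o <- match(kmers(big), kmers(back))
  expect_identical(counts(back)[o], counts(big))

  writeLines(c("AAA\t1", "AAA"), f)
  expect_error(readCountTable(f), "line 2")
  writeLines(c("AAA\t1", "AAT\t0"), f)
  expect_error(readCountTable(f), "line 2.*>= 1")
  writeLines(c("AAA\t1", "AATT\t3"), f)
  expect_error(readCountTable(f), "line 2.*k = 3")
  writeLines("AAA\tx", f)
  expect_error(readCountTable(f), "line 1.*decimal")
})

test_that("sequences can be read from FASTA and FASTQ files", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGT", ">s2", "GGGTTT"), fa)
  expect_identical(unname(readSequences(fa)), c("ACGTACGT", "GGGTTT"))
  tab <- countKmers(fa, k = 5)
  direct <- countKmers(c("ACGTACGT", "GGGTTT"), k = 5)
  expect_identical(counts(tab), counts(direct))
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTAC", "+", "IIIIII"), fq)
  expect_identical(unname(readSequences(fq)), "ACGTAC")
})

test_that("KmerCountTable enforces its invariants", {
  expect_error(KmerCountTable(c("AAA", "AAA"), c(1L, 2L)), "distinct")
  expect_error(KmerCountTable("AAA", 0L), ">= 1")
  expect_error(KmerCountTable(c("AAA", "AC"), c(1L, 1L)), "length")
  expect_error(KmerCountTable("ANA", 1L), "A, C, G, T")
})
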