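# Brute-force oracles, independent of the code paths they check.

# minimizer by full window enumeration over the exposed m-mer order
oracle_minimizer <- function(q, m, seed) {
  wins <- substring(q, seq_len(nchar(q) - m + 1L),
                    seq_len(nchar(q) - m + 1L) + m - 1L)
  h <- mmerOrderHash(wins, seed)
  wins[which.min(h)] # which.min takes the leftmost tie
}

# bucket composition by literal grouping of the full value multiset
oracle_buckets <- function(keys, cnts, m, seed) {
  mins <- vapply(keys, oracle_minimizer, character(1), m = m, seed = seed)
  split(cnts, factor(mins, levels = unique(mins)))
}

# histogram mode with the smallest-value tie rule
oracle_mode <- function(v) {
  h <- table(v)
  as.integer(min(as.integer(names(h)[h == max(h)])))
}

# instantaneous decoding by walking an explicit binary code tree built
# from canonical (length, symbol) assignments recomputed from scratch
oracle_tree_decode <- function(symbols, lengths, bits) {
  o <- order(lengths, symbols)
  symbols <- symbols[o]
  lengths <- lengths[o]
  code <- 0
  tree <- list()
  for (i in seq_along(symbols)) {
    if (i > 1L) code <- (code + 1) * 2^(lengths[i] - lengths[i - 1L])
    path <- as.integer(floor(code / 2^((lengths[i] - 1L):0)) %% 2)
    tree[[paste(path, collapse = "")]] <- symbols[i]
  }
  acc <- character(0)
  for (b in bits) {
    acc <- c(acc, as.character(b))
    hit <- tree[[paste(acc, collapse = "")]]
    if (!is.null(hit)) return(hit)
  }
  stop("no codeword found")
}

# number of N-free k-windows, by direct string inspection
oracle_window_count <- function(seqs, k) {
  total <- 0L
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L))
      if (!grepl("N", substr(s, i, i + k - 1L), fixed = TRUE))
        total <- total + 1L
  }
  total
}

# small random tables without going through the package generators
random_table_manual <- function(n, k, values, seed) {
  set.seed(seed)
  keys <- character(0)
  while (length(keys) < n)
    keys <- unique(c(keys, paste(
      sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")))
  cnts <- if (length(values) == 1L) rep(values, n)
          else sample(values, n, replace = TRUE)
  KmerCountTable(keys[seq_len(n)], cnts)
}
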