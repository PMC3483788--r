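# Independent oracles used across tests. These deliberately avoid the
# code paths they check: tail probabilities come from exhaustive subset
# enumeration or choose() arithmetic, k-mer counts from a naive
# sliding-window tally.

# Exhaustive hypergeometric tails for one (N, n): enumerate all C(N, n)
# draws from a population where items 1..K are successes; returns a
# function (k, K, tail) -> probability.
enum_hyper <- function(N, n) {
  combs <- utils::combn(N, n)
  function(k, K, tail) {
    x <- if (n == 0L) rep(0L, ncol(combs)) else
      colSums(matrix(combs <= K, nrow = n))
    if (tail == "enrichment") mean(x >= k) else mean(x <= k)
  }
}

# choose()-arithmetic enrichment tail, independent of phyper
choose_tail_enrich <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive overlapping k-mer tally over a character vector of sequences;
# windows containing N are skipped.
naive_kmer_counts <- function(seqs, k) {
  out <- integer(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    words <- substring(s, 1:(L - k + 1L), k:L)
    words <- words[!grepl("N", words, fixed = TRUE)]
    t <- table(words)
    for (w in names(t)) out[w] <- (if (w %in% names(out)) out[w] else 0L) + t[[w]]
  }
  out
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
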