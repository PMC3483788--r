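test_that("DUST-style masking flags homopolymers but not random sequence", {
  homo <- utr_set(c(g1 = strrep("A", 50)))
  masked <- mask_low_complexity(homo)
  expect_equal(masked$mask$g1, cbind(start = 0L, end = 50L))

  rnd <- utr_set(c(g1 = random_dna(64, seed = 101)))
  expect_identical(nrow(mask_low_complexity(rnd)$mask$g1), 0L)

  # idempotence: re-masking an already masked record changes nothing
  once <- mask_low_complexity(homo)
  twice <- mask_low_complexity(once)
  expect_identical(once, twice)

  expect_error(mask_low_complexity(homo, window = 3), "window")
})

test_that("redundant k-mers shared by many UTRs are purged", {
  core <- random_dna(30, seed = 5)
  seqs <- setNames(paste0(vapply(1:6, function(i) random_dna(40, seed = 200 + i),
                                 ""), core),
                   sprintf("g%d", 1:6))
  utrs <- mask_redundant(utr_set(seqs), k = 30, max_utrs = 5)
  for (g in names(seqs))
    expect_true(any(utrs$mask[[g]][, 1] <= 40 & utrs$mask[[g]][, 2] >= 70))
  # below the recurrence threshold nothing is masked
  utrs2 <- mask_redundant(utr_set(seqs[1:4]), k = 30, max_utrs = 5)
  expect_true(all(vapply(utrs2$mask, nrow, integer(1)) == 0L))
})

test_that("word counting is overlapping, mask-aware, and total-consistent", {
  u <- utr_set(c(g1 = "GTGCCTTGTGCCTT"))
  wct <- count_words(u, "GTGCCTT")
  expect_identical(unname(wct$counts[1, 1]), 2L)
  expect_identical(unname(wct$totals["g1"]), 8L)

  # overlapping occurrences all counted
  wov <- count_words(utr_set(c(g = strrep("A", 9))), "AAAAAAA")
  expect_identical(unname(wov$counts[1, 1]), 3L)

  # too-short sequence: zero counts, zero total positions
  short <- count_words(utr_set(c(g1 = "ACGTAC")), "GTGCCTT")
  expect_identical(unname(short$counts[1, 1]), 0L)
  expect_identical(unname(short$totals["g1"]), 0L)

  # mask covering part of the only window suppresses it
  m <- utr_set(c(g1 = "GTGCCTT"), masks = list(g1 = cbind(0L, 3L)))
  wm <- count_words(m, "GTGCCTT")
  expect_identical(unname(wm$counts[1, 1]), 0L)
  expect_identical(unname(wm$totals["g1"]), 0L)

  expect_error(count_words(u, "GTGCC"), "length 7")
})

test_that("counts over the complete word space sum to the total positions", {
  utrs <- gen_utrs(15, length_mean = 60, length_sd = 10, seed = 42)$utrs
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  wct <- count_words(utrs, all3, word_length = 3)
  expect_equal(unname(rowSums(wct$counts)), unname(wct$totals))
  expect_identical(wct$grand_total, sum(wct$totals))
})

test_that("masking never increases counts or totals", {
  utrs <- gen_utrs(10, length_mean = 120, length_sd = 10, gc = 0.6,
                   seed = 8)$utrs
  words <- c("GGGGGGG", "GCGCGCG", "ACGTACG")
  before <- count_words(utrs, words)
  masked <- mask_low_complexity(utrs, threshold = 5)  # aggressive
  after <- count_words(masked, words)
  expect_true(all(after$counts <= before$counts))
  expect_true(all(after$totals <= before$totals))
})

test_that("Markov models count unmasked k-mers exhaustively", {
  m <- fit_markov(utr_set(c(g = "AAAA")), order = 1)
  expect_identical(unname(m$counts_m["A"]), 4)
  expect_identical(unname(m$counts_m1["AA"]), 3)

  one <- fit_markov(utr_set(c(g = "ACGT")), order = 1)
  two <- fit_markov(utr_set(c(g1 = "ACGT", g2 = "ACGT")), order = 1)
  expect_equal(two$counts_m1, one$counts_m1 * 2)

  # seeded 10 kb sequence: counts equal a naive sliding-window tally
  s <- random_dna(10000, seed = 77)
  mm <- fit_markov(utr_set(c(g = s)), order = 4)
  ref5 <- naive_kmer_counts(s, 5)
  expect_equal(mm$counts_m1[names(ref5)], unclass(ref5) * 1.0,
               ignore_attr = TRUE)
  expect_equal(sum(mm$counts_m1), sum(ref5), ignore_attr = TRUE)

  # masked windows are excluded
  mN <- fit_markov(utr_set(c(g = "ACGTACGT"),
                           masks = list(g = cbind(3L, 5L))), order = 1)
  refN <- naive_kmer_counts("ACGNNCGT", 2)
  expect_equal(sum(mN$counts_m1), sum(refN))

  expect_error(fit_markov(utr_set(c(g = "ACG")), order = 4), "insufficient")
})

test_that("Markov word probabilities match composition expectations", {
  # i.i.d. uniform 1 Mb: any 7-mer probability ~ 4^-7
  big <- utr_set(c(g = random_dna(1000000, seed = 13)))
  model <- fit_markov(big, order = 4)
  p <- markov_word_probability(model, "GTGCCTT")
  expect_lt(abs(p - 4^-7) / 4^-7, 0.15)

  # order 0 reduces to the base-composition product
  m0 <- fit_markov(utr_set(c(g = "AACGAACG")), order = 0)
  pA <- 4 / 8
  expect_equal(markov_word_probability(m0, "AA"), pA^2)

  # absent sub-word errors and names the offender
  small <- fit_markov(utr_set(c(g = "AAAAAAAAAA")), order = 1)
  expect_error(markov_word_probability(small, "AACAA"), "AC")

  # conditional normalization: per shared prefix the (m+1)-mer
  # probabilities sum to the prefix probability (up to edge effects)
  s <- random_dna(100000, seed = 21)
  m1 <- fit_markov(utr_set(c(g = s)), order = 1)
  all2 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                1, paste, collapse = "")
  tot <- sum(vapply(all2, function(w) markov_word_probability(m1, w), 0))
  expect_lt(abs(tot - 1), 1e-3)
})

test_that("count tables round-trip through TSV", {
  utrs <- gen_utrs(8, length_mean = 80, length_sd = 5, seed = 31)$utrs
  wct <- count_words(utrs, c("ACGUACG", "GGGGGGG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(wct, path)
  back <- read_count_table(path)
  expect_identical(back$counts[rownames(wct$counts), colnames(wct$counts)],
                   wct$counts)
  expect_identical(unname(back$totals[names(wct$totals)]),
                   unname(wct$totals))
})
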