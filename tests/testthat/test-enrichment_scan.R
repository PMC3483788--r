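test_that("hypergeometric tails match enumeration and handle edge cases", {
  # worked example: 10 items, 4 successes, draw 5, observe all 4
  expect_equal(hypergeom_tail(4, 4, 5, 10, "enrichment"), 6 / 252)
  ef <- enum_hyper(10, 5)
  expect_equal(hypergeom_tail(4, 4, 5, 10, "enrichment"), ef(4, 4, "enrichment"))

  expect_equal(hypergeom_tail(0, 3, 4, 10, "enrichment"), 1)
  expect_equal(hypergeom_tail(3, 3, 10, 10, "enrichment"), 1)  # full draw
  expect_error(hypergeom_tail(5, 4, 5, 10), "parameters")
  expect_error(hypergeom_tail(1, 11, 5, 10), "parameters")

  # spot grid against enumeration
  for (N in c(6, 9)) for (n in c(2, N %/% 2)) {
    ef <- enum_hyper(N, n)
    for (K in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_tail(k, K, n, N, "enrichment"),
                   ef(k, K, "enrichment"), tolerance = 1e-12)
      expect_equal(hypergeom_tail(k, K, n, N, "depletion"),
                   ef(k, K, "depletion"), tolerance = 1e-12)
    }
  }
})

test_that("landscape reproduces a hand-enumerated two-bin example", {
  # 4 UTRs of 10 nt (4 word positions each); word in UTR1 and UTR2 only
  w <- "GTGCCTT"
  utrs <- utr_set(c(g1 = paste0(w, "AAA"), g2 = paste0("AAA", w),
                    g3 = "ACACACACAC", g4 = "TGTGTGTGTG"))
  wct <- count_words(utrs, w)
  expect_identical(unname(wct$totals), rep(4L, 4))
  ls <- scan_landscape(c("g1", "g2", "g3", "g4"), wct,
                       scan_config(bin_step = 2, markov_order = 0))
  expect_identical(ls$bins, c(2L, 4L))
  # bin 2: k=2, n=8, K=2, N=16 -> P(X>=2) = C(14,6)/C(16,8)
  p_exp <- choose(14, 6) / choose(16, 8)
  expect_equal(unname(ls$signed[1, "GUGCCUU"]), -log10(p_exp),
               tolerance = 1e-10)
  expect_equal(unname(10^ls$log10p_enrich[1, 1]), p_exp, tolerance = 1e-10)
  # full-list bin: both tails are 1, signed value 0
  expect_equal(unname(ls$signed[2, "GUGCCUU"]), 0)
})

test_that("bins with zero countable positions record a signed value of 0", {
  utrs <- utr_set(c(g1 = "ACG", g2 = "ACGTACGTAC"))  # g1 too short
  wct <- count_words(utrs, "ACGTACG")
  ls <- scan_landscape(c("g1", "g2"), wct,
                       scan_config(bin_step = 1, markov_order = 0))
  expect_equal(unname(ls$signed[1, 1]), 0)
})

test_that("leading-bin statistics nest and missing genes are rejected", {
  sim <- gen_utrs(60, length_mean = 100, length_sd = 10, seed = 19)
  words <- c("ACGTACG", "GGCGCGC", "TTTACGT")
  wct <- count_words(sim$utrs, words)
  genes <- rownames(wct$counts)
  ls <- scan_landscape(sample(genes), wct,
                       scan_config(bin_step = 7, markov_order = 0))
  expect_identical(ls$bins[length(ls$bins)], 60L)  # final partial bin
  expect_true(all(diff(ls$n) >= 0))
  expect_error(scan_landscape(c(genes, "ghost"), wct,
                              scan_config(markov_order = 0)), "ghost")
})

test_that("reversed ranking swaps enrichment and depletion tails exactly", {
  sim <- gen_utrs(40, length_mean = 100, length_sd = 0, seed = 23)
  wct <- count_words(sim$utrs, c("ACGTACG", "CCCAAAT"))
  genes <- rownames(wct$counts)
  cfg <- scan_config(bin_step = 10, markov_order = 0)
  fwd <- scan_landscape(genes, wct, cfg)
  rev_ls <- scan_landscape(rev(genes), wct, cfg)
  # leading bin of b genes in reverse = complement of leading 40-b forward:
  # its enrichment tail equals the forward depletion tail at 40-b
  for (b in c(10, 20, 30)) {
    i_rev <- match(b, rev_ls$bins); i_fwd <- match(40 - b, fwd$bins)
    expect_equal(rev_ls$log10p_enrich[i_rev, ],
                 fwd$log10p_deplete[i_fwd, ], tolerance = 1e-10)
  }
})

test_that("Markov correction replaces the population count by its expectation", {
  sim <- gen_utrs(200, length_mean = 200, length_sd = 20, seed = 29)
  wct <- count_words(sim$utrs, c("ACGTACG", "GATCGAT"))
  bg <- fit_markov(sim$utrs, order = 4)
  genes <- rownames(wct$counts)
  cfg <- scan_config(bin_step = 50, markov_order = 4)
  ls <- scan_landscape(genes, wct, cfg, background = bg)
  pw <- vapply(c("ACGTACG", "GATCGAT"),
               function(w) markov_word_probability(bg, w), 0)
  expect_equal(unname(ls$K), unname(pmin(pmax(round(pw * ls$N), 1), ls$N)))
  expect_true(all(is.finite(ls$signed)))
  expect_error(scan_landscape(genes, wct, cfg), "background")
  bg2 <- fit_markov(sim$utrs, order = 2)
  expect_error(scan_landscape(genes, wct, cfg, background = bg2), "order")
})

test_that("peak words surface planted signal and annotate significance", {
  # plant a word into the top of the ranking
  word <- "GTGCCTT"
  gu <- gen_utrs(150, length_mean = 150, length_sd = 10, gc = 0.5,
                 plant = list(m1 = list(word = word,
                                        genes = sprintf("gene%04d", 1:20),
                                        sites = 3)),
                 seed = 37)
  wct <- count_words(gu$utrs, c(word, "AACCGGT", "TTGGCCA"))
  ls <- scan_landscape(rownames(wct$counts), wct,
                       scan_config(bin_step = 15, markov_order = 0))
  pk <- peak_words(ls, top = 3)
  expect_identical(pk$word[1], "GUGCCUU")
  expect_gt(pk$peak_signed[1], 0)
  expect_lte(pk$peak_bin[1], 30)
  expect_true(pk$above_bonferroni[1])
  expect_identical(nrow(peak_words(ls, top = 0)), 0L)

  lex <- build_lexicon(c(m1 = "UAAGGCACGCGGUGAAUGCC"))
  pk2 <- peak_words(ls, top = 1, lexicon = lex)
  expect_identical(pk2$mirna_ids[1], "m1")
})
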