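make_es <- function(x, cond, det = NULL) expression_set(x, cond, det)

test_that("detection filtering uses a strict threshold over contrasted samples", {
  x <- matrix(rnorm(12), 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  cond <- c("mimic", "mimic", "inhibitor", "inhibitor")

  es_all <- make_es(x, cond, matrix(0, 3, 4))
  expect_setequal(detection_filter(es_all), c("g1", "g2", "g3"))

  es_none <- make_es(x, cond, matrix(0.5, 3, 4))
  expect_warning(u <- detection_filter(es_none), "every gene")
  expect_length(u, 0L)

  det <- matrix(c(0.005, 0.02, 0.01), 3, 4)  # g3 sits exactly at 0.01
  es_mix <- make_es(x, cond, det)
  expect_identical(detection_filter(es_mix, alpha = 0.01), "g1")

  es_nodet <- make_es(x, cond)
  expect_error(detection_filter(es_nodet), "detection")
})

test_that("moderated t handles degenerate and null cases as specified", {
  # identical group means -> t = 0, two-sided p = 1
  x <- rbind(g1 = c(1, 2, 1.5, 1.5), g2 = c(0, 1, 2, -1))
  es <- make_es(x, c("A", "A", "B", "B"))
  de <- moderated_t(es, c("A", "B"), d0 = 0)
  expect_equal(de$t[de$gene_id == "g1"], 0)
  expect_equal(de$p_value[de$gene_id == "g1"], 1)

  # zero residual variance: error with d0 = 0, finite with shrinkage
  x2 <- rbind(g1 = c(1, 1, 2, 2), g2 = c(0, 1, 0, 1))
  es2 <- make_es(x2, c("A", "A", "B", "B"))
  expect_error(moderated_t(es2, c("A", "B"), d0 = 0), "zero residual variance")
  de2 <- moderated_t(es2, c("A", "B"), d0 = 2, s0_sq = 0.1)
  expect_true(all(is.finite(de2$t)))
  expect_lt(de2$t[de2$gene_id == "g1"], 0)  # A below B

  expect_error(moderated_t(make_es(x2[, 1:3], c("A", "A", "B")), c("A", "B")),
               "at least 2 samples")
})

test_that("d0 = 0 recovers the classical pooled two-sample t", {
  set.seed(5)
  x <- matrix(rnorm(50 * 7), 50, 7,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  cond <- c(rep("A", 3), rep("B", 4))
  de <- moderated_t(make_es(x, cond), c("A", "B"), d0 = 0)
  for (i in c(1, 17, 50)) {
    ref <- t.test(x[i, cond == "A"], x[i, cond == "B"], var.equal = TRUE)
    expect_equal(de$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t matches the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(2)
  x <- matrix(rnorm(300 * 8, 8, 1), 300, 8,
              dimnames = list(sprintf("g%03d", 1:300), NULL))
  x[1:30, 1:4] <- x[1:30, 1:4] + 1.2
  cond <- rep(c("A", "B"), each = 4)
  de <- moderated_t(make_es(x, cond), c("A", "B"))
  design <- stats::model.matrix(~ 0 + factor(cond))
  colnames(design) <- c("A", "B")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(x, design),
    limma::makeContrasts(A - B, levels = design)))
  expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(de$p_value, unname(fit$p.value[, 1]), tolerance = 1e-9)
  expect_equal(attr(de, "prior")$d0, unname(fit$df.prior), tolerance = 1e-6)
})

test_that("type-I error under a pure null is close to nominal", {
  set.seed(9)
  x <- matrix(rnorm(500 * 8), 500, 8,
              dimnames = list(sprintf("g%03d", 1:500), NULL))
  de <- moderated_t(make_es(x, rep(c("A", "B"), each = 4)), c("A", "B"))
  fpr <- mean(de$p_value < 0.05)
  half <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_gt(fpr, 0.05 - half)
  expect_lt(fpr, 0.05 + half)
})

test_that("BH step-up adjustment is exact on worked and random cases", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_identical(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # adjusted >= raw, monotone in p rank
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("best probe per gene keeps the most significant, ties by probe id", {
  d <- data.frame(probe_id = c("p2", "p1", "p3", "p9", "p8"),
                  gene_id = c("g1", "g1", "g2", "g3", "g3"),
                  adjusted_p = c(0.2, 0.01, 0.5, 0.1, 0.1),
                  statistic = 1:5)
  out <- best_probe_per_gene(d)
  expect_identical(out$probe_id[out$gene_id == "g1"], "p1")
  expect_identical(out$probe_id[out$gene_id == "g2"], "p3")
  expect_identical(out$probe_id[out$gene_id == "g3"], "p8")
  expect_identical(nrow(out), 3L)
  expect_error(best_probe_per_gene(transform(d, gene_id = c("g1", "", "g2", "g3", "g3"))),
               "gene id")
})

test_that("gene ranking is ascending in t with deterministic ties", {
  de <- data.frame(gene_id = c("gb", "ga", "gc"), t = c(-2, 0, 3))
  expect_identical(rank_genes(de)$gene_id, c("gb", "ga", "gc"))
  tie <- data.frame(gene_id = c("zz", "aa"), t = c(0, 0))
  expect_identical(rank_genes(tie)$gene_id, c("aa", "zz"))
  expect_identical(rank_genes(tie[2:1, ]), rank_genes(tie))
  expect_error(rank_genes(data.frame(gene_id = "g", t = NaN)), "g")
})
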