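# Signed hypergeometric word-enrichment landscapes over leading bins of
# a ranked 3'UTR list.
#
# The ranked list is scanned with leading bins growing by `bin_step`
# sequences at a time (the final bin always covers the whole list). For
# each lexicon word w and bin b the hypergeometric draw is over word
# POSITIONS: k = occurrences of w in the bin, n = countable positions in
# the bin, K = occurrences in the whole list, N = countable positions in
# the whole list. With Markov correction the empirical K is replaced by
# the background-expected count K* = round(p_markov(w) * N). Both tails
# are evaluated; the signed landscape value is +|log10 P| when the
# enrichment tail is the more extreme one and -|log10 P| for depletion
# (ties report +).

#' Hypergeometric tail probability
#'
#' Enrichment tail `P(X >= k)` or depletion tail `P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)` (N items, K successes, n drawn),
#' computed in log space for stability.
#'
#' @param k Observed successes in the draw (vectorized).
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @param tail `"enrichment"` or `"depletion"`.
#' @param log10p Return log10 of the tail probability instead.
#' @return Probability (or its log10).
#' @export
hypergeom_tail <- function(k, K, n, N, tail = c("enrichment", "depletion"),
                           log10p = FALSE) {
  tail <- match.arg(tail)
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0
  if (any(bad))
    stop("hypergeometric parameters violate 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  lp <- if (tail == "enrichment")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Scan configuration
#'
#' @param word_length Word size (default 7).
#' @param bin_step Ranked-list increment per bin (default 100).
#' @param markov_order Background correction order (default 4; 0
#'   disables correction).
#' @param tail Which tails to report (both are always computed).
#' @return A `scan_config` list.
#' @export
scan_config <- function(word_length = 7L, bin_step = 100L, markov_order = 4L,
                        tail = c("both", "enrichment", "depletion")) {
  tail <- match.arg(tail)
  stopifnot(bin_step >= 1L, markov_order >= 0L, word_length > markov_order)
  structure(list(word_length = as.integer(word_length),
                 bin_step = as.integer(bin_step),
                 markov_order = as.integer(markov_order), tail = tail),
            class = "scan_config")
}

#' Word-enrichment landscape over leading bins of a ranked list
#'
#' @param ranked A `ranked_gene_list` (or character vector of gene ids,
#'   most downregulated first).
#' @param counts A `word_count_table` covering every ranked gene; genes
#'   lacking a 3'UTR must be excluded from `ranked` beforehand.
#' @param config A [scan_config()].
#' @param background A `markov_model` (required when
#'   `config$markov_order > 0`).
#' @return Object of class `enrichment_landscape`: list with `bins`
#'   (bin sizes in sequences), `signed` (bins x words matrix of signed
#'   log10 P), `log10p_enrich` / `log10p_deplete` matrices, `K`
#'   (population word counts used), `N`, and `summary` (per-word peak).
#' @export
scan_landscape <- function(ranked, counts, config = scan_config(),
                           background = NULL) {
  genes <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  stopifnot(inherits(counts, "word_count_table"))
  missing_genes <- setdiff(genes, rownames(counts$counts))
  if (length(missing_genes))
    stop(sprintf("ranked gene(s) absent from the count table: %s",
                 paste(utils::head(missing_genes, 5L), collapse = ", ")),
         call. = FALSE)
  C <- counts$counts[genes, , drop = FALSE]
  tot <- counts$totals[genes]
  ngenes <- length(genes)
  step <- config$bin_step
  bins <- unique(c(seq(step, ngenes, by = step), ngenes))
  bins <- bins[bins >= 1L]

  cumC <- apply(C, 2L, cumsum)
  if (ngenes == 1L) cumC <- matrix(cumC, nrow = 1L, dimnames = dimnames(C))
  kmat <- cumC[bins, , drop = FALSE]
  nvec <- cumsum(as.numeric(tot))[bins]
  K_emp <- cumC[ngenes, ]
  N <- sum(as.numeric(tot))

  if (config$markov_order > 0L) {
    if (is.null(background))
      stop("a markov_model background is required when markov_order > 0",
           call. = FALSE)
    if (background$order != config$markov_order)
      stop("background model order does not match the scan configuration",
           call. = FALSE)
    pw <- vapply(colnames(C), function(w) markov_word_probability(background, w),
                 numeric(1))
    K <- pmin(pmax(round(pw * N), 1), N)
  } else K <- K_emp

  nb <- length(bins); nw <- ncol(C)
  Km <- matrix(K, nb, nw, byrow = TRUE)
  nm <- matrix(nvec, nb, nw)
  # clamp observed counts into the support of Hypergeom(N, K, n) so the
  # tails stay finite when the Markov-expected K* falls below the
  # observed count (the P-value then saturates at the extreme point)
  lo <- pmax(0, nm + Km - N)
  hi <- pmin(Km, nm)
  kc <- pmin(pmax(kmat, lo), hi)

  lp_enr <- stats::phyper(kc - 1, Km, N - Km, nm, lower.tail = FALSE,
                          log.p = TRUE) / log(10)
  lp_dep <- stats::phyper(kc, Km, N - Km, nm, lower.tail = TRUE,
                          log.p = TRUE) / log(10)
  signed <- ifelse(lp_enr <= lp_dep, -lp_enr, lp_dep)
  signed[nm == 0] <- 0
  lp_enr[nm == 0] <- 0; lp_dep[nm == 0] <- 0
  dimnames(signed) <- dimnames(lp_enr) <- dimnames(lp_dep) <-
    list(NULL, colnames(C))

  peak_idx <- apply(abs(signed), 2L, which.max)
  summary <- data.frame(word = colnames(C),
                        peak_signed = signed[cbind(peak_idx, seq_len(nw))],
                        peak_bin = bins[peak_idx],
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(bins = bins, signed = signed, log10p_enrich = lp_enr,
                 log10p_deplete = lp_dep, K = K, N = N, n = nvec,
                 config = config, summary = summary),
            class = "enrichment_landscape")
}

#' @export
print.enrichment_landscape <- function(x, ...) {
  top <- x$summary[which.max(abs(x$summary$peak_signed)), ]
  cat(sprintf("enrichment_landscape: %d words x %d bins; extreme word %s (signed log10 P = %.2f at bin %d)\n",
              nrow(x$summary), length(x$bins), top$word, top$peak_signed,
              top$peak_bin))
  invisible(x)
}

#' Most extreme landscape words
#'
#' Words ranked by the absolute value of their most extreme signed
#' log10 P across bins, optionally annotated with source miRNAs and a
#' Bonferroni significance line over words x bins.
#'
#' @param landscape An `enrichment_landscape`.
#' @param top Number of words to return.
#' @param lexicon Optional `seed_lexicon` for miRNA annotation.
#' @param alpha Significance level for the Bonferroni line (default
#'   0.05).
#' @return data.frame `word`, `peak_signed`, `peak_bin`, `mirna_ids`
#'   (if a lexicon is given), `above_bonferroni`; attribute
#'   `bonferroni_line` carries the -log10 threshold.
#' @export
peak_words <- function(landscape, top = 10L, lexicon = NULL, alpha = 0.05) {
  stopifnot(inherits(landscape, "enrichment_landscape"))
  s <- landscape$summary
  s <- s[order(-abs(s$peak_signed), s$word), , drop = FALSE]
  line <- -log10(alpha / (nrow(landscape$summary) * length(landscape$bins)))
  s$above_bonferroni <- abs(s$peak_signed) > line
  if (!is.null(lexicon)) {
    idx <- match(s$word, lexicon$words$word)
    s$mirna_ids <- lexicon$words$mirna_ids[idx]
  }
  out <- utils::head(s, max(top, 0L))
  rownames(out) <- NULL
  attr(out, "bonferroni_line") <- line
  out
}

#' Plot an enrichment landscape
#'
#' Signed log10 P against ranked-list position, one line per word; the
#' `highlight` most extreme words are drawn in color over a gray
#' background of the remaining words.
#'
#' @param x An `enrichment_landscape`.
#' @param highlight Number of extreme words to color (default 3).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.enrichment_landscape <- function(x, highlight = 3L, ...) {
  pk <- peak_words(x, top = highlight)
  hi <- colnames(x$signed) %in% pk$word
  graphics::matplot(x$bins, x$signed[, !hi, drop = FALSE], type = "l",
                    lty = 1, col = "gray70",
                    xlab = "ranked 3'UTRs (leading bin size)",
                    ylab = expression(signed ~ log[10] ~ P),
                    ylim = range(x$signed), ...)
  if (any(hi))
    graphics::matlines(x$bins, x$signed[, hi, drop = FALSE], lty = 1, lwd = 2,
                       col = seq_len(sum(hi)) + 1L)
  graphics::abline(h = 0, col = "black")
  if (any(hi))
    graphics::legend("topright", legend = colnames(x$signed)[hi],
                     col = seq_len(sum(hi)) + 1L, lwd = 2, bty = "n")
  invisible(x)
}

#' Write a landscape as long-format TSV
#'
#' Columns: word, bin_size, signed_log10_p.
#' @param landscape An `enrichment_landscape`.
#' @param path File path.
#' @export
write_landscape <- function(landscape, path) {
  d <- data.frame(word = rep(colnames(landscape$signed),
                             each = length(landscape$bins)),
                  bin_size = rep(landscape$bins, ncol(landscape$signed)),
                  signed_log10_p = as.vector(landscape$signed),
                  stringsAsFactors = FALSE)
  write_tsv(d, path)
}
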