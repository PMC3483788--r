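# 3'UTR sequence store: masking, overlapping word counting, Markov
# background models.
#
# Coordinates are 0-based half-open throughout. Masked bases (and
# ambiguous N) never contribute to word counts, countable positions, or
# k-mer background tallies: a 7-mer window is countable iff it contains
# no masked/ambiguous base.

#' Construct a 3'UTR set
#'
#' @param sequences Named character vector of sequences (names are gene
#'   ids); RNA letters are converted to DNA, case is normalized. `N` is
#'   allowed and treated as masked.
#' @param transcript_ids Optional character vector parallel to
#'   `sequences`.
#' @param masks Optional named list of two-column matrices (start, end),
#'   0-based half-open, flagging masked intervals per gene.
#' @return An object of class `utr_set` with elements `seq`,
#'   `transcript_id`, `mask`.
#' @export
utr_set <- function(sequences, transcript_ids = NULL, masks = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("UTR sequences must be named by gene id", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("duplicate gene ids in UTR set", call. = FALSE)
  seqs <- as_dna(sequences)
  check_alphabet(seqs, c(DNA_LETTERS, "N"), what = "UTR")
  mask <- setNames(vector("list", length(seqs)), names(seqs))
  for (g in names(seqs)) mask[[g]] <- empty_intervals()
  if (!is.null(masks)) {
    for (g in names(masks)) {
      if (!g %in% names(seqs)) stop(sprintf("mask for unknown gene '%s'", g), call. = FALSE)
      mask[[g]] <- normalize_intervals(masks[[g]], nchar(seqs[[g]]))
    }
  }
  structure(list(seq = seqs, transcript_id = transcript_ids, mask = mask),
            class = "utr_set")
}

#' @export
print.utr_set <- function(x, ...) {
  nm <- sum(vapply(x$mask, nrow, integer(1)) > 0L)
  cat(sprintf("utr_set: %d sequences (total %d nt; %d with mask intervals)\n",
              length(x$seq), sum(nchar(x$seq)), nm))
  invisible(x)
}

#' @export
length.utr_set <- function(x) length(x$seq)

empty_intervals <- function() matrix(integer(0), ncol = 2,
                                     dimnames = list(NULL, c("start", "end")))

# Clip to [0, len), drop empties, merge overlapping/adjacent intervals.
normalize_intervals <- function(iv, len) {
  iv <- matrix(as.integer(iv), ncol = 2)
  iv[, 1] <- pmax(iv[, 1], 0L); iv[, 2] <- pmin(iv[, 2], len)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) <= 1L) { colnames(iv) <- c("start", "end"); return(iv) }
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- list(iv[1L, ])
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- out[[length(out)]]
    if (iv[i, 1] <= last[2]) {
      out[[length(out)]][2] <- max(last[2], iv[i, 2])
    } else out[[length(out) + 1L]] <- iv[i, ]
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Sequence text with masked intervals (and native N) written as N.
masked_sequences <- function(utrs) {
  stopifnot(inherits(utrs, "utr_set"))
  out <- utrs$seq
  for (g in names(out)) {
    iv <- utrs$mask[[g]]
    for (i in seq_len(nrow(iv)))
      substr(out[[g]], iv[i, 1] + 1L, iv[i, 2]) <-
        strrep("N", iv[i, 2] - iv[i, 1])
  }
  out
}

# DUST-style triplet score of one window: 10 * sum c(c-1)/2 / (k-1),
# computed over non-ambiguous triplets.
dust_score <- function(trip) {
  trip <- trip[!is.na(trip)]
  k <- length(trip)
  if (k < 2L) return(0)
  cnt <- tabulate(trip + 1L, nbins = 64L)
  10 * sum(cnt * (cnt - 1) / 2) / (k - 1)
}

dust_intervals <- function(seq, threshold, window) {
  n <- nchar(seq)
  if (n < 5L) return(empty_intervals())
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_LETTERS) - 1L
  ntrip <- n - 2L
  trip <- code[1:ntrip] * 16L + code[2:(ntrip + 1L)] * 4L + code[3:(ntrip + 2L)]
  w <- min(window, n)
  starts <- unique(c(seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L)),
                     n - w + 1L))
  hits <- lapply(starts, function(j) {
    tt <- trip[j:min(j + w - 3L, ntrip)]
    if (dust_score(tt) > threshold) c(j - 1L, j + w - 1L) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) empty_intervals() else normalize_intervals(hits, n)
}

#' Mask low-complexity sequence (DUST-style)
#'
#' Slides windows over each sequence, scores triplet composition with a
#' DUST-like statistic, and adds any window scoring above `threshold` to
#' the gene's mask. The sequence text itself is unchanged; the operation
#' is idempotent.
#'
#' @param utrs A `utr_set`.
#' @param threshold Score threshold (default 20, the conventional DUST
#'   level).
#' @param window Window size in nt (default 64); must be >= 4.
#' @return The `utr_set` with extended masks.
#' @export
mask_low_complexity <- function(utrs, threshold = 20, window = 64L) {
  stopifnot(inherits(utrs, "utr_set"))
  if (window < 4L) stop("window must be at least 4", call. = FALSE)
  for (g in names(utrs$seq)) {
    iv <- dust_intervals(utrs$seq[[g]], threshold, window)
    utrs$mask[[g]] <- normalize_intervals(rbind(utrs$mask[[g]], iv),
                                          nchar(utrs$seq[[g]]))
  }
  utrs
}

#' Mask k-mers shared across many UTRs (redundancy purge)
#'
#' Any exact `k`-mer occurring in more than `max_utrs` distinct UTRs is
#' considered repetitive/redundant and all its occurrences are masked.
#'
#' @param utrs A `utr_set`.
#' @param k Word size of the shared fragment (default 30).
#' @param max_utrs Maximum number of distinct UTRs a `k`-mer may occur in
#'   before it is purged (default 5).
#' @return The `utr_set` with extended masks.
#' @export
mask_redundant <- function(utrs, k = 30L, max_utrs = 5L) {
  stopifnot(inherits(utrs, "utr_set"))
  per_gene <- lapply(utrs$seq, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  tab <- table(unlist(per_gene, use.names = FALSE))
  bad <- names(tab)[tab > max_utrs]
  bad <- bad[!grepl("N", bad, fixed = TRUE)]
  if (length(bad) == 0L) return(utrs)
  for (g in names(utrs$seq)) {
    s <- utrs$seq[[g]]
    iv <- list()
    for (b in bad) {
      m <- gregexpr(b, s, fixed = TRUE)[[1L]]
      if (m[1L] != -1L)
        iv[[length(iv) + 1L]] <- cbind(m - 1L, m - 1L + k)
    }
    if (length(iv))
      utrs$mask[[g]] <- normalize_intervals(rbind(utrs$mask[[g]], do.call(rbind, iv)),
                                            nchar(s))
  }
  utrs
}

#' Count overlapping word occurrences in a UTR set
#'
#' Counts, for each gene, the overlapping occurrences of every lexicon
#' word among countable positions (windows free of masked/ambiguous
#' bases), together with the gene's total number of countable word
#' positions.
#'
#' @param utrs A `utr_set`.
#' @param words A `seed_lexicon` or a character vector of words (RNA or
#'   DNA); all must share `word_length`.
#' @param word_length Word size (default 7).
#' @return An object of class `word_count_table`: list with `counts`
#'   (genes x words integer matrix, RNA column names), `totals`
#'   (countable positions per gene), `word_length`, and aggregate
#'   `word_totals` / `grand_total`.
#' @export
count_words <- function(utrs, words, word_length = 7L) {
  stopifnot(inherits(utrs, "utr_set"))
  if (inherits(words, "seed_lexicon")) words <- words$words$word
  words_rna <- unique(as_rna(words))
  words_dna <- as_dna(words_rna)
  if (any(nchar(words_dna) != word_length))
    stop(sprintf("all words must have length %d", word_length), call. = FALSE)
  mseq <- masked_sequences(utrs)
  genes <- names(mseq)
  counts <- matrix(0L, nrow = length(genes), ncol = length(words_dna),
                   dimnames = list(genes, words_rna))
  ok <- nchar(mseq) >= word_length
  if (any(ok)) {
    pd <- Biostrings::PDict(words_dna)
    m <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(mseq[ok]))
    counts[ok, ] <- t(m)
  }
  totals <- vapply(mseq, function(s) {
    n <- nchar(s)
    if (n < word_length) return(0L)
    isn <- cumsum(strsplit(s, "", fixed = TRUE)[[1L]] == "N")
    nwin <- n - word_length + 1L
    in_window <- isn[word_length:n] - c(0L, isn)[1:nwin]
    sum(in_window == 0L)
  }, integer(1))
  structure(list(counts = counts, totals = totals,
                 word_length = as.integer(word_length),
                 word_totals = colSums(counts), grand_total = sum(totals)),
            class = "word_count_table")
}

#' @export
print.word_count_table <- function(x, ...) {
  cat(sprintf("word_count_table: %d genes x %d words; %d total word positions\n",
              nrow(x$counts), ncol(x$counts), x$grand_total))
  invisible(x)
}

#' Write / read a word-count table as long-format TSV
#'
#' Long format (gene_id, word, count) for non-zero counts plus a
#' per-gene total_positions column carried on a `__total__` marker row
#' set; the reader reconstructs the matrix.
#' @param wct A `word_count_table`.
#' @param path File path.
#' @export
write_count_table <- function(wct, path) {
  stopifnot(inherits(wct, "word_count_table"))
  idx <- which(wct$counts > 0L, arr.ind = TRUE)
  d <- data.frame(gene_id = rownames(wct$counts)[idx[, 1]],
                  word = colnames(wct$counts)[idx[, 2]],
                  count = wct$counts[idx], stringsAsFactors = FALSE)
  tot <- data.frame(gene_id = names(wct$totals), word = ".total_positions",
                    count = unname(wct$totals), stringsAsFactors = FALSE)
  # words with zero occurrences everywhere must survive the round trip
  allw <- data.frame(gene_id = ".words", word = colnames(wct$counts),
                     count = 0L, stringsAsFactors = FALSE)
  write_tsv(rbind(d, tot, allw), path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  d <- read_tsv(path)
  words <- unique(d$word[d$gene_id == ".words"])
  tot <- d[d$word == ".total_positions", ]
  genes <- tot$gene_id
  counts <- matrix(0L, length(genes), length(words),
                   dimnames = list(genes, words))
  body <- d[d$gene_id != ".words" & d$word != ".total_positions", ]
  if (nrow(body)) counts[cbind(body$gene_id, body$word)] <- as.integer(body$count)
  totals <- setNames(as.integer(tot$count), genes)
  structure(list(counts = counts, totals = totals,
                 word_length = nchar(words[1L]),
                 word_totals = colSums(counts), grand_total = sum(totals)),
            class = "word_count_table")
}

#' Fit a Markov background model on unmasked sequence
#'
#' Exhaustively counts the `order`-mers and `(order+1)`-mers of the
#' unmasked sequence universe; windows containing masked or ambiguous
#' bases are skipped.
#'
#' @param utrs A `utr_set`.
#' @param order Markov order `m >= 0`.
#' @return Object of class `markov_model`: list with `order`, `counts_m`
#'   (named counts of m-mers; `NULL` for order 0), `counts_m1`
#'   ((m+1)-mer counts), `total_m` (total m-mer positions; unmasked
#'   length for order 0).
#' @export
fit_markov <- function(utrs, order = 4L) {
  stopifnot(inherits(utrs, "utr_set"))
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0", call. = FALSE)
  ss <- Biostrings::DNAStringSet(masked_sequences(utrs))
  base_counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = 1L))
  unmasked_len <- sum(base_counts)
  if (unmasked_len <= order)
    stop("insufficient unmasked sequence to fit the Markov model", call. = FALSE)
  counts_m <- if (order == 0L) NULL else
    colSums(Biostrings::oligonucleotideFrequency(ss, width = order))
  counts_m1 <- colSums(Biostrings::oligonucleotideFrequency(ss, width = order + 1L))
  structure(list(order = order, counts_m = counts_m, counts_m1 = counts_m1,
                 total_m = if (order == 0L) unmasked_len else sum(counts_m)),
            class = "markov_model")
}

#' Markov background probability of a word
#'
#' Chain estimate of the per-position occurrence probability of `word`
#' under the fitted model: the product of (m+1)-mer counts along the
#' word divided by the product of the interior overlap m-mer counts,
#' normalized by the total m-mer count. For order 0 this reduces to the
#' product of base frequencies.
#'
#' @param model A `markov_model`.
#' @param word Word (RNA or DNA), length > model order.
#' @return Probability in (0, 1].
#' @export
markov_word_probability <- function(model, word) {
  stopifnot(inherits(model, "markov_model"))
  w <- as_dna(word)
  L <- nchar(w); m <- model$order
  if (L <= m) stop("word must be longer than the model order", call. = FALSE)
  num_words <- substring(w, 1:(L - m), (1:(L - m)) + m)
  cnt <- model$counts_m1[num_words]
  if (anyNA(cnt) || any(cnt == 0))
    stop(sprintf("degenerate background: sub-word '%s' has zero count",
                 num_words[which(is.na(cnt) | cnt == 0)[1L]]), call. = FALSE)
  lognum <- sum(log(cnt))
  if (m == 0L) {
    logden <- (L - 1) * log(model$total_m)
  } else if (L - m - 1L >= 1L) {
    den_words <- substring(w, 2:(L - m), (2:(L - m)) + m - 1L)
    dcnt <- model$counts_m[den_words]
    if (anyNA(dcnt) || any(dcnt == 0))
      stop(sprintf("degenerate background: sub-word '%s' has zero count",
                   den_words[which(is.na(dcnt) | dcnt == 0)[1L]]), call. = FALSE)
    logden <- sum(log(dcnt))
  } else logden <- 0
  min(exp(lognum - logden - log(model$total_m)), 1)
}
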