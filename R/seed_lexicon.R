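# Seed-matching-site lexicon construction.
#
# For every mature miRNA two 7-nt 3'UTR words are derived:
#   * the 7(2)-type site (7mer-m8): reverse complement of miRNA bases 2-8;
#   * the 7(1A)-type site (7mer-A1): reverse complement of bases 2-7
#     followed by an A (the A sits opposite miRNA position 1).
# The lexicon is the deduplicated union of these words over all miRNAs,
# minus an exclusion list of polyadenylation-signal-like words whose
# positional biases in 3'UTRs cannot be attributed to miRNA action.

#' Default exclusion words (polyadenylation-signal-like 7-mers)
#'
#' Seed-matching words resembling the AAUAAA poly(A) signal; their 3'UTR
#' distribution is driven by polyadenylation, not miRNA targeting.
#' @export
DEFAULT_EXCLUSION_WORDS <- c("CAAUAAA", "UAUUUAU", "UCAAUAA")

normalize_mirna_seq <- function(seq, id = "<mirna>") {
  seq <- as_rna(seq)
  names(seq) <- names(seq)
  check_alphabet(setNames(seq, id), RNA_LETTERS, what = "miRNA")
  seq
}

#' Derive the two seed-matching-site words of a mature miRNA
#'
#' @param sequence Mature miRNA sequence, 5'->3', RNA or DNA letters,
#'   length >= 8.
#' @param id Optional miRNA id used in error messages.
#' @return Named character vector `c(SEVEN_2 = ..., SEVEN_1A = ...)` of
#'   7-letter RNA words.
#' @examples
#' derive_seed_sites("UAAGGCACGCGGUGAAUGCC")
#' @export
derive_seed_sites <- function(sequence, id = NULL) {
  lab <- if (is.null(id)) "miRNA" else sprintf("miRNA '%s'", id)
  seq <- normalize_mirna_seq(sequence, id = if (is.null(id)) "<mirna>" else id)
  if (nchar(seq) < 8L)
    stop(sprintf("%s sequence has length %d; at least 8 bases are required",
                 lab, nchar(seq)), call. = FALSE)
  seven2  <- reverse_complement(substr(seq, 2L, 8L), "RNA")
  seven1a <- paste0(reverse_complement(substr(seq, 2L, 7L), "RNA"), "A")
  c(SEVEN_2 = seven2, SEVEN_1A = seven1a)
}

#' Build a seed-matching-site lexicon from mature miRNAs
#'
#' Identical words arising from different miRNAs (or from both site types)
#' are merged, recording the union of source miRNA ids and site types.
#' Words on the exclusion list are removed from the active lexicon and
#' reported separately, so both the pre- and post-exclusion counts are
#' available.
#'
#' @param mirnas Named character vector of mature miRNA sequences
#'   (names are miRNA ids), or a data.frame with columns `id` and
#'   `sequence`.
#' @param exclusion_words Character vector of 7-mer RNA words to exclude;
#'   defaults to [DEFAULT_EXCLUSION_WORDS]. Use `character()` to disable.
#' @return An object of class `seed_lexicon`: a list with `words` and
#'   `excluded` data.frames (columns `word`, `site_types`, `mirna_ids`),
#'   `n_distinct` (before exclusion) and `n_words` (after exclusion).
#' @export
build_lexicon <- function(mirnas, exclusion_words = DEFAULT_EXCLUSION_WORDS) {
  if (is.data.frame(mirnas)) {
    stopifnot(all(c("id", "sequence") %in% names(mirnas)))
    mirnas <- setNames(as.character(mirnas$sequence), as.character(mirnas$id))
  }
  if (length(mirnas) == 0L) stop("no miRNA sequences supplied", call. = FALSE)
  if (is.null(names(mirnas)) || any(!nzchar(names(mirnas))))
    stop("miRNA sequences must be named by their ids", call. = FALSE)
  seqs <- vapply(seq_along(mirnas),
                 function(i) normalize_mirna_seq(mirnas[[i]], names(mirnas)[i]),
                 character(1))
  names(seqs) <- names(mirnas)
  # identical (id, sequence) records are silently deduplicated;
  # one id with two different sequences is a data error
  keep <- !duplicated(paste(names(seqs), seqs, sep = "\r"))
  seqs <- seqs[keep]
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop(sprintf("miRNA id(s) with conflicting sequences: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)

  rows <- lapply(names(seqs), function(id) {
    s <- derive_seed_sites(seqs[[id]], id = id)
    data.frame(word = unname(s), site_type = names(s), mirna_id = id,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  agg <- lapply(split(tab, tab$word), function(d) {
    data.frame(word = d$word[1L],
               site_types = paste(sort(unique(d$site_type)), collapse = ","),
               mirna_ids = paste(sort(unique(d$mirna_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  words <- do.call(rbind, agg)
  words <- words[order(words$word), , drop = FALSE]
  rownames(words) <- NULL

  exclusion_words <- as_rna(exclusion_words)
  excl_mask <- words$word %in% exclusion_words
  out <- structure(list(
    words = words[!excl_mask, , drop = FALSE],
    excluded = words[excl_mask, , drop = FALSE],
    exclusion_words = exclusion_words,
    n_distinct = nrow(words),
    n_words = sum(!excl_mask)
  ), class = "seed_lexicon")
  rownames(out$words) <- rownames(out$excluded) <- NULL
  out
}

#' @export
print.seed_lexicon <- function(x, ...) {
  cat(sprintf("seed_lexicon: %d distinct seed-matching words (%d after exclusion of %d)\n",
              x$n_distinct, x$n_words, nrow(x$excluded)))
  invisible(x)
}

#' Extract lexicon words
#'
#' @param lexicon A `seed_lexicon`.
#' @param mirna_id Optional miRNA id; restrict to that miRNA's words.
#' @param site_type Optional `"SEVEN_2"` or `"SEVEN_1A"` filter.
#' @return Character vector of RNA words (active lexicon only).
#' @export
lexicon_words <- function(lexicon, mirna_id = NULL, site_type = NULL) {
  stopifnot(inherits(lexicon, "seed_lexicon"))
  w <- lexicon$words
  if (!is.null(mirna_id)) {
    hit <- vapply(strsplit(w$mirna_ids, ",", fixed = TRUE),
                  function(v) mirna_id %in% v, logical(1))
    if (!any(hit) && !mirna_id %in% unlist(strsplit(lexicon$excluded$mirna_ids, ",")))
      stop(sprintf("miRNA '%s' not present in the lexicon", mirna_id), call. = FALSE)
    w <- w[hit, , drop = FALSE]
  }
  if (!is.null(site_type)) {
    hit <- vapply(strsplit(w$site_types, ",", fixed = TRUE),
                  function(v) site_type %in% v, logical(1))
    w <- w[hit, , drop = FALSE]
  }
  w$word
}

#' Write / read a lexicon as TSV
#'
#' Columns: word, site_types, mirna_ids, excluded_flag.
#' @param lexicon A `seed_lexicon`.
#' @param path File path.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "seed_lexicon"))
  a <- lexicon$words;    a$excluded_flag <- rep(FALSE, nrow(a))
  b <- lexicon$excluded; b$excluded_flag <- rep(TRUE, nrow(b))
  write_tsv(rbind(a, b), path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  d <- read_tsv(path)
  out <- structure(list(
    words = d[!d$excluded_flag, c("word", "site_types", "mirna_ids")],
    excluded = d[d$excluded_flag, c("word", "site_types", "mirna_ids")],
    exclusion_words = d$word[d$excluded_flag],
    n_distinct = nrow(d),
    n_words = sum(!d$excluded_flag)
  ), class = "seed_lexicon")
  rownames(out$words) <- rownames(out$excluded) <- NULL
  out
}
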