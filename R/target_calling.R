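# Experimentally-derived miRNA target calling from a mimic-vs-inhibitor
# (or mimic-vs-mock) contrast: a putative direct target is a gene that is
# downregulated (adjusted P below threshold, negative log-fold-change)
# and whose 3'UTR carries at least one seed-matching site of the miRNA.

#' Call putative direct targets of a miRNA
#'
#' @param de A `de_result` for the mimic-vs-inhibitor (or mimic-vs-mock)
#'   contrast of the miRNA.
#' @param counts A `word_count_table`; genes absent from it (no 3'UTR)
#'   are excluded.
#' @param lexicon A `seed_lexicon` containing the miRNA's words.
#' @param mirna_id miRNA whose targets are called.
#' @param alpha Adjusted-P threshold (default 0.05).
#' @return Object of class `target_call_set`: list with `mirna_id`,
#'   `alpha`, `targets` (gene ids) and `table` (data.frame `gene_id`,
#'   `adjusted_p`, `logFC`, `n_sites_7_2`, `n_sites_7_1A`).
#' @export
call_targets <- function(de, counts, lexicon, mirna_id, alpha = 0.05) {
  stopifnot(inherits(counts, "word_count_table"),
            inherits(lexicon, "seed_lexicon"))
  words <- lexicon_words(lexicon, mirna_id = mirna_id)
  if (length(words) == 0L)
    stop(sprintf("miRNA '%s' has no active words in the lexicon", mirna_id),
         call. = FALSE)
  w72  <- intersect(lexicon_words(lexicon, mirna_id, site_type = "SEVEN_2"),
                    colnames(counts$counts))
  w71a <- intersect(lexicon_words(lexicon, mirna_id, site_type = "SEVEN_1A"),
                    colnames(counts$counts))
  if (length(c(w72, w71a)) == 0L)
    stop(sprintf("none of miRNA '%s' words are present in the count table",
                 mirna_id), call. = FALSE)
  keep <- de$gene_id %in% rownames(counts$counts)
  d <- de[keep, , drop = FALSE]
  n72 <- rowSums(counts$counts[d$gene_id, w72, drop = FALSE])
  n71 <- rowSums(counts$counts[d$gene_id, w71a, drop = FALSE])
  hit <- d$adjusted_p < alpha & d$logFC < 0 & (n72 + n71) >= 1
  tab <- data.frame(gene_id = d$gene_id[hit], adjusted_p = d$adjusted_p[hit],
                    logFC = d$logFC[hit], n_sites_7_2 = unname(n72[hit]),
                    n_sites_7_1A = unname(n71[hit]),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$adjusted_p, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(mirna_id = mirna_id, alpha = alpha,
                 targets = tab$gene_id, table = tab),
            class = "target_call_set")
}

#' @export
print.target_call_set <- function(x, ...) {
  cat(sprintf("target_call_set: %d putative direct targets of %s (adjusted P < %g)\n",
              length(x$targets), x$mirna_id, x$alpha))
  invisible(x)
}

#' Write a target call set as TSV
#'
#' @param tcs A `target_call_set`.
#' @param path File path.
#' @export
write_targets <- function(tcs, path) {
  stopifnot(inherits(tcs, "target_call_set"))
  write_tsv(tcs$table, path)
}
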