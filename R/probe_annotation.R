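# Probe-to-transcript resolution: exact longest-common-substring scoring
# (both strands) with a 30-nt perfect-match floor, and a deterministic
# tie-break cascade (source > biotype > 3'UTR length > cDNA length >
# transcript id).

BIOTYPE_RANK <- c(PROTEIN_CODING = 1L, PSEUDOGENE = 2L, OTHER = 3L, NMD = 4L)
SOURCE_RANK <- c(VEGA = 1L, ENSEMBL_CORE = 2L, OTHER = 3L)

# Length of the longest exact common substring of `probe` within
# `subject`, by binary search over run length (a (k+1)-match implies a
# k-match).
longest_match_run <- function(probe, subject) {
  np <- nchar(probe)
  has_run <- function(k) {
    kmers <- unique(substring(probe, 1:(np - k + 1L), k:np))
    any(vapply(kmers, function(w) grepl(w, subject, fixed = TRUE), logical(1)))
  }
  lo <- 0L; hi <- np
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_run(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Align a probe against transcripts by exact substring match
#'
#' Scores each transcript by the longest run of consecutive perfect
#' matches shared with the probe, on either strand, and keeps candidates
#' reaching `min_match`.
#'
#' @param probe_seq Probe sequence (DNA), length >= 30.
#' @param transcripts Named character vector of transcript sequences.
#' @param meta data.frame with columns `transcript_id`, `gene_id`,
#'   `source`, `biotype`, `utr_length`, `cdna_length`.
#' @param min_match Minimum perfect-match run (default 30).
#' @return data.frame of candidates (possibly 0 rows): `probe_id` absent;
#'   columns `transcript_id`, `gene_id`, `match_score`, `source`,
#'   `biotype`, `utr_length`, `cdna_length`.
#' @export
align_probe <- function(probe_seq, transcripts, meta, min_match = 30L) {
  probe_seq <- as_dna(probe_seq)
  if (nchar(probe_seq) < min_match)
    stop(sprintf("probe length %d is below the %d-nt match requirement",
                 nchar(probe_seq), min_match), call. = FALSE)
  probe_rc <- reverse_complement(probe_seq, "DNA")
  scores <- vapply(transcripts, function(tx) {
    tx <- as_dna(tx)
    max(longest_match_run(probe_seq, tx), longest_match_run(probe_rc, tx))
  }, integer(1))
  keep <- which(scores >= min_match)
  if (length(keep) == 0L)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      match_score = integer(0), source = character(0),
                      biotype = character(0), utr_length = integer(0),
                      cdna_length = integer(0), stringsAsFactors = FALSE))
  idx <- match(names(transcripts)[keep], meta$transcript_id)
  if (anyNA(idx))
    stop("transcript metadata missing for aligned transcript(s)", call. = FALSE)
  data.frame(transcript_id = meta$transcript_id[idx],
             gene_id = meta$gene_id[idx],
             match_score = unname(scores[keep]),
             source = meta$source[idx], biotype = meta$biotype[idx],
             utr_length = meta$utr_length[idx],
             cdna_length = meta$cdna_length[idx],
             stringsAsFactors = FALSE)
}

#' Resolve a probe's candidate alignments to a single transcript
#'
#' Selection cascade: (1) maximal match score; (2) curated Vega source
#' preferred; (3) biotype preference PROTEIN_CODING > PSEUDOGENE > OTHER
#' > NMD; (4) longest 3'UTR; (5) longest cDNA; (6) lexicographically
#' smallest transcript id (determinism guarantee).
#'
#' @param candidates data.frame as returned by [align_probe()].
#' @return Single-row data.frame (the winner), or `NULL` when there are
#'   no candidates (probe unmapped).
#' @export
resolve_probe_mapping <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  src <- SOURCE_RANK[match(candidates$source, names(SOURCE_RANK))]
  src[is.na(src)] <- SOURCE_RANK[["OTHER"]]
  bio <- BIOTYPE_RANK[match(candidates$biotype, names(BIOTYPE_RANK))]
  bio[is.na(bio)] <- BIOTYPE_RANK[["OTHER"]]
  o <- order(-candidates$match_score, src, bio,
             -candidates$utr_length, -candidates$cdna_length,
             candidates$transcript_id)
  out <- candidates[o[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a set of probes to unique best transcripts and genes
#'
#' @param probes Named character vector of probe sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param meta Transcript metadata (see [align_probe()]).
#' @param min_match Minimum perfect-match run (default 30).
#' @return data.frame `probe_id`, `transcript_id`, `gene_id`,
#'   `match_score`; unmapped probes are omitted.
#' @export
map_probes <- function(probes, transcripts, meta, min_match = 30L) {
  rows <- lapply(names(probes), function(pid) {
    cand <- align_probe(probes[[pid]], transcripts, meta, min_match)
    best <- resolve_probe_mapping(cand)
    if (is.null(best)) return(NULL)
    data.frame(probe_id = pid, transcript_id = best$transcript_id,
               gene_id = best$gene_id, match_score = best$match_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_id = character(0), transcript_id = character(0),
                      gene_id = character(0), match_score = integer(0))
  out
}
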