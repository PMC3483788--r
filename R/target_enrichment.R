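# Hypergeometric overlap of gene sets against a declared universe:
# miRNA target sets vs stress-response sets, stress sets vs each other.

#' Hypergeometric overlap test between two gene sets
#'
#' Both sets are intersected with the universe before testing; genes
#' falling outside the universe are reported via a warning. Fold
#' enrichment is `k / (|A| * |B| / N)`; the enrichment P-value is
#' `P(X >= k)` and the depletion P-value `P(X <= k)` for
#' `X ~ Hypergeometric(N, |A|, |B|)`.
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates are
#'   removed with a warning).
#' @param universe Character vector: the detected-gene background.
#' @param a_name,b_name Labels carried into the result.
#' @return One-row data.frame of class `overlap_result`: `set_a`,
#'   `set_b`, `universe_size`, `size_a`, `size_b`, `overlap`, `fold`,
#'   `log2_fold`, `p_enrich`, `p_deplete`.
#' @export
overlap_test <- function(set_a, set_b, universe, a_name = "A", b_name = "B") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  for (nm in c("a", "b")) {
    s <- if (nm == "a") set_a else set_b
    if (anyDuplicated(s))
      warning(sprintf("duplicate gene ids in set %s were deduplicated",
                      toupper(nm)), call. = FALSE)
  }
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  out_a <- sum(!set_a %in% universe); out_b <- sum(!set_b %in% universe)
  if (out_a + out_b > 0L)
    warning(sprintf("%d gene(s) of %s and %d of %s fall outside the universe and were dropped",
                    out_a, a_name, out_b, b_name), call. = FALSE)
  A <- intersect(set_a, universe); B <- intersect(set_b, universe)
  N <- length(universe); k <- length(intersect(A, B))
  expected <- length(A) * length(B) / N
  fold <- if (expected > 0) k / expected else NA_real_
  p_enr <- hypergeom_tail(k, length(A), length(B), N, tail = "enrichment")
  p_dep <- hypergeom_tail(k, length(A), length(B), N, tail = "depletion")
  out <- data.frame(set_a = a_name, set_b = b_name, universe_size = N,
                    size_a = length(A), size_b = length(B), overlap = k,
                    fold = fold, log2_fold = log2(fold),
                    p_enrich = p_enr, p_deplete = p_dep,
                    stringsAsFactors = FALSE)
  class(out) <- c("overlap_result", "data.frame")
  out
}

#' Batch overlap tests of target sets against response sets
#'
#' One overlap test per (target set x response set) pair, with BH
#' adjustment of the enrichment P-values across the panel. Pairs where
#' either set is empty after universe restriction are recorded as
#' untestable (NA P-values) rather than erroring.
#'
#' @param target_sets Named list of `target_call_set` objects or gene-id
#'   vectors.
#' @param response_sets Named list of gene-id vectors (e.g. stress-up /
#'   stress-down sets).
#' @param universe Character vector of gene ids.
#' @return data.frame: one row per pair, columns as [overlap_test()]
#'   plus `testable` and `adj_p_enrich`.
#' @export
enrichment_panel <- function(target_sets, response_sets, universe) {
  stopifnot(length(universe) > 0L)
  get_genes <- function(x) if (inherits(x, "target_call_set")) x$targets else x
  rows <- list()
  for (ta in names(target_sets)) {
    for (rs in names(response_sets)) {
      A <- unique(intersect(get_genes(target_sets[[ta]]), universe))
      B <- unique(intersect(response_sets[[rs]], universe))
      if (length(A) == 0L || length(B) == 0L) {
        r <- data.frame(set_a = ta, set_b = rs,
                        universe_size = length(unique(universe)),
                        size_a = length(A), size_b = length(B),
                        overlap = 0L, fold = NA_real_, log2_fold = NA_real_,
                        p_enrich = NA_real_, p_deplete = NA_real_,
                        stringsAsFactors = FALSE)
      } else {
        r <- suppressWarnings(overlap_test(A, B, universe, ta, rs))
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$testable <- !is.na(out$p_enrich)
  out$adj_p_enrich <- NA_real_
  if (any(out$testable))
    out$adj_p_enrich[out$testable] <- bh_adjust(out$p_enrich[out$testable])
  rownames(out) <- NULL
  out
}
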