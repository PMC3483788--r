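# Differential expression ranking: detection filtering, moderated
# two-sample t with empirical-Bayes variance shrinkage, BH adjustment,
# best-probe-per-gene collapse, and ranking by t statistic.

#' Construct an expression set
#'
#' @param exprs Numeric matrix of log2 expression (genes x samples),
#'   rownames = gene ids, no missing values.
#' @param conditions Character vector of condition labels, one per
#'   sample column.
#' @param detection_p Optional numeric matrix of detection P-values,
#'   same shape as `exprs`.
#' @return Object of class `expression_set`.
#' @export
expression_set <- function(exprs, conditions, detection_p = NULL) {
  exprs <- as.matrix(exprs)
  if (anyNA(exprs)) stop("expression matrix contains missing values", call. = FALSE)
  if (is.null(rownames(exprs))) stop("expression matrix needs gene-id rownames", call. = FALSE)
  if (anyDuplicated(rownames(exprs))) stop("duplicate gene ids", call. = FALSE)
  if (length(conditions) != ncol(exprs))
    stop("one condition label per sample column is required", call. = FALSE)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    stopifnot(all(dim(detection_p) == dim(exprs)))
  }
  structure(list(exprs = exprs, conditions = as.character(conditions),
                 detection_p = detection_p),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%s)\n",
              nrow(x$exprs), ncol(x$exprs),
              paste(sprintf("%s:%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' Detection-filtered gene universe
#'
#' Genes detected (detection P strictly below `alpha`) in at least one
#' sample of the contrasted conditions. This set is the universe for
#' downstream enrichment tests.
#'
#' @param es An `expression_set` with detection P-values.
#' @param alpha Detection threshold (default 0.01).
#' @param conditions Condition labels defining the contrast; default all.
#' @return Character vector of gene ids.
#' @export
detection_filter <- function(es, alpha = 0.01, conditions = NULL) {
  stopifnot(inherits(es, "expression_set"))
  if (is.null(es$detection_p))
    stop("no detection P-values in this expression set; rerun without the detection filter",
         call. = FALSE)
  cols <- if (is.null(conditions)) seq_len(ncol(es$exprs)) else
    which(es$conditions %in% conditions)
  if (length(cols) == 0L) stop("no samples match the requested conditions", call. = FALSE)
  pass <- apply(es$detection_p[, cols, drop = FALSE] < alpha, 1L, any)
  universe <- rownames(es$exprs)[pass]
  if (length(universe) == 0L)
    warning("detection filter removed every gene", call. = FALSE)
  universe
}

# Invert the trigamma function by Newton iteration (for the prior df
# moment estimate). x such that trigamma(x) = y.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Moment-matching estimate of the variance prior (d0, s0^2) from the
# per-gene sample variances s2 with d residual df each.
estimate_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s0_sq = NA_real_))
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  v <- stats::var(e) - trigamma(d / 2)
  if (is.na(v) || v <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(v)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t statistics for a condition contrast
#'
#' Per gene, a two-sample t statistic with empirical-Bayes shrinkage of
#' the pooled residual variance toward a prior: the shrunk variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the statistic is referred to a t
#' distribution on `d0 + d` degrees of freedom. The prior `(d0, s0^2)`
#' is estimated by moment matching on the log sample variances unless
#' supplied. With `d0 = 0` the classical pooled two-sample t is
#' recovered.
#'
#' @param es An `expression_set`.
#' @param contrast Character vector of two condition labels `c(A, B)`;
#'   log-fold-changes are `mean(A) - mean(B)`.
#' @param d0,s0_sq Optional fixed prior df / prior variance overriding
#'   the moment estimate.
#' @return Object of class `de_result`: data.frame with columns
#'   `gene_id`, `logFC`, `t`, `df`, `p_value`, `adjusted_p`.
#' @export
moderated_t <- function(es, contrast, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(es, "expression_set"), length(contrast) == 2L)
  ia <- which(es$conditions == contrast[1L])
  ib <- which(es$conditions == contrast[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each contrasted condition needs at least 2 samples", call. = FALSE)
  a <- es$exprs[, ia, drop = FALSE]; b <- es$exprs[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(a); mb <- rowMeans(b)
  d <- na + nb - 2L
  ssq <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / d
  if (is.null(d0)) {
    prior <- estimate_variance_prior(ssq, d)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
  } else {
    if (d0 > 0 && is.null(s0_sq))
      stop("s0_sq must be supplied together with a fixed d0 > 0", call. = FALSE)
    if (d0 == 0) s0_sq <- 0
  }
  if (d0 == 0 && any(ssq == 0))
    stop(sprintf("undefined statistic: zero residual variance with d0 = 0 (e.g. gene '%s')",
                 rownames(es$exprs)[which(ssq == 0)[1L]]), call. = FALSE)
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(ssq)) else
    (d0 * s0_sq + d * ssq) / (d0 + d)
  tt <- (ma - mb) / sqrt(s_tilde_sq * (1 / na + 1 / nb))
  df <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df)
  out <- data.frame(gene_id = rownames(es$exprs), logFC = ma - mb, t = tt,
                    df = df, p_value = p, adjusted_p = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- list(d0 = d0, s0_sq = s0_sq)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: P-values are sorted ascending, `q_i = min_{j
#' >= i} (p_j * m / j)` capped at 1, and mapped back to input order.
#'
#' @param pvals Numeric vector of P-values in \[0, 1\].
#' @return Adjusted P-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("P-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  q <- (m / seq_len(m)) * pvals[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  adj <- numeric(m)
  adj[o] <- q
  adj
}

#' Collapse probe-level results to one best probe per gene
#'
#' Keeps, for each gene, the probe with the smallest adjusted P-value;
#' ties are broken by lexicographic probe id.
#'
#' @param probe_results data.frame with columns `probe_id`, `gene_id`,
#'   `adjusted_p` and any statistic columns to carry along.
#' @return data.frame with one row per gene.
#' @export
best_probe_per_gene <- function(probe_results) {
  req <- c("probe_id", "gene_id", "adjusted_p")
  stopifnot(all(req %in% names(probe_results)))
  if (anyNA(probe_results$gene_id) || any(!nzchar(probe_results$gene_id)))
    stop("every probe row must carry a gene id", call. = FALSE)
  o <- order(probe_results$gene_id, probe_results$adjusted_p,
             probe_results$probe_id)
  d <- probe_results[o, , drop = FALSE]
  out <- d[!duplicated(d$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes from most down- to most upregulated
#'
#' Ascending order of the t statistic (most negative = most
#' downregulated first); ties are broken alphabetically by gene id so
#' the ranking is deterministic.
#'
#' @param de A `de_result` (or data.frame with `gene_id` and `t`).
#' @return Object of class `ranked_gene_list`: data.frame with
#'   `gene_id`, `statistic`.
#' @export
rank_genes <- function(de) {
  stopifnot(all(c("gene_id", "t") %in% names(de)))
  if (any(!is.finite(de$t)))
    stop(sprintf("non-finite ranking statistic for gene(s): %s",
                 paste(utils::head(de$gene_id[!is.finite(de$t)], 5L),
                       collapse = ", ")), call. = FALSE)
  o <- order(de$t, de$gene_id)
  out <- data.frame(gene_id = de$gene_id[o], statistic = de$t[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}
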