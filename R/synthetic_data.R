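# Synthetic-data generators with known ground truth: miRNAs, UTR sets
# with planted seed sites, and expression matrices for
# mimic/inhibitor/mock/stress arms. All generators are pure functions of
# (configuration, seed).

#' Generate random mature miRNAs
#'
#' i.i.d. uniform RNA sequences; candidates whose 7(2)-type seed word
#' collides with an already accepted miRNA are resampled, so every miRNA
#' has a distinct SEVEN_2 word.
#'
#' @param n Number of miRNAs (>= 1).
#' @param length Sequence length (default 22).
#' @param seed Integer seed.
#' @param ids Optional ids (default `sim-miR-1..n`).
#' @param max_tries Resampling budget per miRNA.
#' @return Named character vector of RNA sequences.
#' @export
gen_mirnas <- function(n, length = 22L, seed = 1L, ids = NULL,
                       max_tries = 1000L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length < 8L) stop("miRNA length must be >= 8", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("sim-miR-%d", seq_len(n))
  stopifnot(length(ids) == n)
  with_seed(seed, {
    seqs <- character(0); words <- character(0)
    for (i in seq_len(n)) {
      for (try in seq_len(max_tries)) {
        s <- paste(sample(RNA_LETTERS, length, replace = TRUE), collapse = "")
        w <- derive_seed_sites(s)[["SEVEN_2"]]
        if (!w %in% words) break
        if (try == max_tries)
          stop("could not generate collision-free seed words; word space exhausted",
               call. = FALSE)
      }
      seqs <- c(seqs, s); words <- c(words, w)
    }
    setNames(seqs, ids)
  })
}

# Sample `n_sites` non-overlapping 1-based start positions for a 7-mer in
# a sequence of length len.
plant_positions <- function(len, n_sites, word_length = 7L, max_tries = 200L) {
  if (len < n_sites * word_length) return(NULL)
  for (try in seq_len(max_tries)) {
    pos <- sort(sample.int(len - word_length + 1L, n_sites))
    if (n_sites == 1L || all(diff(pos) >= word_length)) return(pos)
  }
  NULL
}

#' Generate a UTR set with planted seed sites
#'
#' Background sequence is i.i.d. with the requested GC fraction; planted
#' words overwrite the background at uniformly sampled non-overlapping
#' positions (so the sequence length is unchanged).
#'
#' @param n_genes Number of UTRs.
#' @param length_mean,length_sd Normal length distribution (nt), floored
#'   at 30 nt.
#' @param gc GC fraction of the background composition.
#' @param plant Named list, one element per miRNA id:
#'   `list(word =, genes =, sites =)` where `word` is the 7-mer to
#'   plant, `genes` the target gene ids and `sites` a scalar or
#'   per-gene vector of site counts (>= 1).
#' @param seed Integer seed.
#' @return List with `utrs` (a [utr_set()]) and `truth` (planted words,
#'   genes, and exact 0-based positions).
#' @export
gen_utrs <- function(n_genes, length_mean = 400, length_sd = 80, gc = 0.4,
                     plant = NULL, seed = 1L) {
  stopifnot(n_genes >= 1L, gc >= 0, gc <= 1)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    lens <- pmax(30L, as.integer(round(stats::rnorm(n_genes, length_mean, length_sd))))
    seqs <- vapply(lens, function(L)
      paste(sample(DNA_LETTERS, L, replace = TRUE, prob = probs), collapse = ""),
      character(1))
    names(seqs) <- gene_ids
    truth_plant <- list()
    for (mid in names(plant)) {
      p <- plant[[mid]]
      word <- as_dna(p$word)
      wl <- nchar(word)
      sites <- rep_len(p$sites, length(p$genes))
      if (any(sites < 1L)) stop("site count must be >= 1", call. = FALSE)
      if (any(!p$genes %in% gene_ids))
        stop("planted genes must be a subset of generated genes", call. = FALSE)
      positions <- list()
      for (j in seq_along(p$genes)) {
        g <- p$genes[j]
        pos <- plant_positions(nchar(seqs[[g]]), sites[j], wl)
        if (is.null(pos))
          stop(sprintf("UTR of gene '%s' is too short to host %d site(s)",
                       g, sites[j]), call. = FALSE)
        for (q in pos) substr(seqs[[g]], q, q + wl - 1L) <- word
        positions[[g]] <- pos - 1L  # 0-based
      }
      truth_plant[[mid]] <- list(word = as_rna(word), genes = p$genes,
                                 sites = sites, positions = positions)
    }
    list(utrs = utr_set(seqs),
         truth = list(planted = truth_plant, seed = seed))
  })
}

#' Generate an expression matrix for mimic/inhibitor/mock/stress arms
#'
#' Baseline per-gene means are Normal(`baseline_mean`, `baseline_sd`) on
#' the log2 scale; arm effects are additive on planted gene sets
#' (targets are shifted by `target_effect` in the mimic arm and by
#' `-target_effect` in the inhibitor arm; stress-up genes by
#' `stress_effect` in the stress arm); i.i.d. Gaussian noise is added
#' per sample. Detection P-values default to 0 for all genes; a
#' `dropout_frac` fraction of genes gets detection P = 0.5 everywhere.
#'
#' @param gene_ids Character vector of gene ids.
#' @param arms Named integer vector: replicates per condition, each
#'   >= 2. Default 4 each of mimic, inhibitor, mock, stress.
#' @param targets Gene ids receiving the target effect.
#' @param target_effect Delta log2 in the mimic arm (negative for
#'   repression).
#' @param stress_up Gene ids induced in the stress arm.
#' @param stress_effect Delta log2 in the stress arm (positive).
#' @param noise_sd Gaussian noise SD (log2 units).
#' @param baseline_mean,baseline_sd Baseline distribution.
#' @param dropout_frac Fraction of genes flagged undetected.
#' @param seed Integer seed.
#' @return List with `expression` (an [expression_set()]) and `truth`.
#' @export
gen_expression <- function(gene_ids,
                           arms = c(mimic = 4L, inhibitor = 4L, mock = 4L,
                                    stress = 4L),
                           targets = character(0), target_effect = -1.5,
                           stress_up = character(0), stress_effect = 1.5,
                           noise_sd = 0.5, baseline_mean = 8,
                           baseline_sd = 1.5, dropout_frac = 0, seed = 1L) {
  if (any(arms < 2L)) stop("each arm needs at least 2 replicates", call. = FALSE)
  if (dropout_frac < 0 || dropout_frac > 1)
    stop("dropout_frac must lie in [0, 1]", call. = FALSE)
  stopifnot(all(targets %in% gene_ids), all(stress_up %in% gene_ids))
  conditions <- rep(names(arms), arms)
  sample_ids <- unlist(lapply(names(arms),
                              function(a) sprintf("%s_%d", a, seq_len(arms[[a]]))))
  ng <- length(gene_ids); ns <- length(conditions)
  with_seed(seed, {
    base <- stats::rnorm(ng, baseline_mean, baseline_sd)
    mu <- matrix(base, ng, ns, dimnames = list(gene_ids, sample_ids))
    ti <- match(targets, gene_ids)
    if (length(ti)) {
      mu[ti, conditions == "mimic"] <- mu[ti, conditions == "mimic"] + target_effect
      mu[ti, conditions == "inhibitor"] <- mu[ti, conditions == "inhibitor"] - target_effect
    }
    si <- match(stress_up, gene_ids)
    if (length(si) && "stress" %in% conditions)
      mu[si, conditions == "stress"] <- mu[si, conditions == "stress"] + stress_effect
    x <- mu + matrix(stats::rnorm(ng * ns, 0, noise_sd), ng, ns)
    det <- matrix(0, ng, ns, dimnames = dimnames(x))
    if (dropout_frac > 0) {
      drop_idx <- sample.int(ng, round(dropout_frac * ng))
      det[drop_idx, ] <- 0.5
    }
    list(expression = expression_set(x, conditions, detection_p = det),
         truth = list(targets = targets, target_effect = target_effect,
                      stress_up = stress_up, stress_effect = stress_effect,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate a full transfection/stress experiment
#'
#' Generates miRNAs, a UTR set with planted seed sites, and an
#' expression matrix, coupled so that the headline phenomenon --
#' stress-induced transcripts enriched in seed-matching sites -- is
#' dialable through `rho`, the fraction of the stress-up set drawn from
#' seed-carrying genes.
#'
#' The `"benchmark"` preset plants one focal miRNA whose 7(2) word is seeded
#' into `n_carriers` UTRs (1-3 sites each), represses `n_targets` of the
#' carriers in the mimic arm, and couples the stress-up set to the
#' carriers with `rho = 0.8`; two further miRNAs act as signal-free
#' controls. Because each transfection is a separate experiment in the
#' emulated design, the control miRNAs get their own effect-free
#' `ctrl_mimic` / `ctrl_inhibitor` arms: their targets are called from
#' that null contrast, never from the focal miRNA's contrast. The
#' `"null"` preset keeps the same structure with all effect sizes zero
#' and chance-level coupling.
#'
#' @param preset `"benchmark"` or `"null"`.
#' @param seed Integer seed.
#' @param n_genes,n_carriers,n_targets,n_stress_up Set sizes.
#' @param rho Fraction of stress-up genes drawn from seed carriers
#'   (in \[0, 1\]); `NULL` for chance-level sampling.
#' @param target_effect,stress_effect,noise_sd Effect sizes (log2) and
#'   noise SD.
#' @param replicates Replicates per arm.
#' @param n_mirnas Number of miRNAs (first is focal, rest controls).
#' @param utr_length_mean,utr_length_sd,gc UTR generator parameters.
#' @return List: `mirnas`, `lexicon`, `utrs`, `expression`, `truth`
#'   (focal miRNA/word, carriers, targets, stress sets, seeds).
#' @export
simulate_experiment <- function(preset = c("benchmark", "null"), seed = 1L,
                                n_genes = 2000L, n_carriers = 300L,
                                n_targets = 100L, n_stress_up = 200L,
                                rho = 0.8, target_effect = -1.5,
                                stress_effect = 1.5, noise_sd = 0.5,
                                replicates = 4L, n_mirnas = 3L,
                                utr_length_mean = 400, utr_length_sd = 80,
                                gc = 0.4) {
  preset <- match.arg(preset)
  if (preset == "null") {
    target_effect <- 0; stress_effect <- 0; rho <- NULL
  }
  if (!is.null(rho) && (rho < 0 || rho > 1))
    stop("rho must lie in [0, 1]", call. = FALSE)
  seed <- as.integer(seed) %% 1000000000L
  mirnas <- gen_mirnas(n_mirnas, seed = seed)
  focal <- names(mirnas)[1L]
  lexicon <- build_lexicon(mirnas)
  focal_word <- derive_seed_sites(mirnas[[focal]])[["SEVEN_2"]]

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  sets <- with_seed(seed + 1L, {
    carriers <- sort(sample(gene_ids, n_carriers))
    targets <- sort(sample(carriers, n_targets))
    sites <- sample(1:3, n_carriers, replace = TRUE)
    n_from_carriers <- if (is.null(rho))
      round(n_stress_up * n_carriers / n_genes) else round(rho * n_stress_up)
    n_from_carriers <- min(n_from_carriers, n_carriers)
    up_c <- sample(carriers, n_from_carriers)
    up_o <- sample(setdiff(gene_ids, carriers), n_stress_up - n_from_carriers)
    list(carriers = carriers, targets = targets, sites = sites,
         stress_up = sort(c(up_c, up_o)))
  })
  gu <- gen_utrs(n_genes, length_mean = utr_length_mean,
                 length_sd = utr_length_sd, gc = gc,
                 plant = setNames(list(list(word = focal_word,
                                            genes = sets$carriers,
                                            sites = sets$sites)), focal),
                 seed = seed + 2L)
  ge <- gen_expression(gene_ids,
                       arms = setNames(rep(replicates, 6L),
                                       c("mimic", "inhibitor", "mock", "stress",
                                         "ctrl_mimic", "ctrl_inhibitor")),
                       targets = sets$targets, target_effect = target_effect,
                       stress_up = sets$stress_up, stress_effect = stress_effect,
                       noise_sd = noise_sd, seed = seed + 3L)
  list(mirnas = mirnas, lexicon = lexicon, utrs = gu$utrs,
       expression = ge$expression,
       truth = list(preset = preset, focal_mirna = focal,
                    focal_word = focal_word, control_mirnas = names(mirnas)[-1L],
                    carriers = sets$carriers, targets = sets$targets,
                    stress_up = sets$stress_up, rho = rho,
                    target_effect = target_effect,
                    stress_effect = stress_effect, noise_sd = noise_sd,
                    planted = gu$truth$planted, seed = seed))
}
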