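# Shared format readers/writers and the end-to-end pipeline driver.
# Interchange formats: FASTA for sequences, TSV (tab-delimited, header,
# '#' comments) for tables, one-id-per-line text for gene sets.

#' Read a FASTA file
#'
#' Tolerates wrapped lines and CRLF endings; rejects duplicate ids (the
#' first whitespace-delimited token of each header).
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` (U converted to T) or `"RNA"` (T converted to
#'   U); case is normalized either way.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(seqs) <- ids
  if (alphabet == "DNA") as_dna(seqs) else as_rna(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read / write tab-delimited tables
#'
#' TSV with a header row; lines starting with '#' are comments. Malformed
#' rows are reported with their line number.
#'
#' @param path File path.
#' @return data.frame (strings kept as characters).
#' @export
read_tsv <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("malformed TSV '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  out
}

#' @rdname read_tsv
#' @param d data.frame to write.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read / write gene-set files (one gene id per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_set
#' @param genes Character vector to write.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read an expression matrix with design and optional detection TSVs
#'
#' @param matrix_path TSV: first column `gene_id`, remaining columns one
#'   per sample.
#' @param design_path TSV with columns `sample`, `condition`.
#' @param detection_path Optional TSV shaped like the matrix, holding
#'   detection P-values.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, design_path, detection_path = NULL) {
  m <- read_tsv(matrix_path)
  genes <- m[[1L]]
  x <- as.matrix(m[, -1L, drop = FALSE])
  rownames(x) <- genes
  design <- read_tsv(design_path)
  stopifnot(all(c("sample", "condition") %in% names(design)))
  idx <- match(colnames(x), design$sample)
  if (anyNA(idx)) stop("design file does not cover every sample column", call. = FALSE)
  det <- NULL
  if (!is.null(detection_path)) {
    d <- read_tsv(detection_path)
    det <- as.matrix(d[, -1L, drop = FALSE])
    rownames(det) <- d[[1L]]
    det <- det[genes, colnames(x), drop = FALSE]
  }
  expression_set(x, design$condition[idx], detection_p = det)
}

#' Write a simulated experiment to disk
#'
#' Writes miRNA FASTA, UTR FASTA, expression/detection/design TSVs and a
#' plain-text truth summary into `dir`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(mirna_fasta = file.path(dir, "mirnas.fa"),
         utr_fasta = file.path(dir, "utrs.fa"),
         expression = file.path(dir, "expression.tsv"),
         detection = file.path(dir, "detection.tsv"),
         design = file.path(dir, "design.tsv"),
         truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$mirnas, p[["mirna_fasta"]])
  write_fasta(sim$utrs$seq, p[["utr_fasta"]])
  x <- sim$expression$exprs
  write_tsv(data.frame(gene_id = rownames(x), x, check.names = FALSE), p[["expression"]])
  det <- sim$expression$detection_p
  write_tsv(data.frame(gene_id = rownames(det), det, check.names = FALSE), p[["detection"]])
  write_tsv(data.frame(sample = colnames(x), condition = sim$expression$conditions),
            p[["design"]])
  tr <- sim$truth
  write_tsv(data.frame(
    gene_id = sort(unique(c(tr$carriers, tr$targets, tr$stress_up))),
    carrier = sort(unique(c(tr$carriers, tr$targets, tr$stress_up))) %in% tr$carriers,
    target = sort(unique(c(tr$carriers, tr$targets, tr$stress_up))) %in% tr$targets,
    stress_up = sort(unique(c(tr$carriers, tr$targets, tr$stress_up))) %in% tr$stress_up),
    p[["truth"]])
  p
}

#' Pipeline configuration
#'
#' @param mirna_fasta,utr_fasta,expression,design Input paths
#'   (expression/design as in [read_expression()]).
#' @param detection Optional detection TSV path.
#' @param out_dir Output directory.
#' @param contrast Two condition labels for the targeting contrast.
#' @param stress_contrast Optional two labels for a stress contrast,
#'   scanned on the reversed (upregulated-first) ranking.
#' @param bin_step,markov_order Scan parameters.
#' @param alpha Target-calling adjusted-P threshold.
#' @param detection_alpha Detection-filter threshold.
#' @param auto_mask Apply DUST-style low-complexity masking to the UTRs.
#' @param target_mirnas miRNAs for target calling; default all in the
#'   lexicon input.
#' @param response_sets Named list of gene-set file paths for the overlap
#'   stage (skipped when `NULL`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mirna_fasta, utr_fasta, expression, design,
                            detection = NULL, out_dir = ".",
                            contrast = c("mimic", "inhibitor"),
                            stress_contrast = NULL, bin_step = 100L,
                            markov_order = 4L, alpha = 0.05,
                            detection_alpha = 0.01, auto_mask = FALSE,
                            target_mirnas = NULL, response_sets = NULL) {
  cfg <- as.list(environment())
  for (f in c("mirna_fasta", "utr_fasta", "expression", "design")) {
    if (!file.exists(cfg[[f]]))
      stop(sprintf("input file for '%s' does not exist: %s", f, cfg[[f]]),
           call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: lexicon -> UTR word counting -> differential-expression
#' ranking -> enrichment scan -> target calling -> gene-set overlap.
#' Each stage writes its TSV output under `out_dir`; a `run_info.tsv`
#' records parameters and input checksums. Outputs are deterministic
#' functions of the inputs and configuration.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory stage results and the
#'   output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- c(config$mirna_fasta, config$utr_fasta, config$expression,
              config$design, config$detection)
  info <- data.frame(key = c("contrast", "bin_step", "markov_order", "alpha",
                             basename(inputs)),
                     value = c(paste(config$contrast, collapse = ":"),
                               config$bin_step, config$markov_order,
                               config$alpha, unname(tools::md5sum(inputs))))
  write_tsv(info, out("run_info.tsv"))

  lexicon <- build_lexicon(read_fasta(config$mirna_fasta, "RNA"))
  write_lexicon(lexicon, out("lexicon.tsv"))

  utrs <- utr_set(read_fasta(config$utr_fasta, "DNA"))
  if (isTRUE(config$auto_mask)) utrs <- mask_low_complexity(utrs)
  counts <- count_words(utrs, lexicon)
  write_count_table(counts, out("counts.tsv"))

  es <- read_expression(config$expression, config$design, config$detection)
  universe <- if (!is.null(es$detection_p))
    detection_filter(es, alpha = config$detection_alpha,
                     conditions = config$contrast)
  else rownames(es$exprs)

  de <- moderated_t(es, config$contrast)
  de <- de[de$gene_id %in% universe, , drop = FALSE]
  write_tsv(de, out("de.tsv"))
  ranked <- rank_genes(de[de$gene_id %in% rownames(counts$counts), , drop = FALSE])
  write_tsv(ranked, out("ranking.tsv"))

  background <- if (config$markov_order > 0L)
    fit_markov(utrs, order = config$markov_order) else NULL
  cfg_scan <- scan_config(bin_step = config$bin_step,
                          markov_order = config$markov_order)
  landscape <- scan_landscape(ranked, counts, cfg_scan, background)
  write_landscape(landscape, out("landscape.tsv"))
  peaks <- peak_words(landscape, top = 25L, lexicon = lexicon)
  write_tsv(peaks, out("peaks.tsv"))

  mirnas <- config$target_mirnas
  if (is.null(mirnas))
    mirnas <- sort(unique(unlist(strsplit(lexicon$words$mirna_ids, ",", fixed = TRUE))))
  target_sets <- list()
  for (m in mirnas) {
    tcs <- call_targets(de, counts, lexicon, m, alpha = config$alpha)
    target_sets[[m]] <- tcs
    write_targets(tcs, out(sprintf("targets_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", m))))
  }

  panel <- NULL
  if (!is.null(config$response_sets)) {
    rsets <- lapply(config$response_sets, read_gene_set)
    panel <- enrichment_panel(target_sets, rsets, universe)
    write_tsv(panel, out("overlap.tsv"))
  }

  stress_landscape <- NULL
  if (!is.null(config$stress_contrast)) {
    de_s <- moderated_t(es, config$stress_contrast)
    de_s <- de_s[de_s$gene_id %in% intersect(universe, rownames(counts$counts)), ,
                 drop = FALSE]
    ranked_s <- rank_genes(de_s)
    stress_landscape <- scan_landscape(ranked_s, counts, cfg_scan, background)
    write_landscape(stress_landscape, out("landscape_stress.tsv"))
  }

  invisible(list(lexicon = lexicon, counts = counts, de = de, ranked = ranked,
                 landscape = landscape, peaks = peaks,
                 target_sets = target_sets, panel = panel,
                 stress_landscape = stress_landscape, universe = universe,
                 out_dir = config$out_dir))
}
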