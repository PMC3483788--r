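# Shared end-to-end runs of the benchmark-scenario preset (2,000 genes, 100
# planted targets at -1.5 log2 effect, noise SD 0.5, 4 replicates/arm,
# stress/seed coupling rho = 0.8). Computed once per test run and reused
# by the recovery and architecture tests.

benchmark_scenario_run <- function(seed) {
  sim <- simulate_experiment("benchmark", seed = seed)
  counts <- count_words(sim$utrs, sim$lexicon)
  bg <- fit_markov(sim$utrs, order = 4)
  cfg <- scan_config(bin_step = 100, markov_order = 4)

  de <- moderated_t(sim$expression, c("mimic", "inhibitor"))
  tc <- call_targets(de, counts, sim$lexicon, sim$truth$focal_mirna)
  precision <- if (length(tc$targets)) mean(tc$targets %in% sim$truth$targets) else 0
  recall <- mean(sim$truth$targets %in% tc$targets)

  ranked <- rank_genes(de)
  top_down <- peak_words(scan_landscape(ranked, counts, cfg, bg), top = 1)$word

  de_stress <- moderated_t(sim$expression, c("stress", "mock"))
  ranked_up <- rev(rank_genes(de_stress)$gene_id)
  top_up <- peak_words(scan_landscape(ranked_up, counts, cfg, bg), top = 1)$word

  universe <- rownames(sim$expression$exprs)
  p_focal <- overlap_test(tc$targets, sim$truth$stress_up, universe)$p_enrich
  # control miRNAs are scored on their own (signal-free) transfection arms
  de_ctrl <- moderated_t(sim$expression, c("ctrl_mimic", "ctrl_inhibitor"))
  p_ctrl <- vapply(sim$truth$control_mirnas, function(m) {
    g <- call_targets(de_ctrl, counts, sim$lexicon, m)$targets
    if (length(g) == 0L) 1 else
      overlap_test(g, sim$truth$stress_up, universe)$p_enrich
  }, numeric(1))

  list(seed = seed, focal_word = sim$truth$focal_word,
       precision = precision, recall = recall,
       top_down = top_down, top_up = top_up,
       p_focal = p_focal, p_ctrl = p_ctrl)
}

benchmark_scenario_runs <- local({
  cache <- NULL
  function(seeds = 1:20) {
    if (is.null(cache)) cache <<- lapply(seeds, benchmark_scenario_run)
    cache
  }
})
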