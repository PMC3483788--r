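---
title: "Seed-site enrichment landscapes: models, parameters, and design choices"
author: "seedscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-site enrichment landscapes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscape)
```

# The problem and the method

MicroRNAs recognize their targets through short seed-matching sites in
mRNA 3'UTRs: 7-nt words complementary to the miRNA seed region. When a
miRNA is perturbed (a transfected mimic raises its activity, an
inhibitor lowers it), its targets shift coordinately in expression. That
shift leaves a detectable footprint: if transcripts are ordered from
most down- to most upregulated, the miRNA's seed words are concentrated
toward one end of the list.

seedscape implements that detection chain:

1. **Seed lexicon** (`derive_seed_sites`, `build_lexicon`). For every
   mature miRNA, two 7-mers are derived: the *7(2)-type* site (also
   called 7mer-m8), the reverse complement of miRNA bases 2–8; and the
   *7(1A)-type* site (7mer-A1), the reverse complement of bases 2–7
   followed by an A, which sits opposite miRNA position 1. Words
   arising from several miRNAs are merged with their provenance.
   Three polyadenylation-signal-like words (`CAAUAAA`, `UAUUUAU`,
   `UCAAUAA`) are excluded by default because their positional biases in
   3'UTRs reflect polyadenylation, not miRNA action; the exclusion list
   is a plain parameter, and the lexicon reports counts both before and
   after exclusion so either convention can be quoted.

2. **Word counting** (`count_words`). Occurrences are counted
   *overlapping*, at the level of word positions: the units of the
   downstream hypergeometric draw are the 7-mer windows of the UTR set,
   not the sequences. A window is countable only if it contains no
   masked or ambiguous base, so masking reduces both a gene's counts and
   its total positions and the two stay consistent (summing counts over
   the complete word space reproduces the totals).

3. **Ranking** (`moderated_t`, `rank_genes`). Genes are ordered by a
   two-sample t statistic with empirical-Bayes variance shrinkage: the
   pooled residual variance $s_g^2$ (with $d$ residual df) is shrunk
   toward a prior, $\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$,
   and the statistic referred to a t distribution on $d_0 + d$ df. The
   prior $(d_0, s_0^2)$ is estimated by moment matching on the log
   sample variances; with $d_0 = 0$ the classical pooled t is recovered
   exactly, which is the oracle used in the tests (the implementation
   also matches the established empirical-Bayes implementation to
   machine precision on shared inputs). Adjusted P-values use the
   Benjamini–Hochberg step-up, implemented directly and checked
   bitwise against an independent reference.

4. **Enrichment landscape** (`scan_landscape`). The ranked list is
   scanned with leading bins growing by `bin_step = 100` sequences; the
   final bin always covers the whole list. For word $w$ and bin $b$ the
   enrichment P-value is the hypergeometric tail
   $P(X \ge k)$ with $X \sim \mathrm{Hyper}(N, K, n)$, where $k$/$n$
   are the word's occurrences and total word positions in the bin and
   $K$/$N$ the same over the full list. The landscape stores the
   *signed* value, $+|\log_{10} P|$ when the enrichment tail is the
   more extreme one and $-|\log_{10} P|$ for depletion (ties report
   $+$), so the full-list bin is always 0.

5. **Target calling** (`call_targets`). A putative direct target of a
   miRNA is a gene that is downregulated in the mimic-vs-inhibitor
   contrast (adjusted P < `alpha`, negative log-fold-change) and whose
   3'UTR carries at least one of the miRNA's seed words. The default
   `alpha = 0.05` is the conventional cutoff at which the
   downregulated boundary falls near the landscape peak in transfection
   experiments.

6. **Set overlap** (`overlap_test`, `enrichment_panel`). Target sets are
   tested for overlap with response gene sets by the hypergeometric
   enrichment tail against a declared detected-gene universe, with fold
   enrichment $k/(|A||B|/N)$ reported on the natural and log2 scales and
   BH adjustment across a panel of tests.

# Markov background correction

Seed words differ widely in background frequency (CG-poor words are
common in UTRs), so the raw hypergeometric against the empirical
full-list count can reflect composition rather than regulation. With
`markov_order = m > 0` (default 4), a background model is fitted by
exhaustive counting of the unmasked $m$-mers and $(m+1)$-mers of the UTR
universe, and a word's expected per-position probability is the chain
estimate

$$\hat p(w) \;=\; \frac{\prod_{i} C(w_{i..i+m})}{\prod_{i \ge 1} C(w_{i..i+m-1})}
\cdot \frac{1}{\sum_u C_m(u)},$$

the product of $(m+1)$-mer counts over the word divided by the counts of
the interior overlap $m$-mers, normalized by the total $m$-mer count.
For $m = 0$ this reduces to the product of base frequencies, and on
i.i.d. uniform sequence any 7-mer gets $\approx 4^{-7}$. The scan then
replaces the empirical population count $K$ by the expected count
$K^* = \mathrm{round}(\hat p(w) \cdot N)$, bounded to $[1, N]$.

Two numerical choices follow from this design:

* all tail probabilities are computed in log space, so landscapes of
  strongly planted words remain finite and accurate well beyond
  $P = 10^{-300}$;
* because $K^*$ can fall below a word's observed count in a bin, the
  observed count is clamped into the support of
  $\mathrm{Hyper}(N, K^*, n)$ before evaluating the tails; the P-value
  then saturates at the most extreme value the corrected model can
  express rather than degenerating to $-\infty$.

The uncorrected mode (`markov_order = 0`) is the plain hypergeometric
and serves as the reference behavior for all enumeration oracles.

# Masking

UTR inputs are masked in two ways, both recorded as 0-based half-open
intervals that suppress word windows without altering sequence text:

* `mask_low_complexity` slides 64-nt windows and scores triplet
  composition with a DUST-style statistic,
  $10 \sum_t c_t (c_t - 1) / 2 \,/\, (k - 1)$ over the $k$ triplets of
  the window; windows above the conventional threshold of 20 are
  masked. A 50-nt homopolymer scores ~240 and is masked entirely; a
  uniform random 64-mer scores ~5 and is untouched. The operation is
  idempotent.
* `mask_redundant` removes repetitive fragments shared across the UTR
  set: any exact 30-mer occurring in more than 5 distinct UTRs (both
  parameters configurable) is masked everywhere it occurs.

Ambiguous bases (`N`) are treated as masked throughout.

# The synthetic-data generator

`simulate_experiment` produces the full inputs of a transfection/stress
study with known ground truth. The `"benchmark"` preset fixes the study
conditions used throughout validation:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2,000 | genes / UTRs in the universe |
| `n_carriers` | 300 | UTRs carrying 1–3 planted focal seed sites |
| `n_targets` | 100 | carriers repressed in the mimic arm |
| `target_effect` | −1.5 | log2 shift of targets in the mimic arm (mirrored, +1.5, in the inhibitor arm) |
| `n_stress_up` | 200 | genes induced in the stress arm |
| `stress_effect` | +1.5 | log2 induction of stress-up genes |
| `rho` | 0.8 | fraction of the stress-up set drawn from seed carriers |
| `noise_sd` | 0.5 | per-sample Gaussian noise SD (log2) |
| `replicates` | 4 | samples per arm |
| UTR length | N(400, 80) nt | floored at 30 nt |
| baseline | N(8, 1.5) log2 | per-gene mean expression |

Effects are additive on the log2 scale with Gaussian noise — the
simplest model consistent with normalized microarray intensities. The
coupling parameter `rho` dials the headline phenomenon (stress-induced
transcripts enriched in seed sites) from chance level to strong; 0.8 is
the validated preset.

Because each transfection is a separate experiment in the emulated
design, the two control miRNAs get their own effect-free `ctrl_mimic` /
`ctrl_inhibitor` arms, and control target calling uses that null
contrast. Calling control targets from the focal miRNA's contrast would
instead condition on the focal perturbation: the only significant genes
there are the planted targets, so any control word present in a few of
them by chance yields a tiny target set that inherits the targets'
stress coupling — a selection artifact, not control enrichment.

What the generator deliberately does **not** emulate: probe-level
intensities and normalization artifacts, UTR isoform structure,
conservation, heavy-tailed or correlated noise, and miRNA-family seed
sharing beyond what random collisions produce. Passing tests on this
generator therefore demonstrate the correctness and calibration of the
statistical chain under its stated model, not performance on any
particular microarray platform.

# Validation and problem sizes

The test suite validates each stage against independent oracles:
exhaustive subset enumeration for every hypergeometric tail with
population size up to 12; choose()-arithmetic tail sums for larger fixed
examples; naive sliding-window tallies for k-mer counting; the classical
pooled t and the established empirical-Bayes implementation for the
moderated statistic; and an independent step-up reference for BH
adjustment (bitwise equality on 1,000 random vectors).

Calibration and recovery are assessed at the preset study conditions:
1,000 seeded null rankings of 2,000 genes against a 50-word lexicon
(per-bin per-word enrichment P < 0.05 must not exceed its binomial
band, and the landscape peak clears the Bonferroni line over words ×
bins in at most 5% of simulations), and 20 seeded end-to-end runs of the
benchmark scenario (target-calling precision and recall ≥ 0.9; the planted
word tops the landscape at the downregulated end of the mimic contrast
and the upregulated end of the stress contrast; the focal target set is
enriched in the stress-up set at P < 0.001 while both controls are not,
each in ≥ 19 of 20 seeds). These sizes keep the default validation run
to a few minutes while leaving the binomial margins meaningful.

# Worked example

```{r example}
sim <- simulate_experiment("benchmark", seed = 1, n_genes = 400,
                           n_carriers = 80, n_targets = 40, n_stress_up = 60)
counts <- count_words(sim$utrs, sim$lexicon)
bg <- fit_markov(sim$utrs, order = 4)

de <- moderated_t(sim$expression, c("mimic", "inhibitor"))
landscape <- scan_landscape(rank_genes(de), counts,
                            scan_config(bin_step = 50, markov_order = 4), bg)
peak_words(landscape, top = 3, lexicon = sim$lexicon)

targets <- call_targets(de, counts, sim$lexicon, sim$truth$focal_mirna)
targets
overlap_test(targets$targets, sim$truth$stress_up,
             rownames(sim$expression$exprs), "focal targets", "stress-up")
```

```{r plot, fig.width = 6, fig.height = 4}
plot(landscape, highlight = 2)
```

# Known limitations and open choices

* **Site types.** Only the two 7-mer site types are modeled; 6-mers,
  8-mers, offset sites, pairing thermodynamics, and conservation are out
  of scope (sequence-only target prediction is deliberately avoided —
  the experimentally anchored definition of a target is the point of
  the target-calling stage).
* **Word-position universe.** The bin grid grows over ranked
  *sequences* while the hypergeometric operates on word *positions*;
  totals are accumulated per gene and summed over the bin. Whether the
  totals should instead count sequences is an open convention; word
  positions keep totals additive over bins and match the counting
  design.
* **Masking on totals.** Totals are computed uniformly on masked
  sequence for every word; no per-word masking is attempted.
* **Exclusion list.** The polyadenylation-like words are excluded by
  enumeration, not by any similarity rule — the list is a parameter.
* **Probe mapping.** Alignment is exact longest-common-substring
  scoring on both strands (probes are short and the acceptance rule is
  a perfect-match run), so gapped alignments are not found. The
  preference of the `OTHER` biotype between `PSEUDOGENE` and `NMD`, and
  the final lexicographic transcript-id tie-break, are package
  decisions to guarantee a total, deterministic order.
* **Degenerate backgrounds.** A word whose sub-words are absent from
  the background model raises an error naming the sub-word rather than
  silently extrapolating.
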