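# glycoforms

Downstream analysis of deep, multiplexed intact-glycopeptide profiling
experiments in R.

Modern glycoproteomics workflows identify tens of thousands of intact
glycopeptides — a peptide sequence carrying a specific glycan composition at
a specific site — and quantify them across up to 18 TMT reporter channels.
The biology of interest lives downstream of the spectral search:
**microheterogeneity** (how many distinct glycan compositions decorate one
site, and at what stoichiometry), how glycosylation patterns differ between
tissues, which glycoforms sit on the cell surface, how fast individual
glycoforms respond to enzyme inhibition, and whether glycoforms of the same
protein differ in biophysical behaviour (detergent solubility, thermal
stability). `glycoforms` implements that downstream layer as tested,
reusable functions, together with a synthetic-data generator that emulates
the statistical structure of such experiments so every stage can be
benchmarked against known ground truth without any raw data.

## What the package computes

* **Glycan composition model** — parsing of `HexNAc(2)Hex(5)`-style
  composition strings over {HexNAc, Hex, Fuc/dHex, NeuAc, NeuGc, Phospho,
  Sulfo}, monoisotopic masses, and the hierarchical N- and O-glycan
  classification (phospho → sialylated → fucosylated → high mannose →
  paucimannose → small → complex/hybrid; O-mode analogues including
  O-GlcNAc and O-sulfated). Composition databases are screened with three
  plausibility rules: HexNAc ≤ 2·Hex + 1; NeuAc+NeuGc ≤ Hex/2 + 1 and
  Fuc ≤ Hex/2 + 1; NeuAc+NeuGc+Fuc ≤ 5.
* **PSM ingestion** — open-search PSM exports (tab-separated, configurable
  column map), glycan q-value filtering (q ≤ 0.05), O-mode removal of
  N-sequon (N-X-S/T) peptides, collapsing to unique (peptide, composition)
  glycopeptides, and masking of TMT channel leak (channels below 1/16 of
  the per-feature maximum).
* **Quantification** — quantile / median / arsinh-based variance-stabilizing
  normalization; protein-abundance correction by per-glycopeptide regression
  or by the ratio formula
  `corrected = ((g/p) / (median_g/median_p)) * median_g`;
  moderated differential abundance (limma empirical-Bayes) with the
  significance rule |log2 FC| > log2(1.5) (log2(2) for tissue contrasts) and
  Benjamini–Hochberg adjusted p < 0.05.
* **Microheterogeneity** — per-site glycoform counts and bins (1–2 / 3–10 /
  ≥11), fractional intensities, low/high labels at the 90th-percentile
  threshold, within-protein glycosylation-profile similarity (Kendall tau-b
  on composition presence vectors) against a count-preserving shuffle null
  with a Wilcoxon rank-sum comparison, phosphosite proximity (±5 residues),
  and Fisher-exact contingency enrichment with Haldane-corrected log2 odds
  ratios.
* **Tissue specificity** — per-site Pearson correlation of relative
  glycosylation patterns between tissues (sites with >5 glycopeptides),
  classified against the recomputed dataset mean; per-tissue glycan-class
  abundances and top-1% fractional-abundance compositions.
* **Perturbation analysis** — surface-exposure calls (sites with ≥2
  significantly changed glycoforms), cross-enzyme agreement, and neural-gas
  clustering of kinetic log2 fold-change profiles (k = 4 overall, k = 3 for
  the ever-downregulated fucosylated subset).
* **Biophysics** — log2 NP40/SDS solubility ratios and glycoform-vs-protein
  differential solubility; thermal-profile alignment via first-temperature
  internal references and ΔAUC (sum of anchored intensity differences over
  the nine-point 40.4–66.3 °C gradient).
* **Synthetic data** — `simulate_glycoproteome()` and
  `simulate_experiment()` generate PSM tables, matrices, designs and ground
  truth for two-group, time-course, tissue, surface, solubility and melting
  templates.

## Worked example

```r
library(glycoforms)

classify_n(c("HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)Fuc(1)NeuAc(2)",
             "HexNAc(2)Hex(3)"))
#> [1] high_mannose sialylated   paucimannose

# simulate a glycoproteome, ingest it, and summarize site heterogeneity
sim  <- simulate_glycoproteome(sim_config(seed = 1, n_proteins = 40))
rec  <- collapse_unique(qc_filter(sim$psms, q_max = 0.05))
summ <- site_microheterogeneity(rec, mode = "N")
mean(summ$n_glycoforms)        # 15.2 glycoforms per site on average
table(summ$heterogeneity_bin)
#>    low medium   high
#>     49     15     22

# two-group differential abundance with 5% planted four-fold effects
ex <- simulate_experiment("two_group",
        sim_config(seed = 1, n_features = 1000,
                   effect_fraction = 0.05, effect_lfc = 2))
d <- differential(ex$glyco, ex$design, list(c("treated", "control")))
sum(d$significant)   # 50 — exactly the planted features
head(d[d$significant, c("feature", "log2_fc", "p_adj")], 3)
#>    feature log2_fc    p_adj
#> 29  gp0029    2.01 2.98e-45
#> 64  gp0064   -1.96 1.89e-44
#> 71  gp0071    1.90 3.03e-43
```

The 86 simulated sites average 15.2 glycoforms with 57% carrying only one
or two — the heavy-tailed microheterogeneity structure the generator is
built to emulate — and the moderated test recovers all 50 planted four-fold
changes with calibrated significance.

`run_preset()` chains the stages into complete analyses
(`fucosylation_timecourse`, `surface_exposure`, `tissue_atlas`,
`solubility`, `microbiome`, `tpp`), writing tab-separated tables plus a
provenance log; reruns with the same seed are byte-identical.

## Vignette

`vignettes/glycoform-analysis.Rmd` documents the statistical model behind
each stage, the tunable parameters and their defaults, what the simulator
does and does not emulate, and the package's numerical design choices.
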