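---
title: "Models and methods behind glycoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoforms)
```

# Scope

`glycoforms` is the downstream half of an intact-glycopeptide profiling
workflow: it starts from search-engine PSM exports (or its own simulator)
and ends at biological readouts — microheterogeneity statistics,
differential glycoform abundance, tissue specificity, surface exposure,
kinetic clusters, solubility and thermal stability. Spectral search, glycan
assignment and FDR estimation happen upstream and are deliberately out of
scope; the package trusts the export's peptide, site, composition, q-value
and intensity columns.

This vignette documents the statistical models, the tunable parameters
(with defaults and why), the numerical choices, and what the synthetic-data
generator does and does not emulate.

# The glycan composition model

Compositions are residue-count vectors over HexNAc, Hex, Fuc (synonym
dHex), NeuAc, NeuGc, Phospho and Sulfo. Only composition, never topology,
is modeled: HCD fragmentation does not resolve linkage or antennary
structure, so any structure-level claim would overstate the data.

Classification is *hierarchical*: the first matching rule wins, so a glycan
carrying both NeuAc and Fuc is *sialylated*, not fucosylated. For N-glycans
the order is phospho, sialylated, fucosylated, high mannose (HexNAc(2) core
with 4–12 Hex and nothing else), paucimannose (HexNAc(2) with 1–3 Hex),
small (fewer than three HexNAc only), and complex/hybrid for the remainder.
The O-hierarchy inserts O-sulfated after fucosylated and distinguishes
O-GlcNAc (a single HexNAc) from O-hexose cores. Totality and uniqueness —
every valid composition receives exactly one class per mode — are verified
exhaustively over a residue-count grid in the test suite.

Composition databases are screened with three plausibility rules before
use: HexNAc ≤ 2·Hex + 1, NeuAc+NeuGc ≤ Hex/2 + 1 *and* Fuc ≤ Hex/2 + 1,
and NeuAc+NeuGc+Fuc ≤ 5. Two readings were open: the sialic/fucose bound
is applied as two independent constraints (the natural distribution of
"or" over the bound), and Hex/2 is real-valued rather than floored — the
more permissive reading, and for integer counts the two are
indistinguishable anyway. Filtering is idempotent by construction.

# Identification filters and collapsing

PSMs are kept at glycan q ≤ 0.05 (the default confidence cutoff for glycan
assignment in open searches). In O-mode, peptides containing the
N-glycosylation sequon N-X-S/T are removed to prevent N/O misassignment;
the literal pattern (any X) is the default, with an X≠P variant behind a
flag because the proline exclusion is a convention some groups apply and
others do not. A *unique glycopeptide* is a unique (peptide sequence,
glycan composition) pair. Within a pair, MS1 intensity is aggregated with
`max` (a peak-height proxy; summing would double-count re-sampled
precursors) and reporter intensities with element-wise sums (reporter ions
are additive); both choices are arguments.

Reporter channel leak — spurious low-level signal bleeding between TMT
channels — is masked per feature: channels strictly below 1/16 of the
feature's maximum channel become missing; a channel exactly at the boundary
is kept. Masking individual channels rather than dropping whole features
preserves the quantifiable majority of the signal; whole-feature removal is
available as a switch.

# Normalization and protein correction

Three per-sample calibrations are provided. `quantile` and `median` are
limma's standard quantile and median-value normalizations. `vsn_like` is an
inverse-hyperbolic-sine transform followed by a per-sample affine map that
equalizes sample medians and median absolute deviations — a
variance-stabilizing, log-like calibration. Downstream stages depend only
on calibrated log-like intensities, so any method meeting this contract is
interchangeable; the method used is recorded per run.

Glycopeptide intensity confounds glycoform regulation with protein
abundance. Two corrections are implemented, matching two experiment styles:

* **Regression** (log scale): per glycopeptide, ordinary least squares on
  the matched protein profile; the corrected profile is the residuals plus
  the glycopeptide's mean. A zero-variance protein profile yields slope 0
  (input returned, flagged); unmatched glycopeptides pass through flagged.
* **Ratio** (raw scale): `corrected = ((g/p) / (median_g/median_p)) *
  median_g`, evaluated per sample with medians over the matched set. The
  construction is exactly invariant to global rescaling of the protein
  matrix — verified to machine precision at scale factors 0.1, 7 and 1000.
  Per-sample medians are used; a global-median variant would only differ
  by a fixed factor per sample and the per-sample form also absorbs
  loading differences.

Differential abundance uses limma's moderated t (empirical-Bayes variance
shrinkage) on complete-case features, with replicate as an additive
covariate when the design declares one. Significance combines an effect
threshold with an error threshold: |log2 FC| > log2(1.5) and BH-adjusted
p < 0.05 (the tissue-contrast preset raises the effect threshold to
log2(2)). As per-group sample size grows the moderated statistic converges
to the ordinary t; the suite checks this in a heteroscedastic regime, where
the prior degrees of freedom stay finite.

# Microheterogeneity statistics

Sites are binned by distinct-glycoform count as low (1–2), medium (3–10)
and high (≥11); the printed convention "3–11 and 11+" overlaps at 11, so
the partition boundary is placed at 11 in the high bin. Machine-learning
labels mark sites with a single glycoform as *low* and sites strictly above
the dataset's 90th percentile of glycoform counts as *high*; the threshold
is always recomputed and reported, never hard-coded.

Within-protein similarity of glycosylation profiles uses *binary presence
vectors* over the dataset-wide composition universe — presence is the only
replicate-stable summary of "which modifications were observed" — compared
with Kendall tau-b (tie-corrected; for binary vectors the
concordant/discordant counts come from the 2×2 table in closed form). The
null model shuffles the global multiset of composition assignments across
site slots, preserving every site's glycoform count exactly, and the
observed and shuffled tau distributions are compared with a two-sided
Wilcoxon rank-sum test. Rank-sum (unpaired) is the default because a
shuffled pair is not a natural partner of an observed pair; a paired
signed-rank variant is available. The number of permutations is an
argument — the null sharpens with more permutations but the test statistic
stabilizes quickly.

Contingency enrichment (e.g. protein domains × glycan classes) uses the
two-sided Fisher exact test per table cell against the rest of the table,
the sample odds ratio with a Haldane correction of 0.5 when any cell is
zero, BH adjustment across cells, and a conservative default significance
cutoff of adjusted p < 0.001 appropriate for large annotation families.

# Tissue specificity

A site's glycosylation pattern in a tissue is the vector of its
glycopeptides' replicate-averaged intensities rescaled to sum 1 — relative
patterns, so per-tissue loading cancels. Patterns are compared between
tissue pairs with Pearson correlation for sites with more than five
quantified glycopeptides (strictly greater by default; the at-least-five
variant is a flag). The per-site mean over pairs is classified against the
*dataset mean* of those means: below-mean sites are tissue-specific. The
cutoff is recomputed from each dataset because it is a property of the data
distribution, not a constant. Sites missing a tissue pair use the mean of
available pairs and are flagged.

# Surface exposure and kinetics

A site is *affected* by an enzymatic surface treatment when at least two of
its glycoforms change significantly — one significant glycoform is reported
but not trusted. Cross-enzyme agreement is quantified at two levels: the
per-composition counts of significantly changed glycopeptides, and the fold
changes of shared glycopeptides on sites affected by both enzymes.

Kinetic profiles (per-time-point log2 fold changes of features significant
at ≥1 time point) are clustered with neural gas: a rank-based vector
quantizer in which every prototype moves toward each presented input with
weight ε(t)·exp(−rank/λ(t)), both schedules decaying exponentially and
reaching their final values exactly at `t_max`. Defaults are the classical
ε 0.5→0.005, λ k/2→0.01, `t_max = 100·n`, and runs are bit-reproducible
under a seed. Raw fold changes are clustered (standardization is a flag):
the magnitude of regulation is part of the kinetic signature. For kinetic
profiles specifically, `cluster_kinetics()` lengthens the annealing to
`t_max = 1000·n` and keeps the best of three seeded restarts by
quantization error: kinetic prototype shapes (for example a late plateau
versus a gradual monotone decline) can lie close together, and the short
generic schedule can strand a prototype between two such clusters.
Quantization error is non-increasing in k, which the suite verifies.

# Solubility and thermal stability

Solubility is the log2 ratio of mild-detergent (NP40) to
denaturing-detergent (SDS) intensity. Glycoform-specific solubility is the
moderated per-replicate difference between a glycoform's ratio and its
parent protein's ratio, after median-centering both ratio sets per
replicate on the log scale — an additive centering, the log-scale
equivalent of median normalization, which removes global offsets (a uniform
shift of all glycoform ratios produces no calls).

Melting series (nine temperatures, 40.4–66.3 °C) measured in several
multiplex sets are aligned with an internal-reference factor per set: the
across-set mean protein intensity at the first temperature divided by the
set's own mean (the across-set mean is used as the reference rather than a
designated set — no set is privileged). After scaling, quantile
normalization is applied across (set, condition) sample columns over
protein-by-temperature rows, which harmonizes sample distributions without
flattening melting shapes. ΔAUC anchors each condition by subtracting its
own mean of the first two temperatures (removing abundance offsets so only
thermal (de)stabilization remains) and sums the anchored difference across
temperatures — a plain sum, not a trapezoid, since the temperature grid is
common to both conditions. ΔAUC is zero on self-comparison and
antisymmetric; statistical testing of melting differences is out of scope
and ΔAUC is reported descriptively.

# The synthetic-data generator

The generator is first-class, tested code: every downstream stage has at
least one end-to-end recovery test against its ground truth. Its defaults
are the study conditions the analyses assume:

* **Glycoforms per site** follow a zero-truncated two-component mixture:
  with probability 0.5 a site gets 1–2 glycoforms (P(1) = 0.6 within the
  component), otherwise 3 plus a negative-binomial tail (size 0.6, mean
  30.4), giving an overall mean of 17.4 with half of the sites at 1–2 — the
  heavy-tailed shape of deep brain glycoproteome data. A single truncated
  negative binomial cannot reach both the mean and the low-count mass
  simultaneously (at mean 17.4 its 1–2 mass is capped near one third),
  which is why a mixture carries the tail.
* **Compositions** are drawn from the enumerated universe consistent with
  the three database rules, weighted toward simpler compositions; every
  generated composition passes the filter by construction. Within-protein
  composition sharing is planted at a configurable probability (default
  0.5) by re-drawing from compositions already used on the protein's other
  sites.
* **Intensities** are protein abundance (log-normal, median 1e7) times
  per-site Dirichlet fractional abundances (concentration 0.5 — sparse, so
  most glycoforms have low fractional intensity) times log-normal noise
  (sd 0.1 on the log2 scale).
* **Channel leak** replaces a configurable fraction of reporter cells
  (default 5%) with values strictly below 1/16 of the feature's maximum, so
  the masking rule removes exactly the injected cells; at leak rate 0 the
  masking step is a no-op on generated data.
* **Experiment templates** plant the effects each analysis recovers:
  two-group fold changes, four kinetic prototype curves (early plateau,
  late plateau, transient, gradual monotone, all reaching −2 log2 at their
  extremes), tissue-divergent site profiles (independent sparse Dirichlet
  per tissue for a configured 20% of sites), class-dependent surface
  exposure (high-mannose glycoforms exposed at 0.25 versus 0.7 for other
  classes), +1.5 log2 solubility shifts on 10% of glycoforms, and
  sigmoidal melting curves with a planted −2 °C midpoint shift for a
  quarter of proteins plus per-set batch factors.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: spectrum-level artifacts (co-isolation,
oxonium ions, ratio compression beyond multiplicative leak), retention-time
structure, missingness mechanisms other than leak masking,
composition-dependent ionization efficiency (intensities are relative
within a site, as in real data, but the simulator's fractional abundances
are exact ground truth), and correlated biological variation between
features beyond the planted effects. Recovery rates on simulated data are
upper bounds on real-data performance.

# Problem sizes and numerical choices

The test and benchmark battery runs at desk scale, chosen so each property
is measured with adequate precision while the whole suite stays fast:
1,000-feature two-group simulations over 10 seeds for false-discovery
calibration, 50 four-fold spike-ins for power, 20 seeded
shuffle-null runs with 20 permutations each, 100-site tissue simulations,
180-point neural-gas benchmarks, and exhaustive residue-count grids for the
classification proofs. Headline dataset-scale numbers from deep profiling
studies (10^5 unique glycopeptides) depend on raw deposited data and
upstream searches and are not reproducible at this scale; the package's
claims are therefore property-based.

Numerical conventions: fractional intensities must sum to 1 per site within
1e-9; ratio-correction invariance is asserted at 1e-9; tau-b is undefined
(and the pair skipped, counted) when a presence vector is constant;
neural-gas presentation order is a seeded shuffled cyclic sequence and ties
in the final nearest-prototype assignment break toward the lower prototype
index; top-composition ties break deterministically by feature id;
Benjamini–Hochberg is the standard step-up with cumulative minimum, capped
at 1.

# Known limitations

* O-glycosite localization is taken from the search export; HCD data cannot
  localize O-sites, so O-mode "sites" are peptide-level anchors.
* The ratio and regression corrections assume one matched protein profile
  per glycopeptide; shared peptides between proteins are not deconvolved.
* ΔAUC is descriptive; no significance model for melting differences is
  fitted.
* The specificity cutoff for tissue sites (dataset mean correlation) is a
  relative criterion: it adapts to each dataset and is not comparable
  across datasets with different noise levels.
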