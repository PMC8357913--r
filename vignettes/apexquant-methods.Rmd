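---
title: "Statistical methods behind apexquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind apexquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

apexquant analyses cell-type- and compartment-specific proximity-labeling
proteomics quantified with isobaric (TMT) labels. An engineered peroxidase
(APEX2) fused to a compartment anchor — histone H2B for the nucleus, a
nuclear export signal (NES) for the cytosol, an LCK membrane anchor — is
expressed Cre-dependently in a genetically defined cell type; biotinylated
proteins are enriched on streptavidin beads, TMT-labeled, and quantified at
the PSM (peptide-spectrum match) level across one or more multiplexed runs.
The package turns those PSM tables into protein lists with three kinds of
statistical structure: specificity over Cre-negative background (Filter 1),
subcellular compartment assignment (Filter 2), and differential abundance
between cell types or activity states, with a synthetic-experiment
generator that makes every stage testable without raw MS data.

## The quantification model

All modeling is on log2 reporter intensities, which the pipeline treats as
additive in its effects:

* **PSM filtering.** Co-isolation interference ≤ 70 % (inclusive), search
  q-value < 0.01 (strict), unique peptides only. The inclusive/strict mix
  follows how these thresholds are conventionally reported; both are
  arguments of `filter_psms()`. Shared peptides are discarded, never
  redistributed.
* **Quantifiability.** A protein is summarized only with at least two
  unique *features* — distinct (peptide, charge) combinations — so a
  single-peptide protein needs PSMs at two charge states. Features are
  counted per protein across runs and fractions, the most permissive
  reading consistent with the rule. Proteins with exactly one unique
  feature are not discarded: they are reported descriptively through the
  single-PSM rescue path (`rescue_single_psm()`), excluded from inference.
* **Summarization.** Per protein and run, the PSM × channel matrix of log2
  intensities (fractions pooled) is decomposed by Tukey median polish; the
  protein's abundance in a channel is the overall effect plus the channel's
  column effect. Sweeps run row-first; even-length medians use the midpoint
  of the central order statistics; missing cells are skipped; channels with
  no data stay missing. Iteration stops when the largest applied shift
  falls below `tol` (default 1e-9, 200-sweep cap). The tight default makes
  summaries reproducible at negligible cost on PSM-sized matrices — median
  polish usually terminates exactly after a handful of sweeps — and the
  stopping rule is considered part of the algorithm's definition. The core
  is implemented in C++ (`src/medpolish.cpp`) because it runs once per
  protein per run inside simulation studies.
* **Reference normalization.** Every plex carries a pooled reference
  channel. Between-plex (batch) effects are corrected protein-by-protein:
  each run's abundances shift by that run's reference value minus the
  protein's grand mean of reference values across runs. Anchoring on the
  grand mean (rather than the first run) preserves the overall scale.
  After correction a protein's reference values agree exactly across the
  runs where they were observed; within-run contrasts are untouched, so
  the correction can never distort a within-run comparison. Proteins
  lacking a reference value in some run are left unshifted there and
  flagged as unanchored.
* **Median normalizations.** Peptide-level global median normalization
  (per run × channel, toward the grand median) equalizes loading and is
  *off* by default: in a three-construct enrichment experiment the
  construct-level intensity differences are signal, not nuisance. It is
  switched on for cell-type comparisons where loading should be equalized.
  Protein-level median normalization aligns column medians and is
  idempotent.
* **Missing data.** No imputation anywhere. Condition means, variances,
  medians and correlations all use observed values only.

## Moderated inference

Each protein gets a cell-means fit per condition with a pooled
within-condition variance `s²` on `d = Σ(n_g − 1)` degrees of freedom.
Variances are shrunk with an empirical-Bayes scaled inverse-χ² prior whose
hyperparameters `(d0, s0²)` are estimated by method of moments on
`z = log s²`, using digamma/trigamma corrections for the sampling
distribution of a log variance and a Newton inversion of the trigamma
function. When the observed spread of `z` does not exceed the χ²
prediction the prior is degenerate (`d0 = ∞`) and all variances shrink to
`s0²`. The moderated statistic for a contrast `A − B` is

```
t = (mean_A − mean_B) / ( s~ · sqrt(1/n_A + 1/n_B) ),
s~² = (d0·s0² + d·s²) / (d0 + d),   df = d + d0,
```

two-sided throughout, with a normal reference when `df` is infinite.
Proteins with no residual df shrink fully to the prior rather than being
dropped. Welch-style unequal variances are deliberately not offered; the
pooled model is the moderated-t convention. Benjamini–Hochberg adjustment
is applied within each named contrast (each comparison is its own
inference family, matching how per-comparison q-values are reported);
`adjust_by` can widen the family.

## The two-filter classification

**Filter 1 (specificity).** Each construct is contrasted against the
Cre-negative control; a protein is construct-specific when `log2FC > 0`
and `q < 0.05`. Endogenously biotinylated proteins (e.g. the carboxylases
Pcca/Pccb/Acaca) and nonspecific bead binders have no Cre± difference and
fall here. The phrase "adjusted p or q value" is implemented as BH q only —
one test, not two. One structural caveat worth knowing: when the large
majority of quantified proteins are truly enriched (the usual APEX
situation), the BH threshold saturates near α, so the *per-contrast*
retention of a null protein approaches the one-sided α rather than
something smaller, and taking the union over three construct contrasts
roughly triples it. Per comparison the filter removes ≈ 98 % of simulated
background; the union across three constructs retains ≈ 6 %.

**Filter 2 (compartment).** Among Filter-1 survivors, `nucleus` requires a
significantly positive H2B − NES contrast; `membrane` (three-construct
mode) requires a significantly negative H2B − LCK contrast; the H2B − LCK
sign decides the rare protein passing both, so the two calls are mutually
exclusive. In two-compartment mode (no membrane construct) everything not
nucleus-called is `cytosol_nonH2B`. Rank-based (`top k` by log2FC, ties
broken by log2FC desc / q asc / accession asc) and static log2FC cutoffs
are available as alternatives (`alt_cutoff()`).

Order of operations differs by experiment style and is configuration, not
code: `config_compartment()` (filter 1 → filter 2, three-construct),
`config_celltype()` (contaminant-list removal → median normalization →
filter 2 → p-rule cell-type contrasts per stratum), `config_activity()`
(filter 1 → filter 2 → per-stratum renormalization → q-rule case–control
contrast, with single-PSM rescue). Contaminant lists are consumed as plain
text files with `#tag` provenance lines; the upstream criteria that
generate such lists from single-cell atlases (e.g. fold-ratio and
expression cutoffs against striatal astrocytes) are out of scope here —
the lists are inputs.

## Downstream analyses

* **Stratified DE.** Nuclear and cytosolic strata are separate inference
  families: each stratum re-estimates its variance prior and its own BH
  adjustment. The significance rule is configurable because the two
  reference analyses differ: nominal `p < 0.05` for cell-type contrasts
  with modest effect sizes, BH `q < 0.05` for activation contrasts.
* **Transcriptome merging.** DEG sources qualify a gene by
  `adj_p < 0.05` and `|log2FC| > 1`, or by a published cluster membership;
  sources are merged, de-duplicated by gene symbol, direction conflicts
  keep both records flagged. Gene→accession mapping is a user-supplied
  two-column table; no network lookups.
* **Proteogenomic correlation.** Pearson r over shared accessions with the
  t-transform p-value. Which protein fold-change table (nuclear,
  cytosolic, combined) enters the correlation is the caller's choice and
  is recorded in their code, not guessed by the package.
* **Enrichment.** Plain hypergeometric upper tail against the
  identified-protein background, fold enrichment
  `(k/n)/(K/N)`, BH across terms. This is deliberately not the modified
  one-tailed Fisher (EASE) variant some web tools use; with small
  overlaps EASE is more conservative.
* **QC.** Leading log-fold-change MDS: pairwise distance is the RMS of the
  `top_n = 500` largest per-pair log2 differences over proteins complete in
  all samples, embedded by classical (Torgerson) MDS with the sign of each
  dimension fixed by its largest-magnitude coordinate. The per-pair
  selection is the chosen dialect of the leading-logFC distance. %CV is
  reported on the log2 scale (the conventional reporting scale, despite
  its unit oddity; a linear-scale option exists). Replicate correlation is
  pairwise-complete Pearson.

## The synthetic-experiment generator

`simulate_truth()` + `simulate_psm_table()` generate PSM tables with the
structure the pipeline assumes; defaults are chosen once to emulate the
reference study designs:

* 3000 proteins; compartment mixtures over {nucleus, cytosol, membrane}
  from a Dirichlet with concentration (0.4, 0.6, 0.35) — mostly dominant
  proteins with a realistic minority of dual-localized ones, cytosol most
  prevalent.
* 10 % nonspecific bead binders and 5 % endogenously biotinylated
  proteins, both captured construct-independently (zero Cre± difference).
* Capture geometry: construct weight vectors
  H2B = (1, 0.05, 0.02), NES = (0.05, 1, 0.05), LCK = (0.02, 0.05, 1)
  plus a nonspecific leak of 0.02; the capture term is
  `log2(Σ capture·mixture + leak)`, giving pure-compartment enrichment
  contrasts of ≈ 4 log2 units and Cre+/Cre− contrasts of ≈ 5, in line with
  strong proximity-labeling enrichment. H2B and LCK leak into cytosol
  symmetrically, so cytosol-dominant proteins sit near zero in the
  H2B − LCK contrast.
* Conditions are parsed by name: labels containing H2B/NES/LCK take that
  construct's capture; recognized control spellings (CTRL, Cre-…) take
  leak only; `A2a*` labels receive the cell-type effect; `hM3Dq*` labels
  the activity effect; anything else is an untargeted full-capture
  condition (used for clean two-group null designs).
* PSMs per protein per run are `1 + NegBinom(size 2, mean 1.5)`; peptide
  ionization offsets N(0, 1); measurement noise N(0, 0.25²); batch shifts
  N(0, 0.5²) per run; channel shifts N(0, 0.05²); baselines N(16, 2²) on
  the log2 scale. Noise level and PSM-count distribution are calibration
  choices — no quantitative values for them are published — set to give
  replicate correlations ≈ 0.99 and mean %CV of a few percent, matching
  the QC ranges the pipeline is expected to produce.
* The pooled reference channel carries the per-protein mean of all study
  samples' expected log2 signal. A physical pool would average on the raw
  scale; averaging on the log2 scale differs only by a protein-constant
  Jensen offset, which reference normalization is invariant to, and it
  makes the batch-shift cancellation exact — the property the
  normalization tests verify.
* Missingness is a deterministic detection floor (log2 < 6) plus 2 %
  missing-completely-at-random, both small since the pipeline does not
  impute. Filter-violating metadata (5 % each of high co-isolation,
  failing q, shared accessions) exist only to exercise ingest filtering
  and are drawn independently of intensity.

What the generator does *not* emulate: ratio compression from co-isolation
(the interference field is metadata only), spectrum-level effects (m/z,
fragmentation), isotope-impurity leakage, peptide-level missingness
correlated with hydrophobicity or digestion, and run-order drift. Passing
tests therefore demonstrate the statistical pipeline's correctness under
its own model assumptions, not robustness to those instrument-level
artifacts.

## Scoring classification against truth

Simulated proteins are continuous compartment mixtures, so "the right
answer" needs a definition. `score_compartment_calls()` scores
sensitivity over ordinary proteins whose dominant compartment weight is
≥ 0.5 *and* whose true noise-free defining contrast (computed analytically
from the truth with `sim_expected_log2fc()`) has magnitude ≥ 1 — weakly
dominant proteins have small true contrasts and no classifier should be
asked to find them. Symmetrically, specificity excludes proteins dominant
elsewhere whose true contrast crosses the same threshold in the call
direction: a cytosol-dominant protein genuinely captured two-fold more by
the membrane construct has no single correct label. The scoring universe
is restricted to quantified proteins, so quantifiability attrition is
reported separately rather than folded into classification sensitivity.

## Problem sizes used by the checks

The packaged statistical checks run, on one CPU, with: 1000 random PSM
matrices (2–12 × 10–16, 10 % missing) for median-polish oracle
equivalence; 20 × 5000 variances for prior recovery; 1000 p-vectors
(lengths 1–5000) for BH equivalence; 200 global-null experiments of 2000
proteins (4 vs 4, two plexes, batch SD 0.5) for FDR control; six
three-construct experiments of 2000 proteins for classification recovery;
100 experiments of 300 proteins with batch SD 1.0 for exact reference
normalization; 200 activation experiments of 800 proteins (7 vs 7, +0.8
effects on 5 % of nuclear proteins) for stratified-DE power and FDR; 200
draws of 2000 gene pairs at generating correlation 0.6; and one full
3000-protein pipeline run repeated for byte-identical determinism.
`scripts/acceptance.R` re-runs the main analyses at the same defaults from
a caller-supplied seed.

## Known limitations

* Multi-run proteins are combined through reference anchoring of
  per-sample abundances, not a joint mixed model with run effects; with
  a reference channel in every plex the two agree in expectation, but the
  mixed model would borrow strength differently for proteins missing whole
  runs.
* Fractions of a run are pooled into one PSM × channel matrix before
  polishing; per-fraction polishing would differ for proteins with
  strongly fraction-dependent interference.
* The hypergeometric enrichment treats annotation terms independently (no
  GO-DAG topology) and the MDS distance is a QC ordination, not an
  inferential statement.
* Whether a protein absent from the nuclear contrast table can still be
  membrane-called is ambiguous in three-construct mode; such proteins are
  processed from the available basis and flagged rather than dropped.
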