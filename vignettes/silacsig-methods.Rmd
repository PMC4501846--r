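---
title: "Methods: empirical-background interactor calling and PTM regulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical-background interactor calling and PTM regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacsig)
```

## The experimental design being modelled

A triple-SILAC design follows receptor signaling at two time points:
light-labelled cells are mock-treated, medium- and heavy-labelled cells
are stimulated for 5 and 15 min. Every protein group or PTM site then
carries two ratios per replicate — M/L (5 min vs control) and H/L
(15 min vs control) — and all analysis happens on these ratios. The
package assumes ratio normalisation happened upstream (as MaxQuant does)
and never re-normalises; ratios are stored linear-scale and logged
(base 2 throughout) only inside the statistics.

## Interactor calling against an empirical background null

Affinity purifications recover the bait complex plus a large excess of
bead-binding background. The calling procedure estimates the null from
the data:

1. Per channel, each protein is summarised by the **median of its log2
   ratios across replicates** (missing replicates skipped). Medians are
   robust and the enrichment criterion itself is stated on medians.
2. Proteins are sorted ascending by this summary; ties are broken by
   protein ID so the fit is deterministic. The lowest
   `floor(background_fraction * n)` (default 90%) form the background
   set.
3. The cutoff is `median + sd_multiplier * SD`, where the **median is
   taken over all quantified proteins** and the **SD (sample SD, n − 1)
   over the background set only**. Computing the centre on the full
   sample and the spread on the background-restricted sample mirrors the
   sequential way the procedure is defined; the difference
   between the two medians is small (the 45th vs 50th percentile of the
   null) and both are reported in the fitted `silac_background` object.
4. A protein is called at a time point when it has a linear ratio ≥
   `fold_threshold` (default 2) in at least `min_replicates` (default 2)
   replicates of that channel **and** its median log2 ratio exceeds the
   channel cutoff. Overall interactor status is the union over the two
   time points, which is also what assigns proteins to the Venn
   partition. Down-enrichment is not called: depletion from a pull-down
   has no interpretation as complex membership.

Degenerate inputs: fitting requires ≥ 3 quantified proteins and a
background set of ≥ 2; a protein quantified in fewer than
`min_replicates` replicates of a channel cannot pass that channel; an
all-constant table yields SD 0 and a cutoff equal to the median.

### Calibration of the median + 2SD rule

Because the SD is estimated on the lower 90% of the summary
distribution, it is the SD of a *truncated* Normal. For a standard
Normal truncated above its 90th percentile the SD is ≈ 0.8438, so the
cutoff sits at ≈ 1.69 full SDs above the centre and the asymptotic null
exceedance of the cutoff criterion is

\[ 1 - \Phi(2 \sigma_{trunc}) \approx 0.0457, \]

not the 2.3% a naive `median + 2SD` reading suggests.
`expected_null_positive_rate()` computes this closed form for any
background fraction and SD multiplier, and the test suite checks the
simulated null rate against it (20 seeds × 3000 proteins, ±0.01).

A practical consequence, which the recovery benchmark in
`scripts/acceptance.R` quantifies: the rule is sensitive (essentially
all 4-fold spiked interactors are recovered) but not specific when the
background log2 spread is comparable to the effect size. With a
background SD of 0.5 log2 units, ~4.6% of null proteins exceed the
cutoff per channel and the replicate-support filter removes only part of
them — a protein whose latent ratio clears the cutoff usually also has
two replicates above 2-fold — so a substantial fraction of calls are
background exceedances. This is a property of the published rule itself,
faithfully implemented; real datasets temper it because bead backgrounds
are tighter than the deliberately hard benchmark setting, and because
candidate interactors are typically validated orthogonally.

## PTM-site confidence filtering

Sites are kept when localization probability ≥ 0.75, identification
score ≥ 40 and PEP ≤ 0.01 — all boundaries inclusive, taken literally
from the printed inequalities, and applied before any regulation
calling. A missing quality value fails its criterion. The rejection log
records the first failed criterion in the order localization, score,
PEP. The same cutoffs are applied to di-Gly sites by default
(`apply_quality_to_digly = TRUE`), configurable because score/PEP
filtering for di-Gly tables is a convention rather than a necessity.

Di-Gly sites must additionally be internal to their peptide: trypsin
cannot cleave C-terminal to a di-Gly-modified lysine, so a peptide
*ending* in a modified lysine is an artifact. The filters are idempotent
and mutually order-independent, and kept plus rejected always partition
the input.

## Regulation calling and dynamics classes

Per site and channel, the median linear ratio across replicates is
classed up (≥ 2), down (≤ 0.5, boundaries inclusive) or unchanged;
channels with no quantified replicate are `missing`. The default
thresholds are reciprocal, so inverting every ratio swaps up and down
counts exactly — a property the tests assert.

The pair of per-time-point classes maps to a deterministic dynamics
label replacing unsupervised profile clustering: **early-transient**
(up at 5 min, then either no longer up or dropped ≥ `transient_drop`-fold),
**sustained** (up at both, drop < `transient_drop`), **late** (up only at
15 min), **down-regulated** (down somewhere, up nowhere),
**unregulated** (unchanged at both), **mixed** (down at 5 min but up at
15 min). `transient_drop = 2` was chosen so that a 19.5-fold → 2-fold
site — the textbook early-transient profile of IκB-α phosphorylation
after receptor engagement — lands in early-transient even though its
15-min ratio still touches the up threshold. `missing` is treated as
`unchanged` in these rules: an unquantified channel should not invent
regulation.

`residue_class_summary()` reports, per residue class (Tyr vs Ser/Thr)
and time point, site counts and the arithmetic mean linear fold change.
The mean defaults to **all sites quantified at the time point**, with an
up-only option. The all-quantified default was a deliberate choice: a
mean of 1.6-fold, the canonical sustained Ser/Thr magnitude, is
arithmetically impossible as a mean over sites that all cleared a 2-fold
threshold, so the class means people actually quote must include the
unregulated majority.

`ranksum_test()` is the Wilcoxon rank-sum / Mann-Whitney test
(`stats::wilcox.test` underneath): exact enumeration whenever both
groups have ≤ 8 tie-free observations, Normal approximation with tie and
continuity correction otherwise; two-sided exact p-values are the
doubled smaller tail, capped at 1. The suite verifies it against a
from-scratch enumeration of all rank assignments for every pattern up to
6 + 6. `replicate_correlation()` is Pearson on complete log2 pairs
(≥ 3 required).

## Integration and enrichment

`co_regulated_proteins()` joins the layers on protein IDs: a protein is
co-regulated when it carries at least one up-regulated phosphorylation
site *and* one up-regulated di-Gly site (at any time point); interactor
calls, when given, flag signalosome membership. Term enrichment is the
one-sided upper-tail hypergeometric test with Benjamini–Hochberg
correction across the tested terms (k ≥ 1 by default, matching common
GO-tool behaviour; adjusting over all terms is available). The universe
defaults to the proteins quantified in the relevant layer — the only
universe the pipeline can know, and the standard choice; enrichment
against a whole-proteome universe would overstate significance.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not mass spectra:

* **Interactome tables** — protein-level latent log2 ratios are
  `N(0, sigma_background)` for background binders and
  `N(effect, sigma_background)` for a `frac_interactors` minority;
  replicates add `N(0, sigma_replicate)`; each cell is missing
  independently with `dropout_prob` (explicit NA, never zero). Defaults
  (3000 proteins, 5% interactors, effect 2.0 log2 in both channels,
  σ_background 0.5, σ_replicate 0.25, 4 replicates, dropout 0.1) are
  the benchmark conditions used throughout the tests. The additive
  Gaussian noise model is a modelling decision — SILAC log-ratio
  distributions are symmetric and approximately Gaussian in the bulk —
  and it is what makes the median + 2SD null analysable in closed form.
* **PTM tables** — 10,000 phospho and 6,000 di-Gly sites by default,
  matching the scale of a deep BCR-stimulation dataset, drawn over a
  shared pool of 2,500 proteins so the layers overlap. 4.1% of phospho
  sites are Tyr; regulated fractions default to 20% (phospho) and 6%
  (di-Gly). Regulated sites draw a dynamics class — Tyr sites mostly
  early-transient with a 19.5-fold → 2-fold mean profile, Ser/Thr and
  di-Gly sites mostly sustained at ~3.5-fold — then a site-level effect
  `N(class mean, sigma_effect)`. Quality scores are drawn so that
  configurable fractions fail each confidence filter (defaults 10% /
  5% / 5%), and 5% of di-Gly sites are placed at the peptide C-terminus
  to exercise the internal-lysine rule. Unregulated sites have latent
  log2 ratio exactly 0 plus replicate noise.
* Truth labels are drawn before noise; every table row has exactly one
  truth record; a single integer seed drives all randomness and
  identical configurations are byte-identical on disk.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: intensity-dependent ratio variance and
missingness (dropout here is uniform, not abundance-driven), heavy-tailed
background binders, ratio compression, shared-peptide ambiguity between
protein groups, and correlated quality scores. Recovery results on
simulated data are statements about the calling rules under the stated
noise model, not about any particular instrument or sample.

## Numerical and interface choices

* Fixed TSV dialect (`Protein.ID`, `Ratio.M.L.rep{k}`, `Ratio.H.L.rep{k}`,
  site columns `Residue`/`Position`/`Modification`/`Localization.prob`/
  `Score`/`PEP`/`Peptide.Cterm`); a `col_map` hook renames columns of
  real MaxQuant exports at read time. Missing cells are `""`, `NA` or
  `NaN` on input and `""` on output; non-positive ratios are row-level
  validation errors naming the rows.
* Positions are 1-based on the protein; sites are keyed by
  (protein, position, modification) and localisation variants stay
  distinct records.
* The summary report is JSON with recursively sorted keys and
  full-precision numbers, so re-serialisation is byte-identical; no
  timestamps are embedded, making end-to-end runs reproducible byte for
  byte under a fixed configuration.
* Test and benchmark problem sizes: toy fixtures of 5–10 rows for
  hand-checkable oracles; 200 random tables of ≤ 100 proteins for
  exhaustive oracle equivalence; 20 seeds × 3000 proteins for null
  calibration and recovery; full rank-pattern enumeration up to 6 + 6
  for the rank-sum test; all hypergeometric configurations to N = 30.
  These sizes give sub-percent Monte-Carlo error on the calibration
  quantities while keeping the default suite fast.

## Known limitations

* The interactor caller cannot distinguish constitutive from
  stimulation-induced complex members; both pass the same criteria.
* The empirical cutoff is scale-free by construction (≈ the 95.4th
  percentile of the null summaries), so its false-call *count* grows
  linearly with the number of quantified background proteins; the
  replicate-support criterion, which is on an absolute fold scale, is
  what anchors specificity when backgrounds are tight.
* Dynamics classes are coarse by design; they are a transparent,
  deterministic stand-in for profile clustering, not a model of
  kinetics.
* Enrichment ignores the annotation DAG: terms are independent gene
  sets, with no parent-child propagation.
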