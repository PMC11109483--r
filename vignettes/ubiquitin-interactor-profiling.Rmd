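---
title: "Profiling ubiquitin chain interactors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ubiquitin chain interactors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubinteract)
```

## The problem

Ubiquitin (Ub) signals are polymers: chains described by their linkage
residue (K48, K63), their length (Ub2, Ub3, ...), and their topology
(homotypic versus branched, e.g. a Br Ub3 in which one proximal Ub carries
both a K48- and a K63-linked Ub). Which ubiquitin-binding proteins (UbBPs) a
chain recruits depends on all three. `ubinteract` implements the statistical
side of a bait-comparison pulldown experiment designed to resolve this: Ub
chains of defined architecture are immobilized on beads, incubated with cell
lysate in quadruplicate alongside a bead-only control, and the bound
proteomes are quantified by label-free mass spectrometry (iBAQ values per
protein isoform per sample). The package takes such protein-group tables and
answers, per protein: is it a Ub binder at all, and if so, does it prefer a
linkage, a chain length, or the branched topology? A companion module fits
surface plasmon resonance (SPR) steady-state data to validate individual
affinities.

## The preprocessing chain

The pipeline applies, in fixed order:

1. **Flag filtering** (`drop_flagged`): reverse-database, contaminant and
   site-only rows are removed before any statistic.
2. **Dropout-sample removal** (`detect_dropout_samples`): a sample whose
   present-value count falls below `min_fraction` (default 0.5) of its
   dataset's median detection count is removed. The threshold is a package
   convention: "dropout sample" has no standard quantitative definition, and
   0.5 separates failed injections cleanly from ordinary detection
   variation.
3. **Valid-value filtering** (`filter_min_valid`): a protein is kept iff it
   has at least `min_valid = 3` present values in *at least one* bait group.
   The "at least one" reading is deliberate: bait-exclusive binders — the
   objects of interest — are quantified in only one chain type's pulldowns,
   and an all-groups rule would discard them.
4. **Log2 + median normalization** (`log2_median_normalize`): each sample's
   present values are shifted so its median equals the grand median of
   per-sample medians. Any constant anchor gives identical downstream
   statistics, because group-mean differences are shift-invariant; the
   grand median merely keeps values on a familiar scale.
5. **Downshift imputation** (`impute_downshift`): missing values in
   proteomics intensity data are left-censored — a protein is undetected
   because it is absent or below the detection limit, not at random. Each
   missing cell in sample *s* is drawn from
   Normal(*m\_s* − `shift`·*sd\_s*, (`width`·*sd\_s*)²) with the de-facto
   convention `shift = 1.8`, `width = 0.3`, per sample (the standard
   placement for this imputation family; per-sample rather than global
   because detection limits drift between runs). Present cells are never
   altered, and the imputed-cell positions are kept in a provenance
   attribute.

## Two-pass Ub-enrichment prefiltering

Cross-bait comparisons are only meaningful for proteins that bind Ub at all.
`prefilter_ub_enriched` implements this in two passes. Pass 1 processes the
full filtered matrix and tests every Ub bait against the bead-only control
with a moderated t test; proteins with BH-adjusted p < 0.05 *and* log2 fold
change > 0 in at least one contrast are retained. Enrichment must be
*positive*: a protein depleted on a Ub bait relative to empty beads is not a
Ub interactor. Pass 2 returns to the *pre-normalization* matrix, subsets it
to the retained proteins, and re-normalizes and re-imputes it with an
independent seed substream, so that normalization and imputation of the
final matrix reflect only the Ub-enriched population. All cross-bait
statistics (the moderated F test in `significant_across_baits`, the pairwise
contrasts behind the classifiers) are computed on the pass-2 matrix, with a
variance prior re-estimated on that matrix (the two matrices differ, so each
pass gets its own prior).

Median-normalizing a *subset* assumes the subset's bulk is non-differential
across samples. That holds when general (pan-Ub) binders dominate the
Ub-enriched population — which real pulldown interactomes show (bait
interactomes correlate strongly) — and the synthetic generator's defaults
respect it; see below.

## Moderated statistics

The per-protein model is a one-way layout over bait groups on log2
intensities. `fit_groups` estimates group means and a residual variance
pooled across all groups of a dataset (this matches the all-pulldowns F-test
framing and maximizes residual degrees of freedom, d = N − K = 21 for 7
quadruplicate groups). With n = 4 replicates, per-protein variance estimates
are noisy; the package therefore uses the standard empirical-Bayes
hierarchical model in which true variances follow a scaled inverse-χ² prior
(d₀, s₀²), so observed variances are marginally s₀²·F(d, d₀).

`estimate_variance_prior` fits (d₀, s₀²) by moment matching on log sample
variances: after the digamma/log correction for finite d, the excess
variance of the corrected log-variances over trigamma(d/2) estimates
trigamma(d₀/2), inverted by a monotone Newton iteration; s₀² follows from
the corrected mean. Degenerate inputs are handled explicitly: fewer than 10
usable variances, or no excess spread, fall back to d₀ = ∞ (pure prior);
zero sample variances are excluded from estimation but still shrink to a
positive moderated variance.

The moderated statistics replace s² by the posterior
s̃² = (d₀s₀² + d·s²)/(d₀ + d) and gain d₀ degrees of freedom:
t̃ = Δμ̂ / (s̃·√(1/n_A + 1/n_B)) on d + d₀ df, and
F̃ = MS_between / s̃² on (K − 1, d + d₀) df. At d₀ → 0 these reduce exactly
to the classical pooled two-sample t and one-way ANOVA F (tested against
`t.test` and `aov`); at d₀ = ∞ the df is capped at 10⁶ to keep the t/F
distributions numerically ordinary. BH adjustment is applied within each
contrast across proteins.

## Specificity classification

Classification rules are pure functions of the pairwise contrast tables:

- **Linkage** (`classify_linkage`), from K48 Ub3 vs K63 Ub3: `linkage_K48`
  iff adj. p < 0.05 and logFC > 0; mirrored for K63. With several datasets,
  significance in one plus a consistent sign wherever quantified.
- **Length** (`classify_length`), from Ub3 vs Ub2 per linkage: significance
  in at least one dataset *and* logFC beyond the linkage threshold in every
  dataset where the protein appears — > 0.5 for K48, > 0 (sign consistency)
  for K63. The asymmetric thresholds follow the labelling convention of the
  underlying study design.
- **Branch** (`classify_branch`), from Br Ub3 vs the homotypic chains:
  `branch_specific` iff Br vs K48 Ub3 *and* Br vs K63 Ub3 are both
  significant-positive within a dataset; `branch_specific_strict` iff all
  four Br-vs-homotypic contrasts (Ub2 and Ub3, both linkages) pass in every
  dataset; `homotypic_preferring` for the mirrored direction.

Proteins satisfying no rule are left unclassified rather than forced into a
class. When length calls conflict across linkages, both calls are reported.

For interactome correlation between datasets (`interactome_correlation`)
the per-pulldown summary is the fitted group mean from `fit_groups`,
z-scored per protein (`group_profiles`). A single F statistic is one number
per protein, not one per pulldown, so a per-bait model value is the only
coherent reading; the profile source is an explicit function argument, not
hard-wired. Hierarchical clustering (`cluster_profiles`) z-scores rows,
uses Euclidean distance and complete linkage, and cuts at a user-chosen k —
no automatic k selection, matching practice for enrichment heatmaps.

## The synthetic-data generator

`simulate_interactome` generates log2 intensities
x = b_g + δ_gk + ε, ε ~ N(0, σ_rep²), exponentiated to the linear scale,
with planted truth retained so the generator is its own oracle. Defaults:

- **Design**: 7 bait groups (bead control, mono-Ub, K48 Ub2/Ub3, K63
  Ub2/Ub3, Br Ub3) in quadruplicate — the study design the analysis
  assumes.
- **Baseline**: b_g ~ N(25, 2²) log2 iBAQ; replicate noise σ_rep = 0.4.
- **Effect sizes** (log2): preferred-bait δ = 3; length-dependent classes
  add +1.5 on Ub3 over Ub2 of their linkage; branch-specific δ = 3 on Br
  with 1 on homotypic chains (mirrored for branch-excluded); bead binders
  δ = 2 on control and baits alike. These are comfortably detectable at
  n = 4 — clear profile separation, as in real enrichment heatmaps.
- **Cross-binding**: linkage- and length-specific classes carry δ = 2 on
  the branched chain (a Br Ub3 physically contains one linkage of their
  cognate type) and δ = 1 on the other homotypic linkage and mono-Ub
  (UBDs rarely have literally zero affinity for non-preferred chains). A
  zero off-target profile would be biologically unreal and would also
  concentrate baseline-level proteins asymmetrically across baits, making
  the pass-2 median anchor bait-dependent.
- **Class mix**: 70% background, 5% bead binders, 13% pan-Ub binders, 2%
  each of the six specific classes. Pan-Ub binders dominate the
  Ub-enriched fraction, as in real pulldowns — this is also what keeps the
  subset-normalization assumption valid (see above).
- **Missingness**: each present log2 cell x is masked with probability
  1/(1 + exp(β(x − γ))), γ = 22, β = 1 — left-censored, intensity
  dependent, giving realistic single-digit-percent missingness
  concentrated in low-abundance proteins. The real study reports no
  quantitative missingness figures, so these are plausibility choices,
  exposed in `sim_config`.

What the generator does *not* emulate: peptide-level effects, shared-peptide
isoform ambiguity, batch structure, correlated noise between samples, and
abundance-dependent variance. Passing recovery tests therefore demonstrates
the statistical machinery is correct under the generative model, not that
any particular real dataset will behave as cleanly.

Problem sizes used in the shipped tests and acceptance script — two
datasets of 2,000 proteins for end-to-end recovery, 5,000 proteins for null
calibration, 10⁴ draws for imputation-moment and prior-recovery checks —
were chosen to make Monte-Carlo error small relative to the tolerances
being asserted.

## SPR steady-state affinity

`fit_steady_state` fits the 1:1 binding isotherm Req = C·Rmax/(C + K_D) by
unweighted least squares (no published weighting convention exists for
these fits). Numerically, K_D is profiled on the log10 scale over
[10⁻⁴, 10⁴] µM — for fixed K_D the optimal Rmax is a closed-form linear
coefficient, bounded by 10 × max(Req) — with initialization from the
interpolated half-maximal concentration and a 7-point log-grid multi-start
as a safety net against the flat-likelihood weak-binding regime. The fitted
curve satisfies Req(C = K_D) = Rmax/2 exactly, and the estimator is
scale-equivariant in concentration; both identities are used as tests.

`extract_equilibrium` averages the final 5 s of the association phase (the
averaging window and the plateau slope tolerance are package conventions;
vendor software does not publish its settings) and flags, rather than
drops, points that have not plateaued. `fit_triplicates` fits replicates
independently and reports the mean K_D with its sample SD — matching how
triplicate affinities are conventionally reported — alongside a pooled fit.
A fit whose K_D exceeds the highest injected concentration is flagged
(`saturation_flag`): the affinity then lies outside the measured range and
the estimate is weakly constrained.

```{r spr-example}
conc <- spr_concentration_grid(top = 250, n = 13)
trip <- simulate_steady_state(KD = 0.07, Rmax = 60, concentrations = conc,
                              noise_sd = 0.5, n_rep = 3, seed = 1)
fit_triplicates(trip)
```

## Limitations

- The moderated-statistics scheme is the canonical hierarchical-variance
  model; equivalence to any particular external tool's variant is not
  claimed.
- The two-pass prefilter inherits median normalization's compositional
  assumption; datasets whose Ub-enriched fraction is dominated by
  bait-exclusive binders would need a different anchor (e.g. reference
  proteins).
- Gene-level collapse of isoforms is out of scope: each table row is one
  analysis unit.
- Kinetic (k_on/k_off) fitting of sensorgrams, heterogeneous-binding SPR
  models, and GO enrichment itself (the package only exports gene lists)
  are out of scope.
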