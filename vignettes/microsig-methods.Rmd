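---
title: "Methods: discovering group-specific microbial signatures with microsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering group-specific microbial signatures with microsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsig)
```

## The problem

Cohort microbiome surveys ask whether host attributes — here, membership in
one of several subject groups — leave a reproducible imprint on the
community. microsig implements one complete answer chain for species-level
OTU tables and t-RFLP fingerprints: standardize profiles, measure diversity,
ordinate communities, find the taxa that define a group, quantify how
predictive their mere presence is, and test whether a supervised classifier
can recover group membership. Because real cohort data of this design is
rarely shareable, the package carries a first-class synthetic-cohort
generator whose planted ground truth lets every stage be validated
end-to-end.

## The synthetic cohort model

`cohort_spec()` / `generate_cohort()` draw a cohort in two layers:

1. **Detection (richness) layer.** Every taxon t has a planted prevalence
   per group; subject i in group g contains t with probability
   p\[t, g\] (independent Bernoulli draws). Core taxa have prevalence 1
   everywhere; each group's signature taxa have `p_within` (default 0.95)
   in their own group and `p_without` (default 0.05) elsewhere; background
   taxa draw a single cohort-wide prevalence from
   `background_prevalence_range`, so only planted signatures differ between
   groups.
2. **Abundance (evenness) layer.** The abundances of the taxa present in a
   subject are a symmetric Dirichlet draw with the group's concentration
   parameter, turned into counts by allotting each detected taxon one read
   and distributing the remaining sequencing depth multinomially. One read
   per detected taxon makes observed presence equal the Bernoulli layer —
   detection is part of the design, not an artifact of depth — while
   leaving the Dirichlet evenness structure intact. Lower concentration
   means a few taxa dominate: the default gives group G1 concentration 0.3
   against 1.0 elsewhere, producing the depressed-evenness group the design
   calls for.

The two layers separately control richness and evenness, matching how
diversity indices decompose. All randomness flows from the single `seed`
through one generator stream consumed in fixed order, so identical
spec + seed is bit-reproducible.

### Default study design and what it emulates

The defaults emulate a four-ethnicity oral-microbiome survey: 4 groups × 25
subjects, 398 taxa (8 universal core, 10 signature per group, 350
background), expected depth 6336 reads per sample. Background prevalences
are uniform on (0.20, 0.40). That range was fixed by design analysis, not
data fitting: the upper bound must stay well below the 80% prevalence rule
so that, at group size 25, a background taxon essentially never crosses the
signature threshold by sampling noise (binomial tail < 1e-4 per taxon at
prevalence 0.40), and the lower bound pushes expected per-subject richness
to ≈124 taxa, inside the 149 ± 34 band such surveys report. The exact
observed mean richness of a real survey is not reachable at 398 taxa
without background prevalences so high they would masquerade as
signatures; we prioritize clean planted truth over matching one richness
moment. Per-subject richness variance is also smaller than in real data
(binomial only, no subject-level heterogeneity).

What the generator does **not** emulate: sequencing error, chimeras,
compositional correlations between taxa beyond the shared multinomial
total, taxon-abundance tails (no log-normal mega-dominants), or
subject-level covariates. A method that passes on these cohorts is
validated for its arithmetic and its operating characteristics under the
planted model — not certified to find signatures in arbitrary real data.

### Simulated t-RFLP

`random_fragment_map()` assigns each taxon an integer terminal-fragment
length in 50–1200 bp, with a configurable fraction of taxa deliberately
sharing lengths (default 10%), emulating restriction-site collisions.
`generate_trflp()` sums the relative abundances of taxa mapped to the same
length, perturbs each peak with multiplicative log-normal noise (areas must
stay positive; default sd 0.1 on the log scale) and rescales to an
arbitrary total area, as a fragment analyzer reports. Only summarized
peaks are simulated, never electropherogram traces.

## Profile standardization and the variance-stabilizing transform

`standardize_peaks()` follows the conventional two-step: convert areas to
proportions of the sample's own total, zero out peaks under `min_frac`
(default 1%, the usual noise floor), and renormalize the survivors once.
Three deliberate reading choices:

* the floor is **strict** (`p < min_frac` is removed; a peak at exactly 1%
  survives);
* filtering is per sample, against that sample's own total;
* survivors are renormalized once and **not** re-filtered, so a peak may
  legitimately sit just under the floor after renormalization.

Fractional fragment sizes are binned to integer bp on ingest with
round-half-to-even (the bp grid is a package choice; fragment software
reports fractional sizes and no canonical binning exists). Areas meeting in
one bin are summed before standardization.

`arcsine_sqrt()` applies X = sin⁻¹(√p), the classical variance-stabilizing
transform for proportions, mapping \[0, 1\] to \[0, π/2\]. Inputs within
1e-12 outside \[0, 1\] are clamped (float drift); anything further is a
domain error. `transform_matrix()` aligns samples on the union of features,
filling absent features with 0 before transforming, and refuses rows that
do not sum to 1 within 1e-6.

## Diversity, dissimilarity, ordination

Shannon diversity uses natural logarithms. The log base is a convention
choice; nats make equitability J = H/ln S self-consistent, J = 1 exactly at
perfect evenness. J is undefined (NA) for mono-species samples (ln S = 0).

Bray-Curtis dissimilarity d = 1 − 2Σmin(u,v)/(Σu+Σv) is computed on
row-normalized abundances via vegan and stored as a **dissimilarity**
(ordination consumes distances; similarity reporting is a display concern).

`nmds()` minimizes Kruskal stress-1 with monotone regression, delegated to
vegan's `monoMDS`. One start is metric (PCoA) — which alone solves exactly
embeddable configurations — and the remaining `n_restarts - 1` starts are
random; the lowest-stress fit wins, ties to the first. Convergence
thresholds are tightened (`smin = 1e-12`, `sfgrmin = 1e-14`, 500
iterations) so exact configurations reach numerically zero stress rather
than stopping at the library's looser defaults. Stress values are data- and
optimizer-dependent; the contract is reproducibility per
`(D, k, seed, n_restarts)` and best-of-restarts stress, not any particular
optimizer trajectory.

`cluster_separation()` — mean between-group minus mean within-group
dissimilarity — is this package's quantitative stand-in for "the groups
cluster in the ordination", a claim usually made visually. It is 0 in
expectation under no structure and positive under group-specific
composition.

## Prevalence, core microbiome, signatures, consortium likelihood

Presence is a per-subject detection call (`count >= 1` by default;
`abundance > 0` for pre-normalized tables — which rule was used is recorded
in the result). Prevalences are exact fractions per group and overall.

* **Core microbiome**: taxa with overall prevalence ≥ τ (τ = 1 gives the
  strict core present in every subject).
* **Group signatures**: S_g = taxa with within-group prevalence ≥ τ
  (default 80%). The **exclusive** consortium of g is the Venn region
  belonging to S_g alone; universally prevalent taxa (the core) land in
  multi-group regions and in no exclusive set.
* **Consortium likelihood**: subject s *qualifies* for group g when it
  carries strictly more than θ (default 80%) of g's consortium. L_g =
  (qualifying subjects of g) / (all qualifying subjects). Note the
  asymmetry, kept deliberately: signature membership is ≥ τ ("at least
  80%") while coverage qualification is > θ ("more than 80%"). With the
  default denominator (`"all"`) L_g ∈ \[0, 1\] and reads as a precision;
  the alternative `"others"` denominator (qualifying subjects outside g
  only) is also implemented since the field's verbal definition is
  ambiguous — it can exceed 1 and is undefined when no outsider qualifies,
  which is why it is not the default. Likewise the consortium defaults to
  the exclusive Venn set (a flag selects the full ≥ τ set): exclusive sets
  are what group-specific Venn displays present, and shared taxa carry no
  discriminating information.

On the default synthetic design the likelihoods come out at 1.0 — planted
signatures with p_without = 0.05 are near-perfectly exclusive, so any
subject covering > 80% of a consortium is almost surely from its group.
Real cohorts, with partially shared consortia, sit well below 1; the
statistic's discriminating behaviour under overlap is exercised by the
randomized oracle tests rather than the default design.

## Per-taxon group statistics

`taxon_anova()` (classical one-way fixed-effects F) and `taxon_t_test()`
(two-sided two-sample t, pooled variance by default, Welch by flag) compare
group means taxon-by-taxon on the transformed scale. Numerical policies:

* all-constant taxa report p = 1 with a `degenerate` flag instead of
  erroring, so sparse taxa never abort a run;
* perfect separation (zero within-group variance, distinct means) reports
  F = ∞ with an underflow-safe floor p = 1e-300;
* p-values are floored at 1e-300 throughout.

Raw p-values with conventional stars (0.05/0.01/0.001/0.0001) are the
primary display; `adjust_p()` adds Benjamini-Hochberg adjusted values
alongside, since hundreds of simultaneous taxon tests otherwise inflate
discoveries. Both columns are reported, clearly labelled.

## Classification

`classify_cohort()` evaluates a random forest (ranger, single-threaded,
seeded) on a stratified split. The split ratio is 75/25 by default — the
protocol is a package choice since "train, then apply to a test set"
underdetermines it — with per-group test counts by floor-then-largest-
remainder (ties to group order), and an optional repeated mode (mean ± sd
over consecutive sub-seeds) to expose split variance. Features default to
arcsine-square-root-transformed relative abundances; raw proportions and
presence/absence are flags. Sensitivity and specificity are one-vs-rest
per class — the only reading under which a single class of a multi-class
problem can have both numbers — macro-averaged over classes present in
the test set. Forest
hyperparameters stay at ranger's defaults (500 trees) and are echoed into
the report.

## Problem sizes used in the validation suite

The shipped tests run the default study design (100 × 398) for end-to-end
checks, 20 seeds for signature recovery, 10 + 20 seeds for classifier
calibration, 200 random mini-cohorts (≤10 subjects, ≤15 taxa) for exact
rational agreement of the likelihood statistic with brute-force
enumeration, and a 4 × 25-group null cohort with 1000 near-saturating
background taxa for ANOVA type-I calibration (the near-saturating
prevalence keeps transformed abundances continuous, which is what an
F-test calibration can be expected to hold for; heavily zero-inflated taxa
are not near-normal on any scale). These sizes were chosen as the smallest
that make the property bounds sharp.

## Known limitations

* The Dirichlet-multinomial abundance model is a stand-in, not a claim
  about real communities; prevalence-abundance coupling in real data is
  richer.
* NMDS stress on full-size count cohorts (~0.33 at k = 2 for the default
  design) reflects the high-dimensional planted model, which is not
  low-dimensional by construction; stress magnitudes are not comparable
  across datasets or optimizers.
* The consortium likelihood is a precision-style statistic computed on the
  same cohort the signatures were discovered in; it is optimistically
  biased and should be validated on held-out cohorts for real claims.
* Phylogenetic (UniFrac-type) metrics, rarefaction, and compositional
  log-ratio methods are out of scope.
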