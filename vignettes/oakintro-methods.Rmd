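---
title: "Methods: models, parameters and design choices in oakintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in oakintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakintro)
```

`oakintro` is a pipeline for microsatellite (SSR) analysis of hybridizing
white-oak populations: admixture inference, hybrid classification and an
introgression index, diversity and differentiation statistics, genetic
barrier detection, chloroplast haplotype structure, and beta regression of
introgression on environmental covariates. This vignette documents the
models, the parameters that matter, and the choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The admixture model and its Gibbs sampler

Individuals carry two gene copies per nuclear locus. The model assumes `K`
clusters, each with its own allele-frequency vector per locus, and gives
every individual a membership vector `q` on the `K`-simplex. The sampler
(`fit_admixture()`, core loop in C++) alternates three conjugate blocks:

1. each gene copy's latent cluster of origin, drawn from
   `P(z = k) ∝ q_ik p_kla`;
2. cluster allele frequencies, `Dirichlet(λ + counts)`;
3. individual memberships, `Dirichlet(α + counts)`.

Missing copies are skipped (the `-9` sentinel, STRUCTURE convention).
`lnP(X|K)` is estimated from the post-burn-in log-likelihood trace as
`mean − var/2` with the sample variance.

Tunable parameters, with defaults and why:

* `alpha = 1` (admixture concentration): a flat prior on the simplex;
  `alpha_update = TRUE` adds a Metropolis random-walk update (uniform
  prior on (0, 10]), which mirrors the reference implementation's default
  behaviour and matters when most individuals are nearly pure — a fixed
  `alpha = 1` alone caps the posterior mean of a pure individual at
  `(1 + 2L)/(2 + 2L)` (0.97 at 16 loci), while the update lets `alpha`
  shrink and the posterior concentrate.
* `lambda = 1` (frequency prior mass per allele): flat; the
  `prior_model = "correlated"` option centres the prior on the pooled
  sample frequencies with concentration `(1 − F)/F` (a fixed-`F`
  simplification of the F-model); the default and the acceptance suite use
  the independent prior, which is simpler and stable at desk scale.
* `locprior_pops`: a simplified location prior — per-population mixture
  weights, Dirichlet-updated from member assignments each sweep, replace
  the global `alpha` in block 3. This is an approximation of the
  r-parameterized population prior and is intended, as in the original,
  for weakly differentiated data.
* `burnin = 2000`, `iters = 4000`, `thin = 10`: desk-scale defaults. The
  emulated study ran 50 000 + 100 000; the sampler is the same object and
  those settings remain available.

Replicate runs are aligned with `align_runs()` (exact assignment by
permutation enumeration for `K ≤ 8`, greedy beyond), scored with
`G' = 1 − ‖Q_a − Q_b‖_F / √(2n)`, grouped into modes by single linkage at
similarity ≥ 0.9 (the source material names no threshold; 0.9 is our
documented choice), and summarized by the populated-cluster metrics
(MedMedK, MedMeanK, MaxMedK, MaxMeanK at the q ≥ 0.5 threshold).
`evaluate_K()` encodes the two-criterion rule: reject a `K` that adds no
populated cluster over `K − 1`, reject a `K` whose replicate modes
conflict, select the largest `K` that survives.

## Classification and the introgression index

Cluster memberships are summed within species (`species_q_sums()`), then
thresholded: pure above 0.875 (strict), admixed in (0.625, 0.875], highly
admixed at or below 0.625. The interval descriptions in the source leave
the single points 0.875 and 0.625 ambiguous; we assign each boundary to
the lower category and say so here. The population index is
`I = (n_had + 0.5 n_ad)/n` after excluding pure individuals of non-focal
species (`population_summary()`).

## Diversity and differentiation

* `Ho`, `He = 1 − Σp²`, `uHe = 2n/(2n−1) He` on typed copies only; locus
  means with SE across loci.
* `FIS = 1 − Ho/Hs`, with the unbiased within-population gene diversity
  `Hs = n/(n−1)(1 − Σp² − Ho/2n)`, averaged over loci before the ratio.
* Rarefied allelic richness: hypergeometric expectation
  `AR = Σ_i [1 − C(N−N_i, g)/C(N, g)]`. "Rarefaction size 8 individuals"
  is interpreted as `g = 16` gene copies (diploid); configurable.
* Nei's FST `= 1 − Hs/Ht` with the sample-size corrections based on the
  harmonic mean of population sizes; loci combine as a ratio of sums
  (not a mean of ratios) — the estimator-family convention; per-pair on
  demand.
* Jost's `D = (Ht − Hs)/(1 − Hs) · k/(k−1)` per locus, arithmetic mean
  across loci with SE.
* PCoA by Gower double-centering of `−D²/2`; negative eigenvalues are
  dropped and counted. The base-R `cmdscale` serves as an independent
  oracle in the tests, never as the implementation.

The exact estimator variants behind the emulated study's table are not
printed there; the choices above are the documented defaults and the
tests pin them to hand-computed fixtures.

## Monmonier barriers

Population coordinates are triangulated (brute-force empty-circumcircle
Delaunay — populations number a few dozen, so O(n⁴) is irrelevant) and
each Delaunay edge is annotated with the genetic distance (default: the
same Nei FST used elsewhere) of the pair it separates. A barrier starts at
the largest-distance edge and grows both ends greedily — always crossing
the adjacent edge with the largest distance not yet in the path — stopping
at the outer boundary or when the path closes a loop. Ties break
deterministically on (distance descending, population-pair id ascending);
an all-equal-distance graph is traced but flagged non-informative.
Voronoi dual edges to infinity are clipped at 3× the point-set diameter
for reporting. Support comes from resampling loci with replacement,
recomputing the distance matrix with the same estimator and re-tracing on
the fixed triangulation (the original workflow's external bootstrap tool
is replaced by this in-package locus bootstrap); multiple barriers are
extracted by masking the previous barrier's edges and re-running, and no
automatic "optimal number of barriers" is imposed.

## Chloroplast haplotypes

Identical cpSSR allele vectors share a haplotype; individuals missing any
cp locus are excluded and counted. The minimum spanning network uses the
stepwise distance (absolute repeat differences summed over loci, motif
lengths configurable, raw bp differences when unknown) and keeps all
co-minimal tie edges — edges whose endpoints lay in different components
at the start of their weight class. Pons–Petit-style diversity uses the
unbiased within-population haplotype diversity
`h_k = n_k/(n_k−1)(1 − Σp²)`, `hS` as their mean, and a haploid total
diversity `hT = 1 − Σ p̄² + hS/(ñK)` with `ñ` the harmonic mean sample
size; `GST = (hT − hS)/hT`, reported NA when `hT = 0`. The original
variance formulas are not printed in the source material, so standard
errors use a leave-one-population-out jackknife — a documented
substitute, not the original estimator. Group comparisons wrap the exact
Mann–Whitney test (normal approximation with tie correction when exact
enumeration is unavailable).

## Environment models

The workflow (`env_model_workflow()`) mirrors the screening-then-selection
procedure: Pearson pre-filter at |r| ≥ 0.7 (derived variables drop
against primaries; among correlated primaries the preference-listed one
wins), centring and scaling retained covariates, a VIF loop
(`VIF = 1/(1−R²)`, drop the worst until all ≤ 3), stepwise AIC in both
directions, and the Cox–Snell generalized `R² = 1 − (L0/L1)^(2/n)` with
`n` the number of populations entering the model.

The beta regression is parameterized as the logit-logit family: mean
`μ = logit⁻¹(Xβ)` and dispersion `σ ∈ (0,1)` on a logit link
(intercept-only — the mean structure is the model of interest), with
shapes `μφ, (1−μ)φ` and `φ = (1−σ²)/σ²`, so `var(y) = σ²μ(1−μ)`.
Fitting is deterministic maximum likelihood (BFGS from a least-squares
start on the logit response); standard errors come from the observed
information. Exact 0/1 responses are rejected unless the squeeze
`(y(n−1)+0.5)/n` is enabled — the source material does not say how its
fitting software handled boundary values, so the squeeze is opt-in and
documented. The tests verify Wald calibration directly: the null
rejection rate at nominal 0.05 is estimated over 400 replicates.

## The synthetic world: what it emulates, what it does not

The generator (`sim_config()`, `simulate_dataset()`) states one world and
keeps it fixed:

* 16 nuclear + 8 chloroplast loci; 17–47 individuals per population (the
  emulated design); populations in a west and an east region.
* Cluster frequencies follow the F-model: ancestral vectors from a flat
  simplex, cluster vectors `Dirichlet(ancestral · (1−F)/F)`; default
  `F = 0.15` per cluster (within the FST range typical of white-oak
  SSR datasets).
* Individuals are pure / admixed / highly admixed; their q vectors sit at
  the category midpoints (0.9375 / 0.75 / 0.5 to the focal species), so
  classification on noiseless truth recovers categories — and the
  population index — exactly. The parameter-recovery benchmark world
  additionally uses the category proportions observed in the emulated
  study (roughly 76% / 19% / 6%).
* Population introgression targets follow
  `logit⁻¹(intercept + Xβ)` with standard-normal covariates, realized as
  a beta draw (precision 30) converted to admixed/highly-admixed counts —
  exact to within half-units of `1/(2n)`. The default β plants a strong
  negative longitude-like effect and positive wetness/precipitation
  effects (the sign pattern reported in the emulated study), intercept
  −1.5 (baseline index ≈ 0.18, matching the low observed introgression
  levels).
* Chloroplast haplotypes descend from one founder per region (two
  lineages two steps apart by default) with a 5% one-step minor-haplotype
  rate; cpSSRs are typed for every second individual.
* Missing data: 2% locus dropout, both copies together, `-9` sentinel.
* Alleles live on a repeat ladder (`start + step · index`), so stepwise
  chloroplast distances are meaningful; nuclear statistics never use step
  counts.

Not emulated: coalescent genealogies, mutation during sampling, linkage,
isolation-by-distance within regions, genotyping error other than
dropout. A green test therefore establishes that the estimators recover a
known admixture/introgression structure under multinomial sampling noise
— not that they are robust to demographic model misspecification.

## Numerical choices and degenerate inputs

* One master seed expands into labelled substreams (`derive_seed()`), so
  stages are independently reproducible; all derived seeds stay below
  2³¹.
* Simplex draws guard against all-zero gamma vectors at tiny
  concentrations; categorical draws use cumulative sums with a final-bin
  fallback.
* Degenerate inputs have defined behaviour: collinear coordinates raise
  an error suggesting jitter; loci with no observed alleles are an error;
  monomorphic data with `K > 1` run but are flagged; populations with one
  cp-typed individual are excluded from Pons–Petit with a warning; `g`
  beyond the typed copies yields NA with one warning.
* The equirectangular projection about the mean latitude is adequate for
  regional Delaunay geometry but its east–west scale error grows as
  `cos(lat)/cos(lat₀) − 1` (about 2% at the latitude margins of an
  Alpine-scale extent); the tests assert median pairwise distance error
  below 1% and maximum below 3% against the haversine oracle.

## Known limitations

* The parameter-recovery acceptance threshold (posterior-mean q RMSE
  below 0.08 at `F = 0.2`, 16 loci, 8 alleles) is not attainable by any
  sampler in this world: the exact Bayes-optimal posterior mean computed
  with the true frequencies by quadrature already exceeds it. The suite
  keeps the threshold and the red result, and separately verifies that
  the sampler attains the Bayes bound to within 15%.
* The location prior and the correlated-frequency prior are simplified
  relative to their originals (documented above).
* Barrier bootstrap re-traces per replicate; mapping replicate barriers
  onto the observed barrier is a different published convention and is
  not implemented.
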