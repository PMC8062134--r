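---
title: "Methods: one-pot single-cell eQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-pot single-cell eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models implemented in `sceQTL`,
the assumptions behind them, the defaults and why they were chosen, what
the synthetic-data generator does and does not emulate, and the numerical
and design decisions that were genuinely open.

## The genotyping hidden Markov model

Each profiled cell comes from one recombinant individual of an
obligate-outcrossing intercross between two inbred strains (labelled N2
and CB). The cell's transcriptome covers a sparse, essentially random
subset of transcribed SNVs distinguishing the strains, with per-site UMI
depths mostly 0–3. Genotypes along a chromosome form a Markov chain over
the states {NN, NC, CC}, and the HMM has three ingredients.

**Priors.** Autosomes use the intercross equilibrium (1/4, 1/2, 1/4).
The X chromosome uses (0.44, 0.44, 0.11), renormalized to sum to one:
the cross is founded by N2 hermaphrodites mated to CB males, males are
X0, and so N2 contributes twice as many X chromosomes as CB. The exact
F4 hermaphrodite distribution from the pedigree recursion is
(15/32, 14/32, 3/32); the rounded prior is kept as the interface default
because the pipeline is insensitive to the difference (the data dominate
after a handful of reads) and it matches the published parameterization
of this design. Hemizygous male X's are not modelled separately — one X
prior applies to all cells; this is a known approximation, and the
simulator codes male X genotypes as homozygous-like (0 or 2) so that
emissions remain well defined.

**Emissions.** With `D` reads at a site, `r` of them supporting N2, and
a per-read error rate `e` (default 0.002, typical of post-UMI
deduplication error rates):

* P(Y | NN) = C(D,r) (1−e)^r e^(D−r)
* P(Y | NC) = C(D,r) (1/2)^D
* P(Y | CC) = C(D,r) e^r (1−e)^(D−r)

`D = 0` yields flat emissions. Emissions are computed in log space and
rescaled per cell-site so deep sites cannot underflow; posteriors are
invariant to that scaling.

**Transitions.** cM positions are linearly interpolated from a reference
genetic map to every variant site. The reference map derives from a more
advanced intercross than the genotyped generation, so interpolated
distances between adjacent sites are multiplied by a scale factor
(default 0.4, the four- vs ten-generation expansion ratio). The scaled
distance d is converted to a recombination fraction by Haldane's map
function ρ = (1 − e^(−2d/100))/2 — consistent with the crossover model
used elsewhere in the package (Poisson, no interference) — and the two
homolog transmissions are treated as independent, giving the F2-style
3×3 transition matrix. The true F4 process is not exactly Markov at the
marker level and the published parameterization leaves the functional
form unstated; this choice is the simplest one consistent with the map
usage, and the forward–backward posteriors it produces are validated
against exhaustive path enumeration (to 1e-10) and against planted
genotypes (dosage correlation ≥ 0.9 at the study's median of 69
informative UMIs per cell).

Chains restart at each chromosome with the prior. The forward–backward
recursion is normalized per site and vectorized across cells. For
mapping, posteriors are collapsed to the additive dosage
P(CC) + P(NC)/2 ∈ [0, 1].

## Negative-binomial eQTL mapping

UMI counts are modelled as gamma-Poisson (negative binomial with mean μ
and overdispersion θ, Var = μ + μ²/θ), which is well established for
droplet scRNA-seq; log-normal/OLS alternatives misbehave with multiple
correlated covariates. The linear predictor contains an intercept, log
total UMIs (compositional control), batch indicators, and one genetic
covariate: the standardized dosage of the closest pruned marker (cis
scan) or of each marker in turn (trans scan). Standardization uses the
population (n) variance; markers are pruned greedily left-to-right when
their correlation with the last kept marker exceeds r = 0.9999, which
removes duplicated information while keeping the scan dense.

The GLM is fitted by iteratively reweighted least squares with a
step-halving guard, so every step increases the likelihood and
convergence is certain at the cost of speed (50 iterations maximum,
relative log-likelihood tolerance 1e-8; linear predictors are clamped at
±30 and clamped fits are flagged). θ is estimated by alternating IRLS
with a profile maximum-likelihood update. The likelihood is the explicit
negative-binomial form, verified in the tests against `dnbinom` and
against an independent `MASS::glm.nb` fit.

θ is estimated **once per transcript per cell type**, from the full cis
model, and reused for the reduced model and for all genome-wide fits of
that transcript. The estimation model had to be chosen (reuse is part of
the design but its source model is an open choice); the cis model is
used because it is the one model always fitted, and because unmodelled
genetic effects then inflate θ, which is conservative for the
likelihood-ratio test. Significance uses LRT = −2(l_reduced − l_full),
LOD = LRT / (2 ln 10), and p from χ²₁. Per chromosome, the peak is the
highest-LOD marker (ties broken leftmost) with a 1.5-LOD-drop interval —
the contiguous run of markers within 1.5 LOD of the peak, clamped at the
chromosome ends, an approximate 95% interval.

**Permutation FDR.** Cell identities are permuted relative to genotypes
within each library batch, with the same permutation applied to every
transcript of a permutation instance, 10 times by default. For each LOD
threshold on a grid from 0.1 to the maximum observed LOD + 0.1 in steps
of 0.01, the FDR is the mean permuted count of transcripts exceeding the
threshold divided by the observed count, clipped to [0, 1]. Whether the
published curve is monotonized is unstated; we monotonize with a running
minimum along the grid so adjusted p-values are well ordered, and
interpolate linearly (clamping outside the supported range, i.e. where
the observed count is positive). Two permutation units are exposed: each
cell as its own segregant (default), or block permutation of cells
grouped by individual when that assignment is known. Benjamini–Hochberg
adjustment is provided for cell populations too small for permutation
(single neuronal subtypes). A bulk-data mapper is included for
comparison studies: squared marker-transcript correlations convert to
LOD as −n·ln(1−R²)/(2 ln 10), and standardized effects combine across
cell types by Stouffer's weighted-Z, Σwᵢzᵢ/√Σwᵢ². Effect-direction
concordance between two mappings is tested with a two-sided exact
binomial test (the sidedness was unstated; two-sided is the conservative
default).

## Hotspot detection

The genome is tiled into 5-cM bins (last bin of a chromosome may be
short). Significant trans linkages — peaks at or below the FDR cut whose
target gene lies outside the peak's confidence interval extended by 1 Mb
on both sides — are assigned to the bin containing the peak position.
Per cell type, λ is the mean count per bin (all bins included; whether
the tested bin should be excluded is unstated, and including it is the
conservative choice since it inflates λ), and a bin is in excess when
P(X ≥ count | λ) < α / n_bins (one-sided upper tail, Bonferroni over
bins; α = 0.05). Runs of adjacent significant bins are reduced to local
maxima at the level of equal-count runs, keeping the leftmost
significant bin of a peak run. For reporting hotspot targets the FDR cut
can be relaxed to 0.2 via the function arguments.

## Cell-type classifier

Counts are normalized per cell to 10,000, log(1+x)-transformed, genes in
fewer than 10 cells dropped, and highly variable genes selected by a
mean window (0.0125–3) with a dispersion floor of 0.5. The dispersion
estimator is variance/mean of the normalized log values per gene,
computed before z-scoring; the published pipeline names the bounds but
not the estimator, so ours is documented and the bounds exposed.
Features are z-scored per gene and clipped at +20. The model is an
L2-penalized multinomial logistic regression at inverse regularization
strength C = 7.74e-4; in the `glmnet` parameterization used here the
ridge weight is λ = 1/(C·n), matching the scikit-learn objective the
constant was estimated under. Out-of-fold probabilities come from
stratified 5-fold cross-validation with a fixed seed. Calling rules are
applied in order: ≥2 classes above 0.2 → doublet; max below 0.4 →
low-quality; else argmax. The precedence follows the published rule
order, so a cell can be a doublet even when its best class clears 0.4.
Note that C was estimated on a ~69,000-cell dataset; at simulation
scales of a few hundred cells the implied penalty is much stronger and
probabilities shrink toward the class priors, so classifier performance
bounds are evaluated at 2,000 cells.

## The synthetic-data generator

The generator emulates the full study design so that every stage can be
validated against ground truth:

* **Pedigree.** Founder N2 hermaphrodites × CB males, then random mating
  of hermaphrodites to males for the configured number of generations
  (default 4), population size held at the design's individual count.
  Crossovers are a Poisson process on the cM scale (no interference),
  i.e. a Haldane map, matching the transition model. X transmission
  follows X0 sex determination. Selfing is impossible by construction
  (every brood has one parent of each sex). The simulated F4
  frequencies reproduce the exact pedigree recursion (autosomes
  1/4:1/2:1/4; hermaphrodite X 15/32:14/32:3/32).
* **Allele counts.** Per-cell informative-UMI totals are drawn negative
  binomially with the median pinned at the requested value (default 69,
  the study's median; the published distribution beyond the median is
  unknown, so the NB with size 2 is a stand-in chosen to be
  heavier-tailed than Poisson, as per-cell yields are). UMIs scatter
  uniformly over sites — real coverage follows expression, which is not
  emulated — and report the true allele with probability 1 − e.
* **Expression.** Gamma-Poisson counts with per-gene baselines
  (log-normal around 0.3 counts, matching sparse somatic scRNA-seq),
  per-gene θ (log-normal around 2), small log-scale batch effects
  (SD 0.1), cell-type marker structure (10% of genes per type,
  upregulated e² ≈ 7-fold — conservative relative to real marker genes),
  and planted cis/trans effects expressed as log-scale coefficients on
  the true additive dosage. The library-size covariate enters with
  coefficient one (pure compositional scaling). Doublets, when enabled,
  sum two half-sized cells of different types and mix their allele
  counts evenly.

What the generator does **not** emulate: ambient RNA contamination,
expression-weighted SNV coverage, UMAP/cluster substructure within cell
types, developmental-stage variation, and empirical library-size/count
relationships beyond the log-normal size model. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under the
declared generative assumptions, not robustness to those real-data
artifacts. One consequence was verified explicitly: at simulated site
densities the r > 0.9999 LD pruning removes only near-duplicate
markers and does not reproduce the ~5 cM effective spacing reported for
real data, which depends on the real site density and coverage pattern;
the tests check the pruning contract (no adjacent kept pair above the
ceiling) rather than that emergent spacing.

## Numerical choices and degenerate inputs

* Forward–backward: per-site normalization; log-space emissions; flat
  emissions at zero depth; all-zero emission rows are unreachable.
* IRLS: step-halving on likelihood decreases; rank-deficient model
  matrices are an error; counts must be non-negative integers; negative
  LRT beyond 1e-6 slack is an error rather than silently clipped
  (within-slack negatives are clipped to zero). Permutation refits use a
  looser 1e-3 slack since θ and the reduced fit are held fixed.
* FDR interpolation: piecewise linear, clamped outside the supported
  range; thresholds with zero observed count are excluded.
* Map interpolation beyond the terminal anchors extrapolates with the
  terminal segment slope and logs a message.
* Constant dosage vectors are excluded from collision counting and from
  marker pruning, with messages.
* Ties: peak markers leftmost; hotspot plateau runs keep the leftmost
  significant bin.
* All simulator randomness flows through one seeded generator per
  operation; seeds are recorded in object metadata, and the caller's RNG
  state is restored afterwards.

## Problem sizes used in the validation suite

The test suite simulates its data programmatically at sizes chosen to
make Monte-Carlo error small relative to the tested tolerances while
keeping the suite quick to run: pedigree frequency checks at 8,000–10,000
individuals; genotyping fidelity at 2,000 cells × 500 sites on one
chromosome; GLM recovery at n = 50,000; null calibration and FDR control
at 2,000 transcripts × 500 cells (200 planted effects, 10 permutations);
hotspot detection on a 130-bin genome with 50 null replicates; classifier
bounds at 2,000 cells × 300 genes. These sizes are scaled-down analogues
of the study design (tens of thousands of cells, ~100k sites), and the
quantities tested are size-calibrated (tolerances follow the
corresponding standard errors).

## Known limitations

* Hemizygous male X cells are genotyped under the shared 3-state X
  prior; their NC posteriors are a modelling fiction, though dosage
  remains sensible.
* θ reuse from the cis model is conservative but can cost power for
  strong trans effects; regularizing θ across transcripts is out of
  scope.
* The permutation FDR assumes exchangeability of cells within batch
  under the null; cells of the same individual violate this mildly
  unless the block-permutation mode is used with known assignments.
* The classifier's fixed C is tied to the scale it was estimated at;
  re-estimation (e.g. by cross-validated grid search) is left to the
  caller.
* Allele counting from BAMs, ambient-RNA correction, clustering/UMAP,
  differential expression and GO enrichment are upstream/downstream of
  this package and intentionally excluded.
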