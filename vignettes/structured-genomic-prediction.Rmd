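---
title: "Genomic prediction in structured germplasm: model, simulator, and designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in structured germplasm: model, simulator, and designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Germplasm collections of selfing crops such as the common bean (*Phaseolus
vulgaris* L.) are strongly structured: accessions fall into two deeply
diverged gene pools (Andean and Mesoamerican), and within each pool into
genetically diverse landraces and diversity-narrowed breeding lines.
Genomic prediction (GP) ranks candidate material by its genomic estimated
breeding value (GEBV), computed from genome-wide markers and a model
trained on phenotyped accessions. In a structured collection the
composition of the training set is as important as its size: which pool
the training accessions come from, and whether relatives of the
candidates are represented, drives the predictive ability.

structgp implements this workflow end to end — an exact REML RR-BLUP
solver, the marker-quality filters, cross-validation designs over
training-population size and marker number, gene-pool combine/assign
designs, and training-set optimization scenarios that add breeding lines
to landrace training sets — together with a cohort simulator that
reproduces the statistical structure such a collection exhibits, so the
whole pipeline is testable without access to any particular collection.

# The mixed model

`rrblup()` fits the single-random-effect model

$$ y = X\beta + Zu + \varepsilon, \qquad
   u \sim N(0, I\sigma_u^2), \qquad
   \varepsilon \sim N(0, I\sigma_e^2), $$

with $y$ the $N$ training phenotypes, $X$ a fixed-effects design
(intercept-only by default) and $Z$ the $N \times M$ column-centered
genotype matrix. All marker effects share one variance — ridge regression
with the penalty $\lambda = \sigma_e^2/\sigma_u^2$ chosen by restricted
maximum likelihood (REML) rather than by cross-validation.

Two modelling points deserve note. First, the residual variance is a
distinct parameter $\sigma_e^2$: a model in which the residuals shared
the marker-effect variance would have a single variance component and
could not calibrate shrinkage, so two components are always estimated.
Second, the fixed-effect design cannot literally be an identity matrix
for $N$ observations (that would leave no residual degrees of freedom);
the default is an intercept column, and any full-column-rank $X$ is
accepted. We deliberately add no further fixed effects.

## REML by spectral decomposition

The restricted likelihood is the likelihood of the error contrasts
$Q^\top y$, where $Q$ is an orthonormal basis of the complement of
$\mathrm{col}(X)$. With one random effect it profiles down to a
one-dimensional function of $\lambda$: after a single eigendecomposition
of $Q^\top Z Z^\top Q$, each likelihood evaluation costs $O(N)$. The
optimum of $\log\lambda$ is bracketed on a 41-point grid over $[-10, 10]$
and refined by Brent's method to tolerance $10^{-8}$; an optimum pinned
against the bracket is clamped and flagged (`boundary = TRUE`). The
bracket spans variance ratios from $e^{-10}$ to $e^{10}$, far beyond any
ratio a real trait produces; hitting it means the data carry essentially
no (or only) genetic signal. At the optimum, $\beta$ is the GLS estimate
and the marker effects are the BLUP
$\hat u = Z^\top (ZZ^\top + \lambda I)^{-1}(y - X\hat\beta)$, identical
to the ridge solution with penalty $\lambda$. An all-zero $Z$ (or a
constant $y$) short-circuits to ordinary least squares with $u = 0$ and a
warning or flag, since $\lambda$ is then unidentified.

GEBVs for new accessions are $Z_{\text{test}}\,\hat u$, with
$Z_{\text{test}}$ encoded using the *training-set* imputation and
centering constants (`genotype_encoder()` retains them). The
marker-effect form and the kernel (GBLUP) form
$K_{\text{test,train}} (K + \lambda I)^{-1} (y - X\hat\beta)$ are
algebraically identical; the test suite verifies this identity to
$10^{-8}$, and verifies the REML optimum against a brute-force
likelihood grid computed through determinants rather than the spectral
shortcut.

The experiment drivers use an internal multi-trait path
(`rrblup_engine`) that shares the per-training-set decompositions across
traits — one genomic kernel and two eigendecompositions, then $O(N^2)$
per trait. It is unit-tested to agree with per-trait `rrblup()` fits.

## Genotype coding

The common bean is highly self-pollinated, so genotypes are inbred-coded
$\{0, 1\}$ — two homozygote classes, no heterozygotes. `read_vcf()`
treats a `0/1` call as missing by default (for inbred material it is most
likely a genotyping artifact); the `het = "dosage"` option codes
$\{0, \tfrac12, 1\}$ instead, and the solver accepts either, since it
only sees the centered matrix.

# The cohort simulator

`simulate_cohort()` generates the structure the analysis assumes, with
defaults fixed to the composition of the motivating collection: 628
accessions = 484 landraces (223 Andean + 261 Mesoamerican) + 144
breeding lines (60 Andean + 84 Mesoamerican), 10,000 SNPs assigned to 11
chromosomes in contiguous blocks.

* **Divergence.** Per marker, an ancestral frequency is uniform on
  $[0.05, 0.95]$; each pool's frequency is a Balding–Nichols draw,
  $p_{\text{pool}} \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},
  (1-p)\frac{1-F}{F}\right)$. This gives a single interpretable $F_{st}$
  knob; the test suite confirms with an independent Hudson estimator
  that the realized divergence matches it. The default `fst = 0.4`
  reflects the deep differentiation between the Andean and Mesoamerican
  pools; at `fst = 0` the pools are exchangeable and all two-pool
  statistics sit at their permutation null.
* **Landraces** are i.i.d. Bernoulli draws from their pool frequency —
  diverse material, exchangeable within a pool.
* **Breeding lines** are selfed inbred progenies of biparental crosses
  among a founder subset of the pool
  (`max(2, round(founder_fraction * n_breeding))` founders; default
  fraction 0.5). This produces *heterogeneous* pairwise kinship — lines
  sharing a parent are mutually much closer than unrelated pool members —
  which is the property that makes adding half the breeding lines to a
  training set genuinely improve prediction of the other half. A pooled
  drift model (drawing all lines from one drifted frequency vector) was
  rejected: it shifts the whole cluster by a common offset, and Pearson
  correlation is invariant to shifts, so it cannot express the value of
  relatives in the training set.
* **Phenotypes.** `simulate_phenotypes()` samples `n_qtl` causal markers
  (default 100 — polygenic enough for ridge shrinkage to be the right
  model, small enough that individual QTL matter), i.i.d. standard-normal
  effects, and Gaussian noise scaled to the realized genetic variance so
  that $\mathrm{var}(g)/\mathrm{var}(y) = h^2$ (default 0.5) in
  expectation; `h2 = 0` and `h2 = 1` give pure noise and the noiseless
  genetic value exactly. `simulate_trait_panel()` repeats this for a
  multi-trait evaluation (the motivating study scores 15 traits on one
  cohort).
* **Missingness** is completely at random at `missing_rate` (default 0).

What the simulator does *not* emulate: linkage disequilibrium (markers
are independent given pool frequencies — none of the analyses tested
here require LD), genotype-by-environment interaction, dominance or
epistasis, pool-specific QTL effects, and pedigree depth beyond one
generation of crossing. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative behavior of the designs
under additive architecture with population and family structure — not
predictive abilities transferable to any real collection.

# Filtering, subsampling, encoding

`filter_markers()` applies the two marker-quality rules jointly, as
simultaneous VCFtools-style flags: retain a marker only if MAF $> 5\%$
**and** missing fraction $< 50\%$, both *strict* inequalities exactly as
conventionally printed (a marker at exactly 5% MAF or exactly 50%
missing is removed). MAF is computed on non-missing calls. The operation
is idempotent and order-preserving.

`subsample_markers()` reduces the marker set to a target count in
proportion to per-chromosome marker numbers. Since proportionality alone
does not define a rounding rule, quotas use largest-remainder
apportionment — quotas sum exactly to the target, ties in remainder break
by chromosome order — and only the within-chromosome draw consumes
randomness.

Missing calls are mean-imputed per marker and columns centered on the
same constant, so imputed cells sit exactly at zero in the encoded
matrix. Test accessions are always encoded with the training-set
constants; an accession identical to a training accession encodes to an
identical row regardless of which side of the split it is on.

# Evaluation

Predictive ability is the sample Pearson correlation between GEBVs and
observed phenotypes in the testing set, computed per replicate and then
averaged (never pooled across replicates). Degenerate inputs error
rather than being silently dropped.

`topk_overlap()` measures whether the model puts the right accessions at
the top: the fraction shared between the top $k$ by prediction and the
top $k$ by observation. The top-30% form converts the fraction to
$k = \max(1, \mathrm{round}(0.3\,n))$, rounding half away from zero.
"Top" defaults to descending (larger is better) with a per-trait
override, since for traits such as days-to-flowering smaller values may
be preferable. Ties break by the stable accession order, making the
statistic deterministic; under independent rankings its expectation is
the hypergeometric mean $k/n$, which the tests verify by simulation.

# Experiment designs

* **CV grid** (`run_cv_grid()`): for each (population fraction, marker
  count) cell and replicate, the landrace set is subsampled to the
  fraction *first*, markers are drawn, and ten-fold cross-validation runs
  within the subsample. We read "population size" as the effective
  training+testing pool, which makes the fraction axis a true
  training-set-size gradient. One r per replicate is computed on the
  pooled held-out predictions of all folds (a per-fold-average option
  exists); the cell reports the mean over replicates.
* **Optimum** (`find_optimum()`): the plateau rule — the cheapest cell
  (smallest fraction, then smallest marker count) within an absolute
  tolerance (default 0.01) of the grid maximum. "No further significant
  improvement" names no statistical test, so an explicit tolerance is
  the transparent choice.
* **Pool designs** (`run_pool_prediction()`): the five combine/assign
  designs (An+M→An+M, An+M→An, An+M→M, An→An, M→M), each one
  deterministic fit plus predictive ability and the overlap ratios.
* **Scenarios G1–G8** (`run_scenarios()` on a `make_split_plan()`):
  within each pool the breeding lines are split into random halves
  (30/30 Andean, 42/42 Mesoamerican under the default composition); G1–G6
  measure the gain from adding the same-pool and cross-pool halves to the
  landrace training set, G7 versus G8 compares by-pool selection of the
  added half against fully random selection. The random half-split is
  drawn from the same seed stream as the by-pool split so the two are
  paired. Training (including additional) and testing sets are asserted
  disjoint in every design; overlap aborts the run.

# Numerical choices and problem sizes

Reproducibility is seeded everywhere: the simulator, the split plans,
and every CV cell/replicate derive independent streams from the
user-supplied seeds. PCA signs are fixed by forcing the
largest-magnitude loading of each component positive. The $\lambda$
search uses bracket $[-10, 10]$ on the log scale with tolerance
$10^{-8}$.

The shipped test suite and the analysis script exercise the pipeline at
deliberately desk-sized problems — cohorts of a few hundred accessions
and 400–2,000 markers, CV grids with 3–10 replicates, 20-seed replication
for stochastic orderings — sizes at which every statistical property they
assert is already well resolved. The heritability-recovery check uses
200 replicates at $N = 300$, $M = 1000$; the scenario-ordering check uses
20 cohorts with 15-trait panels at `founder_fraction = 0.3`,
$h^2 = 0.6$. Scaling any of these up only tightens the Monte-Carlo
bands.

# Known limitations

* REML is exact but dense: fitting cost is $O(N^2 M + N^3)$ per training
  set, comfortable for collection-scale data ($N$ in the hundreds to low
  thousands) and not intended for biobank scale.
* Marker effects carry no standard errors; the package reports point
  GEBVs and variance components only.
* No multi-kernel, Bayesian-alphabet, or G×E models; GBLUP is used as an
  internal identity check, not as a separate user-facing model.
* The stratified-versus-random contrast (G7 vs G8) is a small effect
  under exchangeable family structure; single random splits can land on
  either side of it, which is why `run_scenarios()` reports per-group r
  for whatever split plan it is given rather than claiming significance.
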