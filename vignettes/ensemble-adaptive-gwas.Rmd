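---
title: "Ensemble fitting and adaptive design for binned-genotype GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble fitting and adaptive design for binned-genotype GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minegwas)
```

## The problem

A genome-wide association study in a crop panel typically has far more
markers than plants: a few hundred accessions measured for a quantitative
trait against hundreds of thousands of SNPs. Single-marker scans ignore
epistasis and carry linkage disequilibrium (LD) implicitly, and classical
experimental design assumes more observations than effects. `minegwas`
takes a different route, developed for adaptive multi-season studies in
*Sorghum bicolor*:

1. **Bin the genome.** Adjacent SNPs are collapsed left-to-right into
   chromosomal regions of at least 50 kb (the "sum method"). LD in a highly
   selfing species such as sorghum (selfing rate about 0.85) decays over
   roughly 3.5–35.5 kb, so distinct bins escape linkage-driven LD and one
   joint model over all bins becomes meaningful. Each design-matrix entry
   is the accession's mean reference-allele dosage over the bin's
   non-missing SNPs, a number in [0, 1].
2. **Fit an ensemble, not a point estimate.** With bins as columns of a
   design matrix $X$, the trait model is $Y = X\beta + \varepsilon$
   (fixed effects) or $Y = X\beta + Zu + \varepsilon$ (mixed). A
   Hamiltonian $H$ measures misfit, the Boltzmann weight
   $Q(\beta, X) \propto e^{-H}$ defines a distribution over parameter
   vectors, and a customized Metropolis random walk accumulates $M$
   parameter vectors from it. The ensemble represents everything the data
   do and do not constrain — the natural currency when $n < p$.
3. **Choose the next experiment.** Given candidate accessions, the
   ensemble predicts each candidate's trait value once per stored
   parameter vector. The covariance (or correlation) matrix of those
   predictions over the ensemble has a determinant that measures the
   prediction-uncertainty ellipsoid volume; the panel maximizing it is the
   maximally informative next experiment. Four selectors search the
   combinatorial space.
4. **Select features.** Chromosomal regions associated with the trait are
   filtered from the ensemble by three complementary rules (projection,
   Bayesian interval, Benjamini–Hochberg), and the survivors mapped to
   genes through a local GFF3 annotation.

## Models and Hamiltonians

For the fixed-effects model the Hamiltonian is the $V$-weighted sum of
squared errors
$$H(\beta) = (Y - X\beta)' V^{-1} (Y - X\beta),$$
with $V$ held fixed and block diagonal at the per-accession sample
variances of the trait ([`v_fixed()`]). Accessions with a single
observation, or with sample variance below a floor of $10^{-6}$ trait
units$^2$, take the pooled within-accession variance so $V$ stays
invertible. Note there is no factor $\tfrac12$: the stationary ensemble
therefore has covariance $\tfrac12 (X'V^{-1}X)^{-1}$, half the sampling
covariance of the GLS estimator — a property asserted directly in the
tests.

For the mixed model the accession variance components become parameters.
Writing $G = XX'$ for the prediction-similarity (Gram) matrix of the
plant-level design, the observation covariance is assembled from one
rank-1 term per observation,
$$V = \sum_{i=1}^n (X x_i)(X x_i)'\, \sigma^2_{j(i)} + \sigma^2 I
     = G\,\mathrm{diag}(\sigma^2_{j(i)})\,G + \sigma^2 I,$$
where $x_i$ is row $i$ of $X$ and $j(i)$ indexes the observation's
accession. Replicate rows of an accession each contribute a term, per the
model's literal per-observation sum. The Hamiltonian is the full negative
multivariate-normal log density,
$$H = \tfrac12 (Y - X\beta)' V^{-1} (Y - X\beta)
     + \tfrac{n}{2}\ln 2\pi + \tfrac12 \ln |V|,$$
which can be negative when $|V|$ is small. The parameters sampled are
$\beta$, the per-accession scales $\sigma_j$ (square roots of the variance
components), and the residual scale.

The normalization of $Q$ cancels in every Metropolis ratio and is never
computed; `log_ensemble_prob()` simply returns $-H$.

## The sampler

A sweep is $p$ single-parameter update attempts with the parameter chosen
uniformly at random — one visit per parameter on average. Each attempt
perturbs one coordinate by `stepwidth * U(-1, 1)` and accepts with
probability $\min(1, e^{-\Delta H})$. Proposals driving any scale negative
are rejected outright (reflection would change the proposal law). The run
has an equilibration phase of `n_equil_sweeps`, then `n_accumulate` blocks
of `n_decorr_sweeps` decorrelation sweeps, storing one parameter vector
per block. Defaults (10,000 / 1,000 / 1,000) match the field protocol the
package was built around; every test and example uses scaled-down
profiles, with the sizes stated below.

For the linear model, $\Delta H$ uses a rank-1 residual update (an $O(n)$
dot product per proposal); the incremental Hamiltonian is checked against
a full recomputation at every phase boundary and the run aborts on drift.
The mixed model refactorizes $V$'s Cholesky only when a scale moves.

**Stepwidth adjuster.** During equilibration the stepwidth of each
parameter class (betas; sigmas — the two classes are plotted separately in
practice and adjusted separately here) is multiplied every
`adjust_every = 1000` sweeps by a factor chosen from the windowed
acceptance rate $r_i$: unchanged while $r_i \in [r_{\min}, r_{\max}]$
(default [0.3, 0.7]); $\times 2/3$ on first falling below $r_{\min}$
(acceptance too low means steps too large); $\times 3/2$ on first
exceeding $r_{\max}$; the previous factor is reused when out of range on
the same side twice, and inverted when the band was crossed. The band
$[E_S \bar S, \bar S / E_S]$ around the running-mean stepwidth $\bar S$
(with $E_S = 10^{-5}$ by default, inside the $10^{-6}$–$10^{-4}$ design
range) freezes adjustment if the stepwidth ever escapes to absurd scales.
The orientation of the grow/shrink factors is the one that moves the
acceptance rate toward the band — larger steps produce larger $|\Delta H|$
and lower acceptance — and the tests drive a 10-parameter Gaussian target
into the band within 20,000 sweeps from initial stepwidths that are
3–4 orders of magnitude off in either direction.

**Initialization.** $\beta$ starts i.i.d. uniform on $(-0.1, 0.1)$;
scales start at the trait's overall sample standard deviation. The law of
the starting point is not prescribed by the algorithm, so a diffuse choice
near zero was adopted once.

## The selection criterion and its searchers

For a candidate subset of size $K$, `score_subset()` builds
$D_{kj} = \mathrm{E}[G_k G_j] - \mathrm{E}[G_k]\mathrm{E}[G_j]$ from
ensemble moments of the predictions $G_k = x_k'\beta$, optionally
normalizes to a correlation matrix $E$, and returns
$\log\det = \sum_k \log \lambda_k$ from the eigenvalues. Eigenvalues below
$10^{-12} \times \max(\lambda_{\max}, 1)$ are floored: $D$ is positive
semidefinite by construction and rank-deficient whenever $K$ exceeds the
ensemble's effective prediction rank, and a raw determinant underflows
near $K \approx 80$ anyway. Larger log-determinant = more informative
panel.

The four searchers:

* `select_suboptimal()` scores every $p_t$-tuple (budget-capped at
  $2\times 10^6$ tuples, `force`-able) and harvests individual accessions
  from the top tuples down, duplicates skipped.
* `select_monte_carlo()` is a Metropolis swap search with Hamiltonian
  $-\log\det$ and temperature 1 by default, returning the best-seen
  subset.
* `select_nc3plus2()` seeds with the best triple and then adds best
  doublets, each round scored jointly with the accessions already chosen
  (scoring tuples in isolation would ignore accumulated information).
  The algorithm-box form (one triple, then doublets only) is the default;
  a cycling variant that alternates triples and doublets is available via
  `cycle = TRUE`.
* `select_greedy()` seeds with the best triple and adds one accession at a
  time by lookahead.

Exact score ties are broken by lexicographic label order, so all selectors
are deterministic given a seed. On pools small enough for exhaustive
search, the tests require greedy to land within 5% of the optimal
log-determinant range and the Monte Carlo searcher to hit the optimum in
at least 80% of seeded runs.

## Feature selection

* **Linear projection** (`linear_projection()`): with $n < p$ the
  directions in the null space of $X'V^{-1}X$ are unconstrained and the
  corresponding coefficients wander during the random walk.
  Eigendecomposing $X'V^{-1}X$, rotating each stored $\beta$, zeroing
  coordinates whose eigenvalue is below $10^{-10} \lambda_{\max}$ (the
  "from $n+1$ on" components when the rank is exactly $n$ — floating point
  does not deliver exact rank, hence a relative threshold), and rotating
  back removes the wandering without changing any fitted value $X\beta$ —
  an identity the tests verify to $10^{-8}$ on every ensemble member.
* **Bayesian interval** (`bayesian_interval()`): a parameter is kept only
  when its equal-tailed 95% ensemble interval excludes zero, using the
  sorted-sample quantile convention (values at indices
  $\lceil 0.025M \rceil$ and $\lceil 0.975M \rceil$).
* **Benjamini–Hochberg** (`benjamini_hochberg()`): $z =$ ensemble mean /
  ensemble standard deviation, two-sided normal p-values, and the standard
  step-up rule at FDR $\alpha = 0.05$ (via `stats::p.adjust`). A literal
  variant that compares each sorted p-value only to its own critical value
  is provided (`variant = "literal"`); it keeps a subset of the step-up
  survivors, so step-up was made the default as the procedure the name
  refers to.

`feature_report()` combines the three: the "projection" mask is the
Bayesian interval applied to the projected ensemble (projection alone
yields no keep/drop decision), the other two masks come from the raw
ensemble, and `intersect_filters()` takes the AND plus the seven Venn
region counts. `one_at_a_time()` is the deliberately overfitting negative
control: a per-column GLS scan plus BH, which keeps far more columns than
the joint filters because binned genotype columns are correlated.

`lrt_year_effect()` compares a pooled fit against per-year fits through
$2(H_{\text{noyear}} - \sum_y H_y)$, oriented so a better-fitting year
model is positive (the final stored Hamiltonians of any two runs can order
either way, so the single statistic is complemented by resampling one
Hamiltonian from each ensemble 1,000 times and reporting the fraction of
draws below zero — the votes for "no year effect"). The degrees of freedom
are declared by the caller, not derived.

## The synthetic-data generator

`sim_config()` + `simulate_genotypes()` + `simulate_traits()` emulate the
features the models rely on: biallelic SNPs spaced on average every
2.5 kb (the 2–3 kb density of the real panel), genotypes drawn at the
inbreeding equilibrium implied by a selfing rate of 0.85
($F = s/(2-s) \approx 0.74$, strongly depressed heterozygosity),
accessions replicated as plants over randomized blocks and years, and
traits generated under the fixed or mixed model with chosen causal bins.
Causal effects default to 0.5–2.0 trait-standard-deviation units with
alternating sign — a stand-in range, configurable, since no canonical
values exist for this knob. Genotypes are independent across SNPs: the
design matrix operates at bin level, so within-bin LD is irrelevant to
everything downstream of binning (it matters only for stress-testing the
reader, and real panels of course violate it). Other real-data features
the generator does **not** emulate: population structure and kinship
beyond the accession variance components, allele-frequency spectra shaped
by selection, genotyping-error patterns, and trait non-normality. Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, not robustness to their violation.

The simulation study (`power_fpr_study()`) mirrors the 10-QTL design:
10 causal bins among ~200, traits simulated, the pipeline (ensemble fit,
then Bayesian interval ∧ BH) applied, and power / false positive rate
tallied against the truth. The scaled-down conditions are 300 accessions
with one plant each over 10 chromosomes of 440 SNPs (~200 bins of
≥ 50 kb), residual standard deviation 0.5. One observation per accession
keeps the design full rank ($n = 300 \ge p \approx 200$): replicate plants
of an accession duplicate design rows, so a replicated layout with fewer
accessions is rank-deficient and its unprojected z-scores are
uninterpretable — the regime the projection filter exists for, but outside
what this calibration study is meant to measure. Chains run at 4,000
equilibration sweeps, 5 decorrelation sweeps and 400 stored vectors:
under-decorrelated chains (e.g. 2 sweeps between stored samples at this
problem size) visibly underestimate ensemble spread and inflate z-scores,
so the decorrelation count was set where the equilibration diagnostics and
the conjugate-sampler checks are clean.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching VCF convention;
  bin span is measured last-SNP − first-SNP + 1 (SNPs are added, not
  fixed windows), and the trailing bin of a chromosome may be shorter than
  the minimum span — it is kept, not merged backward, and flagged in a
  message so the choice is auditable.
* "Normalized" allele counts are mean dosages: sum of reference alleles
  over non-missing SNPs divided by 2 × (SNPs counted). A cell with all
  SNPs missing takes the bin's column mean.
* Missing genotypes are never imputed at read time; the real panel is
  imputed upstream, so the column-mean path is rare in practice.
* The empirical ensemble covariance in the selection criterion uses the
  $1/N$ moment definition, not $1/(N-1)$.
* One global seed fans out to fixed per-module offsets in the CLI so
  subcommand order does not perturb any stream; identical seeds give
  byte-identical outputs end to end.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data:
conjugate checks at $n = 50$, $p = 3$ with 2,000 stored vectors; the
adjuster on a 10-parameter Gaussian target over 20,000 sweeps; selector
oracles on pools of ≤ 10 candidates; the simulation study at the
~200-bin, 300-observation scale above with 10 replicates. Two tests
validate the published sorghum panel counts (232,303 biallelic SNPs;
2,748 bins) and require the BAP VCF on local disk; they state where to put
it and fail otherwise.

## Limitations

* The linear-model ensemble is deliberately not a calibrated posterior
  (no $\tfrac12$ in $H$); its intervals are $\sqrt2$ narrower than
  GLS confidence intervals. The mixed model is the calibrated one.
* The mixed-model sampler refactorizes an $n \times n$ Cholesky on every
  scale move; it is intended for panel-scale $n$ (hundreds), not
  biobank-scale data.
* REML or closed-form mixed-model solvers, kinship matrices, and
  heritability estimators are out of scope, as are read alignment, SNP
  calling, imputation and phasing.
* `genes_in_regions()` uses gene-body overlap with bins only; it does not
  compute distances to nearby genes outside a bin.
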