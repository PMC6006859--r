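---
title: "Methods: simulating and mapping QTL in admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping QTL in admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In livestock and crop genetics, association studies are routinely run on
samples that pool several diverged breeds or lines and their crosses. Breed
composition (BC) then acts as a confounder: any marker whose allele
frequencies differ between breeds correlates with any trait whose mean
differs between breeds, whether or not a QTL is nearby. `admixQTL` simulates
this situation end to end so that competing mapping strategies — single-marker
regression, pedigree mixed models, and Bayesian multiple regression — can be
compared on power, false-positive rate, accuracy and positive predictive
value under a known truth.

# The simulator

## Genome and recombination

The default genome is six 100-cM chromosomes, each carrying 5000 equally
spaced bi-allelic markers (placed at the midpoints of a regular grid, so no
marker sits on a chromosome boundary). Alleles start at frequency 0.5 in the
base population and mutate reversibly with probability 2.5e-5 per locus per
meiosis, applied to each gamete after recombination.

Recombination follows a binomial map function: per chromosome and meiosis the
crossover count is Binomial(N, L/N) with N = 4 and L the map length in
Morgan, so the expected number of crossovers equals the map length while a
hard cap of four crossovers introduces interference. Crossover positions are
i.i.d. uniform on the chromosome and the starting strand is fair. For two
loci d Morgan apart this implies a recombination fraction
r(d) = (1/2)[1 - (1 - 2d/N)^N], which the test suite verifies by Monte
Carlo.

## Demography

All random-mating phases are monoecious random union without selfing, which
keeps the census size equal to the effective size used in the drift
expectations. The timeline is:

1. **Burn-in**: 1000 generations at constant size 1000, building
   mutation–drift–recombination equilibrium LD.
2. **Breed divergence**: four independent samples of 100 drift for 50
   generations at size 100. The expected divergence is
   F = 1 - (1 - 1/200)^50 ≈ 0.22.
3. **Half-sib expansion** (one generation): each breed grows to 1000 as 50
   paternal half-sib families (sires drawn once; each offspring draws its
   sire from the sire set and its dam from the non-sires; family sizes are
   left unequal by chance, averaging 20).
4. **Crossing** (two generations): F1s AB and CD from the expanded cohorts;
   one generation later a fresh AB, the backcross (AB)A, the three-way
   (AB)C, and the four-way (AB)(CD), alongside new pure-breed generations.
   This is the only ordering under which all eight populations (A, B, C, D,
   AB, (AB)A, (AB)C, (AB)(CD)) coexist, at size 1000 each, in the training
   generation.
5. **Admixture**: 1000 individuals sampled without replacement from the
   pooled 8000. The pure breed A cohort of the same generation serves as the
   purebred (PB) comparison dataset.

Breed-composition fractions are tracked exactly (unit vectors at breed
founding, averaged through every cross) and always sum to one. Pedigree is
recorded from the breed cohorts that found the expansion onward; the long
burn-in and drift phases run in compiled code without pedigree, so those
cohorts are pedigree founders. This mirrors real datasets, where deep
pedigree is unavailable and deep coancestry is visible only through the
markers — which is precisely the phenomenon under study. One consequence,
visible in the calibration checks, is that the pedigree relationship matrix
slightly understates very old within-breed coancestry.

## Marker panel

In the training generation, 1000 markers per chromosome are selected among
the segregating loci (0 < freq < 1). Because the selection rule is not
otherwise constrained, the package picks the segregating locus nearest each
of 1000 equally spaced target positions (ties toward the lower index, taken
loci falling through to the next nearest), which preserves the nominal
density of 10 markers/cM. Markers chosen as QTL are removed from the panel
before any scan (5985 panel markers at full scale).

# The trait

Fifteen QTL sit at fixed positions on chromosomes 1–3 (none on 4–6): per the
target table, ten explain 1% of variance, four 3%, one 6% (positions given
genome-cumulatively are converted to within-chromosome coordinates). For each
target the nearest panel marker segregating with MAF > 0.02 in the admixed
cohort is chosen. The target shares sum to 0.28 while h² = 0.30; the shares
are therefore treated as relative weights v'_k = v_k / Σv that partition the
genetic variance σ²_g = h²/(1-h²) (= 3/7 with unit residual). Effects are
|a_k| = sqrt(v'_k σ²_g) / sd(w_k), with sd(w_k) the empirical genotype-count
standard deviation in the admixed cohort (deliberately including
between-breed variance), and random signs. True breeding values are
tbv = Σ a_k w_k and phenotypes add a standard-normal deviate. Realized
heritability on a cohort deviates from 0.30 only through LD between QTL and
sampling noise.

# Association models

All frequentist scans test one marker at a time and refer the Wald statistic
(a/SE)² to chi-square with 1 df. (The denominator-degrees-of-freedom
refinement of REML software Wald tests is not reproduced; at cohort sizes of
1000 the difference is negligible.)

* **SMA**: OLS of y on intercept + marker dosage.
* **SMA_BC**: adds q-1 = 3 breed-fraction covariates (one breed dropped for
  identifiability with the intercept); a joint Wald test of the BC block is
  available separately.
* **MLM / MLM_BC**: y = Xb + w a + u + e with u ~ N(0, A σ²_u), A the
  tabular-method numerator relationship matrix from the recorded pedigree
  (founders unrelated and non-inbred). REML profiles the restricted
  likelihood over λ = σ²_u/σ²_e after a single eigendecomposition of A; a
  flat profile (e.g. A = I, where the two components are non-identifiable) is
  detected and flagged. The default scan mode is P3D: λ is estimated once
  under the no-marker null and reused, with per-marker estimated residual
  scale, so that λ = 0 reduces the scan exactly to its OLS counterpart; mode
  `exact` re-estimates the variance components per marker. P3D is the
  default because the exact mode is quadratic-times-slower at a 6000-marker,
  multi-replicate scale and agrees with P3D closely for small effects (a
  spot check in the test suite).

* **BMR / BMR_BC (BayesCpi)**: y = 1μ [+ Xβ] + Σ γ_k w_k α_k + e with
  α_k = 0 with probability π and N(0, σ²_α) otherwise; one common σ²_α for
  all included markers (the BayesCpi convention, although the prior is stated
  per marker); scaled-inverse-chi-square priors on σ²_α (ν = 4.2) and σ²_e
  (ν = 4); uniform prior on π, giving a Beta(#excluded+1, #included+1) full
  conditional; flat priors on μ and β, sampled by single-site normal
  conditionals. Genotype columns enter raw (0/1/2); the intercept absorbs
  the mean. The ν defaults are configurable; they are a package choice, made
  once, since only the prior means are pinned down by the deterministic
  hyperparameter rule: S²_α is set so the prior mean of σ²_α equals
  σ²_g / (n_QTL · mean(2pq)) over the panel, and S²_e analogously from the
  assumed unit residual variance. The sampler integrates α_k out when
  sampling γ_k, updates the residual vector incrementally, uses no thinning
  for the PIPs (every post-burn-in indicator draw counts), and stores
  monitored scalars (σ²_e, σ²_α, π, model size) for diagnostics (AR-spectral
  effective sample size and Geweke z). Correctness anchors: with fixed
  variances and π = 0 the single-marker posterior mean equals the conjugate
  ridge closed form; on a 3-marker problem the PIPs match exhaustive model
  averaging with analytic marginal likelihoods.

# Significance thresholds

* **NCHR**: each null chromosome (4–6) is divided into non-overlapping bins
  of 40 consecutive panel markers (±2 cM at 10 markers/cM; at reduced panel
  density the bin is rescaled to span 4 cM; incomplete trailing bins are
  dropped). Per replicate and bin the minimum p (frequentist) or maximum PIP
  (Bayesian) is recorded; all bins × replicates of a dataset are pooled and
  the 5% (or 95%) quantile — type-7 linear interpolation, the R default — is
  the dataset-specific threshold. Thresholds are never shared across
  datasets.
* **Meff / Bonferroni**: the effective number of tests is estimated by a
  sliding-window Monte Carlo: test-statistic vectors are drawn from the
  locally correlated Gaussian implied by the genotype-count correlations,
  each marker conditioned on the previous window-1 markers of its chromosome
  (a banded approximation; windows are ridge-stabilized if singular;
  genotype rather than haplotype correlation is used). The empirical 95%
  point of the per-cycle genome-wide max |Z| gives the per-test two-sided
  α*, and Meff = 0.05/α*, applied as threshold α/Meff. This construction is
  sliding-window *style*; exact equivalence with any particular external
  implementation is not claimed.

# Evaluation

A QTL is detected in a replicate if any marker in the closed ±2 cM window
around it passes the threshold; power is the detected fraction over
replicates, averaged over QTL. For FPR/accuracy/PPV the QTL chromosomes are
partitioned: ±2 cM H1 windows (scored one per QTL even when windows overlap)
and, after excising the union of windows, 4-cM H0 segments cut from the left
of each gap, a short leftover forming a final segment scored normally. An H1
window with ≥1 significant marker is a TP (else FN); an H0 segment with ≥1
significant marker is an FP (else TN); so TP + FN = 15 always. FPR is
FP/(FP+TN) per replicate averaged over replicates — the interval-level
reading of "proportion of false positives"; a marker-level denominator was
the open alternative. Null chromosomes are reserved for thresholds and never
scored. All measures are computed per dataset, then averaged across datasets
with standard errors of those means. PPV is undefined (reported missing)
when no positives exist.

# Estimator and measurement conventions

* **F_ST**: pairwise Hudson/Bhatia moment estimator as a ratio of sums over
  loci — numerator (p₁-p₂)² minus within-population sampling corrections,
  denominator p₁(1-p₂)+p₂(1-p₁). Its expectation under pure drift from a
  common base is F = 1-(1-1/(2Ne))^t itself, which makes the simulated
  divergence directly comparable with the drift closed form; the naive
  variance-over-p̄q̄ ratio with a /k variance would converge to F/(2-F)
  instead and was rejected for that reason.
* **LD**: r² is the squared genotype-count correlation between panel marker
  pairs binned by cM distance (closed windows, default half-spacing
  tolerance); monomorphic markers are excluded as their correlation is
  undefined. The headline decay values are measured on the admixed training
  cohort over all segregating panel markers — the cohort choice was open, and
  the admixed cohort is the primary analysis dataset.
* **Datasets**: the study's "32 different QTL minor allele frequencies" are
  realized as 32 dataset seeds: each dataset re-founds the breeds from the
  shared burned-in base, refreshing breed allele frequencies and hence the
  realized QTL MAFs; replicates within a dataset refresh the expansion,
  crossing, admixture, QTL selection and phenotypes. Every stage seed is
  derived deterministically from the master seed (all below 2³¹), so runs
  are reproducible end to end. Resumption of partial runs is not
  implemented; a run is re-executed from its master seed.

# Problem sizes used by the checks

The full design (32 datasets × 20 replicates × 6 models, 100k-sample chains)
is cluster-scale. The package's own checks run two reduced designs, chosen
once as the smallest sizes at which the studied effects are visible:

* a **demography fixture** with the full study demography (1000 burn-in
  generations at Ne 1000; four breeds, 50 generations at Ne 100; expansion,
  crossing, admixture at N = 1000) on a thinned grid of 250 loci per
  chromosome with a 200-marker-per-chromosome panel — used for the LD decay,
  breed divergence, heritability and calibration checks (LD at a given cM
  distance does not depend on grid density);
* the **`ci` preset** (2 datasets × 3 replicates, 400 simulated individuals
  per cohort, 200-marker panels per chromosome, 4k/800 chains) — used for
  the end-to-end method-ranking checks. `deskConfig()` (4 × 5, 20k/2k
  chains) is the larger preset for desk-scale reruns.

Because single-replicate genomic-inflation factors on a few hundred
correlated null markers carry Monte-Carlo spread of about ±0.1, the
calibration check pools p-values over several phenotype replicates before
computing λ, and tests uniformity on a ~4-cM-thinned subset where dependence
between markers is weak.

# What the generator does and does not emulate

It emulates drift, mutation, recombination with interference, breed
divergence, family structure, admixture, and purely additive traits with a
fixed architecture. It does not emulate selection, dominance or epistasis,
sex chromosomes or separate sexes, variable marker spacing beyond the panel
rule, genotyping error, or missing data. Passing checks therefore speak to
the statistical behavior of the mapping methods under stratification and
relatedness — not to robustness against ascertainment, technical noise, or
non-additive genetic architectures in real data.

# Known limitations

* The pedigree relationship matrix starts at the expansion-founder cohorts;
  older within-breed coancestry is visible only through markers.
* The Wald reference is chi-square(1); small-sample denominator-df
  refinements are not reproduced.
* The Meff construction conditions on a banded window and is not an exact
  reproduction of any external tool.
* MCMC reproducibility is bit-exact for a fixed seed on a given platform;
  across platforms floating-point differences can perturb individual draws.
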