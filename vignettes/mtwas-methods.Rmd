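---
title: "Multi-tissue TWAS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue TWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery the package implements,
the assumptions behind it, the tunable parameters and their defaults, and
the design decisions that were genuinely open. It states no empirical
claim that the test suite does not itself compute.

## The problem

Transcriptome-wide association studies (TWAS) proceed in two stages:
train, per gene and tissue, a model predicting expression from nearby
(cis) genotypes; then test whether the genetically regulated portion of
expression associates with a complex trait, either in individual-level
data or through GWAS summary statistics. Multi-tissue expression panels
are rich but ragged: each donor contributes only a subset of tissues, so
every gene's sample-by-tissue expression matrix has many missing
entries, and per-tissue sample sizes are small.

This package addresses that structure in four steps:

1. **Imputation.** Each gene's `N x K` sample-by-tissue matrix is
   completed by iterative per-column random-forest regression on the
   other columns (the missForest scheme). Genotypes are never used here;
   the information exploited is the strong cross-tissue correlation of
   expression.
2. **Cross-tissue (ct) eQTL selection.** Principal components of the
   imputed matrix summarize expression patterns shared across tissues.
   Each retained PC is regressed on the cis-SNP dosages with stepwise
   selection under the extended Bayesian information criterion (EBIC),
   and SNPs selected for earlier PCs are carried as a fixed set when the
   next PC is processed.
3. **Tissue-specific (ts) eQTL selection.** Per tissue, the same
   stepwise EBIC search runs on that tissue's (imputed) expression with
   the ct set fixed; additions beyond the ct set are the ts-eQTLs.
4. **Effect estimation and association.** Effects of the selected SNPs
   are estimated by weighted least squares with imputed samples
   down-weighted by `min(1, N_obs / N_imp)`. Gene-trait z-scores come
   from regressing the trait on predicted expression, or from GWAS
   summary statistics combined with a block LD reference:
   `Z ~ sum_j beta_j (sd_j / sd_gene) z_j`, with `sd_gene` the SD of the
   weighted SNP sum under the reference LD.

## The selection criterion

For a candidate set `S` of SNPs, with Gaussian errors and the residual
variance profiled out,

```
EBIC_lambda(S) = N log(2 pi RSS/N) + N + |S| log N + 2 lambda |S| log M,
```

where `M` is the number of cis-SNP candidates. The `log M` term is what
distinguishes EBIC from BIC: it charges for the size of the model space
searched, which matters when candidates are plentiful relative to `N`.
The search is the classical stepwise scheme with a fixed-set contract:
forward additions while EBIC decreases (ties to the lowest SNP index,
for determinism), backward eliminations over non-fixed terms, then
exhaustive enumeration of all subsets of the surviving non-fixed terms
(capped at `max_enumeration = 15`, i.e. 2^15 fits; beyond that the
backward result stands and the skip is logged). Fixed-set members are
never removable. Every candidate model is evaluated through precomputed
cross-products (`X'X`, `X'y`), so one model costs one small Cholesky
solve and the enumeration stage is cheap; subsets whose normal equations
are singular (collinear columns) are treated as inadmissible.

**How often does a null gene select nothing?** The first forward
addition fires when the best of `M` score statistics (approximately
chi-square with 1 df) exceeds the penalty `log N + 2 lambda log M`. At
`N = 500`, `M = 30`, `lambda = 0.5` the penalty is 9.62 and each null
SNP clears it with probability 0.0019, so the empty-model rate has a
closed-form ceiling of about `(1 - 0.0019)^30 = 0.944`. This is worth
keeping in mind when interpreting "no eQTLs selected" as evidence of no
signal: at these settings roughly one null gene in twenty will carry a
spurious selection. A larger `lambda` trades this false-positive rate
against selection power.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `lambda` | 0.5 | EBIC tuning parameter. 0.5 is the canonical choice retaining selection consistency when `M` grows polynomially in `N`; exposed as a CLI flag because no single value suits every candidate density. |
| `eigenvalue_cutoff` | 2.0 | Keep expression PCs whose correlation-matrix eigenvalue is at least 2 (a PC explaining two tissues' worth of variance). |
| `min_pcs` | 1 | With all eigenvalues below the cutoff the first PC is still used, so every gene gets a ct-selection pass. |
| `max_enumeration` | 15 | Cap (in non-fixed terms) on the exhaustive final stage. |
| `n_trees` | 100 | Trees per imputation forest. |
| `max_iter` | 10 | Sweep cap for the imputation iteration. |
| `min_obs_per_tissue` | 10 | Tissues with fewer observed samples for a gene are dropped from that gene's matrix. |
| `window_bp` | 1e6 | Cis-window flank around the gene body, inclusive; the common TWAS convention. |
| `maf_threshold` | 0.05 | QC floor on minor allele frequency; strand-ambiguous A/T and C/G SNPs are dropped by default. |

The forest `mtry` is set to all `K - 1` donor columns: with the handful
of predictors available per gene (tissues, not SNPs), subsampling
predictors at each split would only add variance.

## Imputation details

Columns are visited in ascending missingness order after a mean-value
initialization. After each full sweep the relative change
`sum((curr - prev)^2) / sum(curr^2)` over the originally missing entries
is computed; the iteration stops the first time this quantity increases,
and the previous sweep's values are kept (the standard missForest
stopping-and-rollback rule), or at `max_iter` sweeps. Observed entries
are never touched — the output is bit-identical to the input wherever
the mask is `TRUE` — and the mask is carried along so the later weighted
least squares knows `N_obs` and `N_imp` per tissue.

## The weighting scheme and when imputation helps

Imputed rows enter effect estimation with weight
`min(1, N_obs / N_imp)`; observed rows always have weight 1. Two regimes
follow, and the package's own simulations exhibit both:

* **Sparsely observed tissues** (`N_obs << N_imp`, the situation that
  motivates multi-tissue borrowing): imputation enlarges the effective
  training set, the weight caps the influence of the imputed majority,
  and prediction improves over training on the few observed samples.
* **Mostly observed tissues** (`N_obs >= N_imp`, e.g. 30% missingness):
  the weight saturates at 1, so imputed rows — whose values are
  cross-tissue predictions and therefore carry no tissue-specific
  signal — enter selection and estimation at full weight. They
  attenuate ts-eQTL effect estimates, and when the observed rows alone
  are already ample for the effect sizes present, a model trained on
  observed rows only can match or beat the imputed fit. The
  cross-validation ablation in the acceptance suite runs at exactly this
  regime (30% missing-completely-at-random, strong effects) and
  documents the resulting ordering rather than hiding it.

## The synthetic-data generator

The simulator is first-class, tested code and the fixture source for
every test. It emulates:

* **Genotypes:** two haplotypes per person from a latent AR(1) Gaussian
  process thresholded at per-SNP MAF quantiles (a Gaussian copula).
  `ld_rho` tunes linkage disequilibrium; per-SNP MAFs are drawn from
  `maf_range` and stored, so an independent cohort from the *same*
  population (an LD reference panel) can be drawn by passing the stored
  MAFs back with a new seed.
* **Expression:** per tissue,
  `E[, k] = X_ct b + X_ts(k) c_k + lambda_f F + eps`, with the ct
  effects shared by all tissues, each ts SNP active in exactly one
  tissue, and a per-sample shared factor `F` driving cross-tissue
  correlation — the signal the imputation step exploits.
* **Missingness:** per-tissue missing-completely-at-random masking.
* **Traits and GWAS:** `Y = gamma E_tissue + (direct SNP effects) +
  noise`, standardized; per-SNP marginal z-scores use the same
  `slope / se` t-form as the individual-level gene test, which is what
  makes the summary-statistic approximation agree with the
  individual-level z-score to high precision in-sample.

Default condition (used throughout the tests): `N = 500` samples,
`M = 30` cis-SNPs with `ld_rho = 0.3`, `K = 6` tissues, 3 ct-eQTLs and 2
ts-eQTLs per tissue of magnitude 0.8 with random signs, unit shared
factor and unit noise, 30% missingness. Effect magnitudes are fixed (not
drawn) so that recovery statistics refer to a known signal strength.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: population structure and relatedness;
non-random (tissue- or expression-dependent) missingness; non-Gaussian
expression noise and count-level measurement error; realistic cis-LD
block structure beyond AR(1); confounders of the kind PEER factors are
meant to absorb (covariates are accepted as input but never estimated).

## Numerical choices

* PC signs are fixed so each score vector correlates nonnegatively with
  mean expression across tissues; selection is sign-invariant but the
  trace otherwise would not be reproducible.
* Perfect fits inside the stepwise search are guarded by flooring the
  RSS at `1e-12 * y'y`; the exported `ebic()` refuses `rss <= 0`.
* Singular weighted normal equations in `wls_fit()` fall back to a
  ridge of `1e-8` on the diagonal, with a warning.
* The LD quadratic form `sum_jl beta_j beta_l sd_j sd_l R_jl` is
  regularized (ridge `1e-6 * mean(diag(R))`) *only* when it is not
  numerically positive: an unconditional ridge would perturb the exact
  single-SNP identity `Z = sign(beta) z_j`.
* Exact-fit individual-level z-scores are capped at ±40 and flagged
  rather than returned infinite.
* Gene pruning visits genes in ascending P (ties by gene id) and keeps a
  gene iff its predicted expression has `r^2 <= 0.5` with every
  already-kept gene; the multi-gene resolution order is a declared
  choice — only the pairwise rule is fixed by convention.
* All simulator and forest randomness flows from explicit integer seeds
  (R's default Mersenne-Twister; `ranger` with `num.threads = 1` and a
  per-column, per-sweep seed), so every pipeline stage is bit-reproducible.
* The CLI fans one global seed out to per-stage sub-seeds by a fixed
  affine map, so stages can be re-run independently yet deterministically.

## Cross-validation protocol

Five folds, assigned round-robin after ordering samples by how many
tissues observe them (stratifying folds by observedness). Per fold,
imputation runs on the training rows only; the held-out rows stay
unimputed, and their observed entries are predicted from genotypes.
Per-fold prediction `R^2` values are averaged across folds; the
predictability F test (`F = r^2 (n - 2) / (1 - r^2)` on `(1, n - 2)`
df) is evaluated on the held-out predictions pooled over folds, and BH
FDR control is applied across genes. Two ablations share the harness:
per-tissue EBIC selection on the imputed matrix without the ct/ts
partition, and per-tissue selection on observed samples only without
imputation.

Problem sizes used by the test suite and the acceptance script (chosen
as the package's own standard conditions): selection-oracle checks at
`N = 300`, `M = 10` against full enumeration; partition recovery over
25–50 genes at the default condition; imputation benchmarks over 12–20
genes; summary-vs-individual agreement over 40–100 genes at `N = 2000`;
calibration over 2000 null replicates; cross-validation ablations over
15–50 genes.

## Known limitations

* Covariate factors (PEER-like) are inputs, never estimated.
* Missingness is assumed ignorable (MCAR/MAR); informative missingness
  will bias both the imputation and the downweighting rationale.
* The summary-statistic test assumes the LD reference matches the GWAS
  population; mismatched allele frequencies degrade the approximation.
* Interaction and nonlinear genotype terms are out of scope for the
  selection stage (the imputation forest is the only nonlinear step).
* The enumeration stage guarantees a within-path optimum (all subsets of
  the forward–backward survivor set), not a global one; the oracle tests
  show agreement with full enumeration at small `M`.
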