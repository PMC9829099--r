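---
title: "Pattern component modeling of representational similarity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern component modeling of representational similarity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmrsa)
```

## The model

A region's representational content is summarized by a condition-by-condition
similarity matrix **S**: each cell is the mean Fisher-z Pearson correlation
between the multivoxel activation patterns of two conditions' trials. Pattern
component modeling treats the vectorized upper triangle of **S** (21 cells for
6 conditions, diagonal included) as a response and decomposes it into a
weighted sum of *patterns of interest* (POIs) — idealized similarity matrices
`M_k` with entries in {−1, 0, +1}:

$$\mathrm{vec}(S) = \beta_0 + \sum_k \beta_k\,\mathrm{vec}(M_k) + \varepsilon$$

Participants' vectors are stacked into a single ordinary-least-squares
regression (21 cells × N participants observations), so each `β_k` is a
group-level mean similarity increment in Fisher-z units. Stacking, rather than
averaging per-participant fits, is what gives the hold-out validation its
F(1, 21·n − 2) reference distribution — (1, 145) at the 7-participant
hold-out — and is therefore part of the model definition, not an
implementation convenience.

Assumptions worth keeping in mind: cells are treated as exchangeable
observations (no modeling of the correlation between cells sharing a
condition); POI regressors enter unscaled and uncentered, so betas remain
interpretable as mean-z differences but POIs with larger support can absorb
more variance per unit beta; and participants enter as fixed replicates (no
random effects — inference about the *population* of participants is delegated
to the Monte Carlo cross-validation).

## The experiment design and POI library

`build_design()` declares the two-task tactile conditioning layout: an
aversive-pressure task and an appetitive-brush task, each with 2 CS+ faces
(paired with touch), 1 CS− face, 6 CS-US paired blocks and 7 CS-only blocks —
36 paired trial events and 26 blocks in total. Only paired-block trials enter
the similarity analysis; CS-only blocks are carried solely for the block
count. The canonical condition order is fixed as P+1, P+2, P−, B+1, B+2, B−
so that vectorizations and fixtures are deterministic (no ordering is
scientifically privileged).

Conditions carry the class attributes the POIs are built from: touch type,
contextual valence (brush delivery and pressure *absence* are the positive
events), tactile salience (touch vs CS−), face identity, and outcome
probability (CS− is the rare outcome at 2 : 1). `standard_library()` derives
the 13 base POIs from these classes, plus two lateralized specific-touch
patterns (rST/lST) for unilateral somatosensory analyses. Two constructions
deserve comment:

* **Diagonal cells.** Within-condition cells are included in a POI's support
  whenever its verbal definition covers same-condition trial pairs — all POIs
  except temporal adjacency (TA). TA models carry-over between temporally
  adjacent trials; because condensation removes the autocorrelation diagonal,
  the within-condition average contains no same-block pairs, so TA's diagonal
  stays 0.
* **Lateralized grouping.** rST groups all three non-pressure-side conditions
  (P−, B+1, B+2, B−) as one "generic scanner touch" state, mirroring the
  grouping logic of ST; the alternative (excluding the opposite task's CS−)
  is defensible but less consistent with the inclusive phrasing of the
  specific-touch construct, and we adopt the inclusive reading once.
* **Touch-valence support.** TV sets +1 *within* the pressure trials and
  *within* the brush trials, and −1 across them; the within-group +1 follows
  the same visual-key semantics as every other bipolar POI (AV, Sa).

Because AV = 2(PE + NE) − J and Sa = 2(nST + VE) − J (J the all-ones matrix,
collinear with the intercept), the full 13-POI design matrix is exactly
rank-deficient. `fit_model()` refuses such sets with a collinearity error; the
search simply treats them as ineligible, and the "All" reference fit drops
aliased columns by pivoting and counts parameters from the effective rank.

## RSA stage

Trial similarity is plain Pearson correlation across voxels, Fisher
transformed at the trial level *before* condensation (the transform and the
down-sampling are sequential operations, in that order). Condensation averages
30 ordered same-condition cells (autocorrelation diagonal removed) for each
within-condition cell and the complete 36-cell cross block for each
between-condition cell. Averages stay on the z scale throughout; no
back-transform to r before averaging (averaging z is the variance-stabilized
choice, and only differences matter downstream).

Numerical choices: `atanh` is clamped at |r| = 1 − 1e−7 (z ≈ 8.4) so
collinear patterns stay finite; rows with zero variance or non-finite values
are rejected rather than imputed, because silent imputation changes
similarity; symmetry of inputs to `vectorize()` is enforced to 1e−8.

## Search

`gbfs_search()` implements greedy best-first forward selection under BIC with
the Gaussian form `n·log(RSS/n) + (k + 1)·log(n)`, counting the residual
variance as a parameter. Level 1 fits every POI alone against the
intercept-only baseline; the requirement that even the first POI beat that
baseline by more than `delta_accept = 2` makes the method safe on null data
(empty final set) instead of always returning something. At each level the
best improving candidate is accepted, and every other candidate that (a)
itself passes the acceptance rule and (b) lies within `delta_equiv = 2` of the
level's best spawns an additional path; equivalency branching applies at every
level, including level 1. A path terminates when no remaining POI improves its
BIC by more than 2; the final model is the terminal set with minimum BIC and
`n_path` counts completed paths.

Tie-breaking and bookkeeping: exact BIC ties (within 1e−9) resolve by library
order, making the search deterministic; branches that would re-create a POI
set already being explored are merged rather than duplicated — and a path
whose accepted candidates are *all* merged away is discarded, not counted as a
terminal, since counting it would fabricate a shorter completed path that the
acceptance rule never endorsed.

## Validation

`mccv()` draws `n_rs` participants without replacement each iteration
(defaults 1000 iterations, RS = 60, HO = 7, matching a 67-participant study;
each iteration approximates one fold of a 10-fold validation), runs the full
search on the random sample, reconstructs the fitted similarity vector
`β₀ + Σ β_k M_k`, and regresses the stacked hold-out cells on that single
tiled predictor. One group-level reconstruction is tiled per hold-out
participant — per-participant reconstructions would change the denominator df
away from 21·n − 2. The summary reports, per POI, the proportion of iterations
in which it was identified, against the chance threshold
(mean selected-set size) / (library size), with mean betas reported only above
that threshold. `npath_compare()` contrasts per-iteration n-path counts across
regions with a one-way fixed-effects ANOVA on the raw per-iteration values and
all pairwise equal-variance t tests, Bonferroni-adjusted by the number of
pairs; all-identical degenerate input returns F = 0, p = 1 rather than NaN.

## Synthetic data

Two generators make every stage testable with known ground truth.

`gen_similarity()` draws each participant's 21-cell vector as the linear POI
mixture plus iid Gaussian cell noise. Its defaults are the canonical
two-component somatosensory configuration — weights nST = 0.12, ET = 0.06,
intercept 0.05, cell noise SD 0.02, 67 participants — chosen to mirror the
magnitude ordering of a primary-somatosensory profile (a dominant nonspecific
touch component roughly twice the task component) at the study's sample size;
they are fixed once and used unchanged everywhere, including the acceptance
script.

`gen_voxel_patterns()` works one level down: the condition-level target
mixture is expanded to a 36 × 36 trial matrix, projected to the nearest
positive semidefinite matrix by eigenvalue clipping at zero (no rescaling of
the retained spectrum; the max-abs repair deviation is reported in the ground
truth so tests can bound it), and used as the shared component of a trial
covariance `shared_var · PSD(target) + noise_var · I`; each voxel's 36-trial
profile is an independent zero-mean Gaussian draw. Mean-zero profiles make
voxelwise Pearson correlation approximate the normalized covariance, so the
condensed similarity converges on (a monotone image of) the target mixture as
voxels grow.

What the generators deliberately do *not* emulate: hemodynamic time-series
structure, autocorrelated or drifting fMRI noise, participant heterogeneity in
weights (a jitter hook exists but recovery tests run with it off), and
spatial voxel covariance. Passing recovery tests therefore demonstrate that
the estimator chain is correct and well-calibrated under its own model; they
do not certify behaviour under realistic fMRI noise, which is exactly what the
hold-out validation stage is for on real data.

## Problem sizes used in tests

The shipped test and acceptance runs use scaled-down but structurally
faithful sizes, chosen so the whole suite runs in well under a minute while
keeping every estimate comfortably away from its decision boundaries: MCCV
recovery at 100 iterations (identification proportions have binomial SE ≤
0.05 there, far from the 0.9/0.1 criteria), brute-force best-subset
verification over all 2^13 POI subsets on the 60-participant simulation,
law-of-large-numbers checks at 5000 participants, and voxel-covariance
convergence at 20,000 voxels. Summary definitions are identical at any
iteration count.

## Known limitations

* Greedy search bounds the subsets examined; the brute-force comparison is
  a test oracle, not a runtime option, and on adversarial data the greedy
  terminal set may be suboptimal (it is provably never better than the
  exhaustive optimum).
* BIC model comparison treats similarity cells as independent observations;
  the printed df inherit that idealization.
* POIs are binary by design; graded model RDMs and cross-validated distance
  measures (e.g. crossnobis) are out of scope.
* The named library is defined only for the default 6-condition design;
  other designs use `build_poi()` directly.
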