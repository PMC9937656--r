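---
title: "Methods: statistical design of the kinsub pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical design of the kinsub pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Acute chemical-genetic inhibition of an analog-sensitive kinase, combined
with SILAC phosphoproteomics, yields per-phosphosite log2 ratios of starved
versus unstarved cells under two arms — vehicle (DMSO) and ATP-analog
inhibitor — at two starvation timepoints (5 and 15 min), with five
biological replicates per cell. A parallel on-beads in vitro kinase assay
(OBIKA) compares the immobilized, re-phosphorylated proteome incubated with
purified wild-type kinase against a kinase-dead mutant, five replicates per
genotype. The pipeline turns these two tables into:

1. per-site starvation effect sizes with confidence intervals,
2. class I/II kinase-dependence calls,
3. a bona fide direct-target set (significant in vivo *and* in vitro),
4. kinetic clusters of the responding sites, and
5. a position-specific consensus motif of the target windows.

`kinsub` is organised as an analysis workflow: the numbered scripts under
`analysis/` narrate one synthetic study end to end, while every computation
lives in the package and is exercised by the test suite.

# Statistical model

## Per-site random-effects effect estimation

For one site, let $y_{tr}$ be the vehicle-arm log2 ratio at timepoint $t$
(5, 15 min) in biological replicate $r = 1, \dots, k$. We fit the one-way
random-intercept model

$$y_{tr} = \mu + b_r + e_{tr}, \qquad
  b_r \sim N(0, \tau^2), \quad e_{tr} \sim N(0, \sigma^2),$$

treating replicates as random effects so that the between-replicate
variability widens the uncertainty of the combined effect $\mu$. Sites are
fitted independently (the per-site reading of a site-level random-effects
analysis); a single global fit pooling all sites would shrink per-site
effects and was deliberately not adopted, because the classification rules
below need per-site effect sizes and intervals.

Estimation is closed-form method of moments on the replicate means:
$\mathrm{MS}_B = t_h \cdot \mathrm{var}(\bar y_{\cdot r})$ with $t_h$ the
harmonic mean of per-replicate observation counts (2 for complete data),
$\hat\tau^2 = \max\{0, (\mathrm{MS}_B - \mathrm{MS}_W)/t_h\}$, and
$\widehat{\mathrm{SE}}(\hat\mu) = \sqrt{\mathrm{MS}_B / (k\, t_h)}$.
Under normality and balance, $\hat\mu / \widehat{\mathrm{SE}}$ is *exactly*
$t$-distributed with $k - 1$ degrees of freedom — the replicate means are
i.i.d. normal — which gives exact tests and intervals without iterative
likelihood. The acceptance suite verifies this calibration empirically
(type-I error in [0.04, 0.06], CI coverage in [0.94, 0.96] over 50
global-null datasets). An iterative REML fit (e.g. `lme4`) would estimate
the same quantities; the moment estimator was chosen because it is
closed-form, exactly calibrated in the balanced design, and testable
against a brute-force ANOVA oracle to 1e-10.

## Kinase-dependence contrast and classification

Per timepoint, vehicle is compared to inhibitor with a two-sided pooled
Student's t-test (Welch available), and Benjamini–Hochberg adjustment is
applied within each timepoint's family. Classification:

* **criterion (i)** — starvation induction: random-effects $p < 0.05$ with
  positive effect;
* **criterion (ii)** — kinase dependence: BH $q < 0.05$ with positive
  vehicle-minus-inhibitor difference at 5 *or* 15 min;
* **class I** = (i) and (ii); **class II** = (ii) only; otherwise not
  significant.

Only upregulation counts in both criteria: a kinase adds phosphate, so a
site that *loses* phosphorylation on starvation, or gains it under
inhibition, is not a candidate target. Class II captures constitutively
phosphorylated targets — already phosphorylated in rich medium, lost upon
acute inhibition — which show no starvation induction but a clear inhibitor
contrast.

Two conventions are deliberately asymmetric and configurable: the in vivo
contrast uses strict `<` on $q$, the OBIKA branch uses `≤`. BH families are
per-timepoint by default (`timepoint_family = "pooled"` merges them)
because the timing categories (both / early-only / late-only) are defined
by per-timepoint significance.

## Missing values

Label-ratio MS data mix two missingness mechanisms, and the pipeline uses
two matching imputation regimes:

* **Down-shifted normal** (Perseus-style), for structurally missing data:
  each missing cell in a sample column is drawn from
  $N(m - 1.8\,s,\ (0.3\,s)^2)$, where $m, s$ are the observed column mean
  and sd. The constants 0.3 (width) and 1.8 (down-shift) are the Perseus
  defaults and are configuration values, not hard-coded. This left-censored
  abstraction mimics low-abundance measurements below the detection limit.
* **Normal-model MLE**, for partially observed groups: under an ignorable
  normal model the MLE of the group mean given the observed replicates is
  the observed mean, so missing cells are set to it. Deterministic and
  mean-preserving by construction. A left-censored (truncated-normal) MLE
  would impute lower values; the ignorable-normal reading is the default
  and the choice is surfaced in the documentation.

The OBIKA policy combines them by a per-site rule: kinase-dead group with
zero observed replicates → down-shift draws (the site is presumed
unphosphorylated without active kinase); at least one observed → MLE; WT
missing values → MLE. In vivo, the protein table is down-shift-imputed
before protein normalization, and MLE is applied to the inhibitor-arm
groups before the t-tests.

Imputation never touches observed cells (asserted bitwise in the tests),
and each stochastic stage draws from its own RNG stream derived from the
master seed and a stage label, so adding a stage never perturbs earlier
draws.

## Protein normalization and filters

Sites are normalized by subtracting the protein-level log2 ratio per
sample, removing protein-abundance drift. Sites without protein-level
quantification are kept unnormalized and flagged rather than dropped —
dropping them would discard a large fraction of sites with no evidence of
artefact — and users can exclude flagged sites downstream. Filters:
localization probability strictly > 0.75; proteins quantified in ≥ 2
replicates within at least one design cell (the per-cell reading is the
default; a pooled mode exists because the original convention is
ambiguous); sites quantified in ≥ 3 vehicle replicates at either timepoint
("either … or" = the `any_timepoint` mode); OBIKA sites in ≥ 3 WT
replicates. All filters are idempotent and never alter retained values.

## Intersection

The common universe is the set of site keys surviving both branches'
quantification filters; bona fide targets are common-universe sites that
are class I/II in vivo *and* OBIKA-significant (positive WT − dead
difference required — a kinase cannot remove phosphate). Recovery metrics
in the tests are conditional on this universe: a site never quantified in a
branch cannot be recovered by any statistic, so unconditional recall would
measure the missingness process, not the method.

## Kinetic clustering

Class I/II sites are represented by replicate-mean log2 ratios per
arm × timepoint, z-normalized per row (mean 0, sd 1, $n-1$ denominator;
zero-variance rows are zeroed and flagged), and clustered with
average-linkage agglomeration on Euclidean distances, the tree cut at
$k = 5$ (a display choice, not estimated — no automatic $k$ selection).
Linkage is configurable (complete, Ward-D2).

One geometric caveat drives a design decision: with only the two
vehicle-arm columns, every z-normalized row collapses to
$(\pm 1/\sqrt 2, \mp 1/\sqrt 2)$, so at most two profile shapes are
distinguishable and three planted kinetic classes cannot be separated in
principle. The module's default remains vehicle-only (the two-timepoint
reading of the ratio heatmap), but the recovery studies and the workflow
scripts pass `include_inhibitor = TRUE`, clustering on all four condition
columns, where early/sustained/late shapes are geometrically distinct.
Cluster labels compare the mean vehicle z-score at 5 versus 15 min with a
margin of 0.5 z-units: `early_transient`, `late`, or `sustained`.

## Motif enrichment

15-mer windows (flank 7, the community standard for kinase motifs) are
extracted around each phosphoacceptor, `_`-padded at termini, with a hard
residue-match guard against coordinate-convention bugs. For each
(position, residue) cell, the foreground count is tested against the
background frequency with a two-sided binomial test; enrichment is
$\log_2\big(\tfrac{(c + 0.5)/(n + 1)}{f_{bg}}\big)$ with pseudocount 0.5,
and BH runs across all tested cells (center excluded — it is always S/T;
padding excluded on both sides). The default background is the windows of
all tested-but-not-shortlisted sites, the standard choice in motif
enrichment; uniform or user-supplied frequency backgrounds are supported.
Consensus calls report cells with $q < 0.01$ and enrichment > 1, plus
pooled residue classes (basic K/R, hydrophobic L/I/V/M/F) so that two
individually sub-threshold basic residues can jointly reach significance —
the expected pattern for an AMPK-family kinase is basic at −3/−4 and Leu
at +4. The binomial test (rather than Fisher's exact on the 2×2) was
chosen for determinism and speed; with the large backgrounds used here the
two agree closely.

# The synthetic-data generator

The generator emulates the study design: two arms × two timepoints × five
replicates of per-site log2 ratios versus unstarved control, a parallel
protein-level table, an OBIKA table (5 WT / 5 kinase-dead), a proteome
FASTA, and a ground-truth ledger. Values are simulated directly on the
log2-ratio scale — the pipeline never needs raw intensities. Key choices:

* **Effects.** Planted responders get a base effect
  $\sim N(\mu_e, \sigma_e)$ clamped below at 0.25 log2 units (targets are
  upregulated by construction); the inhibitor arm retains
  `inhibitor_attenuation` (default 0.1) of it. Kinetic classes scale the
  off-timepoint by `transient_factor` (0.25): early-transient sites decay
  by 15 min, late sites have not yet responded at 5 min.
* **Variance components.** Replicate intercepts (`replicate_tau`, default
  0.3 log2) are shared across the two timepoints within an arm — matching
  the random-effects model — because the two timepoint labels derive from
  one mixed sample per replicate. Residual noise `noise_sd` defaults to
  0.5 log2, a typical site-level SILAC ratio sd.
* **Protein drift.** Per-protein, per-sample drift
  ($\sigma = 0.4$) enters both the site values and the protein table, so
  protein normalization demonstrably reduces variance; the protein table
  adds small measurement noise (0.1).
* **Missingness.** MNAR is logistic in the latent value,
  $P(\text{miss}) = \mathrm{plogis}(-(y - m_0)\beta)$ with midpoint −2.5
  and slope 0.8 (≈ 12% missing at $y = 0$, 40% at $y = -2$), plus 2% MCAR —
  ~15% missing cells overall, at the low end of typical phosphoproteome
  missingness but enough to exercise every imputation branch. The latent
  matrices are retained so tests can verify that missing cells have lower
  latent values than observed ones.
* **OBIKA.** Direct substrates (80% of responders by default) have
  kinase-dead values centered at −2 (the site barely exists without active
  kinase) and WT values `obika_effect` (default 3 log2) above them, so the
  same MNAR mechanism concentrates missingness exactly in the kinase-dead
  cells of true substrates; all other sites sit at 0 in both genotypes.
* **Proteome.** Uniform-composition random sequences, phosphoacceptor
  placed at each site position; motif carriers (the direct substrates)
  receive Arg at −3, Arg/Lys at −4, Leu at +4, independently per position
  with probability `motif_fidelity` (default 0.9; settable per position).
* **Localization probabilities** are Beta(9, 1), so the 0.75 filter removes
  about 7.5% of sites.

What it does **not** emulate: spectra, peptides, charge states, SILAC
channel crosstalk, multiplicity > 1 site records, correlated co-regulation
between sites of one protein, or heavy-tailed/batch-structured noise.
Passing tests therefore demonstrate the pipeline's statistical behaviour
under a faithful but idealized error model, not performance on any
particular real dataset.

# Study designs used by the tests and acceptance script

Fixed before the acceptance suite was written, by the power analysis below:

* **Null calibration** — 50 datasets of ~2000 sites (500 proteins × 4
  sites), 5 replicates, no planted targets, missingness off: isolates the
  calibration of the statistical core (imputation has its own contracts).
  Expected: ≤ 1% class calls, 5% type-I, 95% coverage.
* **Recovery** — 20 datasets of ~2000 sites with 200 planted responders at
  exactly 2.0 log2 (sustained kinetics), noise 0.5, tau 0.3, attenuation
  0.1, 80% direct substrates at OBIKA effect 3: a pre-hoc power
  calculation (noncentral-t, BH threshold ≈ 0.05·R/m) predicted per-site
  detection ≈ 0.93 and precision ≈ 0.93, giving headroom over the 0.90
  bounds. Complete-data configuration, consistent with defining recovery
  conditional on quantified sites.
* **Kinetics recovery** — 150 targets in three equal classes at effect 2.5
  with noise 0.15 / tau 0.1 (well-separated profiles), clustered on the
  four condition columns with $k = 3$.
* **Motif recovery** — 150 carrier windows at fidelities 0.9 (−3 R),
  0.9 (−4 R/K), 0.8 (+4 L) against a uniform background; null motif runs
  resample the foreground from the background.

These sizes keep the full test suite under a minute of compute while
leaving the Monte-Carlo bounds comfortably away from their thresholds.

# Numerical conventions and degenerate inputs

* Zero-variance random-effects fits (all replicate means equal) return the
  machine-floor p-value for non-zero effects, $p = 1$ for zero effects, a
  point confidence interval, and a degeneracy flag — not an error.
* Zero pooled variance in a t-test: $p = 1$ for equal means, machine floor
  otherwise.
* BH propagates missing p-values and computes $m$ over the tests actually
  performed.
* Tables are tab-separated, `.` decimal, `NaN` for missing; comma decimals
  reject the row with a warning rather than silently coercing.
* Site keys are `protein|position` with 1-based residue positions.
* Cluster ids are relabeled contiguously in order of first appearance, so
  assignments are deterministic given input row order.

# Known limitations

* The moment estimator's exactness argument assumes balance; with heavy
  unbalance the harmonic-mean correction is an approximation.
* MLE imputation treats missingness in the imputed group as ignorable;
  under strong MNAR in the inhibitor arm it biases imputed values upward.
* BH assumes independence/PRDS across sites; phosphosites on one protein
  are correlated in real data.
* The motif module tests cells independently; it does not model
  inter-position dependence or deconvolve mixtures of motifs.
* With only two timepoints, "kinetics" is a coarse three-way shape
  classification, not a rate estimate.
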