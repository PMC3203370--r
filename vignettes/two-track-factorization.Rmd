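---
title: "Two-track matrix factorization of expression data: consensus FastICA and non-smooth NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-track matrix factorization of expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfgex)
```

## The problem

A bulk microarray study of hippocampal tissue contrasts a handful of severe
Alzheimer's disease (AD) samples with controls — the design this package
emulates is 5 disease and 8 control samples over 6398 genes. With so few
samples, supervised per-gene testing is fragile; instead, two unsupervised
matrix factorizations are run side by side and their gene lists integrated:

* **Independent component analysis (ICA).** The samples-by-genes matrix
  $X^T$ is modelled as $X^T = A S$: rows of $S$ are statistically
  independent *expression modes* over genes, and the mixing matrix $A$
  holds the weight of every mode in every sample profile. A mode whose
  mixing column has one sign in the disease group and the opposite sign in
  controls discriminates the phenotype; its extreme loadings are candidate
  disease genes, signed up/down.
* **Non-smooth nonnegative matrix factorization (nsNMF).** The nonnegative
  genes-by-samples matrix is modelled as $V \approx W S_\theta H$ with
  $W \ge 0$ (columns are *metagenes*), $H \ge 0$ (rows are *encoding
  vectors* over samples), and the $k \times k$ smoothing matrix
  $S_\theta = (1-\theta) I + \frac{\theta}{k} \mathbf{1}\mathbf{1}^T$.
  Placing the smooth factor in the middle forces sparseness onto both $W$
  and $H$, so each metagene concentrates on a local gene module and each
  encoding vector on a subset of samples — a biclustering. Samples are
  classified by their most highly expressed metagene, and sorting genes by
  a metagene and samples by its encoding vector collects the module into a
  contiguous block.

The two models impose different constraints (independence versus
nonnegativity-with-sparseness) and typically agree on few genes, which is
precisely why their union is informative. `integrate_gene_sets()` reports
both lists, their overlap, and per-gene direction conflicts.

## The ICA engine

`fastica_consensus()` standardizes nothing itself — it consumes the output
of `standardize_samples()`, which centers and scales every sample to unit
standard deviation (n−1 denominator). Whitening then maps the sample
profiles to identity covariance, dropping directions with covariance
eigenvalue below $10^{-10}$ times the largest (with a warning; the model is
otherwise square, one component per sample).

Each restart runs the symmetric fixed-point iteration with contrast
derivative $g(u) = \tanh(a_1 u)$, $a_1 = 1$ by default, and symmetric
decorrelation $(WW^T)^{-1/2}W$ after every step. Convergence is
$\max_c \lvert 1 - \lvert\langle w^{new}_c, w_c\rangle\rvert\rvert <$
`ica_tol` ($10^{-6}$).

**Stabilization.** On data where only a few directions are meaningfully
non-Gaussian — exactly the planted-mode regime, where most whitened
directions carry nothing but Gaussian noise — the undamped iteration never
settles: it cycles indefinitely at a convergence measure orders of
magnitude above tolerance, and a reference implementation behaves the same
way. The engine therefore takes a one-off damped step ("stroke", step size
$2^{-s}$ after $s$ strokes, floored at $1/64$) whenever the convergence
measure has not improved for 30 consecutive iterations, restoring the full
step immediately afterwards. A single damped step breaks a cycling orbit
but leaves every fixed point and its stability type untouched; this
matters, because a *permanently* damped iteration turns saddle points
(partial mixtures of two sources) into attractors and visibly degrades
recovery. Clean super-Gaussian problems converge in a handful of full
Newton steps and never stroke.

**Consensus.** The algorithm is restarted `ica_n_restarts` (default 100)
times from seeded random rotations. Components of every converged run are
matched to the first converged run by greedy absolute-Pearson pairing of
source rows; a component's stability is its mean $|r|$ across matched
partners, and the returned decomposition is the converged run with the
highest mean stability — a lightweight form of the stability-clustering
idea, chosen over full centrotype clustering for transparency. Zero
converged restarts is a hard error. Sign indeterminacy is fixed by forcing
nonnegative skewness on every source row; permutation indeterminacy is
absorbed downstream by phenotype-anchored scoring.

**Component scoring.** The visual criterion "the mixing column separates
the groups by sign" is formalized in `score_components()` as
`sign_separation` (best achievable fraction of samples whose entry sign
matches a group-constant assignment) plus a Welch $t$ statistic between
group entries; components are ranked by $|t|$. The pipeline mines all
components with perfect sign separation, falling back to the top-ranked
one. Gene calling standardizes the chosen source row to z-scores and keeps
$|z| \ge 2.5$ (inclusive). The threshold is applied to *standardized*
loadings so that 2.5 means the same thing on every mode; the mode is first
oriented so the disease group (first group in label order) has positive
mean mixing weight, making "up" interpretable.

## The nsNMF engine

`nsnmf_once()` initializes $W$ and $H$ from a seeded uniform draw on
$(\varepsilon, 1]$ and applies the divergence-form multiplicative updates
with the substitution scheme: $W S_\theta$ replaces $W$ when updating $H$,
and $S_\theta H$ replaces $H$ when updating $W$. Because
$(W S_\theta) H = W (S_\theta H) = W S_\theta H$, both half-steps
monotonically nonincrease the generalized Kullback–Leibler divergence
$D(V \,\|\, W S_\theta H)$, which is recorded every iteration; the KL form
follows the divergence update family the method descends from. Entries are
floored at `epsilon_floor` ($10^{-9}$) after every update so a
multiplicative zero can never absorb a factor entry.

Two numerical choices deserve note:

* **Normalization is deferred to the end of a run.** Unit-$\ell_1$ columns
  of $W$ (with the inverse scale absorbed into $H$) make loadings
  comparable across metagenes, but rescaling does not commute with
  $S_\theta$ — $(W D^{-1}) S_\theta (D H) \ne W S_\theta H$ for non-scalar
  $D$ — so a per-iteration rescale would break the descent guarantee. The
  factorization therefore runs unnormalized and is rescaled once after the
  final iteration.
* **Fixed iteration budget.** The default is 2000 iterations and 40
  restarts at $k = 2$, the study's settings; the restart with the lowest
  final objective wins. An optional relative-objective early stop
  (`conv_tol`) exists but is off by default so that reported traces always
  have the full budget.

$\theta$ defaults to 0.5 (the study never prints its value; 0.5 sits midway
and demonstrably sparsifies — the suite checks that median Hoyer
sparseness of metagenes at $\theta = 0.7$ strictly exceeds $\theta = 0$).
Nonnegativity of the input is the caller's responsibility via
`make_nonnegative()`, which shifts only gene rows containing a negative
value by minus their row minimum: that floors those rows at exactly zero
while preserving every within-gene difference, and leaves untouched both
already-nonnegative rows and already-nonnegative matrices. The nsNMF track
consumes the raw (unstandardized) matrix, since sample standardization
would destroy nonnegativity.

## The synthetic-data generators

Real data for this design are not redistributable, so the generators plant
known structure at the study's shape (5 + 8 samples, 6398 genes by
default; tests use a few hundred to a few thousand genes):

* `simulate_ica_dataset()` plants sparse super-Gaussian modes: a standard
  normal background with a fraction `frac_significant` (default 0.02) of
  genes spiked to $|z| =$ `signal_z` (default 4), signs recorded as the
  up/down truth. Spikes on a normal background give the heavy tails the
  tanh contrast targets, and double as the significant genes selection
  must recover. One mixing column has group-constant magnitude and
  opposite signs per group, so it perfectly sign-separates the phenotype
  before Gaussian noise (`noise_sd`, default 0.5) is added.
* `simulate_nmf_dataset()` plants `k` disjoint gene modules (loading
  $\approx$ `load_high` = 5 against a `load_low` = 0.25 background) and
  group-specific encodings (each group loads $\approx 1$ on its own
  metagene, $\approx 0.1$ elsewhere), plus zero-truncated Gaussian noise so
  the matrix stays nonnegative. Truncated-Gaussian noise is the simplest
  model preserving the $V \ge 0$ contract.

What the generators do **not** model: probe-level artifacts (PM/MM,
saturation), batch effects, correlated noise, or realistic library-size
variation. Passing recovery tests therefore demonstrates that the
algorithms find the structure they assume, at the study's scale and a
plausible signal-to-noise ratio — not that the pipeline is robust to every
pathology of real microarray data.

## Problem sizes used by the test suite

Recovery properties are checked at 2000 genes (ICA track, 4 planted modes,
20 restarts, 20 simulation seeds) and 500 genes (NMF track, 2 modules of
50 genes, best of 40 restarts × 2000 iterations, 20 seeds); KL descent on
20 random 50×10 problems over $k \in \{2,3\}$,
$\theta \in \{0, 0.5, 0.9\}$; structural shape conformance at the full
6398 × 13 design. These sizes make every planted effect comfortably
detectable while each suite run completes on a laptop.

## Degenerate inputs and tie rules

* Constant samples cannot be standardized and constant mixing columns get
  $t = 0$ (ranked last); both are explicit, not NaN.
* A duplicated sample (rank-deficient covariance) reduces the whitened
  dimension with a warning; a zero-variance sample is an error.
* Equal group means in NMF direction calling resolve to "down"; argmax
  ties in sample classification resolve to the lowest metagene index;
  sorting ties keep original order. All arbitrary, all fixed, all
  documented.
* Missing values are rejected at load time rather than imputed — the
  pipeline's inputs are complete by construction and no imputation rule is
  part of the method.

## Known limitations

* The discriminating-component rule (perfect sign separation, else top
  $|t|$) formalizes a judgement the original analysis made by eye; on weak
  phenotypes several components may tie at separation 1.0 and all are
  mined.
* Consensus selects one best run rather than averaging matched components;
  with unstable data the stability scores flag this rather than hide it.
* No rank-selection procedure for $k$; the configured value is used.
* `run_all()` executes restarts serially; reproducibility, not wall-clock
  speed, is the design goal.
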