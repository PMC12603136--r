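---
title: "Residue-level deuterium uptake by Bayesian change-point modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level deuterium uptake by Bayesian change-point modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxcp)
```

## The problem

Bottom-up hydrogen–deuterium exchange mass spectrometry (HDX-MS) measures
deuterium uptake per proteolytic *peptide*, not per residue. Because
peptides overlap, the data carry partial residue-level information, but
recovering it is an ill-posed linear inverse problem: naive inversion of
the peptide–residue coupling matrix is unstable, produces uptakes outside
[0, 1] and non-monotone "kinetics", and ignores that neighbouring residues
in the same structural element tend to exchange similarly.

`hdxcp` treats deconvolution as Bayesian inference in a generative model
whose latent quantity is each residue's uptake curve, and whose prior
encodes smoothness along the sequence through a change-point process. The
posterior is explored with a reversible-jump MCMC sampler, so the number of
kinetic segments is itself inferred, and every posterior draw automatically
satisfies the physics: uptake in [0, 1] and non-decreasing in time.

## The model

**Residue kinetics.** Residue $r$ has uptake
$$\mu_r(t) = (1-\pi_r)\left(1-e^{-b_r t^{p_r}}\right) +
             \pi_r\left(1-e^{-d_r t}\right),$$
a convex mixture of a stretched-exponential (Weibull) CDF — rate $b_r$
(1/s$^{p}$), stretch $p_r \in (0,1)$ — and a single-exponential CDF with
rate $d_r$ (1/s). The mixture weight $\pi_r$ lets the data choose between
the two kinetic families or interpolate. Being a mixture of CDFs, $\mu_r$
is 0 at $t=0$, bounded by 1, and monotone — the structural guarantee that
the classical solvers lack. (The curve is implemented as this convex
mixture; any reading of the formula that escapes [0, 1] would contradict
the model's own premise.)

**Observation model.** A peptide spanning residues start..end reports the
sum of $\mu_r(t)$ over its *exchangeable amides*
$\mathcal{R}_i = \{r : \text{start}_i + 2 \le r < \text{end}_i,\ r \neq
\text{Pro}\}$: the first two residues back-exchange too fast to retain
label and prolines have no amide hydrogen. The end-exclusive bound is
applied literally as the package's default convention; an
`inclusive_end` switch exists because the community is not unanimous about
the C-terminal residue. Observations (as fractions of a fully deuterated
control, rescaled to amide units) follow a Laplace distribution centred on
that sum with scale $l_i\sigma^2$, where $l_i = |\mathcal{R}_i|$. The
Laplace choice is deliberately heavy-tailed for robustness to outlier
peptides; the length factor lets long peptides be more variable. We take
the "scale multiplied by length" prescription literally as scale
$= l_i\sigma^2$; readings that use $l_i\sigma$ only re-scale $\sigma$ and
change none of the downstream statistics. Peptides with an empty
exchangeable set are flagged non-informative and excluded from the
likelihood with a warning.

**Change-point prior.** Parameters are piecewise constant along the
sequence: $K \sim \text{Pois}(\lambda)$ change points at ordered-uniform
positions in $(1, R)$ (a Poisson-process construction; locations are
continuous reals, residue membership uses $\tau_{k-1} \le r < \tau_k$).
Per segment, $\pi, p \sim \text{Beta}$, $b, d \sim$ Gamma with
hyper-rates that themselves carry Gamma hyperpriors (borrowing strength
across segments), and $\log\sigma \sim N(m, v^2)$.

## Defaults and what they mean

The model structure fixes the prior families but not their numbers; the
defaults below are this package's own choices, exposed in
`default_hyperparameters()` and `sampler_config()`:

* $\lambda = \max(1, R/25)$ — about one kinetic segment per 25 residues,
  growing with protein length as longer chains contain more structural
  transitions.
* $\pi, p \sim \text{Beta}(1,1)$; $b, d \sim \text{Gamma}(1,
  \text{rate})$ with $\text{rate} \sim \text{Gamma}(1,1)$ — weakly
  informative, covering second-scale to day-scale kinetics on the usual
  15 s–15,000 s exposure grid.
* $\log\sigma \sim N(-3, 1)$ — median noise scale $e^{-3} \approx 0.05$
  in normalized-uptake units, spanning roughly 0.007–0.4 within ±2 SD.
* Birth probability $\rho = 0.5$; random-walk proposals on transformed
  scales (logit for $\pi, p$; log for $b, d, \sigma$) with optional
  Robbins–Monro adaptation toward 30% acceptance during burn-in only, so
  the post-burn-in kernel is a fixed Markov kernel.
* The $\sigma$-vs-noise validation uses six injected noise scales in a
  doubling design (0.005 to 0.16), so adjacent levels are separated well
  beyond the posterior-mean estimation error of $\sigma$.
* Chain defaults 30,000 iterations, 10,000 burn-in, thin 10. The
  examples and tests in this package use shorter chains (a few thousand
  iterations) on problems of R = 30–60 with 25–55 peptides; with the
  data-driven initialization below these reach posterior-mean uptake RMSE
  < 0.05 against known truths, which is the regime the package's
  validation targets.

## Sampler

Each iteration performs, in fixed order for reproducibility: `n_rj`
dimension moves (birth with probability $\rho$, else death; the default is
one per sweep, and raising it is a cheap way to decorrelate the $K$ and
$\tau$ chains since each move costs one likelihood evaluation), a
Metropolis–Hastings
sweep over segment parameters and $\sigma$, and a conjugate Gibbs update
of the Gamma hyper-rates. Birth splits a uniformly chosen interval at a
uniform location and draws both daughter segments' parameters from the
prior; death deletes a uniformly chosen change point (over the $K$
present) and redraws the merged segment from the prior. Because proposals
are prior draws, the Jacobian is 1 and prior terms cancel against the
kernels; with the likelihood held flat the chain provably samples the
prior, which the test suite verifies by χ² against Pois($\lambda$) and KS
uniformity of the change-point locations — an end-to-end correctness check
of the trans-dimensional kernel.

**Initialization** is pragmatic rather than random: generalized-inverse
residue estimates per timepoint, projected onto [0, 1]; per-residue
least-squares fits of the kinetic curve on transformed scales; L1 trend
filtering (total-variation denoising, the same ADMM core as the
fused-LASSO baseline) of the four parameter tracks; segments read off the
filtered jump pattern; $\sigma$ from the median absolute normalized
residual. Rank deficiency is handled by the minimum-norm pseudo-inverse
and failed curve fits fall back to neutral values.

**Degenerate inputs.** Residues never covered by any peptide are carried
along by the prior (their posterior is prior-dominated); the sampler
raises an error on divergence ($\sigma > 10^6$ or a 5,000-sweep window
with no accepted move) rather than returning garbage.

## Reconstruction errors, probabilities, EFDR

With posterior-mean peptide predictions $\hat\mu_i$, the reconstruction
error is $\text{RE}_i = y_i - \hat\mu_i$. Per residue, the covering
peptides' length-normalized REs give the signed average (SignedARE), the
average magnitude (ARE), and the *sum* (TRE). Summation is the point:
several overlapping peptides erring in the same direction amplify, while
opposing errors cancel — redundancy becomes evidence. In differential
mode the model is fitted on the perturbed state and its predictions are
compared with the reference (APO) observations on the reference's own
peptide map; the reported effect is predicted − observed, so protection
is negative and de-protection positive.

Null calibration uses the model's own noise: per posterior sample $m$, a
TRE null draw is the sum of $n_r$ independent Laplace$(0, \sigma^{(m)})$
variates. Using the $\sigma$ draw directly (rather than $\sigma^2$, the
likelihood's normalized residual scale) widens the null and makes the
probabilities deliberately conservative — the calibration tests confirm
the observed false discovery proportion stays below the nominal level. One
null draw per posterior sample is the default (`n_inner` raises it).
EFDR at threshold $\tau$ is the mean posterior error probability among
calls, $\sum(1-p_i)\mathbb{1}\{p_i \ge \tau\} / \sum\mathbb{1}\{p_i \ge
\tau\}$, and the calling cutoff is the smallest observed $p$ below which
the EFDR would exceed the level. Averaging TRE over timepoints before
computing probabilities is the recommended summary when effects are
small; per-timepoint results are always reported alongside.

## Baselines

Four classical comparators share the interface `peptide_table ->
residues x times matrix`, each solved independently per timepoint (the
equations carry no temporal coupling, which is exactly why they can
violate monotonicity): the generalized inverse (unconstrained, the
documented pathology generator), box-constrained least squares (L-BFGS-B),
the fused LASSO $\tfrac12\|y - Cu\|_2^2 + \lambda\|Du\|_1$ on the [0,1]
box (two-split ADMM, tolerance $10^{-8}$, so results are
solver-independent to reported precision; the standard squared-error form
of the objective is used), and redundancy-weighted residue averaging.
Units: peptide uptakes enter in exchangeable-amide units so that the
binary coupling matrix (row sums $l_i$) maps residue fractions onto them —
normalization happens before inversion.

## Benchmark

The leave-digests-out design trains a residue-level model on one
protease's peptide map and predicts the *other* proteases' peptide uptakes
by summing inferred residue values. Digests are first placed on a common
scale by per-timepoint correction factors (ratio of medians over shared
peptides; the held-out digest is scaled to the training digest — which
side is scaled is configurable since either convention is defensible).
Errors are summarized by the median absolute deviation per digest ×
timepoint cell with peptide-level bootstrap (peptides are the exchangeable
unit, 1,000 resamples by default), alongside bounds/monotonicity violation
percentages with tolerance $10^{-9}$. MAD is computed on
fraction-of-control uptake. The package ships a fully synthetic
triple-digest analogue (one ground truth, three independently generated
maps, triplicate training digest, singlicate held-out digests, Laplace
noise at ~3% of the control on the fraction scale) so the benchmark
machinery is testable end to end without any external data. One caveat
the synthetic analogue makes explicit: with singlicate held-out digests
the held-out MAD has an irreducible observation-noise floor — an oracle
that predicts with the generating truth attains the same MAD as the best
methods — so at this scale the meaningful comparisons are mean error
relative to that floor and dominance over the unstable or over-smoothed
baselines, not per-cell win counts among near-floor methods.

## Conformational signature analysis

For a panel of states fitted against one reference, row $c$ of the
signature matrix $X$ is state $c$'s time-averaged differential TRE
profile. PCA (column-centred, unscaled — residues share units, and
variance-scaling would inflate low-signal residues) gives scores per state
and orthonormal residue loadings. With an annotation $y$ (two-class or
continuous; missing labels are projected, not fitted), a one-predictive +
one-orthogonal O-PLS decomposition separates $y$-correlated from
$y$-orthogonal variation. Uncertainty: the analysis is repeated on
signature matrices built from individual posterior samples (50 replicates
by default), each projection rigidly aligned to the posterior-mean
projection by a Procrustes transform without scaling (shape comparison
across equal-unit projections), after a deterministic sign convention
(largest-magnitude loading positive). A residue whose aligned loading
interval crosses zero is flagged: its contribution cannot be asserted as
non-zero. Time-averaged TRE feeds the signature matrix by default;
per-timepoint variants are a configuration choice.

## What the synthetic generator does and does not emulate

`simulate_truth` + `simulate_peptide_map` + `simulate_uptake_data`
reproduce the model's data-generating process at benchmark scale
(R ≈ 50–100, 30–55 peptides of length 5–20, exposures 15/150/1500/15000 s,
3 replicates, Laplace noise with the length factor), plus the localized
protection protocol (all peptides covering a residue scaled by
0.80/0.90/0.95). This validates correctness of inference and calibration
*under the model*. It does not emulate: back-exchange gradients,
bimodal/EX1 spectra, systematic inter-replicate drift, intensity-dependent
noise, or peptide misassignment. Passing tests therefore demonstrate
algorithmic fidelity, not robustness to every artefact of real LC-MS data;
the cross-digest benchmark on real multi-protease tables is the intended
real-data check, and the reader/normalizer layer accepts such exports.

## Known limitations

* Exchange chemistry (intrinsic rates, protection-factor back-calculation)
  is out of scope; the model works on normalized uptake directly.
* A single global $\sigma$ is shared across residues (by design, to borrow
  strength); strongly heteroscedastic peptides are handled only through
  the Laplace tails and the length factor. In differential comparisons
  each state uses its own fitted $\sigma$ draws for its null.
* Change-point structure is one-dimensional in sequence; contacts that
  couple distant residues are not modelled.
* The sampler is single-chain per call; run several seeds and compare
  (`run_rjmcmc` is deterministic given `seed`) for convergence assessment.
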