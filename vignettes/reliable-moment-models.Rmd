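---
title: "Reliable Moment maximum entropy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliable Moment maximum entropy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmme)
```

## The model

`rmme` models the joint distribution of binary population spiking patterns
$x \in \{0,1\}^N$ (one pattern per time bin, $x_i = 1$ if neuron $i$ spiked)
with a log-linear / maximum entropy family

$$P(x) = \frac{1}{Z}\exp\Big\{\sum_F \theta_F \prod_{i \in F} x_i\Big\},$$

where each *feature* $F$ is a subset of neurons, $\theta_F$ is its
interaction parameter, and $Z$ normalizes over all $2^N$ patterns. First-order
features control firing rates, second-order features pairwise correlations,
and higher-order features genuine multi-neuron coordination beyond what rates
and pairs explain. The maximum entropy principle makes this the least
committal distribution that matches the expectations of the chosen features.

The scientific problem is choosing *which* features to fit. Including all
features up to order $k$ costs $O(N^k)$ parameters, and high-order sample
moments are noisy because synchronous spiking is rare, so indiscriminate
inclusion overfits.

## Reliable moments and the selection threshold

The Reliable Moment (RM) criterion keeps every feature whose *uncentered
sample moment* clears a threshold:

$$\Big\langle \prod_{i \in F} x_i \Big\rangle \ge p_{\min}.$$

For binary data this moment equals the marginal probability that all neurons
of $F$ spike in the same bin. Two consequences:

1. **Downward closure.** A product of indicators can never exceed any of its
   sub-products, so the moment of a set is bounded by the moment of each
   subset. Thresholding moments therefore yields feature sets in which every
   higher-order feature brings all of its lower-order subsets along —
   a higher-order interaction is never fitted "bare".
2. **Apriori search.** The same hierarchy justifies the level-wise
   (frequent-itemset) search in `identify_reliable_moments()`: order-$k$
   candidates are generated only from selected order-$(k-1)$ features
   sharing a common prefix, and the search terminates at the first empty
   level. `reliable_moments_bruteforce()` is the exponential oracle used in
   the tests to prove the pruned search exact.

The threshold itself can be tied to a sampling-error argument rather than
chosen ad hoc: with $M$ samples, requiring the 95% confidence interval of a
moment's relative error to stay below $\alpha$ gives

$$p_{\min} = \frac{1}{1 + M(\alpha/2)^2},$$

implemented in `threshold_from_error()`. Ties are kept ($\ge$, not $>$): the
displayed set definitions use $\ge$ and tie behavior must be fixed for
reproducibility even though it only matters on a measure-zero set.
`max_order` (default unlimited) exists purely as a guard for pathologically
dense data.

## Parameter fitting

Two fitting routes share the surface `fit_parameters()`:

- **Minimum Probability Flow (`method = "mpf"`, default).** MPF avoids $Z$
  entirely by penalizing probability flow from the data states to their
  single-bit-flip neighbours:
  $$K(\theta) = \frac{1}{M}\sum_{x \in \text{data}} \sum_{i=1}^N
  \exp\Big\{\tfrac12\big(\log w(x^{(i)}) - \log w(x)\big)\Big\},$$
  with $w$ the unnormalized weight and $x^{(i)}$ the neighbour with bit $i$
  flipped. The single-bit-flip neighbourhood is the standard connectivity
  choice; it makes each term touch only the features containing the flipped
  neuron. The implementation precomputes a sparse design matrix (rows =
  site $\times$ data pattern) so each objective/gradient evaluation is one
  sparse mat-vec; the gradient is exact and is checked against finite
  differences in the tests. When the empirical distribution lies inside the
  model class, $K$ is stationary exactly at the generating parameters.
- **Exact maximum likelihood (`method = "exact_ml"`).** The convex reference:
  gradient = (exact model moments − data moments) via full $2^N$ enumeration,
  followed by Newton steps (the Hessian is the feature covariance under the
  model) that drive the moment mismatch to machine precision. Feasible to
  $N \le 20$; used in tests at small $N$ as the oracle that MPF is compared
  against, and wherever moment matching to $10^{-8}$ matters.

Numerical choices: $\theta$ initializes at 0 (the unique symmetric choice);
BFGS with analytic gradients for up to 200 parameters and limited-memory
L-BFGS-B beyond that (the dense BFGS inverse-Hessian update is $O(p^2)$ per
iteration and dominates for the thousands of features a low threshold can
select); convergence is declared at gradient norm $10^{-6}$, with a warning
and the best iterate returned after 500 iterations otherwise. An optional
ridge penalty (`l2_penalty`, default 0) is available but off by default.

## Normalization

MPF returns unnormalized weights; `fit_rm()` attaches $\log Z$ by one of:

- **exact** — brute-force $2^N$ summation, guarded at $N \le 25$ and the
  default up to $N = 20$;
- **good_turing** — the summed weights of the *observed* patterns estimate
  $Z \cdot C$ with $C$ the model mass on the observed support; $C$ is
  estimated by the Good–Turing coverage $1 - N_1/M$ ($N_1$ = patterns seen
  exactly once). The coverage is floored at $10^{-6}$ with a warning because
  nearly-all-singleton data carry no information about unseen mass. The
  coverage-ratio construction is this package's documented reading of the
  Good–Turing partition estimator; the Gibbs route below is the built-in
  cross-check, and both are validated against exact enumeration on 10-neuron
  populations in the tests;
- **gibbs_silent_state** — the silent pattern has weight 1, so its model
  probability is exactly $1/Z$; sampling and inverting the silent-state
  frequency estimates $Z$. Errors out (pointing at Good–Turing) when the
  silent state is never sampled.

## The Reliable Interaction baseline

`fit_ri()` implements the pattern-frequency baseline the RM criterion was
designed to improve on. Features are the supports of spiking *patterns* whose
frequency clears a threshold; $Z_{RI}$ is the inverse silent-state frequency;
parameters are solved algebraically, in increasing support size, so that
every reliable pattern is interpolated exactly:

$$\theta_S = \log\big(Z_{RI}\hat P(x_S)\big) - \sum_{T \subsetneq S,\ T \in \text{features}} \theta_T.$$

The construction is instantaneous and exact on the fitted patterns, but
pattern frequencies obey no subset hierarchy, so the feature set need not be
downward-closed: on the three-neuron toy fixture at threshold 0.1 it infers a
*pure triplet* model from data generated by a purely pairwise ground truth.
Because the partition estimate belongs to the data distribution rather than
to the inferred model form, the result is not a normalized distribution
(`ri_total_mass()` exposes this), and predictions for below-threshold
patterns — all collapsing toward $1/Z_{RI}$ times whatever fitted features
happen to be active — can be incoherent, including "frequencies" above 1.
`ri_pattern_frequency()` deliberately does not clamp them.

## Ground-truth simulators

Three generators define the package's study conditions; their defaults are
the conditions under which all experiments and tests run.

- **Toy fixture** (`toy_model()`, `toy_exact_distribution()`): $N = 3$
  homogeneous neurons, $\theta_i = -\alpha$, $\theta_{ij} = +\beta$, default
  $\alpha = 1$, $\beta = 1.2$. All eight probabilities are closed-form
  (0.1896 / 0.0698 / 0.0852 / 0.3455 by spike count), which makes every
  selection and fitting claim checkable to high precision.
- **Random pairwise populations** (`sample_ground_truth_pairwise()`):
  $\theta_i \sim \mathcal N(-3,\,0.25)$,
  $\theta_{ij} \sim \mathcal N(0,\,2/N)$, defaults chosen to give a few Hz
  per neuron at 20 ms bins and a broad, weak correlation distribution —
  the cortical regime. The negative first-order mean is essential: a
  positive mean of the same magnitude would drive per-bin firing
  probabilities toward 1, i.e. tens of Hz, far from the intended regime;
  likewise a pair variance of $2N$ instead of $2/N$ would produce
  order-of-magnitude stronger couplings than the intended weak-correlation
  regime. Since the ground truth here is purely pairwise, any fitted
  higher-order parameter is by construction spurious, which is what the
  comparison experiments measure.
- **Dichotomized Gaussian populations** (`sample_cortical_targets()`,
  `dg_calibrate()`, `dg_sample()`): rates drawn lognormal with mean 4 Hz and
  SD 2 Hz (converted to per-bin probabilities at 20 ms), pairwise Pearson
  targets $\mathcal N(0.1,\,0.05^2)$. Calibration sets thresholds
  $\gamma_i = \bar\Phi^{-1}(p_i)$ exactly and solves each latent correlation
  by bracketed root-finding on the bivariate normal orthant probability
  (via `mvtnorm`). Thresholding a latent Gaussian induces dense higher-order
  correlations — the property that makes DG data a stress test for models
  fitted with only low-order features.

**A calibration caveat.** A matrix of independently drawn pairwise targets
need not be jointly achievable by any Dichotomized Gaussian: the implied
latent correlation matrix can be indefinite. When that happens
`dg_calibrate()` projects to the nearest correlation matrix (Higham's
alternating projections) and records both the projection distance and the
analytically achieved pairwise correlations (attributes
`projection_distance`, `achieved_corr`). The residual distortion is
irreducible — it reflects infeasibility of the targets, not estimator noise —
and it is why round-trip tests of calibration compare against
achievable-side errors of a few times $10^{-2}$ at worst for $N = 20$
target draws. Per-pair targets are also clipped into the Fréchet-feasible
interval (shrunk by $10^{-3}$) before root-finding, with clip counts
recorded.

## Sampling

`gibbs_sample()` runs sequential single-site Gibbs updates in fixed site
order with $P(x_i = 1 \mid x_{-i}) = \sigma(\Delta_i)$, $\Delta_i$ being the
sum of $\theta$ over features containing $i$ whose other members are active.
One retained sample = one full sweep; defaults are 1000 burn-in sweeps and no
thinning — conservative for the weakly coupled models generated here, and
validated by a chi-square equilibration test against exact enumeration at
$N = 4$. The inner loop is compiled (Rcpp) and draws from R's RNG, so a seed
fully determines the raster. 10,000 samples of 20 ms bins correspond to
200 s of recording, the recording length used in the comparison experiments.

## Evaluation

Because the RI baseline is unnormalized, Kullback–Leibler divergence is
unusable for model comparison; `dissimilarity()` instead computes the
weighted mean absolute base-2 log ratio
$d(P,Q) = \sum_{x \in D} P(x)\,|\log_2 P(x)/Q(x)|$ over a domain $D$ of
patterns — by default every pattern observed in the reference data,
*including* singletons. The model side is evaluated in log space
(log-weight minus log-partition), so astronomically small model
probabilities remain finite contributions instead of underflowing; a model
that assigns *exactly* zero to an observed pattern is an error, since the
metric is undefined there. The reference side may be an empirical
distribution or — when the ground truth is itself a tractable model — exact
ground-truth probabilities, which is the sharper test of rare-pattern
prediction: empirical singleton frequencies are all quantized to $1/M$,
while exact probabilities span orders of magnitude.

`split_old_new()` partitions test patterns by whether they occurred in
training; `hoi_magnitude_stats()` summarizes $|\theta|$ over orders $\ge 3$;
`run_comparison_experiment()` drives the full protocol: per ground-truth
population, fit RM models over a moment-threshold grid (default 5 log-spaced
values in $[0.001, 0.05]$) and RI models over a frequency-threshold grid
(default $[10^{-5}, 5\times10^{-3}]$ — lower because pattern frequencies are
smaller than marginal moments, which makes matching grid positions
comparable in parameter count), and tabulate feature counts, higher-order
magnitudes, dissimilarities on all/old/new patterns, and fit times.

## Problem sizes

The package's experiments and acceptance-level tests run at desk scale,
chosen as the package's own defaults: 5 populations of $N = 20$ neurons per
ground-truth class, 5 thresholds per model family, training and test sets of
$M = 10{,}000$ bins (200 s at 20 ms), $10^5$ samples for Monte-Carlo
round-trip checks, and 20 replicates for partition-estimator calibration at
$N = 10$. Full-scale reruns (more populations, denser grids) are a matter of
passing larger arguments to `run_comparison_experiment()`.

## What the synthetic data do and do not show

The generators emulate stationary, binned population activity with realistic
rates, weak pairwise correlations, and (for DG) dense higher-order structure.
They do not emulate temporal dependencies across bins, nonstationarity,
stimulus drive, or recording artifacts. Tests passing on these data show the
estimators are correct and well-calibrated *under the model assumptions*;
they do not certify performance on real recordings, where bin-width choice,
nonstationarity, and unmodeled latencies all intrude.

## Conventions and limitations

- Neuron indices are 1-based; spiking patterns map to integer keys with
  neuron 1 in the least-significant bit. The bit-order convention is this
  package's choice and is documented rather than inherited.
- Binary validation is strict: a 0.999 entry is an error, never coerced.
- Brute-force enumeration (exact $Z$, exact moments, total RI mass) is
  guarded at $N \le 25$; `exact_ml` at $N \le 20$.
- MPF is non-convex in general; on data far from the model class the
  optimizer can stall at the iteration cap (it warns and returns the best
  iterate). The convex `exact_ml` route exists precisely to audit such fits
  at small $N$.
- Very low RI thresholds (below $1/M$) make every observed pattern
  "reliable"; the recursion then telescopes enormous alternating parameters,
  and predictions for unfitted patterns can overflow to absurd magnitudes.
  This is a faithful property of the construction, reported as-is.
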