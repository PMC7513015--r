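# rmme — Reliable Moment maximum entropy models for spike data

`rmme` fits maximum entropy (log-linear) models with **adaptively selected
pairwise and higher-order interactions** to binary population spike rasters
(M time bins × N neurons). It is aimed at systems neuroscientists who want to
ask which multi-neuron interactions a dataset can actually support, fit them,
and get a *normalized* probability distribution they can use for
information-theoretic analysis.

## The model

Population spiking patterns `x ∈ {0,1}^N` are modeled as

    P(x) = (1/Z) exp{ Σ_F θ_F Π_{i∈F} x_i },

one interaction parameter θ per neuron subset F ("feature"). The problem is
choosing the features. The **Reliable Moment (RM)** criterion keeps every
feature whose uncentered sample moment ⟨Π_{i∈F} x_i⟩ — for binary data, the
probability that all neurons of F spike in one bin — is at least a threshold
p_min. Because a set's moment never exceeds any subset's moment, the selected
set is *downward-closed*: no higher-order interaction is ever fitted without
its lower-order parts. The threshold can be tied to a sampling-error bound,
p_min = 1 / (1 + M(α/2)²), so "reliable" means "estimable to relative error α
at the 95% level from M samples".

Parameters are fitted by Minimum Probability Flow (no partition function
needed) or exact maximum likelihood (convex oracle, N ≤ 20), and the model is
normalized exactly (N ≤ 25), by a Good–Turing coverage estimate, or from the
silent-state frequency of Gibbs samples. The **Reliable Interaction (RI)**
baseline — feature selection by pattern frequency, algebraic parameters,
Z from the inverse silent-state frequency — is included for comparison,
together with ground-truth simulators (random pairwise maximum entropy
populations; Dichotomized Gaussian populations with lognormal rates and
normally distributed correlations) and evaluation metrics for held-out data.

## Worked example

Fit RM and RI models to 200 s of simulated data from a 20-neuron pairwise
ground-truth population, and ask how much spurious higher-order structure
each infers:

```r
library(rmme)
gt    <- sample_ground_truth_pairwise(20, seed = 1)
train <- gibbs_sample(gt, 10000, seed = 101)   # 10,000 bins = 200 s at 20 ms
test  <- gibbs_sample(gt, 10000, seed = 102)

m <- fit_rm(train, p_min = 0.001)              # moment-thresholded maxent fit
table(feature_orders(m$features))
#>   1   2   3
#>  20 174  22
unlist(hoi_magnitude_stats(m))                 # orders >= 3
#>      count   mean_abs     sd_abs
#> 22.0000000  0.2949136  0.1900068

ri <- fit_ri(empirical_distribution(train), 2e-4)
unlist(hoi_magnitude_stats(ri))
#>       count    mean_abs      sd_abs
#> 198.0000000   0.9341353   0.7629551
```

The ground truth is purely pairwise, so every higher-order parameter is
spurious: the RM fit infers 22 of them with mean magnitude 0.29, the RI fit
198 with mean magnitude 0.93. On held-out data both models describe the
observed patterns comparably:

```r
td <- empirical_distribution(test)
dissimilarity(td, m)    #> 0.3973486   (weighted mean |log2 P/Q|, bits)
dissimilarity(td, ri)   #> 0.3579748
```

but for *previously unseen* patterns, weighed by their exact ground-truth
probabilities, the normalized RM model extrapolates nearly twice as well:

```r
sp  <- split_old_new(empirical_distribution(train), td)
gtz <- set_log_partition(gt, exact_log_partition(gt), "exact")
dissimilarity(gtz, m,  key_to_pattern(sp$new, 20))   #> 0.008327755
dissimilarity(gtz, ri, key_to_pattern(sp$new, 20))   #> 0.01489653
```

`run_comparison_experiment()` runs this protocol across populations and
threshold grids for both ground-truth classes; `vignettes/` documents the
methods, defaults, and numerical choices. A command-line front end
(`inst/cli/rmme.R`) exposes `make-ground-truth`, `simulate`, `fit-rm`,
`fit-ri` and `evaluate` subcommands over text rasters and JSON models.

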