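# emgsynergy

Muscle synergy analysis asks how the central nervous system coordinates many
muscles with few commands: multi-channel surface EMG recorded during a task is
reduced to a small set of *synergies* — fixed weightings across muscles driven
by shared time-varying excitation primitives. Several factorisation methods
can perform this reduction, and they make different assumptions about the
probability distribution of the data. `emgsynergy` implements the full
comparison pipeline for the four methods most used in the field —
non-negative matrix factorisation (NMF), principal component analysis (PCA),
independent component analysis (ICA) and factor analysis (FA) — scored both
by reconstruction accuracy and by how well each method's primitives match the
*distribution* of the muscle activation patterns. It is aimed at motor
control and biomechanics researchers choosing a factorisation method for
gait-type data.

## The model and metrics

Activation patterns form an L×N matrix **x** (L muscles, N time points of the
normalised gait cycle). All methods fit the linear synergy model

    x = w h + e

with **w** (L×K) the synergy weights and **h** (K×N) the excitation
primitives, minimising ‖x − x̃‖ under method-specific constraints
(non-negativity for NMF; orthogonal primitives for PCA; pre-whitening plus a
kurtosis-maximising rotation for ICA; principal-axis loadings for FA).
Methods are compared with:

* **VAF** = 1 − ‖x − x̃‖²⁄‖x‖² (global, uncentred). The number of synergies
  K is the smallest value at which every method exceeds 85% VAF.
* **Maximum dissimilarity D**: the two-sample Kolmogorov–Smirnov statistic
  D = max|F(x_l) − F(h_k)| between the empirical CDFs of each muscle pattern
  and each primitive, reduced by worst case over muscles and then over
  primitives.
* **Occurrence of agreement**: the percentage of muscle–primitive pairs for
  which the KS test fails to reject distribution equality at α = 0.05.

Because public gait EMG with this exact protocol is not available, the
package ships a seeded generator of gait-like raw EMG whose amplitude
distribution is controllable: each channel is a generalized-Gaussian carrier
(calibrated in closed form) modulated by a burst gait envelope, reproducing
the documented decrease of EMG excess kurtosis from ≈1.75 (walking,
near-Laplacian) to ≈1.1 (fast running, towards Gaussian), along with a
ground-truth synergy simulator for parameter-recovery studies.

## Worked example

```r
library(emgsynergy)

## ground-truth dataset: 10 muscles, 3 synergies, noise sd 0.05
sim <- simulate_synergy_dataset(noise_sd = 0.05, seed = 42)

fit <- synergy(sim$x, "nmf", k = 3, seed = 1)
fit
#> Muscle synergy decomposition (NMF), K = 3
#>   10 muscles x 200 time points; VAF = 0.9923
#>   674 iterations

ks_compare(sim$x, fit)
#> KS comparison (10 muscles x 3 primitives, NMF):
#>   maximum dissimilarity D = 0.5550
#>   occurrence of agreement = 3.3% (alpha = 0.05)

select_synergy_count(sim$x, seed = 1)   # VAF > 85% for all methods
#> [1] 3
```

The VAF of 0.992 says the three-synergy NMF reconstruction captures 99.2% of
the signal energy; the selection confirms K = 3 is the smallest K at which
all four methods clear 85%. `D` and the agreement percentage quantify how
close the primitives' amplitude distribution is to that of the activations
(smaller D / larger agreement = closer).

Raw-EMG simulation and preprocessing:

```r
tr <- simulate_emg_trial("walk", seed = 1)
dist_summary(as.vector(tr$signal))
#> n = 16500: mean -0.007195, sd 1, skewness 0.04397, excess kurtosis 1.735
x <- preprocess_trial(tr)    # 30-400 Hz band-pass, rectify, 6 Hz envelope,
dim(x)                       # cycle-normalised 10 x 200 activation matrix
#> [1]  10 200
```

An end-to-end batch comparison (simulate → preprocess → factorise → score →
repeated-measures ANOVA) is available through `simulate_trials()` and
`run_comparison()`; see the methods vignette
(`vignettes/synergy-comparison.Rmd`) for the science and the design choices.

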