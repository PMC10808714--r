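# flimmix

Determining the fractional contributions of individual fluorophores to a
mixed fluorescence decay, directly from time-correlated single-photon
counting (TCSPC) histograms.

## The problem

Fluorophores with overlapping emission spectra cannot be separated by
optical filtering, but they can be separated by their fluorescence
lifetimes. A pulsed-excitation TCSPC measurement of a mixture yields a
multi-exponential decay

$$I(t) = \sum_{i=1}^{n} \alpha_i\, e^{-t/\tau_i},$$

and the quantity of interest is each fluorophore's share of the
collected signal,

$$P_i = \frac{\alpha_i \tau_i}{\sum_j \alpha_j \tau_j}.$$

Recovering all $(\alpha_i, \tau_i)$ by free multi-exponential fitting is
ill-posed when lifetimes are close. `flimmix` instead regresses $P$
directly from the binned histogram with a small fully connected neural
network (hidden layers 40–20–10 for two fluorophores, 70–50–30–10 for
more; ReLU; Adam on mean-squared error, batch 500, 20 epochs, learning
rate 1e-3), trained on Monte-Carlo simulated curves and optionally
fine-tuned on labelled measured curves. The package is aimed at people
designing or analysing lifetime-multiplexed assays: FLIM, lifetime flow
cytometry, multiplex biosensing.

It provides:

* **a photon-level TCSPC simulator** (`simulate_decay()`,
  `generate_dataset()`) with laser pulse shape (Gaussian core +
  exponential turn-off), SPAD timing jitter, fixed acquisition window
  and Poisson background at a configured SNR, plus the exact closed-form
  expectation (`expected_histogram()`);
* **the neural fraction estimator** (`flim_ann()`, `predict()`,
  `fine_tune()`), deterministic under a seed;
* **a fixed-lifetime non-negative least-squares baseline**
  (`ls_fixed_tau_fit()`) — the classical reference method;
* **accuracy/precision statistics** per fluorophore
  (`evaluate_fractions()`: mean offset, offset standard deviation in
  signed and absolute conventions, $R^2$);
* **lifetime-spacing experiments** (`sweep_spacing_two()`,
  `sweep_middle_lifetime_three()`, `find_min_spacing()`,
  `fit_spacing_law()`, `max_distinguishable()`) that measure how
  precision depends on the lifetime spacing $\Delta\tau$ and distil a
  minimal-spacing design law $\Delta\tau_{\min} = 10^{aN+b}$ for $N$
  fluorophores at a 5% precision target;
* **a command-line interface** (`inst/cli/flimmix.R`) wrapping
  simulate / train / predict / evaluate / sweep / law with YAML configs
  and CSV/JSON artifacts.

## A worked example

Two fluorophores with lifetimes 10.6 ns and 5.6 ns, mixed 100 µl : 50 µl
with intensity factors 1 : 1.8:

```r
library(flimmix)

study <- instrument_config()   # 1.28 us window, 312.5 ps bins, SNR 100
mx <- mixture_sample(c(10.6, 5.6), volumes_ul = c(100, 50),
                     intensity_factors = c(1, 1.8))
mx
#> Fluorophore mixture (2 components)
#>   lifetime_ns fraction amplitude
#> 1        10.6   0.5263   0.04965
#> 2         5.6   0.4737   0.08459

curve <- simulate_decay(mx, study, seed = 1)
snr_of(curve)        # ~100: peak counts over tail noise level

ls_fixed_tau_fit(curve, c(10.6, 5.6), study)
#> Fixed-lifetime least-squares fit
#>   lifetime_ns fraction
#> 1        10.6   0.5501
#> 2         5.6   0.4499
#>   background 15.9 counts/bin; residual norm 338.6
```

The least-squares fit, with the lifetimes known and held fixed, recovers
the true fractions (0.526 / 0.474) to a few percent from a single curve.
The neural estimator is trained on simulated mixtures with random
fractions and evaluated on held-out curves:

```r
train <- generate_dataset(10000, c(10.6, 5.6), study, seed = 2)
test  <- generate_dataset(2000,  c(10.6, 5.6), study, seed = 3)
fit <- flim_ann(train)
evaluate_fractions(predict(fit, test), test$labels)
#> Fraction-recovery report (per fluorophore)
#>  component    n mean_offset_signed mean_offset_abs offset_std_signed
#>          1 2000          -0.002399         0.01071           0.01313
#>          2 2000           0.002399         0.01071           0.01313
#>  offset_std_abs r_squared
#>        0.007964    0.9979
#>        0.007964    0.9979
```

Read: across 2,000 unseen mixtures the estimator's fraction estimates
are essentially unbiased (mean signed offset −0.24 percentage points),
spread by about 1 percentage point, and track the truth with
$R^2 = 0.998$ — the regime where this 5 ns lifetime spacing is easily
resolved. As the spacing shrinks the histogram stops carrying component
information; the estimator then collapses to the prior mean and the
absolute offsets plateau at their flat-prior closed forms (mean 25%,
spread ≈14.4%, $R^2 \to 0$). `find_min_spacing()` locates, for each
fluorophore count, the smallest spacing that still achieves 5%
precision, and `fit_spacing_law()` summarises those minima as
$\Delta\tau_{\min} = 10^{aN+b}$; with lifetimes limited to ~20 ns this
caps lifetime multiplexing at four fluorophores
(`max_distinguishable()`).

The CLI runs the same pipeline from the shell:

```sh
Rscript inst/cli/flimmix.R simulate --config sim.yaml --out data/ --seed 7
Rscript inst/cli/flimmix.R train    --config train.yaml --out model/
```

## The methods vignette

`vignettes/lifetime-unmixing.Rmd` documents the simulator's physical
model and its limits, the estimator's representation and training
choices, the evaluation conventions, and the design decisions behind the
spacing experiments.
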