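---
title: "Unmixing fluorophores by lifetime: models, estimator and design rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing fluorophores by lifetime: models, estimator and design rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

When several fluorophores with overlapping emission spectra are excited
together, spectral filtering cannot tell them apart — but their
fluorescence *lifetimes* can. A time-correlated single-photon counting
(TCSPC) measurement of the mixture yields a decay histogram following a
multi-exponential law

$$I(t) = \sum_{i=1}^{n} \alpha_i \, e^{-t/\tau_i},$$

with per-component amplitudes $\alpha_i$ and lifetimes $\tau_i$. The
quantity of biological interest is usually not the parameter pair but the
**fractional contribution** of each fluorophore to the collected signal,

$$P_i = \frac{\alpha_i \tau_i}{\sum_j \alpha_j \tau_j},$$

because $\alpha_i\tau_i$ is the time-integral of component $i$'s decay.
Free multi-exponential fitting of $(\alpha_i, \tau_i)$ is a classic
ill-posed problem: when lifetimes are close, many parameter combinations
fit the data equally well. `flimmix` implements the direct route — a
small feed-forward neural network regressing $P$ from the binned
histogram — together with the Monte-Carlo simulator used to train it, a
constrained least-squares reference method, evaluation statistics, and
the spacing experiments that turn precision into a fluorophore-choice
design rule.

For mixtures prepared volumetrically, the ground truth is
$P_{\mathrm{ref},i} = I_{0,i} v_i / \sum_j I_{0,j} v_j$ with per-volume
intensity factors $I_{0,i}$ and volumes $v_i$
(`reference_fractions()`).

## The decay simulator

`simulate_decay()` samples photons one at a time:

1. the emitting component is chosen with probability $P_i$ — by the
   definition of $P$ as the fraction of collected signal, this makes the
   simulated labels exact by construction;
2. the fluorescence delay is $\mathrm{Exp}(\tau_i)$;
3. the laser emission offset follows the pulse model: a Gaussian core
   (FWHM 1.25 ns by default, $\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$)
   plus an exponential turn-off tail (600 ps characteristic time);
4. detector (SPAD) timing jitter adds a zero-mean Gaussian
   ($\sigma$ = 150 ps by default);
5. the arrival time is binned on a 312.5 ps grid over a 1.28 µs window
   (4096 bins, half-open bins indexed by start time); photons outside
   the window — including negative arrivals produced by the Gaussian
   blur — are dropped, not clamped.

A constant-rate Poisson background is added per bin; its level is set
from the configured SNR, defined as peak expected signal over background
level (default 100). The default photon budget is $5\times10^4$ signal
photons per curve. The budget and the jitter magnitude are not uniquely
dictated by published hardware descriptions; both are explicit,
configurable `instrument_config()` fields, and the defaults are what we
consider a realistic single-acquisition budget for a SPAD array at these
count rates.

The noise-free expectation (`expected_histogram()`) has a closed form:
the arrival-time distribution is the convolution of two exponentials
(fluorescence and laser turn-off) with a Gaussian (laser core + jitter),
i.e. a signed combination of exponentially-modified-Gaussian CDFs. The
implementation evaluates it in log space so the
$e^{\sigma^2/2\tau^2}$ factor cannot overflow for short lifetimes, and
nudges the two time constants apart when they collide (the Erlang
limit). This closed form serves three independent roles: the
chi-square goodness-of-fit oracle for the Monte-Carlo sampler, the
per-component basis shapes of the least-squares baseline, and the
background-level calibration.

The photon loop itself runs in C++ with a dedicated xoshiro256++ RNG and
ziggurat samplers (the generic R RNG costs ~100 ns per photon, which
dominates dataset generation at $10^4$ curves). The kernel's seed is
drawn from R's RNG stream, so `set.seed()` semantics are preserved:
identical seeds give bit-identical curves. Dataset generation derives a
counter-based sub-seed per curve, so any curve can be regenerated in
isolation and reproducibility does not depend on generation order.

Training labels are drawn from a flat Dirichlet prior over the fraction
simplex (`generate_dataset()`, configurable concentration). The flat
prior matters for interpreting degenerate limits: an estimator that
collapses to the prior mean has mean absolute offset $1/4$ and absolute
offset spread $1/(4\sqrt3) \approx 0.144$ for two components — exactly
the plateau the experiments show when lifetimes coincide.

**What the simulator does not emulate:** detector dead time, pile-up
(count rates are assumed below its influence, so sampling photons in
aggregate rather than per pulse is statistically equivalent),
afterpulsing, pixel cross-talk, array geometry, read-out gaps, spectral
effects, and lifetime heterogeneity within one fluorophore. Passing
tests therefore validate the method under idealised Poisson + IRF +
background statistics; on real instruments the second training stage
(`fine_tune()` on measured, labelled curves) is the mechanism that
absorbs the mismatch.

## The estimator

`flim_ann()` trains a fully connected feed-forward network mapping the
normalised leading bins of a curve to the fraction vector:

* hidden layers (40, 20, 10) for two components and (70, 50, 30, 10)
  for three or more, ReLU activations;
* minibatch Adam on mean-squared error, batch size 500, 20 epochs,
  learning rate $10^{-3}$ — a fixed short schedule, no early stopping or
  validation-based selection;
* deterministic given the config seed (initialisation and shuffling).

Two representation choices are ours and deserve justification:

* **Input window.** The network reads the leading `input_bins` bins
  (default 256, i.e. 80 ns — several times the longest lifetime of
  common fluorophores, so essentially all decay information is inside).
  Auto-configured experiments scale this window to cover at least eight
  times the longest lifetime in play, because spacing ladders for five
  components reach lifetimes around 40 ns where a fixed 80 ns window
  would truncate most of the slow components' signal.
* **Normalisation.** Each input row is divided by its total counts
  (which makes predictions invariant to overall intensity — a ×10
  brighter curve predicts identically) and then multiplied by
  `input_bins` so bin values are $O(1)$. The rescaling is pure optimiser
  conditioning: with raw sum-normalised inputs (mean $1/256$), the fixed
  20-epoch schedule underconverges for three or more components.

The output head is linear — no softmax, matching plain MSE training —
and is initialised at the prior mean (weights zero, bias $1/K$). The
symmetric head initialisation makes the entire training trajectory
exactly equivariant under relabelling of the components, a property the
test suite asserts to machine precision. At inference, raw outputs are
clipped to $[0,1]$ and renormalised to sum to one; this is recorded
post-processing, not part of the loss.

`fine_tune()` continues training from existing weights on a second
labelled set (fresh optimiser moments, own schedule), leaving the
original model untouched — the supervised adaptation stage for measured
curves whose lifetimes have shifted, e.g. by chemical interaction.

## The least-squares reference

With lifetimes known and held fixed, the histogram is a non-negative
linear combination of per-component expected shapes plus a constant
background. `ls_fixed_tau_fit()` solves this by Lawson–Hanson NNLS
(unweighted by default; an optional Poisson-variance weighting mode
divides rows by $\sqrt{\max(y,1)}$). Non-negativity is enforced because
unconstrained amplitude fitting is unstable precisely in the
close-lifetime regime of interest; the constrained fixed-$\tau$ fit is
the fair classical baseline, and on noise-free input it is exact to
solver tolerance. Because it uses the true basis shapes at full
resolution, it doubles as an information-limit probe (see below).

## Evaluation conventions

For each fluorophore, `evaluate_fractions()` reports the mean offset
$\langle\Delta P\rangle = \frac1N\sum(P_{\mathrm{est}}-P_{\mathrm{ref}})$,
the population standard deviation of the offsets about their own mean,
and the squared Pearson correlation $R^2$ (a constant prediction is
scored 0; regression-against-identity $R^2$ is available as an option).
Both a **signed** and an **absolute** offset convention are computed and
carried in every report. The signed convention is the natural
accuracy/precision reading; the absolute convention is the one under
which the uninformative-limit plateau takes the closed-form values
$25\%$ / $14.4\%$, and it is the convention the spacing experiments use
throughout. For two components the offsets of one fluorophore are
exactly the negatives of the other (fractions sum to one), so the
per-component statistics are mirror images.

## Spacing experiments and the design law

`sweep_spacing_two()` scans the lifetime spacing
$\Delta\tau = \tau_B - \tau_A$ at fixed $\tau_A = 4$ ns, training a
fresh estimator per grid point and replicate (3 replicates by default,
statistics averaged across replicates). Precision and accuracy improve
steeply with spacing and $R^2$ saturates towards one; below
$\Delta\tau \approx 0.1$ ns the curves carry essentially no component
information and the MSE-optimal response approaches the prior mean,
producing the plateau described above. At generous photon budgets the
collapse is not perfectly total: in our runs at 0.05 ns spacing the
offsets sit on the plateau closed forms while a small nonzero
correlation with the truth survives ($R^2$ of order 0.1), fluctuating
with training stochasticity.

`sweep_middle_lifetime_three()` reproduces the three-fluorophore
experiment: $\tau_A = 4$ ns and $\tau_C = 10$ ns fixed, the middle
lifetime moving between them. The middle component is always the
hardest; its precision is best near uniform spacing, where the two gaps
are balanced. The precision curves of the outer components cross
slightly *below* the uniform-spacing point in our runs (near 2.4 ns
rather than 3 ns): at equal absolute gaps the slow pair is closer in
relative terms ($10/7 < 7/4$), so the slow component remains the harder
of the two until the middle lifetime moves somewhat past the midpoint.

`find_min_spacing()` turns precision into a design rule: for $N$
fluorophores on an equally spaced ladder starting at 4 ns, it bisects on
the spacing against a 5% held-out precision target and
`fit_spacing_law()` fits $\log_{10}\Delta\tau_{\min}$ against $N$,
yielding a law of the form $\Delta\tau_{\min} = 10^{aN+b}$.
`max_distinguishable()` converts the law and a usable lifetime span
(most common fluorophores stay under 20 ns) into the largest feasible
fluorophore count — four at the 5% target under the default conditions.

Two methodological choices here:

* **Aggregation.** The 5% target applies to the *mean* of the
  per-fluorophore standard deviations. The conservative alternative —
  the worst component — is available (`aggregate = "worst"`), but at
  single-acquisition photon budgets it is unattainable for $N \ge 4$ at
  *any* spacing: the middle components of a four-step ladder are
  information-limited, not spacing-limited. The fixed-$\tau$
  least-squares fit on the full-resolution curve, which knows the true
  lifetimes and basis shapes, already shows ≈10% spread for the worst
  component there, so no trained estimator can reach 5% on that
  reading. The mean reading is the one under which a minimal-spacing
  law exists at all in this regime.
* **Replicate escalation.** Bisection evaluations run one replicate
  first and escalate to the full 3-replicate average only within
  ±0.01 of the target, where the decision is genuinely close. Grid
  sweeps always use the full replicate count.

## Numerical and protocol choices

* Bin convention: half-open $[t, t+\Delta)$, time zero at window start,
  bins indexed by start time.
* Degenerate inputs: all-zero amplitude products, duplicate lifetimes in
  the LS basis, constant references in $R^2$, and missing seeds all
  raise informative errors rather than returning NaN.
* Seeds are mandatory wherever randomness occurs; every experiment
  object records the seeds needed to regenerate it exactly.
* Held-out protocol: all reported statistics come from a fresh test set
  simulated with a disjoint seed, never from training curves.
* Problem sizes: the standard experiment uses $10^4$ training and
  2,000 test curves (matching the scale at which the estimator's
  precision saturates); the packaged acceptance checks run the
  two-fluorophore anchors at exactly that scale, the three-fluorophore
  sweep at 8,000 training curves over a 5-point grid with 3 replicates,
  and the spacing-law search at $10^4$ training / 800 test curves with
  bisection tolerance 0.2 ns.

## Known limitations

* The estimator is specific to the instrument configuration and
  component count it was trained on; curves with a different binning
  must be re-binned or the model re-trained (`predict()` errors on bin
  mismatch rather than guessing).
* Near the precision target the $\sigma(\Delta\tau)$ curve is shallow
  for $N \ge 4$, so $\Delta\tau_{\min}$ for large $N$ carries larger
  uncertainty than for $N = 2, 3$ — visible in the evaluation tables
  that `find_min_spacing()` attaches to its result.
* Simulated precision is an upper bound on real-world precision;
  reference-fraction uncertainty in pipetted mixtures adds error that
  simulation does not see.

## A worked session

```{r example}
library(flimmix)

study <- instrument_config()           # 4096 x 312.5 ps, SNR 100
mx <- mixture_sample(c(10.6, 5.6), volumes_ul = c(100, 50),
                     intensity_factors = c(1, 1.8))
curve <- simulate_decay(mx, study, seed = 1)

# classical reference: fixed-lifetime NNLS
ls_fixed_tau_fit(curve, c(10.6, 5.6), study)

# neural estimator: simulate labelled training data, fit, evaluate
train <- generate_dataset(10000, c(10.6, 5.6), study, seed = 2)
test  <- generate_dataset(2000, c(10.6, 5.6), study, seed = 3)
fit <- flim_ann(train)
evaluate_fractions(predict(fit, test), test$labels)
```
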