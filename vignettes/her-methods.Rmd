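---
title: "Heartbeat-evoked response analysis: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat-evoked response analysis: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hertools)
```

## The problem this package addresses

The brain responds to each heartbeat: averaging neural activity
time-locked to the ECG R-peak yields a heartbeat-evoked response (HER).
In experiments where participants let their thoughts wander during long
fixation periods and then rate the interrupted thought on continuous
scales (for instance, self-relatedness scales), the question is whether
the single-trial HER amplitude preceding the probe covaries with those
ratings, and whether that covariation is genuinely locked to heartbeats
rather than to slow, rating-correlated background activity.

The package implements the full analysis chain for this question:

1. R-peak detection in the ECG by QRS-template correlation;
2. preprocessing of the neural channels (zero-phase Butterworth
   band-pass, optional downsampling, bipolar re-referencing);
3. extraction of epochs −100…600 ms around the two R-peaks that precede
   each stimulus by at least 700 ms, amplitude/dynamic-range artifact
   rejection, and per-trial averaging into one HER per trial and site;
4. a per-timepoint Pearson correlation between single-trial HER
   amplitude and ratings, tested with a cluster-based permutation test
   restricted to 300–600 ms post R-peak (the window free of
   cardiac-field artifact), with Bonferroni correction across sites;
5. a surrogate-heartbeat control that reassigns heartbeat timings
   across trials;
6. a group-level median-split ("high" vs "low" ratings) cluster-based
   paired t-test with sign-flip permutations;
7. a heart-rate confound check (correlation between the pre-stimulus
   RR interval and the ratings).

Because no patient data are distributable, every stage is validated on
a synthetic-session generator with known ground truth.

## The statistical model

At epoch sample $t$, with $n$ analyzable trials, HER amplitude $x_i(t)$
and rating $y_i$:

$$ r(t) = \mathrm{cor}(x(t), y), \qquad
   t(t) = \frac{r(t)\sqrt{n-2}}{\sqrt{1-r(t)^2}}. $$

Samples inside the test window whose two-tailed $p$ falls below the
cluster-forming threshold (0.05 by default, i.e. $|t| >
t_{0.975,\,n-2}$) are grouped into maximal runs of temporally adjacent,
same-sign samples; each cluster is summarized by its summed $t$. The
ratings are shuffled (10 000 times by default) with respect to the
HERs; each shuffle contributes the maximum positive and the minimum
negative cluster sum to two null distributions. An observed positive
cluster is referred to the maximum distribution, a negative one to the
minimum distribution. The group test is identical in structure but uses
the per-sample paired $t$ across subjects on the high-minus-low
difference, with random within-subject condition sign flips as the
permutation scheme.

### Monte Carlo p-values, ties, exactness

* Default estimator: $(\text{hits} + 1)/(n_{\text{perm}} + 1)$, which
  cannot return 0 and is the standard finite-sample-valid choice. The
  literal "proportion of elements" estimator is available
  (`estimator = "proportion"`).
* Ties between a permutation extreme and the observed statistic count
  as "at least as extreme" (conservative), with a relative tolerance of
  `1e-8` so a permutation that reproduces the observed statistic (the
  identity) ties despite floating-point noise.
* For $n \le 9$ trials all $n!$ rating permutations can be enumerated
  (`exact = TRUE`), and for $n \le 16$ subjects all $2^n$ sign
  patterns; $p$ is then the exact proportion with the identity
  included. The test suite checks both against independent brute-force
  oracles.

### Per-tail testing and the familywise rate

The procedure tests each observed cluster against its *own-sign*
extreme distribution at the full $\alpha$, with no doubling — the
literal reading of the standard two-tailed cluster-permutation recipe.
Both tails are therefore each tested at $\alpha$, and the familywise
probability of calling *any* cluster significant in a pure-noise
session is close to $2\alpha$ (the acceptance report measures it on
200 simulated null sessions at $\alpha = 0.05$). This is a property of
the recipe,
not a bug; it is why the acceptance check that expects the familywise
rate inside a binomial band around 0.05 stays red under the default.
`tail_correction = "double"` doubles the Monte Carlo p-values (capped
at 1), which restores a nominal two-tailed familywise $\alpha$; the
same simulations land inside the band under that option. Reports
produced by the package state that the default is a per-tail test.

### Zero-variance samples

A sample where the HER has zero variance across trials has an undefined
correlation: it is propagated as `NA`, treated as sub-threshold, and
therefore breaks cluster adjacency. It is never silently set to zero.

## The synthetic world

`simulate_session()` generates a complete session under a stated world
(`sim_config()`); defaults are chosen once, as follows, and the
acceptance checks run under them:

* **Trial timing** — fixations uniform on 13.5–29.9 s ending in a
  stimulus; 5 s lead-in, 6 s inter-trial interval. Stimuli are placed
  so at least two R-peaks precede each stimulus by ≥ 700 ms within the
  trial (the generator shifts a stimulus by whole mean-RR steps in the
  rare case this fails, which cannot occur at default fixations).
* **ECG** — QRS built from Gaussian Q/R/S components (R width 7 ms SD),
  plus P wave and a T wave at R + 269 ms (a typical R–T interval);
  mean RR 0.85 s with i.i.d. Gaussian jitter, SD 50 ms truncated at
  ±3 SD (a typical resting SDNN); additive white noise with SD 0.1 of
  the R amplitude.
* **Ratings** — latent equicorrelated Gaussian mapped through the
  normal CDF, i.e. a Gaussian copula with uniform marginals on [0, 1].
  Two scales ("I", "Me") with latent correlation 0.91 by default. The
  source experiments report no rating distributions, so uniform
  marginals are a convention, not an estimate.
* **Neural channels** — 1/f background noise (exponent 1) with
  per-sample SD 0.5 recording units; at every heartbeat a Gaussian
  evoked kernel (latency 425 ms, SD 12 ms) with peak amplitude
  `her_baseline + coupling_beta * rating` for beats inside a trial.
  The kernel SNR is set so the kernel shape is recoverable by
  averaging at realistic trial counts (30–60 epochs); real single-trial
  HERs have far lower SNR than this.
* **Implied correlation** — at the kernel peak, the generator's
  closed-form implied Pearson correlation between trial HER amplitude
  and rating is
  $\beta\sigma_y / \sqrt{\beta^2\sigma_y^2 + \sigma_\varepsilon^2}$
  with $\sigma_y = 1/\sqrt{12}$ and
  $\sigma_\varepsilon = \text{noise SD}/\sqrt{2}$ (two epochs averaged
  per trial). `coupling_beta_for_r()` inverts it; this calibration is
  defined on *raw* (unfiltered) amplitudes — band-pass filtering
  removes noise power and raises the realized correlation, so the
  filtered pipeline detects such coupling more easily.
* **Cardiac-field artifact** — an optional damped oscillation after
  each R-peak, tapered to exactly zero at 280 ms, i.e. strictly outside
  the 300–600 ms analysis window (with the same seed, the late samples
  of a CFA and a no-CFA session are bit-identical).
* **Confound fixture** — an optional slow drift proportional to
  `rating − 0.5` over each fixation, plateauing after the first quarter
  of the fixation (the slow-drift limit). It creates genuine
  HER-amplitude/rating correlation at any epoch position without being
  heartbeat-locked.

What the generator does **not** emulate: volume conduction and montage
geometry beyond a simple per-contact gain, epileptic activity, real
QRS/T morphological variability, rating–heart-rate coupling (the source
experiments report none), or realistic single-trial SNR. A green test
therefore establishes the correctness and calibration of the analysis
machinery, not field performance on clinical recordings.

## Design choices where the method description was open

* **R-peak placement.** Within each supra-threshold correlation
  episode the peak is placed at the maximum of the *correlation* trace,
  estimated as the centroid of the supra-threshold correlation mass.
  The matched filter is the optimal timing estimator under additive
  noise; placing the peak on the raw signal maximum instead
  (`peak_on = "signal"`) misplaced ~30% of peaks by more than 2 ms at
  the default noise level in simulation, so it is not the default.
  Detection runs on wideband ECG: a 0.5–25 Hz band-pass blurs QRS and
  T waves into near-identical smooth bumps and destroys the
  discriminability that template correlation relies on (observed as
  T-wave false positives in simulation).
* **Template construction.** Provisional peaks from a robust amplitude
  heuristic on the z-scored ECG, segments realigned to their maxima and
  averaged, then one refinement pass with the provisional template.
  A user-supplied waveform overrides construction.
* **Rejection thresholds.** The conventional published limits (±200,
  300-in-20 ms) are implausible if read as millivolts for bipolar
  physiology; the package treats them as configurable numbers in
  recording units with defaults 200/300. The sliding 20 ms window is
  evaluated at every sample (strictest reading), spanning
  `round(20 ms × fs) + 1` samples, and "a range of 300 or more"
  rejects.
* **"Preceding by at least 700 ms"** means R-peak time ≤ stimulus −
  0.7 s; the epoch may extend to R + 600 ms, i.e. up to stimulus −
  100 ms.
* **Trials left with a single epoch** after rejection keep that epoch
  as their HER by default (flagged in `n_epochs`); `min_epochs = 2`
  drops them.
* **Zero-phase filtering** (forward–backward, odd-extension padding) so
  HER latencies are not shifted; the band-pass is applied as a cascade
  of second-order sections because expanding an eighth-order narrow
  band transfer function is numerically unstable (pole radii cross 1
  after polynomial rounding).
* **Median-split ties** go, in trial order, to the currently smaller
  group ("low" first when equal), so the imbalance is at most one and
  the split depends only on ranks.
* **Surrogate timing transfer** re-expresses each trial's two R-peak
  times relative to its stimulus before transfer, so surrogate epochs
  stay inside the receiving trial's fixation; assignments whose epochs
  would run off the recording are redrawn and logged. The tail follows
  the observed extreme cluster: minimum surrogate sums for a negative
  observed cluster, maximum for a positive one.
* **Group permutation scheme** is within-subject condition sign flips,
  the standard exact construction for a paired design.

## Known limitations

* The surrogate control has an asymmetry worth knowing: if a strong
  rating-correlated drift coexists with a *rating-independent*
  heartbeat-locked response, timing reassignment misaligns that evoked
  response, inflates across-trial variance, and dilutes near-saturated
  correlations — the observed statistic then looks extreme for a
  reason unrelated to heartbeat-locking of the *effect*. The
  surrogate-control validation therefore uses the pure confound world
  (no heartbeat-locked component); mixed worlds make the control
  conservative in the direction of rejecting.
* The per-tail familywise rate discussed above (~2α under the default).
* EDF output quantizes to 16 bits over each channel's range and stores
  physical ranges in 8-character ASCII fields; round-trip error is
  bounded by range/65535/2 plus that ASCII precision.
* Monte Carlo p-values move between runs within
  $\sqrt{p(1-p)/n_\mathrm{perm}}$; all entry points take seeds and are
  bit-reproducible given one.

## What the validation suite establishes

The test suite (`tests/testthat/`) checks every operation against
independent brute-force oracles (per-sample correlation, elementwise
cluster scans, sliding-range loops, exhaustive permutation and
sign-flip enumerations), verifies determinism byte-for-byte through the
command-line pipeline, and measures type-I calibration, parameter
recovery (implied |r| = 0.5 coupling at 400–450 ms), surrogate
power/specificity, and R-peak accuracy on the generator at the stated
defaults. `scripts/acceptance.R` recomputes those measurements from
scratch against the installed package and writes them as JSON. Nothing
in this vignette states an empirical result that those scripts do not
themselves compute.
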