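# hertools

Single-trial and group-level analysis of **heartbeat-evoked responses
(HERs)** in intracranial or scalp electrophysiology, for experiments in
which participants let their thoughts develop during long fixation
periods and then rate the interrupted thought on continuous scales.
The package answers two questions: *does the amplitude of the neural
response to heartbeats preceding the probe covary, trial by trial, with
the ratings?* and *is that covariation genuinely locked to heartbeats?*

It is aimed at electrophysiologists analysing ECG-synchronized iEEG /
EEG / MEG-ROI data, and at methodologists who want a fully testable
reference implementation: a synthetic-session generator with known
ground truth makes every stage verifiable without patient data.

## The statistic at the core

For each recording site, epochs are extracted −100…600 ms around the
two R-peaks preceding each stimulus by ≥ 700 ms, artifact-rejected
(|x| > 200 or a 20 ms dynamic range ≥ 300, in recording units) and
averaged into one HER per trial. With n trials, HER amplitude x_i(t)
and rating y_i,

    r(t) = cor(x(t), y),      t(t) = r(t) * sqrt(n-2) / sqrt(1 - r(t)^2)

Samples in 300–600 ms post R-peak (the window free of cardiac-field
artifact) with two-tailed p < 0.05 are clustered by temporal adjacency
and sign; each cluster's summed t is referred to the distribution of
extreme (max-positive / min-negative) cluster sums over shuffles of the
ratings — the Monte Carlo p — then Bonferroni-corrected across sites.
Two controls: a **surrogate-heartbeat test** (the pair of pre-stimulus
heartbeat timings of trial i is reassigned to trial j; ratings never
move) and a **heart-rate check** (correlation of the pre-stimulus RR
interval with the ratings). The group analysis median-splits trials
into "high"/"low" per subject and runs the same cluster machinery on
the paired t with within-subject sign flips.

## Worked example

Simulate a session whose heartbeat-locked response is coupled to the
"I" rating scale at an implied single-sample correlation of −0.5
(ratings on the two scales correlate at 0.91, so the effect is equally
visible through the "Me" scale — as happens with strongly correlated
self-relatedness ratings):

```r
library(hertools)

cfg <- sim_config(n_trials = 40, seed = 7)
cfg$coupling_beta <- coupling_beta_for_r(-0.5, cfg)
ses <- simulate_session(cfg)

ecg   <- get_channel(ses$recording, "ECG")
tpl   <- build_template(ecg, 1000)
peaks <- qc_ibi(detect_r_peaks(ecg, tpl, 1000))
peaks
#> <rpeak_series> 1299 peaks, IBI 850 +/- 49 ms, 0 flagged interval(s)

rec <- bandpass(ses$recording)              # 0.5-25 Hz, zero phase
ep  <- reject_artifacts(extract_her_epochs(rec, peaks, ses$trials))
her <- average_trial_her(ep)                # one HER per trial

ratings <- setNames(ses$trials$Me_rating, ses$trials$trial_id)
res <- bonferroni(
  cluster_permutation_correlation(her, ratings, n_perm = 10000, seed = 1),
  n_tests = 2)                              # two sites tested, say
res
#> <cluster_result> single-trial correlation, window 300..600 ms, 10000 permutation(s), n = 40
#>   negative cluster 407..441 ms: sum(t) = -125.7, Monte Carlo p = 0.0207, corrected p = 0.0414
#>   positive cluster 544..563 ms: sum(t) = 47.9, Monte Carlo p = 0.1304, corrected p = 0.2608
#>   note: each cluster is tested against its own-sign extreme distribution (per-tail test)
```

The negative cluster at 407–441 ms recovers the injected coupling
(ground truth window 400–450 ms, negative sign); the positive cluster
is noise and stays non-significant. The heart-rate confound check is
null, as the generator contains no rating–RR coupling:

```r
rr <- prestim_rr(peaks, ses$trials)
heart_rate_control(rr, ratings[names(rr)])
#> heart-rate control: r = -0.009, t(38) = -0.06, p = 0.96
```

The surrogate control (`surrogate_heartbeat_test()`) confirms
heartbeat-locking by showing that reassigning heartbeat timings across
trials destroys the cluster statistic.

A subcommand CLI drives the same pipeline file-to-file (EDF recordings,
TSV trial tables / peaks / clusters, JSON manifests):

```sh
Rscript -e 'hertools::her_cli()' simulate --seed 7 --out d/sim --n-trials 40 --coupling-r -0.5
Rscript -e 'hertools::her_cli()' rpeaks   --recording d/sim/recording.edf --out d/pk
Rscript -e 'hertools::her_cli()' analyze  --recording d/sim/recording.edf \
    --peaks d/pk/peaks.tsv --trials d/sim/trials.tsv --out d/an \
    --scale I --window 300 600 --n-perm 10000 --seed 1
```

Fixed seeds give byte-identical output files across reruns.

## Calibration note

The default decision rule tests each observed cluster against its
own-sign extreme permutation distribution at the full alpha (the
literal two-tailed cluster-permutation recipe). Both tails are then
each tested at alpha, so the familywise null rate of "any significant
cluster" is about 2·alpha (measured ≈ 0.10 at alpha = 0.05). The
corresponding acceptance check, which expects a binomial band around
0.05, is therefore red by design under the default;
`tail_correction = "double"` restores nominal two-tailed calibration
and passes the same band. See the methods vignette
(`vignettes/her-methods.Rmd`) for the full discussion.
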