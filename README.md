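# burstsupp

Burst suppression (BS) — the alternation of high-amplitude bursts and
near-isoelectric suppressed periods in the EEG of deeply anesthetised
patients — is a routinely monitored risk marker for postoperative delirium
(POD) in elderly surgical patients. `burstsupp` is an R package for
anesthesia-EEG research groups that need three things in one place:

1. **An automated BS detector** for multichannel frontal EEG (Fp1, Fp2, F7,
   F8): a rectified-signal moving-average envelope is thresholded per
   channel, suppression is accepted only where *all* channels agree, bursts
   are classified by the ACNS polyphasic criteria (≥ 0.5 s, ≥ 4 phases), BS
   epochs are delimited from the first to the last suppression of a run, and
   each recording is summarised by its total suppressed time and
   burst-suppression ratio, BSR = 100 · (suppressed time) / (analysed time).
2. **Expert-annotation calibration**: the suppression threshold θ and
   envelope window *w* are chosen by exhaustive grid search minimising the
   mean squared BS-duration error against annotated ground truth, and the
   detector's accuracy is reported as per-recording median absolute errors
   under stratified k-fold cross-validation (stratified by anesthetic
   agent, so propofol and sevoflurane EEG are balanced across folds).
3. **Cohort statistics** for the agent × BS × POD question: contingency
   analysis (uncorrected χ², relative risk, Cohen's
   h = |2·asin√p₁ − 2·asin√p₂|, two-proportion power), Mann–Whitney
   comparisons of skewed BS durations, and multivariable logistic models of
   POD — including the interaction model whose product term
   (sevoflurane × any BS) decomposes into conditional odds ratios relative
   to the propofol/no-BS cell:
   OR(sevo+BS) = OR(sevo) · OR(BS) · OR(interaction).

Because raw clinical recordings are rarely shareable, the package also ships
ground-truth simulators: anesthesia-like EEG with agent-specific spectra
(propofol: alpha + slow-delta; sevoflurane: theta) and injected suppression
episodes, and patient cohorts with a prescribed conditional POD-risk
structure. Every stochastic function is deterministic given its seed.

## Worked example

```r
library(burstsupp)

## simulate 120 s of propofol EEG with one BS episode
## (3 suppressions x 4 s, bursts of 1.5 s in between)
spec <- eeg_sim_spec("propofol", duration = 120, fs = 178,
                     episodes = data.frame(onset = 30, supp_dur = 4,
                                           burst_dur = 1.5, n_alt = 3),
                     seed = 5)
sim <- simulate_eeg(spec)

## detect at the default 5 uV threshold, 0.5 s envelope window
s <- detect_bs(sim$recording)
s
#> <bs_summary> 120 s analysed
#>   suppressed time: 11.1404 s (BSR 9.284%)
#>   BS epochs: 1 spanning 14.7528 s
#>   any BS: TRUE
duration_error(s, sim$truth)
#> duration_error      bsr_error
#>      0.8595506      0.7162921
```

The injected truth is 12 s of suppression in one 14.75 s epoch; at the
uncalibrated default threshold the detector recovers 11.14 s (the ~0.86 s
shortfall is envelope smearing at the six segment boundaries). Calibration
removes most of that:

```r
corp <- simulate_corpus(n_per_group = 10, intensity = "low",
                        duration = 120, fs = 178, seed = 17)
cv <- bs_calibrate(corp, k = 5, seed = 17)
cv
#> <bs_cv> 5-fold stratified cross-validation (20 recordings)
#>   median |BS duration error|: 0 s  [IQR 0-0.05056]
#>   median |BSR error|: 0 %
```

(A median of 0 is expected: under the low episode intensity about half of
the recordings carry no BS at all, and the calibrated detector produces no
false positives on them.)

Cohort analysis on a simulated cohort with the default risk structure
(conditional odds ratios 1.50, 1.63, and 1.50 · 1.63 · 3.80 = 9.30):

```r
coh <- simulate_cohort(cohort_sim_spec(n = 20000, seed = 11))
fit_interaction_model(coh)$conditional_or
#>                cell odds_ratio    ci_lo    ci_hi
#> 1    propofol_no_bs   1.000000       NA       NA
#> 2       propofol_bs   1.390507 1.277142 1.513934
#> 3 sevoflurane_no_bs   1.523843 1.402938 1.655167
#> 4    sevoflurane_bs   8.953897 8.078354 9.924334
```

## Command line

A thin CLI over the same functions lives at `inst/cli/bsdetect.R`
(subcommands `detect`, `cv`, `simulate-eeg`, `simulate-cohort`,
`analyze-cohort`); after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bsdetect.R", package="burstsupp"))')" \
  detect --input rec.edf --out summary.json --annotations-out pred.csv
```

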