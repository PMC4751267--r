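# snrlb

Objective subject exclusion for event-related potential (ERP) studies.

Deciding which subjects' ERPs are "too noisy" to analyse is usually
done by eye — qualitative, unstandardised, and open to investigator
bias. `snrlb` replaces it with a statistic: the **lower bound of a
bootstrap confidence interval on the ERP signal-to-noise ratio**
(SNR_LB). A subject whose waveform has statistically exceeded a stated
SNR level stays in the sample; one that has not is excluded by a rule
anyone can reproduce and report.

## The statistic

For a baseline-corrected waveform,

```
SNR_ERP = 20 * log10(RMS_post / RMS_pre)   [dB]
```

the RMS voltage over the post-stimulus window of interest relative to
the pre-stimulus baseline RMS (0 dB = no more signal than noise). From
a subject's full pool of `N` usable segments, `S` segments are drawn
with replacement, signal-averaged, baseline-corrected and scored;
repeating this `B = 9999` times yields a distribution of SNR values,
and **SNR_LB** is the lower bound of its equal-tailed 90% percentile
interval. `S` is matched to the per-condition trial count
(`choose_S()`), so SNR_LB describes waveforms at the averaging depth
the analysis will actually use. The recommended minimum inclusion
criterion is **3.0 dB** (ties pass; criteria below 0 dB warn).

The package also ships the method's full Monte Carlo validation as
seed-reproducible functions — a synthetic ERP subject generator
(canonical Gabor-plus-Gaussian waveform in 30 Hz low-passed 1/f
noise), bootstrap-count error analysis, presence and quality ROC
studies, fit–SNR correlation, and the zero-SNR noise calibration —
plus preprocessing utilities (baseline correction, linear detrending,
±150 µV artifact rejection, electrode pooling) and a small CLI.

## Worked example

```r
library(snrlb)

# Two simulated subjects: a clean one and one at the noise boundary
good <- synth_subject(synthetic_spec(noise_multiplier = 10,
                                     subject_id = "S01", seed = 1))
weak <- synth_subject(synthetic_spec(noise_multiplier = 38,
                                     subject_id = "S02", seed = 2))

cfg <- bootstrap_config(S = 100, B = 9999, seed = 7)
d <- bootstrap_snr(good, cfg)
d
#> <snr_distribution: B = 9999, N = 800, S = 100; mean 9.51 dB, 90% CI [4.78, 14.21] dB>

lbs <- c(S01 = snr_ci(d)$lower_db, S02 = snr_lb(weak, cfg))
round(lbs, 2)
#>   S01   S02
#>  4.78 -0.55

classify_subject(lbs, criterion = 3.0)
#>   S01   S02
#>  TRUE FALSE

sample_summary(lbs, criterion = 3.0)
#> <sample_summary: n = 2; mean 2.12, median 2.12, SD 3.77, IQR 2.66, range [-0.55, 4.78] dB; 1 failing 3.0 dB>
```

S01's waveform has statistically exceeded 4.78 dB of SNR and is
retained at the 3.0 dB criterion; S02's lower bound sits below 0 dB —
its evoked response never reliably emerges over baseline noise — so it
is excluded, and the summary line is what a methods section would
report for the sample. `choose_S(rep(100, 8))` returns `100`: an
experiment with 800 artifact-free trials split over eight conditions
bootstraps 100-segment averages.

Real data enter through `read_segments()` (a headerless CSV voltage
matrix, rows = trials, plus a JSON sidecar with `fs` and `t_start_ms`),
or through the CLI:

```sh
inst/exec/snrlb simulate --out subject.csv --multiplier 10 --seed 1
inst/exec/snrlb compute subject.csv --conditions 8 --out report.json
inst/exec/snrlb validate --study presence-roc --seed 1
```

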