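# finpulse

Passive acoustic monitoring of fin whales (*Balaenoptera physalus*) around
seismic surveys asks a simple question with several moving parts: do
detections of the stereotyped 20-Hz pulse — a ~1-s downsweep from about
23 Hz to 18 Hz — drop when airgun arrays are firing, and is the drop more
than an artefact of the shots acoustically masking the calls? `finpulse`
implements that analysis end to end as a tested, reusable R pipeline:

1. **Synthetic scenes** (`simulate_scene`, `simulate_counts`): annotated
   low-frequency soundscapes — downsweep whale pulses over pink ambient
   noise, impulsive airgun shots every 16 s each masking 5.5 s on average
   (range 2.7–7.7 s) — and hourly count tables with the mixed
   negative-binomial structure the inference stage assumes. Every
   downstream stage is testable without any recordings.
2. **Spectrogram frontend** (`stft_bandlimit`, `pcen`, `to_input`): 30-s
   frames at 200 Hz → 256-point Hann STFT at 75% overlap → 4–80 Hz
   band-limiting → per-channel energy normalisation (PCEN) → a 97 × 90 × 3
   tensor.
3. **CNN frame detector** (`build_detector`, `train_detector`,
   `predict_detector`): a small convolutional backbone, global average
   pooling, dense 512/256 head with dropout 0.5/0.2, softmax(2); Adam with
   a staircase learning-rate decay (0.001 × 0.75 every 90 steps). Binary
   detections at threshold 0.5 (`classify_detections`), evaluated by
   confusion counts, precision/recall/F1, ROC/AUC and a Youden-J optimal
   threshold (`roc_curve`, `optimal_threshold`).
4. **Aggregation** (`hourly_counts`, `summarize_counts`, `daily_totals`):
   pulse-positive 30-s frames per instrument-hour, partitioned into the
   survey periods Shooting 1 (JD 156–173), Quiet 1 (174–196), Shooting 2
   (197–212) and Quiet 2 (213–218); corrupt days are blanked as missing.
5. **Count model** (`fit_nb_glmm`, `emm_periods`, `pairwise_contrasts`,
   `nb_glmm_diagnostics`): hourly counts `y ~ NB2(mu, theta)` with
   `log mu = beta[period] + b_instrument + b_instrument:day`, fitted by a
   Laplace-approximation maximum-likelihood routine written for this
   package; estimated marginal means on the response scale with Wald 95%
   CIs, Tukey-adjusted pairwise rate ratios, and simulation-based residual
   diagnostics.
6. **Masking correction** (`build_table1`): worst-case accounting —
   masked hours = shots × 5.5 s, masked fraction per shooting period, the
   correction factor `1/(1 − mean fraction)`, corrected shooting means and
   observed vs worst-case percentage drops.
7. **Reporting** (`loess_smooth`, `uncertainty_ribbon`, `period_boxes`):
   LOESS (span 0.3) daily trends with a detector-uncertainty ribbon scaled
   by FPR = 0.158 and FNR = 0.132, and per-period box summaries.

## Worked example

The masking-corrected detection table from the survey's printed inputs
(66,898 and 84,417 shots over 432 and 384 h of shooting; per-instrument
pooled quiet/shooting mean hourly detections):

```r
library(finpulse)
build_table1()
#> Masked time: Shooting 1 102/432 h (23.7%); Shooting 2 129/384 h (33.6%)
#> Mean masked fraction 0.286, correction factor 1.40
#>   instrument quiet_mean shooting_mean pct_drop_observed corrected_shooting_mean
#> 1      OBS18       76.2          16.6              78.2                    23.2
#> 2      OBS46       58.4          16.2              72.3                    22.7
#> 3      OBH56       67.8          26.6              60.8                    37.2
#>   pct_drop_worst_case
#> 1                69.6
#> 2                61.1
#> 3                45.1
#> Mean drop: observed 70.4%, worst case 58.6%
```

Detections drop 60.8–78.2% during shooting (mean 70.4%); even if every
single airgun shot had hidden a call, the guaranteed drop is still
45.1–69.6%. The full count-model analysis on simulated data with the
study's structure:

```r
counts <- simulate_counts(count_sim_config(seed = 1))
fit <- fit_nb_glmm(counts)
emm_periods(fit)          # per-period mean detections/hour with 95% CIs
pairwise_contrasts(fit)   # Tukey-adjusted rate ratios between periods
```

The scripts under `analysis/` run the stages in order
(`Rscript analysis/01_simulate_scenes.R`, ... `05_trends.R`) and write
their tables and figures under `results/`.

## Vignette

`vignettes/finpulse-methods.Rmd` describes the models and their
assumptions, what the synthetic scenes do and do not emulate, the
numerical choices in the Laplace fitter, and known limitations.
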