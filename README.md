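# atmbeat

Automated template matching (ATM) for recognizing hERG-inhibitor-induced
arrhythmia in impedance-based cardiomyocyte mechanical beating signals, at
the single-beat level.

Cardiomyocytes on an interdigitated electrode array modulate the electrode
impedance as they contract. Demodulating the 10 kHz drive carrier yields a
slow periodic "mechanical beating" trace; hERG K⁺-channel blockers
(astemizole, droperidol, sertindole, ...) provoke EAD-like extra
contractions that appear as additional peaks within a beat. `atmbeat`
classifies every valley-to-valley beat unit by the Pearson correlation

r(X, Y) = Cov(X, Y) / sqrt(Var[X] · Var[Y])

between the beat and a stored template that is first **dynamically
length-matched** to the beat by cubic-spline interpolation and resampling.
A beat is arrhythmic when its correlation with the rhythmic template falls
below 0.94 (rhythmic-template mode), or when its best correlation over a
set of arrhythmic templates exceeds 0.90 (arrhythmic-multitemplate mode,
max rule). The package covers the whole chain:

| stage | functions |
| --- | --- |
| carrier synthesis / FFT amplitude demodulation | `synth_carrier()`, `demodulate()` |
| conditioning (5-point smoothing, 10× spline upsampling) | `smooth5()`, `upsample()` |
| beat segmentation (adaptive-threshold valley detection) | `detect_valleys()`, `extract_beats()`, `beat_features()` |
| template matching and calibration | `extract_template()`, `fit_template_length()`, `pearson_r()`, `match_beat()`, `pairwise_self_similarity()`, `calibrate_threshold()` |
| evaluation | `accuracy_from_counts()`, `evaluate_predictions()`, `summarize_group()` |
| synthetic ground-truth experiments | `sim_config()`, `synth_trace()`, `atm_experiment()`, `run_pipeline()` |

A synthetic beating-signal simulator with per-beat ground truth is a
first-class part of the package (no recordings are deposited with the
source analysis); see `vignette("atm-methods")` for the waveform model and
every numerical design decision.

## Worked example

```r
library(atmbeat)

# 40 beats alternating rhythmic / 2-peak / rhythmic / 3-peak morphologies
lt <- synth_trace(sim_config(n_beats = 40,
  morphology_schedule = c("rhythmic", "arrhythmic_2peak",
                          "rhythmic", "arrhythmic_3peak"),
  rng_seed = 42))
lt
#> <labeled_trace> 40 beats (20 rhythmic / 20 arrhythmic), <impedance_trace> 5005 samples @ 12.8 ms, 64.051 s, range [6.685, 6.761] a.u.

hr <- upsample(smooth5(lt$trace), 10)   # 12.8 ms -> 1.28 ms
v  <- detect_valleys(hr)                # 41 valleys -> 40 beats
beat_features(upsample(lt$trace, 10), detect_valleys(upsample(lt$trace, 10)))
#> <beat_features> peak 6.758 / valley 6.687 a.u. (amplitude 0.07111); peak interval 1.562 s / valley interval 1.562 s

tpl   <- extract_template(hr, v, beat_choice = 1, label = "rhythmic")
beats <- assign_truth_labels(extract_beats(hr, v), lt)
res   <- match_beats(beats, list(rhythmic = tpl))   # threshold 0.94
res[[2]]
#> <match_result> beat 2 -> arrhythmic (r: rhythmic=0.8863)

evaluate_predictions(res, vapply(beats, `[[`, "", "truth_label"))
#> <atm_eval_report> 40/40 matched, accuracy 100.00%
```

The mean features above read back the simulator's configured levels
(peak 6.758 / valley 6.687 a.u., period 1.563 s within a sample interval);
beat 2, a two-peak beat, correlates only 0.886 with the rhythmic template
and is flagged arrhythmic; all 40 beats match their ground-truth labels.

The two template modes compared on one 240-beat mixed experiment
(`atm_experiment(n_beats = 240, seed = 1)`):

```text
<atm_eval_report> [rhythmic_template] 240/240 matched, accuracy 100.00%
<atm_eval_report> [arrhythmic_multitemplate] 210/240 matched, accuracy 87.50%
```

The rhythmic template recognizes every beat, while the arrhythmic
multitemplates miss the peak-shifted two-peak variants (their correlation
with both canonical arrhythmic templates stays below 0.90) — the
characteristic failure mode that motivates rhythmic-template ATM.

## Command line

A thin wrapper over the same functions ships in `inst/cli/atm.R`:

```sh
atm=$(Rscript -e 'cat(system.file("cli", "atm.R", package = "atmbeat"))')
Rscript $atm simulate --n-beats 40 --seed 42 \
    --schedule rhythmic,arrhythmic_2peak --out trace.csv --labels labels.csv
Rscript $atm preprocess --in trace.csv --smooth 5 --upsample 10 --out trace_hr.csv
Rscript $atm extract-template --in trace_hr.csv --beat 1 --label rhythmic --out tpl.json
Rscript $atm match --in trace_hr.csv --template tpl.json --mode rhythmic --rth 0.94 --out results.csv
Rscript $atm evaluate --results results.csv --truth labels.csv --out report.json
```

(`demod`, `segment`, `calibrate` and an all-in-one `run` subcommand are
also available; `--help` lists options.)

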