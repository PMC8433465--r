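test_that("beat morphologies validate their invariants", {
  expect_error(beat_morphology("rhythmic", peak_level = 1, valley_level = 1),
               "peak_level")
  expect_error(beat_morphology("arrhythmic_2peak"), "secondary peak")
  expect_error(
    beat_morphology("arrhythmic_3peak",
                    secondary_peak_delays = c(0.7, 0.6),
                    secondary_peak_relative_amplitudes = c(0.5, 0.5)),
    "strictly increasing")
  expect_error(
    beat_morphology("arrhythmic_2peak",
                    secondary_peak_delays = 0.7,
                    secondary_peak_relative_amplitudes = 1.5),
    "relative amplitudes")
  m <- atm_morphologies()
  expect_named(m, c("rhythmic", "arrhythmic_2peak", "arrhythmic_3peak",
                    "arrhythmic_2peak_shifted", "arrhythmic_3peak_shifted"))
  expect_equal(m$arrhythmic_3peak$kind, "arrhythmic_3peak")
})

test_that("beat waveform meets its endpoint, peak and sample-count contract", {
  morphs <- atm_morphologies()
  # 1.563 s at 12.8 ms -> 122 samples
  w <- make_beat_waveform(morphs$rhythmic, 1.563, 0.0128)
  expect_length(w, 122L)
  expect_equal(w[1], 6.687, tolerance = 1e-12)
  expect_equal(w[length(w)], 6.687, tolerance = 1e-12)
  expect_equal(max(w), 6.758, tolerance = 1e-3)

  dominant <- function(v) {
    thr <- min(v) + 0.25 * (max(v) - min(v))
    i <- 2:(length(v) - 1)
    sum(v[i] > v[i - 1] & v[i] > v[i + 1] & v[i] > thr)
  }
  expect_equal(dominant(w), 1L)
  expect_equal(dominant(make_beat_waveform(morphs$arrhythmic_2peak,
                                           1.563, 0.0128)), 2L)
  expect_equal(dominant(make_beat_waveform(morphs$arrhythmic_3peak,
                                           1.563, 0.0128)), 3L)
  expect_equal(dominant(make_beat_waveform(morphs$arrhythmic_3peak_shifted,
                                           1.563, 0.0128)), 3L)

  expect_error(make_beat_waveform(morphs$rhythmic, 0.1, 0.0128), "10 sample")
  expect_error(
    make_beat_waveform(beat_morphology("rhythmic", peak_level = 5,
                                       valley_level = 5), 1.5, 0.0128),
    "peak_level")
})

test_that("synthetic traces are deterministic and label-conserving", {
  cfg <- sim_config(20, morphology_schedule = c("rhythmic",
                                                "arrhythmic_2peak"),
                    rng_seed = 7)
  a <- synth_trace(cfg)
  b <- synth_trace(cfg)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$truth_valley_times, b$truth_valley_times)
  expect_length(a$truth_labels, 20L)
  expect_length(a$truth_valley_times, 21L)
  expect_equal(a$truth_labels,
               rep(c("rhythmic", "arrhythmic"), 10))
  # all-rhythmic schedule -> every label rhythmic
  allr <- synth_trace(sim_config(10, rng_seed = 1))
  expect_true(all(allr$truth_labels == "rhythmic"))
})

test_that("inter-valley intervals track the configured period", {
  cfg <- sim_config(100, beat_period_cv = 0.01, rng_seed = 3)
  lt <- synth_trace(cfg)
  iv <- diff(lt$truth_valley_times)
  se <- 0.01 * 1.563 / sqrt(100)
  expect_lt(abs(mean(iv) - 1.563), 3 * se)
  expect_true(all(abs(iv - 1.563) <= 3 * 0.01 * 1.563 + 1e-12))
})

test_that("trace samples respect the amplitude bounds", {
  cfg <- sim_config(30, morphology_schedule = "arrhythmic_3peak",
                    noise_sd = 0.02 * default_amplitude(), rng_seed = 5)
  lt <- synth_trace(cfg)
  lo <- 6.687 - 5 * cfg$noise_sd - cfg$drift_amplitude
  hi <- 6.758 + 5 * cfg$noise_sd + cfg$drift_amplitude
  expect_true(all(lt$trace$values >= lo & lt$trace$values <= hi))
})

test_that("YAML simulation configs round-trip through read_sim_yaml", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_beats: 6",
               "beat_period_cv: 0.02",
               "morphology_schedule: [rhythmic, arrhythmic_2peak]",
               "rng_seed: 9"), path)
  cfg <- read_sim_yaml(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_beats, 6L)
  expect_equal(cfg$beat_period_cv, 0.02)
  expect_equal(cfg$morphology_schedule[[2]]$kind, "arrhythmic_2peak")
  expect_identical(synth_trace(cfg)$trace$values,
                   synth_trace(cfg)$trace$values)
  # CLI-style seed override
  expect_equal(read_sim_yaml(path, rng_seed = 33)$rng_seed, 33L)
  writeLines("n_beats: 4\nfoo: 1", path)
  expect_error(read_sim_yaml(path), "unknown key")
})

test_that("carrier synthesis modulates amplitude and validates sampling", {
  flat <- impedance_trace(rep(2.5, 100), 0.0128)
  car <- synth_carrier(flat, sample_rate = 1e5)
  expect_s3_class(car, "carrier_recording")
  # constant trace -> constant envelope equal to the trace value
  env <- demodulate(car)
  expect_true(all(abs(env$values - 2.5) < 1e-9))
  expect_error(synth_carrier(flat, sample_rate = 2e4, carrier_freq = 1e4),
               "4 x carrier_freq")
  expect_error(carrier_recording(1:10, 2e4, 1e4), "4 x carrier_freq")
})
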