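test_that("pearson_r matches hand-computed and oracle values", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # direct covariance/variance arithmetic: Cov = 4/3, Var = 5/3 each
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 2, 3), c(1, 2)), "length mismatch")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("pearson_r agrees with an independent two-pass oracle", {
  oracle <- function(x, y) {
    cxy <- mean((x - mean(x)) * (y - mean(y)))
    cxy / sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- pearson_r(x, y)
    expect_lt(abs(r - oracle(x, y)), 1e-12)
    expect_lt(abs(r - stats::cor(x, y)), 1e-12)
    # symmetry, affine invariance, sign flip
    expect_equal(pearson_r(y, x), r, tolerance = 1e-14)
    expect_equal(pearson_r(3.7 * x + 2, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(-2 * x, y), -r, tolerance = 1e-12)
  }
})

test_that("template extraction honours beat choice, seeds, and bounds", {
  fx <- analysis_trace(20, seed = 6)
  v <- detect_valleys(fx$hr)
  beats <- extract_beats(fx$hr, v)
  tpl1 <- extract_template(fx$hr, v, beat_choice = 1L)
  expect_equal(tpl1$values, beats[[1]]$values)
  ra <- extract_template(fx$hr, v, beat_choice = "random", rng_seed = 42)
  rb <- extract_template(fx$hr, v, beat_choice = "random", rng_seed = 42)
  expect_identical(ra$values, rb$values)
  expect_match(ra$source, "seed 42")
  expect_error(extract_template(fx$hr, v, beat_choice = 99L),
               "does not exist")
  expect_error(extract_template(fx$hr, integer(), beat_choice = 1L),
               "no complete beats")
})

test_that("template length matching is exact at equal lengths and linear", {
  ramp <- c(0, 1, 2, 3)
  expect_equal(fit_template_length(ramp, 4L), ramp)
  expect_equal(fit_template_length(ramp, 7L),
               c(0, 0.5, 1, 1.5, 2, 2.5, 3), tolerance = 1e-12)
  expect_error(fit_template_length(rep(2, 10), 20L), "constant")
  expect_error(fit_template_length(ramp, 3L), "target_length")
})

test_that("length matching agrees with a dense-grid oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(10:500, 1)
    target <- sample(10:500, 1)
    v <- cumsum(rnorm(n))
    got <- fit_template_length(v, target)
    expect_length(got, target)
    expect_equal(got[1], v[1], tolerance = 1e-9)
    expect_equal(got[target], v[n], tolerance = 1e-9)
    # oracle: dense spline evaluation at m * (target - 1) + 1 points,
    # strided by m (the smallest integer multiple covering the template)
    m <- max(1L, ceiling((n - 1) / (target - 1)))
    dense <- stats::spline(seq_len(n), v, n = m * (target - 1L) + 1L,
                           method = "fmm")$y
    expect_lt(max(abs(got - dense[seq(1, length(dense), by = m)])), 1e-6)
  }
  v <- cumsum(rnorm(122))
  expect_length(fit_template_length(v, 135L), 135L)
})

test_that("beat classification follows the threshold rules of both modes", {
  fx <- analysis_trace(12, seed = 8)
  v <- detect_valleys(fx$hr)
  beats <- extract_beats(fx$hr, v)
  tpl <- extract_template(fx$hr, v, 1L, label = "rhythmic")
  # self-match: r = 1 >= 0.94 -> rhythmic
  res <- match_beat(beats[[1]], list(rhythmic = tpl), match_config())
  expect_equal(res$predicted_label, "rhythmic")
  expect_equal(unname(res$correlations[1]), 1.0, tolerance = 1e-12)

  # synthetic correlations exercise the multitemplate max rule through
  # purpose-built templates: beat == template T_II
  cfg_m <- match_config("arrhythmic_multitemplate")
  t2 <- atm_template(beats[[2]]$values, beats[[2]]$sample_interval,
                     "arrhythmic_2peak")
  t3 <- atm_template(beats[[3]]$values, beats[[3]]$sample_interval,
                     "arrhythmic_3peak")
  res2 <- match_beat(beats[[3]], list(T_I = t2, T_II = t3), cfg_m)
  expect_equal(res2$predicted_label, "arrhythmic")
  expect_equal(res2$winning_template, "T_II")

  # degenerate beat is flagged, never silently rhythmic
  flat <- structure(list(values = rep(1, 200), sample_interval = 0.00128,
                         start_time = 0, peak_indices = integer(),
                         truth_label = NA_character_),
                    class = "atm_beat")
  expect_equal(match_beat(flat, list(rhythmic = tpl),
                          match_config())$predicted_label, "unclassifiable")

  # mode/template consistency is enforced
  expect_error(match_beat(beats[[1]], list(t2), match_config()),
               "exactly one rhythmic template")
  expect_error(match_beat(beats[[1]], list(tpl), cfg_m),
               "arrhythmic templates only")
})

test_that("multitemplate mode takes the maximum correlation as output", {
  # templates constructed so the beat correlates 0.92 / 0.95-ish with them:
  # check the decision boundary arithmetic directly on the rule
  cfg <- match_config("arrhythmic_multitemplate")
  phi <- seq(0, 1, length.out = 200)
  base <- sin(pi * phi)
  t_lo <- atm_template(base + 0.28 * sin(2 * pi * phi), 0.00128,
                       "arrhythmic_2peak")
  t_hi <- atm_template(base + 0.10 * sin(2 * pi * phi), 0.00128,
                       "arrhythmic_3peak")
  beat <- base
  res <- match_beat(beat, list(T_I = t_lo, T_II = t_hi), cfg)
  expect_equal(res$winning_template, "T_II")
  expect_equal(res$predicted_label,
               if (max(res$correlations) > 0.9) "arrhythmic" else "rhythmic")
  # both correlations below threshold -> rhythmic
  t_far <- atm_template(rev(base) + 0.8 * cos(3 * pi * phi), 0.00128,
                        "arrhythmic_2peak")
  res2 <- match_beat(beat, list(T_I = t_far), cfg)
  expect_true(max(res2$correlations) < 0.9)
  expect_equal(res2$predicted_label, "rhythmic")
})

test_that("classification is invariant under positive affine trace transforms", {
  fx <- analysis_trace(16, schedule = c("rhythmic", "arrhythmic_2peak"),
                       seed = 13)
  classify <- function(tr) {
    v <- detect_valleys(tr)
    tpl <- extract_template(tr, v, 1L, label = "rhythmic")
    vapply(match_beats(extract_beats(tr, v), list(rhythmic = tpl)), `[[`,
           "", "predicted_label")
  }
  hr2 <- impedance_trace(40 * fx$hr$values + 11, fx$hr$sample_interval)
  expect_identical(classify(hr2), classify(fx$hr))
})

test_that("pairwise self-similarity has unit diagonal and high same-class floor", {
  beats <- class_beats("rhythmic", seed = 21, n_beats = 12L, noise_sd = 0)
  m <- pairwise_self_similarity(beats)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, nrow(m)))
  expect_gt(min(m[upper.tri(m)]), 0.98)
  # identical beats correlate exactly 1
  two <- pairwise_self_similarity(list(beats[[1]], beats[[1]]))
  expect_equal(two[1, 2], 1.0, tolerance = 1e-12)
  # degenerate member flagged missing
  m2 <- pairwise_self_similarity(list(beats[[1]]$values, rep(1, 500)))
  expect_true(is.na(m2[1, 2]))
  expect_error(pairwise_self_similarity(beats[1]), "at least 2")
})

test_that("threshold calibration ceils the cross-class maximum to 2 decimals", {
  cal <- calibrate_threshold(c(0.9977, 0.995, 0.9962), c(0.935967, 0.86))
  expect_equal(cal$threshold, 0.94)
  expect_length(cal$flagged, 0L)
  expect_equal(calibrate_threshold(1, 0.8999)$threshold, 0.90)
  expect_equal(calibrate_threshold(1, 0.90)$threshold, 0.90)
  expect_error(calibrate_threshold(1, c(0.5, 0.991)), "not separable")
  expect_error(calibrate_threshold(numeric(), 0.5), "non-empty")
  # same-class outliers below the threshold are reported, as a warning record
  expect_warning(
    cal2 <- calibrate_threshold(c(0.995, 0.939604), c(0.935967)),
    "below threshold")
  expect_equal(cal2$flagged, 0.939604)
  expect_equal(cal2$threshold, 0.94)
})

test_that("templates survive a JSON round trip", {
  tpl <- atm_template(sin(seq_len(50) / 5) + seq_len(50) / 100, 0.00128,
                      "arrhythmic_2peak", source = "segment A beat 3")
  path <- withr::local_tempfile(fileext = ".json")
  write_template_json(tpl, path)
  back <- read_template_json(path)
  expect_equal(back$values, tpl$values, tolerance = 1e-12)
  expect_equal(back$label, tpl$label)
  expect_equal(back$sample_interval, tpl$sample_interval)
  expect_equal(back$source, tpl$source)
})
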