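# shared fixture builders (everything is generated in code at test time)

# smoothed + upsampled analysis trace for a given morphology schedule
analysis_trace <- function(n_beats, schedule = "rhythmic", seed = 1L,
                           noise_sd = NULL, cv = 0.01, factor = 10L) {
  lt <- synth_trace(sim_config(n_beats, morphology_schedule = schedule,
                               noise_sd = noise_sd, beat_period_cv = cv,
                               rng_seed = seed))
  list(labeled = lt, hr = upsample(smooth5(lt$trace), factor))
}

# beats of a single morphology class, segmented from a synthetic trace
class_beats <- function(kind, seed, n_beats = 30L, cv = 0.01,
                        noise_sd = NULL) {
  fx <- analysis_trace(n_beats, kind, seed, noise_sd = noise_sd, cv = cv)
  extract_beats(fx$hr, detect_valleys(fx$hr))
}

default_amplitude <- function() 6.758 - 6.687
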