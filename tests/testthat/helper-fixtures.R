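# shared helpers: small, fast scenario and movie constructions

wtParams <- function() oscillatorPreset("wild-type fit")

# a small lattice scenario for fast network tests
tinyScenario <- function(cellsPerLobe = 16, duration = 72, seed = 1L, ...) {
  scenarioPreset("neonate-wt", seed = seed, cellsPerLobe = cellsPerLobe,
                 duration = duration, ...)
}

# noise-free oscillator sharing the wild-type anchor
quietParams <- function(damping = 0.05) {
  OscillatorParams(alpha = 1, period = 24, damping = damping,
                   dR = 0, dPhi = 0)
}

# full preset pipeline: simulate, render, preprocess
presetPipeline <- function(preset, seed, imaging = ImagingModel()) {
  sc <- scenarioPreset(preset, seed = seed)
  run <- simulateNetwork(sc)
  mov <- renderMovie(run, imaging = imaging, seed = seed)
  preprocessMovie(mov)
}

# movie with one cosine per pixel at given periods/phases (T x N)
cosineMovie <- function(periods, phases = rep(0, length(periods)),
                        T = 144, amplitudes = rep(1, length(periods))) {
  t <- seq_len(T) - 1
  A <- vapply(seq_along(periods), function(k)
    amplitudes[k] * cos(2 * pi * t / periods[k] + phases[k]), numeric(T))
  BiolumMovie(A, coords = data.frame(x = seq_along(periods), y = 0))
}
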