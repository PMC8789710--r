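# Shared simulated fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) assign(key, build(), envir = .fixtures)
  .fixtures[[key]]
}

# 20 s noise-free stenotic recording with natural preload variability
cleanSim <- function() fixture("clean", function()
  simulateRecording(
    variability = variabilityParams(noise_p_sd = 0, noise_v_sd = 0),
    duration = 20, fs = 250))

# same conditions with the default measurement noise
noisySim <- function() fixture("noisy", function()
  simulateRecording(duration = 20, fs = 250))

# default 8-patient pre/post cohort
defaultCohort <- function() fixture("cohort", function()
  simulateCohort(n_patients = 8, seed = 7))

# rectangular loop traced as a sampled recording: V 50-100 ml, P 10-110
# mmHg, counterclockwise; returns the recording plus a hand-built beat row
rectangleBeat <- function(fs = 1000) {
  ivc_p <- seq(10, 110, length.out = 51)[-51]      # V = 100
  ej_v <- seq(100, 50, length.out = 101)[-101]     # P = 110
  ivr_p <- seq(110, 10, length.out = 51)[-51]      # V = 50
  fil_v <- seq(50, 100, length.out = 101)[-101]    # P = 10
  p <- c(ivc_p, rep(110, 100), ivr_p, rep(10, 100))
  v <- c(rep(100, 50), ej_v, rep(50, 50), fil_v)
  rec <- pvRecording(c(p, p), c(v, v), fs)         # two cycles
  beat <- data.frame(start = 1L, end = 301L, i_ed = 1L, i_es = 151L,
                     i_dpdtmax = 25L, i_dpdtmin = 175L,
                     ectopic = FALSE, rr = 300 / fs)
  list(rec = rec, beat = beat)
}

# random star-shaped simple polygon around a center (valid input for both
# the shoelace and a fan-triangulation oracle)
randomStarLoop <- function(n = 24) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 5, 40)
  data.frame(volume = 75 + r * cos(th), pressure = 60 + r * sin(th))
}

# independent polygon area by fan triangulation from the centroid
fanTriangulationArea <- function(v, p) {
  cx <- mean(v); cy <- mean(p)
  n <- length(v)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + ((v[i] - cx) * (p[j] - cy) - (v[j] - cx) * (p[i] - cy)) / 2
  }
  abs(a)
}

# synthetic monoexponential relaxation trace: P = p0 * exp(-t/tau_s),
# constant volume, packaged with a beat row pointing at the decay start
expDecayBeat <- function(tau_s = 0.025, p0 = 80, fs = 1000, dur = 0.4) {
  t <- seq(0, dur, by = 1 / fs)
  rec <- pvRecording(p0 * exp(-t / tau_s), rep(60, length(t)), fs)
  beat <- data.frame(start = 1L, end = length(t) + 1L, i_ed = 1L,
                     i_es = 2L, i_dpdtmax = 1L, i_dpdtmin = 1L,
                     ectopic = FALSE, rr = dur)
  list(rec = rec, beat = beat)
}
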