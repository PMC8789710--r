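test_that("a rectangular loop gives the closed-form stroke work and volumes", {
  rb <- rectangleBeat()
  bi <- beatIndices(rb$rec, rb$beat, smooth_ms = 0)
  expect_equal(bi$sw, 5000, tolerance = 1e-9)
  expect_equal(bi$sv, 50)
  expect_equal(bi$edv, 100); expect_equal(bi$esv, 50)
  expect_equal(bi$ef, 0.5)
  expect_equal(bi$ea, 110 / 50)
})

test_that("per-beat identities hold on every analyzed beat", {
  rep <- analyzeRecording(noisySim()$recording, n_beats = 10)
  bi <- perBeat(rep)
  expect_equal(bi$sv, bi$edv - bi$esv, tolerance = 1e-12)
  expect_equal(bi$ea * bi$sv, bi$esp, tolerance = 1e-9)
  expect_equal(bi$ef * bi$edv, bi$sv, tolerance = 1e-9)
  expect_true(all(bi$dpdt_min < 0 & bi$dpdt_max > 0))
  expect_true(all(bi$sw > 0 & bi$ef > 0 & bi$ef < 1))
})

test_that("detected ESP agrees with the simulator's end-systolic pressure", {
  sim <- cleanSim()
  b <- beats(segmentBeats(sim$recording))
  tl <- beatLog(sim$truth)
  for (i in seq_len(nrow(b))) {
    bi <- beatIndices(sim$recording, b[i, , drop = FALSE])
    j <- which.min(abs(tl$start_s - (b$start[i] - 1) / 250))
    expect_lt(abs(bi$esp - tl$esp[j]) / tl$esp[j], 0.05)
  }
})

test_that("ectopic and non-ejecting beats are refused", {
  rb <- rectangleBeat()
  bad <- rb$beat; bad$ectopic <- TRUE
  expect_error(beatIndices(rb$rec, bad), "ectopic")
  # swap landmarks so ESV > EDV
  ne <- rb$beat; ne$i_ed <- ne$i_es; ne$i_es <- 1L
  ne$i_dpdtmax <- ne$i_ed + 10L
  expect_error(beatIndices(rb$rec, ne), "non-ejecting")
})

test_that("tau_half matches the closed-form half-life of an exponential", {
  eb <- expDecayBeat(tau_s = 0.025)
  expect_equal(tauHalf(eb$rec, eb$beat), 25 * log(2), tolerance = 1e-3)
  # doubling the sampling rate barely moves the interpolated estimate
  eb2 <- expDecayBeat(tau_s = 0.025, fs = 2000)
  expect_lt(abs(tauHalf(eb2$rec, eb2$beat) - tauHalf(eb$rec, eb$beat)), 0.5)
})

test_that("tau_half errors when the decay plateaus above half", {
  fs <- 1000
  t <- seq(0, 0.4, by = 1 / fs)
  p <- 48 + 32 * exp(-t / 0.02)            # floor at 60% of P(0) = 80
  rec <- pvRecording(p, rep(60, length(t)), fs)
  beat <- data.frame(start = 1L, end = length(t) + 1L, i_ed = 1L,
                     i_es = 2L, i_dpdtmax = 1L, i_dpdtmin = 1L,
                     ectopic = FALSE, rr = 0.4)
  expect_error(tauHalf(rec, beat), "relaxation window truncated")
})

test_that("tau_exp recovers the generator constant and the ln2 relation", {
  eb <- expDecayBeat(tau_s = 0.025)
  expect_equal(tauExp(eb$rec, eb$beat), 25, tolerance = 0.1 / 25)
  ratio <- tauHalf(eb$rec, eb$beat) / tauExp(eb$rec, eb$beat)
  expect_equal(ratio, log(2), tolerance = 0.01)
  short <- eb$beat; short$end <- short$i_dpdtmin + 4L
  expect_error(tauExp(eb$rec, short), "too short")
  neg <- pvRecording(80 * exp(-seq(0, 0.4, by = 1e-3) / 0.025) - 5,
                     rep(60, 401), 1000)
  expect_error(tauExp(neg, eb$beat), "non-positive")
})

test_that("tau estimates resist catheter-scale noise", {
  clean <- analyzeRecording(cleanSim()$recording, n_beats = 10)
  noisy <- analyzeRecording(noisySim()$recording, n_beats = 10)
  for (f in c("tau_half", "tau_exp")) {
    rel <- abs(indices(noisy)[[f]] - indices(clean)[[f]]) /
      indices(clean)[[f]]
    expect_lt(rel, 0.15)
  }
})

test_that("PRSW is exact on linear data and guards its preconditions", {
  edv <- c(90, 95, 100, 105, 110)
  bi <- data.frame(edv = edv, sw = 70 * edv - 1000)
  expect_equal(prsw(bi), 70, tolerance = 1e-12)
  expect_error(prsw(bi[1:3, ]), "beats")
  flat <- data.frame(edv = rep(100, 6), sw = rnorm(6, 5000))
  expect_error(prsw(flat), "spread")
})

test_that("PRSW from natural preload variability is positive and stable", {
  v <- vapply(1:3, function(sd) {
    s <- simulateRecording(
      variability = variabilityParams(noise_p_sd = 0, noise_v_sd = 0,
                                      seed = sd),
      duration = 20, fs = 250)
    indices(analyzeRecording(s$recording, n_beats = 10))[["prsw"]]
  }, numeric(1))
  expect_true(all(v > 0))
  expect_lt((max(v) - min(v)) / mean(v), 0.15)
})

test_that("elastance slopes are exact on collinear data", {
  esv <- c(40, 45, 50, 55, 60)
  bi <- data.frame(esv = esv, esp = 2.5 * esv + 10,
                   edv = esv + 50, edp = 0.14 * (esv + 50) + 1)
  es <- espvrSlope(bi)
  expect_equal(es[["slope"]], 2.5, tolerance = 1e-12)
  ed <- edpvrSlope(bi)
  expect_equal(ed[["slope"]], 0.14, tolerance = 1e-12)
  expect_error(espvrSlope(bi[1:2, ]), "beats")
  bi$esv <- 50
  expect_error(espvrSlope(bi), "spread")
})

test_that("ESPVR slope recovers a nonzero-V0 generator within 20%", {
  sim <- simulateRecording(
    elastance = elastanceParams(emax = 2.5, v0 = 5),
    variability = variabilityParams(noise_p_sd = 0, noise_v_sd = 0,
                                    seed = 2),
    duration = 20, fs = 250)
  rep <- analyzeRecording(sim$recording, n_beats = 10)
  expect_lt(abs(indices(rep)[["ees"]] - 2.5) / 2.5, 0.20)
})

test_that("the Windkessel closed form evaluates exactly and in its limits", {
  expect_equal(windkesselEa(list(r_t = 1.2, t_s = 0.3, t_d = 0.5,
                                 tau = 0.5)),
               1.2 / (0.3 + 0.5 * (1 - exp(-1))), tolerance = 1e-12)
  # no diastole: Ea = R_T / t_s
  expect_equal(windkesselEa(list(r_t = 1.2, t_s = 0.3, t_d = 0,
                                 tau = 0.5)), 4)
  # tau -> 0: exponential term vanishes
  expect_equal(windkesselEa(list(r_t = 1.2, t_s = 0.3, t_d = 0.5,
                                 tau = 0)), 4)
  # tau -> infinity: tau (1 - exp(-t_d/tau)) -> t_d
  expect_equal(windkesselEa(list(r_t = 1.2, t_s = 0.3, t_d = 0.5,
                                 tau = 1e9)), 1.2 / 0.8, tolerance = 1e-6)
})

test_that("the global report composes its quantities consistently", {
  rep <- analyzeRecording(noisySim()$recording, n_beats = 10)
  v <- indices(rep)
  expect_equal(v[["co"]], v[["hr"]] * v[["sv"]] / 1000, tolerance = 1e-12)
  md <- recordingMetadata(noisySim()$recording)
  expect_equal(v[["svi"]], v[["sv"]] / md$bsa, tolerance = 1e-12)
  expect_equal(v[["ci"]], v[["co"]] / md$bsa, tolerance = 1e-12)
  expect_equal(v[["zva"]], (md$sap + md$mean_gradient) / v[["svi"]],
               tolerance = 1e-12)
  expect_equal(v[["vac_ea_ees"]], v[["ea"]] / v[["ees"]], tolerance = 1e-12)
  expect_equal(v[["vac_ea_ees"]] * v[["vac_ees_ea"]], 1, tolerance = 1e-12)
  expect_equal(rep@nBeats, 10L)
})

test_that("missing BSA degrades loudly, not silently", {
  rec <- noisySim()$recording
  md <- recordingMetadata(rec)
  bare <- pvRecording(pressure(rec), volume(rec), samplingRate(rec),
                      metadata = md[setdiff(names(md), "bsa")])
  bt <- flagExtrasystoles(segmentBeats(bare))
  ss <- selectSteadyState(bt, bare, 10)
  expect_warning(rep <- globalReport(bare, ss), "BSA missing")
  expect_true(is.na(indices(rep)[["svi"]]))
  expect_true(is.na(indices(rep)[["ci"]]))
  expect_true(is.na(indices(rep)[["zva"]]))
})

test_that("shoelace stroke work matches a fan-triangulation oracle", {
  set.seed(42)
  for (i in 1:25) {
    lp <- randomStarLoop()
    a1 <- abs(pvloop:::shoelaceArea(lp$volume, lp$pressure))
    a2 <- fanTriangulationArea(lp$volume, lp$pressure)
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})
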