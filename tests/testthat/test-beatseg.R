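test_that("a noise-free recording at HR 60 segments into ~1 s beats", {
  sim <- simulateRecording(
    variability = variabilityParams(rr_mean = 1.0, noise_p_sd = 0,
                                    noise_v_sd = 0),
    duration = 20, fs = 250)
  bt <- segmentBeats(sim$recording)
  b <- beats(bt)
  expect_true(nrow(b) >= 18 && nrow(b) <= 20)
  expect_true(all(abs(b$rr - 1.0) < 0.1))
  # beats tile the analyzed span without overlap
  expect_true(all(b$start[-1] == b$end[-nrow(b)]))
})

test_that("degenerate input raises the no-cycles error", {
  flat <- pvRecording(rep(50, 5000), rep(80, 5000), fs = 250)
  expect_error(segmentBeats(flat), "no cycles detected")
  expect_error(segmentBeats(pvRecording(1:50, 1:50, 250)), "too short")
})

test_that("beat count matches the simulator's emitted beats", {
  sim <- simulateRecording(
    variability = variabilityParams(ectopic_rate = 0.08, seed = 4,
                                    noise_p_sd = 0, noise_v_sd = 0),
    duration = 20, fs = 250)
  b <- beats(segmentBeats(sim$recording))
  tl <- beatLog(sim$truth)
  # detection cannot see the leading partial beat or beats truncated at
  # the end of the emitted span
  contained <- sum(tl$start_s + tl$rr <= 20)
  expect_lte(abs(nrow(b) - contained), 1)
})

test_that("detected end-diastole lies within 30 ms of the simulator's", {
  sim <- cleanSim()
  b <- beats(segmentBeats(sim$recording))
  fs <- samplingRate(sim$recording)
  offs <- vapply((b$i_ed - 1) / fs, function(t)
    min(abs(beatLog(sim$truth)$t_ed - t)), numeric(1))
  expect_lt(max(offs), 0.030)
})

test_that("dP/dt landmarks are the derivative extremes of their beat", {
  sim <- cleanSim()
  rec <- sim$recording
  bt <- segmentBeats(rec)
  dpdt <- pvloop:::smoothedDerivative(pressure(rec), samplingRate(rec), 20)
  b <- beats(bt)
  for (i in seq_len(nrow(b))) {
    seg <- b$start[i]:(b$end[i] - 1L)
    expect_equal(dpdt[b$i_dpdtmax[i]], max(dpdt[seg]))
    expect_equal(dpdt[b$i_dpdtmin[i]], min(dpdt[seg]))
  }
})

test_that("segmenting a doubled recording doubles the beats", {
  rec <- cleanSim()$recording
  n1 <- nrow(beats(segmentBeats(rec)))
  rec2 <- pvRecording(rep(pressure(rec), 2), rep(volume(rec), 2),
                      samplingRate(rec))
  n2 <- nrow(beats(segmentBeats(rec2)))
  expect_lte(abs(n2 - 2 * n1), 1)
})

test_that("RR-deviant beats and successors of short beats are flagged", {
  mk <- function(rr) {
    fs <- 250
    ends <- cumsum(round(rr * fs))
    starts <- c(1L, ends[-length(ends)] + 1L)
    beatTable(data.frame(
      start = starts, end = ends + 1L, i_ed = starts,
      i_es = starts + 3L, i_dpdtmax = starts + 1L,
      i_dpdtmin = starts + 4L, ectopic = FALSE,
      rr = (ends + 1L - starts) / fs), fs)
  }
  # constant RR: nothing flagged
  expect_equal(sum(beats(flagExtrasystoles(mk(rep(1, 20))))$ectopic), 0)
  # one extrasystole + compensatory pause among regular beats:
  # exactly those two beats flagged
  rr <- rep(1, 20); rr[10] <- 0.6; rr[11] <- 1.4
  fl <- beats(flagExtrasystoles(mk(rr)))$ectopic
  expect_identical(which(fl), c(10L, 11L))
  expect_error(flagExtrasystoles(mk(c(1, 1))), "at least 3")
})

test_that("a clean simulated run yields zero ectopy flags", {
  bt <- flagExtrasystoles(segmentBeats(cleanSim()$recording))
  expect_equal(sum(beats(bt)$ectopic), 0)
})

test_that("simulator-labeled ectopics are flagged across seeded runs", {
  tot <- 0L; found <- 0L
  for (sd in 1:10) {
    sim <- simulateRecording(
      variability = variabilityParams(ectopic_rate = 0.08, seed = sd),
      duration = 20, fs = 250)
    bt <- flagExtrasystoles(segmentBeats(sim$recording))
    b <- beats(bt)
    tl <- beatLog(sim$truth)
    span_end <- (max(b$end) - 1) / 250
    ect <- tl[tl$ectopic & tl$start_s + tl$rr <= span_end, , drop = FALSE]
    for (t in ect$start_s) {
      k <- which.min(abs((b$start - 1) / 250 - t))
      tot <- tot + 1L
      if (b$ectopic[k]) found <- found + 1L
    }
  }
  expect_gt(tot, 5)
  expect_gte(found / tot, 0.95)
})

test_that("the steady-state window has minimal EDV variance", {
  rec <- noisySim()$recording
  bt <- flagExtrasystoles(segmentBeats(rec))
  ss <- selectSteadyState(bt, rec, n_beats = 10)
  expect_equal(nrow(beats(ss)), 10L)
  # exhaustive window scan oracle
  b <- beats(bt)
  edv <- volume(rec)[b$i_ed]
  vars <- vapply(seq_len(nrow(b) - 9L), function(s) {
    idx <- s:(s + 9L)
    if (any(b$ectopic[idx])) Inf else stats::var(edv[idx])
  }, numeric(1))
  expect_equal(stats::var(volume(rec)[beats(ss)$i_ed]), min(vars))
})

test_that("steady-state selection enforces its preconditions", {
  rec <- cleanSim()$recording
  bt <- flagExtrasystoles(segmentBeats(rec))
  nb <- nrow(beats(bt))
  # asking for exactly the available beats returns the full list
  full <- selectSteadyState(bt, rec, n_beats = nb)
  expect_equal(beats(full)$start, beats(bt)$start)
  expect_error(selectSteadyState(bt, rec, n_beats = nb + 5),
               "insufficient unflagged beats")
})
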