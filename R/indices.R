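# Per-beat and per-recording hemodynamic index battery.

#' Signed shoelace area of a closed polygon
#'
#' Area of the closed (V, P) trajectory by the shoelace formula (last
#' vertex implicitly joined to the first). Positive sign = counterclockwise
#' in the (V, P) plane (ejection at high pressure), the physiological loop
#' orientation; stroke work is the magnitude.
#'
#' @param v,p Equal-length coordinate vectors (ml, mmHg).
#' @return Signed area in mmHg*ml.
#' @examples
#' shoelaceArea(c(100, 100, 50, 50), c(10, 110, 110, 10))  # 5000
#' @export
shoelaceArea <- function(v, p) {
  n <- length(v)
  j <- c(2:n, 1L)
  sum(v * p[j] - v[j] * p) / 2
}

#' Per-beat hemodynamic indices
#'
#' Computes, for one segmented beat, the loop-derived battery: EDV, ESV,
#' EDP, ESP (pressure/volume at the end-diastolic and end-systolic
#' landmarks), SV = EDV - ESV, EF = SV/EDV, stroke work as the area of the
#' closed PV loop (shoelace over the beat's samples), the smoothed dP/dt
#' extremes, the two isovolumic-relaxation constants (half-decay and
#' exponential-fit, ms), the Starling contractile index
#' SCI = dP/dt_max / EDV, and the effective arterial elastance
#' Ea = ESP/SV.
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param beat A single row of a \linkS4class{BeatTable}'s beat data frame.
#' @param smooth_ms Derivative smoothing window, ms.
#' @return One-row data.frame with columns \code{edv}, \code{esv},
#'   \code{edp}, \code{esp}, \code{sv}, \code{ef}, \code{sw},
#'   \code{dpdt_max}, \code{dpdt_min}, \code{tau_half}, \code{tau_exp},
#'   \code{sci}, \code{ea}, \code{rr}. A clockwise (self-intersecting or
#'   inverted) loop raises a warning and the signed-area magnitude is
#'   reported.
#' @examples
#' sim <- simulateRecording(duration = 12, fs = 200)
#' bt <- segmentBeats(sim$recording)
#' beatIndices(sim$recording, beats(bt)[1, ])
#' @export
beatIndices <- function(rec, beat, smooth_ms = 20) {
  stopifnot(is(rec, "PVRecording"), nrow(beat) == 1L)
  if (isTRUE(beat$ectopic))
    stop("refusing to compute indices on a beat flagged ectopic")
  p <- pressure(rec); v <- volume(rec); fs <- samplingRate(rec)
  seg <- beat$start:(beat$end - 1L)
  # landmark values read from the 20 ms smoothed channels (noise
  # robustness); loop area from the raw samples (zero-mean noise cancels)
  ps <- smoothMs(p, fs, smooth_ms); vs <- smoothMs(v, fs, smooth_ms)
  edv <- vs[beat$i_ed]; edp <- ps[beat$i_ed]
  esv <- vs[beat$i_es]; esp <- ps[beat$i_es]
  sv <- edv - esv
  if (sv <= 0) stop("non-ejecting beat: SV = ", round(sv, 2), " ml <= 0")
  ef <- sv / edv
  sa <- shoelaceArea(v[seg], p[seg])
  if (sa < 0)
    warning("clockwise loop orientation; reporting |area| as stroke work")
  dpdt <- smoothedDerivative(p, fs, smooth_ms)
  data.frame(
    edv = edv, esv = esv, edp = edp, esp = esp, sv = sv, ef = ef,
    sw = abs(sa),
    dpdt_max = max(dpdt[seg]), dpdt_min = min(dpdt[seg]),
    tau_half = tauHalf(rec, beat),
    tau_exp = tryCatch(tauExp(rec, beat), error = function(e) NA_real_),
    sci = max(dpdt[seg]) / edv,
    ea = esp / sv,
    rr = beat$rr)
}

#' Isovolumic relaxation half-time (Tau, pressure half-decay definition)
#'
#' The time for LV pressure to fall from its value at the dP/dt-minimum
#' landmark to half that value, with linear interpolation between samples.
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param beat One beat row (needs \code{i_dpdtmin} and \code{end}).
#' @return Tau in ms.
#' @examples
#' fs <- 1000; t <- seq(0, 0.4, by = 1 / fs)
#' rec <- pvRecording(80 * exp(-t / 0.025), rep(60, length(t)), fs)
#' beat <- data.frame(start = 1, end = length(t) + 1, i_ed = 1, i_es = 1,
#'                    i_dpdtmax = 1, i_dpdtmin = 1, ectopic = FALSE,
#'                    rr = 0.4)
#' tauHalf(rec, beat)  # 25 * log(2) ~ 17.3 ms
#' @export
tauHalf <- function(rec, beat) {
  p <- pressure(rec); fs <- samplingRate(rec)
  i0 <- beat$i_dpdtmin
  last <- min(beat$end - 1L, length(p))
  p0 <- p[i0]
  target <- p0 / 2
  seg <- i0:last
  below <- which(p[seg] <= target)
  if (!length(below))
    stop("relaxation window truncated: pressure never falls to half of ",
         round(p0, 1), " mmHg before beat end")
  i1 <- seg[below[1L]]
  if (i1 == i0) return(0)
  # linear interpolation between i1-1 and i1
  pa <- p[i1 - 1L]; pb <- p[i1]
  frac <- if (pa == pb) 0 else (pa - target) / (pa - pb)
  ((i1 - 1L - i0) + frac) / fs * 1000
}

#' Isovolumic relaxation constant by exponential fit
#'
#' Zero-asymptote monoexponential model: least-squares slope of
#' \code{log(P)} against time from the dP/dt-minimum landmark until pressure
#' has fallen to within 5 mmHg of the beat's diastolic floor; returns
#' \code{-1/slope} in ms.
#'
#' @inheritParams tauHalf
#' @param min_samples Minimal number of samples required in the fit window.
#' @return Tau in ms.
#' @export
tauExp <- function(rec, beat, min_samples = 8L) {
  p <- pressure(rec); fs <- samplingRate(rec)
  i0 <- beat$i_dpdtmin
  last <- min(beat$end - 1L, length(p))
  seg <- i0:last
  floor_p <- min(p[seg])
  stop_at <- which(p[seg] <= floor_p + 5)
  i1 <- if (length(stop_at)) seg[stop_at[1L]] else last
  win <- i0:i1
  if (length(win) < min_samples)
    stop("fit window too short: ", length(win), " samples (need >= ",
         min_samples, ")")
  pw <- p[win]
  if (any(pw <= 0))
    stop("non-positive pressures in relaxation window; ",
         "zero-asymptote fit undefined")
  tt <- (win - i0) / fs
  sl <- stats::cov(tt, log(pw)) / stats::var(tt)
  if (sl >= 0) stop("pressure not decaying in relaxation window")
  -1 / sl * 1000
}

#' Preload recruitable stroke work (PRSW)
#'
#' Ordinary least-squares slope of stroke work against end-diastolic volume
#' across the analyzed beats (mmHg); the load-insensitive contractility
#' index. Requires natural beat-to-beat preload variability to spread EDV.
#'
#' @param bi Data frame of per-beat indices (\code{\link{beatIndices}} rows).
#' @param min_beats Minimal number of beats.
#' @param min_spread Minimal EDV range, ml.
#' @return Slope in mmHg.
#' @examples
#' edv <- c(90, 95, 100, 105, 110)
#' bi <- data.frame(edv = edv, sw = 70 * edv - 1000)
#' prsw(bi)  # 70
#' @export
prsw <- function(bi, min_beats = 5L, min_spread = 2) {
  if (nrow(bi) < min_beats)
    stop("need >= ", min_beats, " beats for the PRSW regression")
  if (diff(range(bi$edv)) <= min_spread)
    stop("EDV spread ", round(diff(range(bi$edv)), 2),
         " ml too small for PRSW; provide preload-variability data")
  unname(stats::coef(stats::lm(sw ~ edv, data = bi))[2L])
}

#' Slopes of the end-systolic and end-diastolic pressure-volume relations
#'
#' \code{espvrSlope}: least-squares slope of ESP against ESV across beats
#' (Ees, mmHg/ml); \code{edpvrSlope}: slope of EDP against EDV (Eed,
#' end-diastolic stiffness). Both also return the per-beat ratio variant
#' (mean ESP/ESV, resp. mean EDP/EDV), labeled distinctly — the ratio
#' assumes a zero volume intercept.
#'
#' @inheritParams prsw
#' @param min_spread Minimal volume range, ml.
#' @return Named numeric: \code{slope} and \code{ratio}.
#' @examples
#' bi <- data.frame(esv = c(40, 45, 50, 55, 60),
#'                  esp = 2.5 * c(40, 45, 50, 55, 60) + 10)
#' espvrSlope(bi)["slope"]  # 2.5
#' @export
espvrSlope <- function(bi, min_beats = 5L, min_spread = 1) {
  if (nrow(bi) < min_beats)
    stop("need >= ", min_beats, " beats for the ESPVR regression")
  if (diff(range(bi$esv)) <= min_spread)
    stop("ESV spread too small for an ESPVR slope")
  c(slope = unname(stats::coef(stats::lm(esp ~ esv, data = bi))[2L]),
    ratio = mean(bi$esp / bi$esv))
}

#' @rdname espvrSlope
#' @export
edpvrSlope <- function(bi, min_beats = 5L, min_spread = 1) {
  if (nrow(bi) < min_beats)
    stop("need >= ", min_beats, " beats for the EDPVR regression")
  if (diff(range(bi$edv)) <= min_spread)
    stop("EDV spread too small for an EDPVR slope")
  c(slope = unname(stats::coef(stats::lm(edp ~ edv, data = bi))[2L]),
    ratio = mean(bi$edp / bi$edv))
}

#' Arterial elastance from the three-element Windkessel closed form
#'
#' Evaluates \deqn{E_A = R_T / [t_s + \tau (1 - e^{-t_d/\tau})]} with
#' \eqn{R_T} the total vascular resistance (characteristic impedance plus
#' peripheral resistance), \eqn{t_s}/\eqn{t_d} the systolic and diastolic
#' periods and \eqn{\tau} the diastolic pressure-decay time constant.
#' \eqn{\tau = 0} is handled as the analytic limit (the exponential term
#' vanishes).
#'
#' @param w List or named vector with \code{r_t} (mmHg s/ml), \code{t_s},
#'   \code{t_d}, \code{tau} (all s).
#' @return Ea in mmHg/ml.
#' @examples
#' windkesselEa(list(r_t = 1.2, t_s = 0.3, t_d = 0.5, tau = 0.5))
#' @export
windkesselEa <- function(w) {
  w <- as.list(w)
  stopifnot(w$r_t > 0, w$t_s > 0, w$t_d >= 0, w$tau >= 0)
  eterm <- if (w$tau == 0) 0 else w$tau * (1 - exp(-w$t_d / w$tau))
  w$r_t / (w$t_s + eterm)
}

#' Per-recording hemodynamic index report
#'
#' Assembles the full battery over the analyzed (steady-state, unflagged)
#' beats: per-beat indices averaged; HR = 60/mean RR; CO = HR x mean SV /
#' 1000 (l/min); with metadata, SVI = mean SV / BSA, CI = CO / BSA and the
#' valvulo-arterial impedance Zva = (systolic arterial pressure + mean
#' gradient) / SVI; the multi-beat regression slopes (PRSW, Ees, Eed) and
#' the ventricular-arterial coupling ratio in both orientations
#' (\code{vac_ea_ees} = Ea/Ees, the conventional headline, and
#' \code{vac_ees_ea} = Ees/Ea).
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param bt A \linkS4class{BeatTable} of the beats to analyze (ectopic
#'   beats are dropped).
#' @param smooth_ms Derivative smoothing window, ms.
#' @return An \linkS4class{IndexReport}. If BSA or arterial metadata are
#'   missing the dependent indices are set NA with a warning, never
#'   silently zero.
#' @examples
#' sim <- simulateRecording(duration = 16, fs = 200)
#' bt <- flagExtrasystoles(segmentBeats(sim$recording))
#' rep <- globalReport(sim$recording, selectSteadyState(bt, sim$recording, 8))
#' rep
#' @export
globalReport <- function(rec, bt, smooth_ms = 20) {
  stopifnot(is(rec, "PVRecording"), is(bt, "BeatTable"))
  b <- beats(bt)
  b <- b[!b$ectopic, , drop = FALSE]
  if (!nrow(b)) stop("no unflagged beats to analyze")
  bi <- do.call(rbind, lapply(seq_len(nrow(b)), function(i)
    beatIndices(rec, b[i, , drop = FALSE], smooth_ms)))
  hr <- 60 / mean(b$rr)
  md <- recordingMetadata(rec)
  mean_sv <- mean(bi$sv)
  co <- hr * mean_sv / 1000
  if (is.null(md$bsa)) {
    warning("BSA missing from metadata: SVI, CI and Zva reported as NA")
    svi <- ci <- NA_real_
  } else {
    svi <- mean_sv / md$bsa
    ci <- co / md$bsa
  }
  zva <- if (!is.null(md$sap) && !is.null(md$mean_gradient) &&
             is.finite(svi)) (md$sap + md$mean_gradient) / svi else {
    if (is.finite(svi))
      warning("arterial pressure/gradient missing: Zva reported as NA")
    NA_real_
  }
  es <- tryCatch(espvrSlope(bi), error = function(e) {
    warning("ESPVR not estimable: ", conditionMessage(e))
    c(slope = NA_real_, ratio = mean(bi$esp / bi$esv))
  })
  ed <- tryCatch(edpvrSlope(bi), error = function(e) {
    warning("EDPVR not estimable: ", conditionMessage(e))
    c(slope = NA_real_, ratio = mean(bi$edp / bi$edv))
  })
  pw <- tryCatch(prsw(bi), error = function(e) {
    warning("PRSW not estimable: ", conditionMessage(e)); NA_real_
  })
  ees <- es[["slope"]]; mean_ea <- mean(bi$ea)
  vals <- c(
    hr = hr,
    edv = mean(bi$edv), esv = mean(bi$esv),
    edp = mean(bi$edp), esp = mean(bi$esp),
    sv = mean_sv, ef = mean(bi$ef), sw = mean(bi$sw),
    svi = svi, co = co, ci = ci,
    dpdt_max = mean(bi$dpdt_max), dpdt_min = mean(bi$dpdt_min),
    tau_half = mean(bi$tau_half), tau_exp = mean(bi$tau_exp, na.rm = TRUE),
    sci = mean(bi$sci),
    ea = mean_ea, zva = zva,
    prsw = pw,
    ees = ees, ees_ratio = es[["ratio"]],
    eed = ed[["slope"]], eed_ratio = ed[["ratio"]],
    vac_ea_ees = mean_ea / ees, vac_ees_ea = ees / mean_ea)
  units <- c(
    hr = "beats/min", edv = "ml", esv = "ml", edp = "mmHg", esp = "mmHg",
    sv = "ml", ef = "fraction", sw = "mmHg*ml", svi = "ml/m2",
    co = "l/min", ci = "l/min/m2", dpdt_max = "mmHg/s",
    dpdt_min = "mmHg/s", tau_half = "ms", tau_exp = "ms",
    sci = "mmHg/(ml*s)", ea = "mmHg/ml", zva = "mmHg*m2/ml",
    prsw = "mmHg", ees = "mmHg/ml", ees_ratio = "mmHg/ml",
    eed = "mmHg/ml", eed_ratio = "mmHg/ml",
    vac_ea_ees = "ratio", vac_ees_ea = "ratio")
  new("IndexReport", indices = vals, units = units,
      nBeats = nrow(b), perBeat = bi)
}
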