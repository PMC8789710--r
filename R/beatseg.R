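# Beat segmentation and landmark detection.
#
# Beat boundary = end-diastole, found as the volume maximum in the window
# preceding each dP/dt-max event; dP/dt-max events are peaks of the smoothed
# pressure derivative. Half-open [start, end) beats, 1-based sample indices.

# moving-average smoothing over a window of `ms` milliseconds (odd number of
# samples, centered)
smoothMs <- function(x, fs, ms = 20) {
  w <- max(1L, round(ms / 1000 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(x)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[
    (pad + 1L):(pad + length(x))]
}

# central finite-difference derivative of a 20 ms moving-average-smoothed
# signal, per second
smoothedDerivative <- function(x, fs, ms = 20) {
  xs <- smoothMs(x, fs, ms)
  n <- length(xs)
  d <- numeric(n)
  d[2:(n - 1L)] <- (xs[3:n] - xs[1:(n - 2L)]) * fs / 2
  d[1L] <- d[2L]; d[n] <- d[n - 1L]
  d
}

# local maxima of x with height >= min_height, separated by >= min_dist
# samples (greedy, highest first)
findPeakIdx <- function(x, min_height, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] &
                x[2:(n - 1L)] > x[3:n] &
                x[2:(n - 1L)] >= min_height) + 1L
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_dist))
      keep <- c(keep, i)
  sort(keep)
}

#' Segment a PV recording into cardiac beats
#'
#' Detects one beat per dP/dt-max event (peaks of the smoothed pressure
#' derivative above a threshold), places the beat boundary at end-diastole
#' (the volume maximum in the window preceding the event), and locates the
#' within-beat landmarks: end-systole (maximal P/V ratio between the dP/dt
#' extremes) and the dP/dt extremes themselves.
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param min_prominence Minimal height of a dP/dt peak to count as a beat,
#'   mmHg/s.
#' @param smooth_ms Moving-average window for the derivative, ms.
#' @param ed_window_ms Window before each dP/dt-max event searched for the
#'   end-diastolic volume maximum, ms.
#' @param min_rr_s Minimal separation of successive dP/dt-max events, s.
#' @return A \linkS4class{BeatTable}. Beats are half-open sample intervals
#'   \code{[start, end)}; the ectopic flag is all-FALSE (see
#'   \code{\link{flagExtrasystoles}}).
#' @examples
#' sim <- simulateRecording(duration = 12, fs = 200)
#' bt <- segmentBeats(sim$recording)
#' bt
#' @export
segmentBeats <- function(rec, min_prominence = 200, smooth_ms = 20,
                         ed_window_ms = 250, min_rr_s = 0.3) {
  stopifnot(is(rec, "PVRecording"))
  p <- pressure(rec); v <- volume(rec); fs <- samplingRate(rec)
  n <- length(p)
  if (n < 3L * round(fs * min_rr_s))
    stop("recording too short: need at least ~3 cardiac cycles")
  v <- smoothMs(v, fs, smooth_ms)     # noise-robust landmark detection
  ps <- smoothMs(p, fs, smooth_ms)
  dpdt <- smoothedDerivative(p, fs, smooth_ms)
  ev <- findPeakIdx(dpdt, min_prominence, round(min_rr_s * fs))
  if (length(ev) < 3L)
    stop("no cycles detected: fewer than 3 dP/dt-max events above ",
         min_prominence, " mmHg/s")
  win <- max(1L, as.integer(round(ed_window_ms / 1000 * fs)))
  # end-diastole = onset of the end-diastolic volume plateau (mitral
  # closure): earliest sample within v_tol of the window's volume maximum,
  # so the landmark does not drift into the pressure upstroke. v_tol
  # adapts to the measured channel noise (first-difference MAD estimates
  # the raw noise SD; smoothing divides it by sqrt(window)).
  v_raw_sd <- stats::mad(diff(volume(rec))) / sqrt(2)
  w_sm <- max(1, round(smooth_ms / 1000 * fs))
  v_tol <- 0.5 + 3 * v_raw_sd / sqrt(w_sm)
  ed <- vapply(ev, function(i) {
    lo <- max(1L, i - win)
    w <- v[lo:(i - 1L)]
    as.integer(lo + which(w >= max(w) - v_tol)[1L] - 1L)
  }, integer(1))
  # one beat per consecutive pair of end-diastoles
  nb <- length(ed) - 1L
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    s0 <- ed[b]; s1 <- ed[b + 1L]          # [s0, s1)
    seg <- s0:(s1 - 1L)
    i_dmax <- ev[b]
    i_dmin <- seg[which.min(dpdt[seg])]
    if (i_dmin <= i_dmax) i_dmin <- i_dmax + 1L
    es_rng <- i_dmax:i_dmin
    ratio <- ps[es_rng] / pmax(v[es_rng], 1e-6)
    i_es <- es_rng[which.max(ratio)]
    if (i_es <= i_dmax) i_es <- i_dmax + 1L
    rows[[b]] <- data.frame(
      start = s0, end = s1, i_ed = s0, i_es = i_es,
      i_dpdtmax = i_dmax, i_dpdtmin = i_dmin,
      ectopic = FALSE, rr = (s1 - s0) / fs)
  }
  beatTable(do.call(rbind, rows), fs)
}

#' Flag extrasystolic (and post-extrasystolic) beats
#'
#' A beat is flagged ectopic when its RR interval deviates by more than
#' \code{rr_tol} from the running median RR; the immediately following beat
#' (the compensatory, post-extrasystolic beat with aberrant loading) is
#' flagged as well. Existing flags are never unset.
#'
#' @param bt A \linkS4class{BeatTable} (>= 3 beats).
#' @param rr_tol Relative RR deviation triggering a flag (default 0.20).
#' @return The \linkS4class{BeatTable} with updated ectopic flags.
#' @examples
#' sim <- simulateRecording(duration = 12, fs = 200)
#' bt <- flagExtrasystoles(segmentBeats(sim$recording))
#' @export
flagExtrasystoles <- function(bt, rr_tol = 0.20) {
  stopifnot(is(bt, "BeatTable"))
  b <- beats(bt)
  if (nrow(b) < 3L) stop("need at least 3 beats to judge RR deviation")
  rr <- b$rr
  k <- min(nrow(b) - (1 - nrow(b) %% 2), 7L)
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3L) stats::runmed(rr, k, endrule = "median")
         else rep(stats::median(rr), length(rr))
  dev <- abs(rr - med) / med
  flag <- dev > rr_tol
  # the beat after a short-coupled (true extrasystolic) beat is the
  # post-extrasystolic beat with aberrant loading; a long-deviant beat is
  # the compensatory pause itself and does not propagate further
  short <- flag & rr < med
  after <- c(FALSE, short[-length(short)])
  b$ectopic <- b$ectopic | flag | after
  beatTable(b, samplingRate(bt))
}

#' Select the steady-state analysis window
#'
#' Returns the contiguous run of \code{n_beats} unflagged beats whose
#' end-diastolic-volume proxy (volume at the end-diastole landmark) has
#' minimal variance — the most stationary stretch of the recording.
#'
#' @param bt A \linkS4class{BeatTable} with ectopic flags set.
#' @param rec The parent \linkS4class{PVRecording}.
#' @param n_beats Number of beats to analyze (default 10).
#' @return A \linkS4class{BeatTable} restricted to the selected window.
#' @examples
#' sim <- simulateRecording(duration = 16, fs = 200)
#' bt <- flagExtrasystoles(segmentBeats(sim$recording))
#' ss <- selectSteadyState(bt, sim$recording, n_beats = 8)
#' @export
selectSteadyState <- function(bt, rec, n_beats = 10) {
  stopifnot(is(bt, "BeatTable"), is(rec, "PVRecording"))
  b <- beats(bt)
  v <- volume(rec)
  clean_runs <- rle(!b$ectopic)
  if (sum(!b$ectopic) < n_beats || max(clean_runs$lengths[clean_runs$values]) < n_beats)
    stop("insufficient unflagged beats: need a contiguous run of ",
         n_beats, ", have at most ",
         if (any(clean_runs$values)) max(clean_runs$lengths[clean_runs$values]) else 0L)
  edv <- v[b$i_ed]
  best <- NULL; best_var <- Inf
  for (s in seq_len(nrow(b) - n_beats + 1L)) {
    idx <- s:(s + n_beats - 1L)
    if (any(b$ectopic[idx])) next
    vv <- stats::var(edv[idx])
    if (vv < best_var) { best_var <- vv; best <- idx }
  }
  beatTable(b[best, , drop = FALSE], samplingRate(bt))
}
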