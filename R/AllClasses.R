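#' @import methods
NULL

#' Uniformly sampled left-ventricular pressure-volume recording
#'
#' Container for a conductance-catheter-style recording: simultaneous LV
#' pressure (mmHg) and volume (ml) sampled at a fixed rate, plus
#' per-recording metadata (body surface area, invasive arterial pressures,
#' mean transvalvular gradient, subgroup labels). Time of sample k is
#' (k - 1)/fs seconds.
#'
#' @slot pressure Numeric vector, LV pressure in mmHg.
#' @slot volume Numeric vector, LV volume in ml (same length).
#' @slot fs Sampling rate, Hz.
#' @slot metadata Named list; recognised entries include \code{bsa} (m2),
#'   \code{sap} (systolic arterial pressure, mmHg), \code{mean_gradient}
#'   (mean transvalvular gradient, mmHg) and free-form labels.
#' @export
setClass("PVRecording",
  representation(pressure = "numeric", volume = "numeric",
                 fs = "numeric", metadata = "list"),
  prototype(pressure = numeric(), volume = numeric(),
            fs = 250, metadata = list()))

setValidity("PVRecording", function(object) {
  msg <- NULL
  if (length(object@pressure) != length(object@volume))
    msg <- c(msg, "pressure and volume must have equal length")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@pressure) || any(!is.finite(object@pressure)))
    msg <- c(msg, "pressure contains non-finite values")
  if (anyNA(object@volume) || any(!is.finite(object@volume)))
    msg <- c(msg, "volume contains non-finite values")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PVRecording
#'
#' @param pressure,volume Equal-length numeric vectors (mmHg, ml).
#' @param fs Sampling rate, Hz.
#' @param metadata Named list of per-recording metadata.
#' @return A \linkS4class{PVRecording}.
#' @examples
#' rec <- pvRecording(rep(10, 500), rep(100, 500), fs = 100)
#' @export
pvRecording <- function(pressure, volume, fs, metadata = list()) {
  new("PVRecording", pressure = as.numeric(pressure),
      volume = as.numeric(volume), fs = as.numeric(fs),
      metadata = metadata)
}

#' Table of segmented cardiac beats
#'
#' One row per detected cardiac cycle. Beats are half-open sample intervals
#' [start, end) whose boundary is end-diastole; landmark columns give the
#' sample indices (1-based) of end-diastole, end-systole and the dP/dt
#' extremes, an ectopic flag, and the RR interval in seconds.
#'
#' @slot beats A data.frame with columns \code{start}, \code{end},
#'   \code{i_ed}, \code{i_es}, \code{i_dpdtmax}, \code{i_dpdtmin},
#'   \code{ectopic}, \code{rr}.
#' @slot fs Sampling rate of the parent recording, Hz.
#' @export
setClass("BeatTable",
  representation(beats = "data.frame", fs = "numeric"))

setValidity("BeatTable", function(object) {
  b <- object@beats
  need <- c("start", "end", "i_ed", "i_es", "i_dpdtmax", "i_dpdtmin",
            "ectopic", "rr")
  if (!all(need %in% names(b)))
    return(paste("beats must have columns:", paste(need, collapse = ", ")))
  if (nrow(b)) {
    ok <- b$start <= b$i_ed & b$i_ed <= b$i_dpdtmax &
      b$i_dpdtmax < b$i_es & b$i_es <= b$i_dpdtmin & b$i_dpdtmin < b$end
    if (!all(ok))
      return("landmark ordering violated: need start <= i_ed <= i_dpdtmax < i_es <= i_dpdtmin < end")
    if (any(abs(b$rr - (b$end - b$start) / object@fs) > 1e-9))
      return("rr must equal (end - start)/fs")
  }
  TRUE
})

#' Construct a BeatTable
#' @param beats Data frame of beats (see \linkS4class{BeatTable}).
#' @param fs Sampling rate, Hz.
#' @return A \linkS4class{BeatTable}.
#' @export
beatTable <- function(beats, fs) new("BeatTable", beats = beats, fs = fs)

#' Per-recording hemodynamic index report
#'
#' Summary of the full index battery over the analyzed steady-state beats:
#' per-beat means of the loop-derived indices plus the composed global
#' quantities (HR, CO, CI, SVI, Zva, PRSW, multi-beat elastance slopes, and
#' the ventricular-arterial coupling ratio in both orientations).
#'
#' @slot indices Named numeric vector of index values.
#' @slot units Named character vector of units, parallel to \code{indices}.
#' @slot nBeats Number of beats analyzed.
#' @slot perBeat Data frame of per-beat indices the means were taken over.
#' @export
setClass("IndexReport",
  representation(indices = "numeric", units = "character",
                 nBeats = "integer", perBeat = "data.frame"))

setValidity("IndexReport", function(object) {
  if (length(object@units) && is.null(names(object@indices)))
    return("indices must be named")
  TRUE
})

#' Ground truth of a simulated recording
#'
#' The generating parameter blocks of a simulated PV recording together with
#' derived true values (mean transvalvular gradient, arterial elastance via
#' the Windkessel closed form, end-systolic elastance, isovolumic
#' pressure-decay half-time), the per-beat simulator log, and the internal
#' noise-free state trajectories.
#'
#' @slot elastance,afterload,valve,variability The parameter blocks.
#' @slot derived Named numeric vector of true derived values.
#' @slot beatLog Data frame, one row per emitted beat (start time, rr,
#'   ectopic flag, true landmark times and values).
#' @slot internal Data frame of dense noise-free state trajectories
#'   (time, plv, volume, pao, flow, gradient) on the emitted clock.
#' @export
setClass("SimTruth",
  representation(elastance = "list", afterload = "list", valve = "list",
                 variability = "list", derived = "numeric",
                 beatLog = "data.frame", internal = "data.frame"))

#' Canonical 40-point pressure-volume loop
#'
#' A PV loop reduced to the fixed scheme used for loop averaging: four limbs
#' (isovolumic contraction, ejection, isovolumic relaxation, filling), each
#' resampled to 10 points equally spaced by arc length, 40 points in total.
#' Each limb includes its starting corner and excludes its ending corner.
#'
#' @slot points Data frame with columns \code{volume}, \code{pressure},
#'   \code{limb} (factor with the four limb labels in cycle order).
#' @export
setClass("CanonicalLoop", representation(points = "data.frame"))

setValidity("CanonicalLoop", function(object) {
  p <- object@points
  if (!all(c("volume", "pressure", "limb") %in% names(p)))
    return("points needs columns volume, pressure, limb")
  if (nrow(p) != 40L) return("a canonical loop has exactly 40 points")
  if (!all(table(p$limb) == 10L)) return("each limb must have 10 points")
  if (anyNA(p$volume) || anyNA(p$pressure)) return("NA coordinates")
  TRUE
})

#' Paired pre/post cohort of hemodynamic index reports
#'
#' One row per patient with subgroup labels and optional procedural
#' covariates, plus parallel matrices of pre- and post-intervention index
#' values (patients in rows, indices in columns).
#'
#' @slot patients Data frame: \code{id}, \code{ef_class} ("reduced" or
#'   "preserved"), \code{af}, \code{mi} (logical), and optional covariates
#'   such as \code{rvp_count}, \code{contrast_ml}.
#' @slot pre,post Numeric matrices of index values, same dimnames.
#' @export
setClass("CohortTable",
  representation(patients = "data.frame", pre = "matrix", post = "matrix"))

setValidity("CohortTable", function(object) {
  if (nrow(object@pre) != nrow(object@patients) ||
      nrow(object@post) != nrow(object@patients))
    return("pre and post must have one row per patient")
  if (!identical(colnames(object@pre), colnames(object@post)))
    return("pre and post must share index columns")
  TRUE
})

setMethod("show", "PVRecording", function(object) {
  n <- length(object@pressure)
  cat(sprintf("PVRecording: %d samples at %g Hz (%.1f s)\n",
              n, object@fs, n / object@fs))
  if (n) cat(sprintf("  pressure %.1f-%.1f mmHg, volume %.1f-%.1f ml\n",
                     min(object@pressure), max(object@pressure),
                     min(object@volume), max(object@volume)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "BeatTable", function(object) {
  b <- object@beats
  cat(sprintf("BeatTable: %d beats (%d flagged ectopic), mean RR %.3f s\n",
              nrow(b), sum(b$ectopic), if (nrow(b)) mean(b$rr) else NA))
})

setMethod("show", "IndexReport", function(object) {
  cat(sprintf("IndexReport over %d beats\n", object@nBeats))
  v <- object@indices
  for (nm in names(v))
    cat(sprintf("  %-12s %10.4g %s\n", nm, v[[nm]],
                if (nm %in% names(object@units)) object@units[[nm]] else ""))
})

setMethod("show", "CanonicalLoop", function(object) {
  cat("CanonicalLoop: 40 points (10 per limb)\n")
  cat(sprintf("  V range %.1f-%.1f ml, P range %.1f-%.1f mmHg\n",
              min(object@points$volume), max(object@points$volume),
              min(object@points$pressure), max(object@points$pressure)))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@beatLog), "emitted beats\n")
  d <- object@derived
  for (nm in names(d)) cat(sprintf("  %-22s %.4g\n", nm, d[[nm]]))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d patients, %d indices (pre & post)\n",
              nrow(object@patients), ncol(object@pre)))
})
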