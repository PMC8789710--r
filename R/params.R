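#' Ventricular elastance parameters
#'
#' Parameters of the time-varying elastance model of the left ventricle.
#' Instantaneous LV pressure is \eqn{P(t) = E(t) (V(t) - V_0)}, where the
#' elastance waveform rises from the diastolic floor \code{emin} to the
#' end-systolic value \code{emax} following a normalized double-Hill
#' activation curve.
#'
#' @param emax End-systolic (maximal) elastance, mmHg/ml. This is the
#'   generative analog of the end-systolic pressure-volume relationship
#'   slope (Ees).
#' @param emin Diastolic (minimal) elastance, mmHg/ml; the generative analog
#'   of end-diastolic stiffness (Eed).
#' @param v0 Unstressed volume, ml (volume intercept of the ESPVR).
#' @param t_act Time-to-peak parameter of the activation curve, as a
#'   fraction of the cardiac cycle.
#' @param t_rel Relaxation-timing parameter of the activation curve, as a
#'   fraction of the cardiac cycle. Must exceed \code{t_act}.
#' @param shape Two positive exponents of the double-Hill curve: the first
#'   controls the steepness of activation, the second the abruptness of
#'   relaxation (larger = faster pressure decay, shorter Tau).
#' @return A validated list of class \code{"ElastanceParams"}.
#' @examples
#' ep <- elastanceParams(emax = 3.5)
#' @export
elastanceParams <- function(emax = 3.5, emin = 0.15, v0 = 0,
                            t_act = 0.27, t_rel = 0.42,
                            shape = c(1.9, 14)) {
  p <- list(emax = emax, emin = emin, v0 = v0,
            t_act = t_act, t_rel = t_rel, shape = shape)
  stopifnot(
    "emax must exceed emin > 0" = emax > emin && emin > 0,
    "v0 must be >= 0"           = v0 >= 0,
    "need 0 < t_act < t_rel < 1" = t_act > 0 && t_act < t_rel && t_rel < 1,
    "shape must be two positive exponents" =
      length(shape) == 2 && all(shape > 0)
  )
  class(p) <- c("ElastanceParams", "list")
  p
}

#' Arterial afterload (three-element Windkessel) and filling parameters
#'
#' @param zc Characteristic impedance of the proximal aorta, mmHg s/ml.
#' @param rp Peripheral resistance, mmHg s/ml.
#' @param c Total arterial compliance, ml/mmHg.
#' @param pven Venous/atrial filling pressure, mmHg.
#' @param rmv Mitral inflow resistance, mmHg s/ml.
#' @return A validated list of class \code{"AfterloadParams"}.
#' @examples
#' ap <- afterloadParams()
#' @export
afterloadParams <- function(zc = 0.06, rp = 1.55, c = 0.45,
                            pven = 14, rmv = 0.03) {
  p <- list(zc = zc, rp = rp, c = c, pven = pven, rmv = rmv)
  stopifnot("all afterload parameters must be > 0" =
              all(unlist(p) > 0))
  class(p) <- c("AfterloadParams", "list")
  p
}

#' Aortic valve parameters
#'
#' The valve imposes a quadratic orifice pressure loss
#' \eqn{\Delta P = (q / (K \cdot EOA))^2} during forward flow (Gorlin-type
#' law; \code{k} plays the role of the Gorlin constant, ~44.3 ml/s per cm2
#' per sqrt(mmHg) for the aortic position).
#'
#' @param eoa Effective orifice area, cm2. Severe aortic stenosis is
#'   conventionally EOA < 1.0 cm2.
#' @param k Orifice constant linking flow (ml/s) to gradient (mmHg).
#' @return A validated list of class \code{"ValveParams"}.
#' @examples
#' vp <- valveParams(eoa = 0.7)
#' @export
valveParams <- function(eoa = 0.7, k = 44.3) {
  stopifnot("eoa must be > 0" = eoa > 0, "k must be > 0" = k > 0)
  p <- list(eoa = eoa, k = k)
  class(p) <- c("ValveParams", "list")
  p
}

#' Beat-to-beat variability and measurement-noise parameters
#'
#' Controls the stochastic components of a simulated recording: RR-interval
#' jitter (large \code{rr_cv} emulates atrial fibrillation), slow AR(1)
#' fluctuation of the filling pressure (the preload variability that spreads
#' EDV across beats, needed for PRSW/ESPVR regressions), ectopic beats, and
#' additive white measurement noise on the catheter channels.
#'
#' @param rr_mean Mean RR interval, s.
#' @param rr_cv Coefficient of variation of RR intervals (0.15-0.25 is
#'   AF-like irregularity; ~0.02 is sinus rhythm).
#' @param preload_sd SD of the beat-to-beat AR(1) fluctuation of the venous
#'   filling pressure, mmHg.
#' @param ectopic_rate Probability per beat of an extrasystole (short-coupled
#'   weak beat followed by a compensatory pause).
#' @param noise_p_sd,noise_v_sd SD of additive Gaussian noise on pressure
#'   (mmHg) and volume (ml).
#' @param seed Integer seed for all stochastic terms.
#' @return A validated list of class \code{"VariabilityParams"}.
#' @examples
#' vb <- variabilityParams(rr_mean = 60 / 65)
#' @export
variabilityParams <- function(rr_mean = 60 / 65, rr_cv = 0.02,
                              preload_sd = 1.0, ectopic_rate = 0,
                              noise_p_sd = 1.0, noise_v_sd = 2.0,
                              seed = 1L) {
  p <- list(rr_mean = rr_mean, rr_cv = rr_cv, preload_sd = preload_sd,
            ectopic_rate = ectopic_rate, noise_p_sd = noise_p_sd,
            noise_v_sd = noise_v_sd, seed = as.integer(seed))
  stopifnot(
    "rr_mean must be positive"            = rr_mean > 0,
    "rr_cv, preload_sd, noise SDs >= 0"   =
      all(c(rr_cv, preload_sd, noise_p_sd, noise_v_sd) >= 0),
    "ectopic_rate must be in [0, 0.5)"    =
      ectopic_rate >= 0 && ectopic_rate < 0.5
  )
  class(p) <- c("VariabilityParams", "list")
  p
}
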