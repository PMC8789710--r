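# Lumped-parameter cardiovascular simulator: time-varying elastance LV,
# quadratic-orifice aortic valve, three-element Windkessel afterload,
# constant-pressure venous filling through a mitral resistance.

# Normalized double-Hill activation curve on cycle fraction s in [0, 1].
# phi(s) = [(s/a1)^n1 / (1 + (s/a1)^n1)] * [1 / (1 + (s/a2)^n2)],
# scaled so max(phi) = 1.
normalizedActivation <- function(s, elastance) {
  a1 <- elastance$t_act; a2 <- elastance$t_rel
  n1 <- elastance$shape[1]; n2 <- elastance$shape[2]
  raw <- function(u) {
    h1 <- (u / a1)^n1
    (h1 / (1 + h1)) / (1 + (u / a2)^n2)
  }
  sg <- seq(0, 1, length.out = 2001)
  phi_max <- max(raw(sg))
  raw(s) / phi_max
}

# True isovolumic pressure-decay half-time implied by the elastance
# waveform, in ms: with volume clamped, P(t) tracks E(t); measure the time
# from the steepest-decline point of E to where the excess pressure
# (E - emin scaled) has fallen to half the level at that point.
activationDecayHalftimeMs <- function(elastance, period) {
  sg <- seq(0, 1, length.out = 4001)
  p_iso <- elastance$emin +
    (elastance$emax - elastance$emin) * normalizedActivation(sg, elastance)
  dp <- diff(p_iso)
  i0 <- which.min(dp)                       # steepest decline ~ dP/dt min
  target <- p_iso[i0] / 2
  below <- which(p_iso[i0:length(p_iso)] <= target)
  if (!length(below)) return(NA_real_)
  i1 <- i0 + below[1] - 1L
  # linear interpolation between grid points
  s_cross <- sg[i1 - 1L] + (sg[i1] - sg[i1 - 1L]) *
    (p_iso[i1 - 1L] - target) / (p_iso[i1 - 1L] - p_iso[i1])
  (s_cross - sg[i0]) * period * 1000
}

#' Simulate a conductance-catheter-like PV recording
#'
#' Integrates a time-varying-elastance left ventricle ejecting through a
#' quadratic-orifice (stenotic) aortic valve into a three-element Windkessel,
#' and filling from a venous reservoir through a mitral resistance. Fixed-step
#' 4th-order Runge-Kutta at a 1 ms internal step; the first 10 beats are a
#' discarded warm-up transient so emitted samples start in periodic steady
#' state. Beat-to-beat variability (RR jitter, AR(1) preload fluctuation,
#' ectopic beats) and additive measurement noise are controlled by
#' \code{variability}.
#'
#' @param elastance An \code{\link{elastanceParams}} block.
#' @param afterload An \code{\link{afterloadParams}} block.
#' @param valve A \code{\link{valveParams}} block.
#' @param variability A \code{\link{variabilityParams}} block.
#' @param duration Emitted recording length, s (>= 10).
#' @param fs Output sampling rate, Hz (>= 100).
#' @param bsa Body surface area stored in the recording metadata, m2.
#' @return A list with elements \code{recording} (a
#'   \linkS4class{PVRecording}; metadata holds BSA, the measured systolic
#'   arterial pressure and measured mean transvalvular gradient) and
#'   \code{truth} (a \linkS4class{SimTruth} with the generating parameters,
#'   derived true values and the per-beat log).
#' @examples
#' sim <- simulateRecording(duration = 12, fs = 200)
#' sim$truth
#' @export
simulateRecording <- function(elastance = elastanceParams(),
                              afterload = afterloadParams(),
                              valve = valveParams(),
                              variability = variabilityParams(),
                              duration = 20, fs = 250, bsa = 1.9) {
  stopifnot(
    "duration must be >= 10 s" = duration >= 10,
    "fs must be >= 100 Hz"     = fs >= 100,
    inherits(elastance, "ElastanceParams"),
    inherits(afterload, "AfterloadParams"),
    inherits(valve, "ValveParams"),
    inherits(variability, "VariabilityParams")
  )
  runWithSeed(variability$seed, {
    n_warm <- 10L
    dt <- 1e-3

    ## --- beat schedule ------------------------------------------------
    rr_mean <- variability$rr_mean
    rr <- numeric(0); ect <- logical(0)
    emitted_time <- 0; i <- 0L
    while (emitted_time < duration + 2 * rr_mean) {
      i <- i + 1L
      if (i > 1L && ect[i - 1L]) {              # compensatory pause
        rr_i <- 1.4 * rr_mean; e_i <- FALSE
      } else if (i > n_warm &&
                 stats::runif(1) < variability$ectopic_rate) {
        rr_i <- 0.6 * rr_mean; e_i <- TRUE      # short-coupled ectopic
      } else {
        z <- stats::rnorm(1, 0, variability$rr_cv)
        rr_i <- rr_mean * (1 + max(min(z, 3 * variability$rr_cv),
                                   -3 * variability$rr_cv))
        rr_i <- max(rr_i, 0.35)
        e_i <- FALSE
      }
      rr[i] <- rr_i; ect[i] <- e_i
      if (i > n_warm) emitted_time <- emitted_time + rr_i
    }
    n_beats <- i
    n_step_beat <- pmax(round(rr / dt), 50L)
    rr <- n_step_beat * dt                      # rr quantized to the grid

    ## per-beat modulation
    ar <- 0.7; x <- 0
    pven_b <- numeric(n_beats)
    for (b in seq_len(n_beats)) {
      x <- ar * x + sqrt(1 - ar^2) * stats::rnorm(1)
      pven_b[b] <- afterload$pven + variability$preload_sd * x
    }
    emax_b <- ifelse(ect, 0.7 * elastance$emax, elastance$emax)

    ## --- integration --------------------------------------------------
    emin <- elastance$emin; v0 <- elastance$v0
    zc <- afterload$zc; rp <- afterload$rp; cart <- afterload$c
    rmv <- afterload$rmv
    a_orif <- 1 / (valve$k * valve$eoa)^2

    N <- sum(n_step_beat)
    plv_t <- numeric(N + 1L); vol_t <- numeric(N + 1L)
    pc_t <- numeric(N + 1L); q_t <- numeric(N + 1L)
    beat_start_step <- cumsum(c(0L, n_step_beat[-n_beats])) + 1L

    V <- afterload$pven / emin + v0             # relaxed filling equilibrium
    Pc <- 60
    qin_cum <- 0; qout_cum <- 0
    step <- 0L

    # activation looked up on a half-step grid per beat
    for (b in seq_len(n_beats)) {
      ns <- n_step_beat[b]
      sg <- seq(0, 1, length.out = 2L * ns + 1L)
      E_g <- emin + (emax_b[b] - emin) * normalizedActivation(sg, elastance)
      pv <- pven_b[b]
      for (j in seq_len(ns)) {
        if (j == 1L) {
          plv_t[step + 1L] <- E_g[1L] * (V - v0)
          vol_t[step + 1L] <- V
          pc_t[step + 1L] <- Pc
          dp0 <- E_g[1L] * (V - v0) - Pc
          q_t[step + 1L] <- if (dp0 > 0)
            (-zc + sqrt(zc^2 + 4 * a_orif * dp0)) / (2 * a_orif) else 0
        }
        E1 <- E_g[2L * j - 1L]; E2 <- E_g[2L * j]; E3 <- E_g[2L * j + 1L]
        d1 <- pvDeriv(E1, V, Pc, pv, v0, rmv, zc, a_orif, rp, cart)
        d2 <- pvDeriv(E2, V + dt / 2 * d1[1L], Pc + dt / 2 * d1[2L],
                      pv, v0, rmv, zc, a_orif, rp, cart)
        d3 <- pvDeriv(E2, V + dt / 2 * d2[1L], Pc + dt / 2 * d2[2L],
                      pv, v0, rmv, zc, a_orif, rp, cart)
        d4 <- pvDeriv(E3, V + dt * d3[1L], Pc + dt * d3[2L],
                      pv, v0, rmv, zc, a_orif, rp, cart)
        V <- V + dt / 6 * (d1[1L] + 2 * d2[1L] + 2 * d3[1L] + d4[1L])
        Pc <- Pc + dt / 6 * (d1[2L] + 2 * d2[2L] + 2 * d3[2L] + d4[2L])
        qin_cum <- qin_cum + dt / 6 * (d1[3L] + 2 * d2[3L] + 2 * d3[3L] + d4[3L])
        qout_cum <- qout_cum + dt / 6 * (d1[4L] + 2 * d2[4L] + 2 * d3[4L] + d4[4L])
        step <- step + 1L
        plv <- E3 * (V - v0)
        plv_t[step + 1L] <- plv
        vol_t[step + 1L] <- V
        pc_t[step + 1L] <- Pc
        dp <- plv - Pc
        q_t[step + 1L] <- if (dp > 0)
          (-zc + sqrt(zc^2 + 4 * a_orif * dp)) / (2 * a_orif) else 0
      }
      if (!is.finite(V) || V <= v0 || V >= v0 + 400)
        stop("integration left physiological volume bounds (beat ", b,
             ", V = ", round(V, 1), " ml): check emin/pven/rmv")
      if (!is.finite(Pc) || Pc <= 0 || Pc >= 500)
        stop("integration left physiological arterial-pressure bounds ",
             "(beat ", b, ", Pc = ", round(Pc, 1),
             " mmHg): check rp/c/zc")
    }

    ## --- assemble emitted recording ------------------------------------
    t_int <- (0:N) * dt
    t0 <- t_int[beat_start_step[n_warm + 1L]]
    te <- t_int - t0
    keep <- te >= 0
    n_out <- floor(duration * fs) + 1L
    t_out <- (seq_len(n_out) - 1L) / fs
    t_out <- t_out[t_out <= max(te)]
    p_out <- stats::approx(te[keep], plv_t[keep], xout = t_out)$y
    v_out <- stats::approx(te[keep], vol_t[keep], xout = t_out)$y
    p_meas <- p_out + stats::rnorm(length(p_out), 0, variability$noise_p_sd)
    v_meas <- v_out + stats::rnorm(length(v_out), 0, variability$noise_v_sd)

    pao_t <- pc_t + zc * q_t
    grad_t <- a_orif * q_t^2

    ## --- per-beat truth log (emitted beats only) ------------------------
    emitted <- (n_warm + 1L):n_beats
    sg_peak <- seq(0, 1, length.out = 2001)
    s_peak <- sg_peak[which.max(normalizedActivation(sg_peak, elastance))]
    log_rows <- lapply(emitted, function(b) {
      s0 <- beat_start_step[b]
      s1 <- s0 + n_step_beat[b] - 1L
      es_step <- s0 + round(s_peak * n_step_beat[b])
      ej <- s0:s1
      ejecting <- q_t[ej] > 0
      data.frame(
        start_s = te[s0], rr = rr[b], ectopic = ect[b],
        t_ed = te[s0], t_es = te[es_step],
        edv = vol_t[s0], edp = plv_t[s0],
        esp = plv_t[es_step], esv = vol_t[es_step],
        ejection_s = sum(ejecting) * dt,
        mean_gradient = if (any(ejecting))
          mean(grad_t[ej][ejecting]) else 0)
    })
    blog <- do.call(rbind, log_rows)

    ## --- derived truth ---------------------------------------------------
    tau_wk <- rp * cart
    t_s <- mean(blog$ejection_s[!blog$ectopic])
    t_d <- mean(blog$rr[!blog$ectopic]) - t_s
    ea_wk <- windkesselEa(list(r_t = zc + rp, t_s = t_s, t_d = t_d,
                               tau = tau_wk))
    emit_steps <- beat_start_step[n_warm + 1L]:(N + 1L)
    ejecting <- q_t[emit_steps] > 1e-9
    true_grad <- if (any(ejecting))
      mean(grad_t[emit_steps][ejecting]) else 0
    sap <- max(pao_t[emit_steps])
    map <- mean(pao_t[emit_steps])

    derived <- c(
      mean_gradient = true_grad,
      ea_windkessel = ea_wk,
      emax = elastance$emax,
      tau_ms = activationDecayHalftimeMs(elastance, rr_mean),
      t_s = t_s, t_d = t_d, tau_windkessel = tau_wk,
      sap = sap, map = map,
      volume_conservation_residual =
        abs((qin_cum - qout_cum) - (vol_t[N + 1L] - vol_t[1L])),
      n_warmup_discarded = n_warm
    )

    internal <- data.frame(
      time_s = te[emit_steps], plv = plv_t[emit_steps],
      volume = vol_t[emit_steps], pao = pao_t[emit_steps],
      flow = q_t[emit_steps], gradient = grad_t[emit_steps])

    rec <- pvRecording(
      p_meas, v_meas, fs,
      metadata = list(bsa = bsa, sap = sap, map = map,
                      mean_gradient = true_grad,
                      hr_nominal = 60 / rr_mean))
    truth <- new("SimTruth", elastance = unclass(elastance),
                 afterload = unclass(afterload), valve = unclass(valve),
                 variability = unclass(variability), derived = derived,
                 beatLog = blog, internal = internal)
    list(recording = rec, truth = truth)
  })
}

# Two-state derivatives: V (LV volume) and Pc (Windkessel compliance
# pressure); returns c(dV, dPc, q_in, q_out). The aortic flow solves the
# series combination of the characteristic impedance and the quadratic
# orifice loss: Plv - Pc = Zc q + (q / (K EOA))^2.
pvDeriv <- function(E, V, Pc, pven, v0, rmv, zc, a_orif, rp, cart) {
  plv <- E * (V - v0)
  qmv <- if (pven > plv) (pven - plv) / rmv else 0
  dp <- plv - Pc
  qav <- if (dp > 0) (-zc + sqrt(zc^2 + 4 * a_orif * dp)) / (2 * a_orif)
         else 0
  c(qmv - qav, (qav - Pc / rp) / cart, qmv, qav)
}

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards.
runWithSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Model a transcatheter valve replacement on the parameter blocks
#'
#' Returns post-intervention valve and ventricular parameter blocks: the
#' effective orifice area is replaced by the (strictly larger) prosthesis
#' EOA, and contractility/relaxation are scaled by configurable factors.
#' Effect sizes are scenario knobs, not asserted physiology; the defaults
#' encode a larger orifice with an early contractility drop and slowed
#' relaxation.
#'
#' @param valve,elastance Pre-intervention parameter blocks.
#' @param intervention List with \code{eoa_post} (cm2, must exceed the pre
#'   EOA), \code{emax_factor} (multiplies emax), \code{relax_factor}
#'   (> 1 slows the elastance decay, lengthening Tau roughly in
#'   proportion), and optional \code{emin_factor}.
#' @return List with updated \code{valve} and \code{elastance} blocks.
#' @examples
#' post <- applyTavi(valveParams(0.7), elastanceParams(),
#'                   list(eoa_post = 1.8, emax_factor = 0.6,
#'                        relax_factor = 1.12))
#' @export
applyTavi <- function(valve, elastance,
                      intervention = list(eoa_post = 1.8,
                                          emax_factor = 0.6,
                                          relax_factor = 1.12)) {
  stopifnot(inherits(valve, "ValveParams"),
            inherits(elastance, "ElastanceParams"))
  eoa_post <- intervention$eoa_post
  if (is.null(eoa_post) || eoa_post <= valve$eoa)
    stop("intervention must strictly increase the effective orifice area ",
         "(pre EOA ", valve$eoa, " cm2)")
  emax_f <- intervention$emax_factor %||% 1
  emin_f <- intervention$emin_factor %||% 1
  relax_f <- intervention$relax_factor %||% 1
  new_valve <- valveParams(eoa = eoa_post, k = valve$k)
  new_el <- elastanceParams(
    emax = elastance$emax * emax_f,
    emin = elastance$emin * emin_f,
    v0 = elastance$v0,
    t_act = elastance$t_act,
    t_rel = elastance$t_rel,
    shape = c(elastance$shape[1], elastance$shape[2] / relax_f))
  list(valve = new_valve, elastance = new_el)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
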