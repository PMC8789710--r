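# Loop canonicalization and averaging: the numerization scheme that turns a
# plotted PV loop into 4 limbs x 10 arc-length-equispaced points = 40
# points, and pointwise averaging of such loops.

# cumulative arc length of a polyline in raw (ml, mmHg) coordinates
arcLength <- function(v, p) {
  c(0, cumsum(sqrt(diff(v)^2 + diff(p)^2)))
}

# resample an open polyline to n points equally spaced by arc length,
# including the first vertex and excluding the last
resampleLimb <- function(v, p, n = 10L) {
  s <- arcLength(v, p)
  total <- s[length(s)]
  if (total <= 0) {                      # degenerate limb: repeat the corner
    return(data.frame(volume = rep(v[1L], n), pressure = rep(p[1L], n)))
  }
  at <- total * (seq_len(n) - 1L) / n
  data.frame(volume = stats::approx(s, v, xout = at, ties = "ordered")$y,
             pressure = stats::approx(s, p, xout = at, ties = "ordered")$y)
}

#' Canonicalize a PV loop to 40 points (10 per limb)
#'
#' Decomposes a closed PV loop polyline into its four limbs — isovolumic
#' contraction, ejection, isovolumic relaxation, filling — and resamples
#' each limb to 10 points equally spaced by arc length (each limb includes
#' its starting corner and excludes its ending corner), 40 points total.
#' Corners: end-diastole = the maximal-volume vertex (lowest pressure on
#' ties), end-systole = the maximal P/V vertex, and the limb transitions at
#' the volume extrema between them along the cycle.
#'
#' @param loop Matrix or data.frame with columns volume (ml) and pressure
#'   (mmHg): ordered vertices of one closed loop, first vertex not
#'   repeated at the end. At least 8 vertices.
#' @return A \linkS4class{CanonicalLoop}.
#' @examples
#' rect <- data.frame(volume = c(100, 100, 50, 50),
#'                    pressure = c(10, 110, 110, 10))
#' # insert intermediate vertices so each side is a polyline
#' canonicalizeLoop(loopFromTrace(rect$volume, rect$pressure))
#' @export
canonicalizeLoop <- function(loop) {
  loop <- as.data.frame(loop)
  names(loop)[1:2] <- c("volume", "pressure")
  v <- as.numeric(loop$volume); p <- as.numeric(loop$pressure)
  if (length(v) < 8L) stop("need at least 8 loop vertices")
  if (anyNA(v) || anyNA(p)) stop("NA coordinates in loop")
  n <- length(v)

  # orient counterclockwise in (V, P): ejection traverses high pressure
  # from high to low volume
  if (shoelaceArea(v, p) < 0) { v <- rev(v); p <- rev(p) }

  # end-diastole: maximal volume, ties (within 2% of the volume range, so
  # a noisy flat diastolic plateau counts as tied) broken toward low
  # pressure — the corner where filling ends and contraction starts
  ed_tol <- 0.02 * max(diff(range(v)), 1e-9)
  i_ed <- which(v >= max(v) - ed_tol)
  i_ed <- i_ed[which.min(p[i_ed])]
  ord <- ((i_ed - 1L + 0:(n - 1L)) %% n) + 1L # vertices starting at ED
  vv <- v[ord]; pp <- p[ord]

  # end-systole: maximal P/V vertex
  i_es <- which.max(pp / pmax(vv, 1e-9))
  if (i_es <= 1L || i_es >= n)
    stop("degenerate loop: end-systole coincides with end-diastole")

  # transitions at the volume extrema between the two main corners (with a
  # 2% of volume-range tolerance so the flat isovolumic limbs of rounded
  # loops keep their full extent): onset of ejection = last near-maximal-
  # volume vertex before ES; onset of filling = last near-minimal-volume
  # vertex after ES
  v_tol <- 0.02 * max(diff(range(vv)), 1e-9)
  seg1 <- 1:i_es
  i_oe <- max(seg1[vv[seg1] >= max(vv[seg1]) - v_tol])
  if (i_oe >= i_es) i_oe <- i_es - 1L
  if (i_oe < 2L) i_oe <- 2L
  seg2 <- i_es:n
  i_of <- max(seg2[vv[seg2] <= min(vv[seg2]) + v_tol])
  if (i_of <= i_es) i_of <- i_es + 1L

  corners <- c(1L, i_oe, i_es, i_of)
  if (any(diff(corners) < 1L) || i_of > n)
    stop("degenerate loop: could not order the four corners")

  limb_names <- c("isovolumic-contraction", "ejection",
                  "isovolumic-relaxation", "filling")
  segs <- list(1L:i_oe, i_oe:i_es, i_es:i_of, c(i_of:n, 1L))
  pts <- do.call(rbind, lapply(seq_along(segs), function(k) {
    idx <- segs[[k]]
    d <- resampleLimb(vv[idx], pp[idx], 10L)
    d$limb <- limb_names[k]
    d
  }))
  pts$limb <- factor(pts$limb, levels = limb_names)
  rownames(pts) <- NULL
  new("CanonicalLoop", points = pts)
}

#' Pointwise mean of canonical loops
#'
#' Arithmetic mean of corresponding points across canonical loops; the limb
#' structure is preserved. With a single loop (or N copies of one loop) the
#' result is that loop itself.
#'
#' @param loops List of \linkS4class{CanonicalLoop} objects (>= 1).
#' @return A \linkS4class{CanonicalLoop}.
#' @export
meanLoop <- function(loops) {
  if (!length(loops)) stop("need at least one canonical loop")
  stopifnot(all(vapply(loops, is, logical(1), "CanonicalLoop")))
  ref <- loopPoints(loops[[1L]])
  vmat <- vapply(loops, function(l) loopPoints(l)$volume, numeric(40L))
  pmat <- vapply(loops, function(l) loopPoints(l)$pressure, numeric(40L))
  out <- data.frame(volume = rowMeans(as.matrix(vmat)),
                    pressure = rowMeans(as.matrix(pmat)),
                    limb = ref$limb)
  new("CanonicalLoop", points = out)
}

#' Extract one closed loop polyline from a segmented beat
#'
#' Convenience bridge from a recording and one beat row to the loop
#' polyline expected by \code{\link{canonicalizeLoop}}.
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param beat One row of a beat table.
#' @param smooth_ms Optional moving-average smoothing (ms) applied to both
#'   channels before extraction; 0 = raw samples.
#' @return Data frame with columns \code{volume}, \code{pressure}.
#' @export
beatLoop <- function(rec, beat, smooth_ms = 0) {
  seg <- beat$start:(beat$end - 1L)
  p <- pressure(rec); v <- volume(rec)
  if (smooth_ms > 0) {
    p <- smoothMs(p, samplingRate(rec), smooth_ms)
    v <- smoothMs(v, samplingRate(rec), smooth_ms)
  }
  data.frame(volume = v[seg], pressure = p[seg])
}

#' Build a dense loop polyline from sparse vertices
#'
#' Linearly interpolates extra vertices along each edge of a sparse closed
#' polygon so corner-detection has material to work with (e.g. turning a
#' 4-vertex rectangle into a 40-vertex polyline).
#'
#' @param volume,pressure Vertex coordinates of the closed loop (first
#'   vertex not repeated).
#' @param per_edge Number of interpolated points per edge.
#' @return Data frame with columns \code{volume}, \code{pressure}.
#' @export
loopFromTrace <- function(volume, pressure, per_edge = 10L) {
  n <- length(volume)
  vs <- ps <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    f <- (seq_len(per_edge) - 1L) / per_edge
    vs <- c(vs, volume[i] + f * (volume[j] - volume[i]))
    ps <- c(ps, pressure[i] + f * (pressure[j] - pressure[i]))
  }
  data.frame(volume = vs, pressure = ps)
}

#' Area of a canonical loop
#'
#' Shoelace area of the 40-point polygon, mmHg*ml (magnitude).
#'
#' @param x A \linkS4class{CanonicalLoop}.
#' @return Numeric area.
#' @export
loopArea <- function(x) {
  stopifnot(is(x, "CanonicalLoop"))
  abs(shoelaceArea(loopPoints(x)$volume, loopPoints(x)$pressure))
}
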