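# Delimited-text I/O: recordings (time_s,pressure_mmHg,volume_ml + sidecar
# JSON metadata), beat tables, canonical loops, and index-report export.

#' Write / read a PV recording as delimited text
#'
#' The on-disk format is a comma-separated file with header
#' \code{time_s,pressure_mmHg,volume_ml} plus an optional sidecar JSON
#' (\code{<file>.json}) holding the metadata (and, for simulated
#' recordings, the ground-truth parameter blocks and derived values).
#'
#' @param rec A \linkS4class{PVRecording}.
#' @param file Output path for the CSV.
#' @param truth Optional \linkS4class{SimTruth} to embed in the sidecar.
#' @return \code{writePVRecording}: the file path, invisibly.
#' @export
writePVRecording <- function(rec, file, truth = NULL) {
  stopifnot(is(rec, "PVRecording"))
  df <- data.frame(time_s = sampleTimes(rec),
                   pressure_mmHg = pressure(rec),
                   volume_ml = volume(rec))
  utils::write.csv(df, file, row.names = FALSE)
  side <- list(fs = samplingRate(rec), metadata = recordingMetadata(rec))
  if (!is.null(truth))
    side$truth <- list(elastance = truth@elastance,
                       afterload = truth@afterload,
                       valve = truth@valve,
                       variability = truth@variability,
                       derived = as.list(truth@derived))
  jsonlite::write_json(side, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePVRecording
#' @param file Input CSV path (sidecar JSON picked up automatically when
#'   present).
#' @param fs Sampling rate override; by default inferred from the time
#'   column, which must be uniform.
#' @return \code{readPVRecording}: a \linkS4class{PVRecording}.
#' @export
readPVRecording <- function(file, fs = NULL) {
  df <- utils::read.csv(file)
  need <- c("time_s", "pressure_mmHg", "volume_ml")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6)
    stop("non-uniform sampling in time_s")
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  md <- list()
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$metadata)) md <- side$metadata
    if (!is.null(side$fs)) fs <- side$fs
  }
  pvRecording(df$pressure_mmHg, df$volume_ml, fs, metadata = md)
}

#' Export a beat table as delimited text
#'
#' One row per beat: sample indices of the boundaries and landmarks, the
#' ectopic flag and the RR interval.
#'
#' @param bt A \linkS4class{BeatTable}.
#' @param file Output CSV path.
#' @return The file path, invisibly.
#' @export
writeBeatTable <- function(bt, file) {
  stopifnot(is(bt, "BeatTable"))
  utils::write.csv(beats(bt), file, row.names = FALSE)
  invisible(file)
}

#' Read / write canonical loops
#'
#' Canonical loops travel as \code{volume_ml,pressure_mmHg,limb} CSV; plain
#' two-column \code{volume_ml,pressure_mmHg} files are accepted as raw loop
#' polylines for \code{\link{canonicalizeLoop}}.
#'
#' @param x A \linkS4class{CanonicalLoop}.
#' @param file CSV path.
#' @return \code{writeCanonicalLoop}: the path, invisibly;
#'   \code{readLoopVertices}: a data.frame with \code{volume},
#'   \code{pressure}.
#' @export
writeCanonicalLoop <- function(x, file) {
  stopifnot(is(x, "CanonicalLoop"))
  pts <- loopPoints(x)
  utils::write.csv(data.frame(volume_ml = pts$volume,
                              pressure_mmHg = pts$pressure,
                              limb = pts$limb),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCanonicalLoop
#' @export
readLoopVertices <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("volume_ml", "pressure_mmHg") %in% names(df)))
    stop("expected columns volume_ml, pressure_mmHg")
  data.frame(volume = df$volume_ml, pressure = df$pressure_mmHg)
}

#' Serialize an index report to JSON
#'
#' Writes the index values with their units and the number of analyzed
#' beats.
#'
#' @param report An \linkS4class{IndexReport}.
#' @param file Output JSON path.
#' @return The path, invisibly.
#' @export
writeIndexReport <- function(report, file) {
  stopifnot(is(report, "IndexReport"))
  jsonlite::write_json(
    list(n_beats = report@nBeats,
         indices = as.list(indices(report)),
         units = as.list(report@units)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
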