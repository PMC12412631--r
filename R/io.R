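#' Text-based recording and result serialization
#'
#' Recordings, schedules and probe layouts are serialized as plain JSON
#' (full double precision) so that a run can be archived and re-read
#' without loss: a written-then-read recording is numerically identical.
#' Event tables additionally export as tab-separated text.
#'
#' @name io
NULL

#' Write / read a recording as JSON
#'
#' The payload (data array, sampling rate, stage, wavelengths, channel
#' table, stimulus schedule) round-trips exactly: numbers are written at
#' full precision and the data array's dimensions are stored explicitly.
#'
#' @param rec a `nirs_recording`.
#' @param path output file path (`.json`).
#' @export
write_recording <- function(rec, path) {
  obj <- list(
    layout_name = rec$layout_name, fs = rec$fs, stage = rec$stage,
    wavelengths = rec$wavelengths, chromophores = rec$chromophores,
    dim = dim(rec$data), data = as.numeric(rec$data),
    time = rec$time,
    channels = rec$channels,
    schedule = if (!is.null(rec$schedule)) list(
      blocks = rec$schedule$blocks, duration = rec$schedule$duration,
      initial_rest = rec$schedule$initial_rest,
      isi_range = rec$schedule$isi_range, seed = rec$schedule$seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("dim", "data", "fs", "stage"))
    if (is.null(obj[[field]])) stop("malformed recording file: missing ", field)
  sched <- NULL
  if (!is.null(obj$schedule)) {
    sched <- structure(list(blocks = as.data.frame(obj$schedule$blocks),
                            duration = obj$schedule$duration,
                            initial_rest = obj$schedule$initial_rest,
                            isi_range = obj$schedule$isi_range,
                            seed = obj$schedule$seed),
                       class = "paradigm_schedule")
  }
  rec <- new_recording(obj$layout_name, obj$fs, obj$stage,
                       array(obj$data, dim = obj$dim), obj$wavelengths,
                       if (!is.null(obj$channels)) as.data.frame(obj$channels),
                       sched, obj$time)
  rec$chromophores <- obj$chromophores
  rec
}

#' Write a schedule as a plain-text events table
#'
#' Tab-separated columns `onset`, `duration`, `condition`.
#'
#' @param schedule a `paradigm_schedule`.
#' @param path output path.
#' @export
write_events_table <- function(schedule, path) {
  utils::write.table(schedule$blocks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a brain image as tabular text
#'
#' One row per vertex: id, coordinates, surface tag, HbO and HbR values.
#'
#' @param img a `brain_image` (single frame).
#' @param path output path (tab-separated).
#' @export
write_image_table <- function(img, path) {
  utils::write.table(image_table(img), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
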