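# Plain-text (JSON) fixture container: one file holding the data array, the
# sampling rate, channel labels, and optional event/behavior tables.  Used by
# the test-suite and the simulator so no binary interchange format is needed;
# EDF remains the interchange format for real recordings.

#' Write a fixture container
#'
#' @param recording an [eeg_recording()].
#' @param path output path (conventionally `.json`).
#' @param events optional event table (see [read_events()] for the columns).
#' @param behavior optional behavior table (see [read_behavior()]).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(recording, path, events = NULL, behavior = NULL) {
  obj <- list(
    format = "itfx-fixture", version = 1L,
    fs = recording$fs,
    channel_labels = recording$channel_labels,
    meta = recording$meta,
    data = apply(recording$data, 1L, identity, simplify = FALSE)
  )
  if (!is.null(events)) obj$events <- events
  if (!is.null(behavior)) obj$behavior <- behavior
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a fixture container
#'
#' @param path path written by [write_fixture()].
#' @return A list with elements `recording`, `events` (or `NULL`),
#'   `behavior` (or `NULL`).
#' @export
read_fixture <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_itfx("unreadable fixture file: ", path, " (",
                              conditionMessage(e), ")", class = "itfx_io_error"))
  if (!identical(obj$format, "itfx-fixture"))
    stop_itfx("not an itfx fixture container: ", path,
              class = "itfx_format_error")
  data <- obj$data
  if (is.list(data)) data <- do.call(rbind, data) else data <- rbind(data)
  rec <- eeg_recording(data, fs = obj$fs,
                       channel_labels = obj$channel_labels,
                       meta = as.list(obj$meta))
  ev <- if (!is.null(obj$events)) as.data.frame(obj$events) else NULL
  bh <- if (!is.null(obj$behavior)) as.data.frame(obj$behavior) else NULL
  list(recording = rec, events = ev, behavior = bh)
}
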