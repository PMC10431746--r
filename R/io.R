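## Plain-text persistence: CSV for tabular/array data, JSON for metadata and
## provenance. Every artifact written by the pipeline carries the resolved
## configuration verbatim in a JSON sidecar, and no timestamps, so reruns
## with the same configuration are bit-identical.

#' Write a connectivity map with metadata sidecar
#'
#' @param map a `connectivity_map`.
#' @param path CSV path (`<path>.json` gets the metadata).
#' @export
write_fc_map <- function(map, path) {
  df <- data.frame(vertex = seq_along(map), aec = as.numeric(map))
  write.csv(df, path, row.names = FALSE)
  meta <- list(band = attr(map, "band"), seed = attr(map, "seed"),
               n_epochs = attr(map, "n_epochs"),
               fisher = attr(map, "fisher"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a connectivity map written by [write_fc_map()]
#' @param path CSV path.
#' @return a `connectivity_map`.
#' @export
read_fc_map <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(df$aec, band = meta$band, seed = meta$seed,
            n_epochs = meta$n_epochs, fisher = meta$fisher,
            class = "connectivity_map")
}

#' Write an event table
#' @param events data frame with columns `sample`, `condition`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  write.csv(events[, c("sample", "condition")], path, row.names = FALSE)
  invisible(path)
}

#' Read an event table
#' @param path CSV path.
#' @export
read_events <- function(path) read.csv(path)

#' Write a behavioral response table
#' @param table behavioral data frame.
#' @param path CSV path.
#' @export
write_behavior <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral response table
#' @param path CSV path.
#' @export
read_behavior <- function(path) read.csv(path)

#' Write a sensor recording as CSV (channels x samples) with JSON geometry
#'
#' Large recordings are better regenerated from their configuration; this
#' text format exists for interoperability on small data.
#'
#' @param recording a `sensor_recording`.
#' @param path CSV path.
#' @export
write_recording <- function(recording, path) {
  write.csv(as.data.frame(recording$data), path, row.names = FALSE)
  meta <- list(sfreq = recording$sfreq,
               channel_names = recording$channel_names)
  if (!is.null(recording$sensors)) {
    meta$positions <- recording$sensors$pos
    meta$orientations <- recording$sensors$ori
    meta$types <- recording$sensors$type
  }
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Write arbitrary provenance/metadata JSON
#' @param x list to serialize.
#' @param path JSON path.
#' @export
write_provenance <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}
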