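#' Save and load sensor recordings
#'
#' Recordings and other pipeline artifacts are stored as RDS containers;
#' label tables travel as CSV and run summaries as JSON.
#'
#' @param recording a `sensor_recording`.
#' @param path file path.
#' @return `load_recording` returns a validated `sensor_recording`.
#' @export
save_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$data) || is.null(x$sampling_rate)) {
    stop("not a sensor recording container: ", path)
  }
  if (is.null(x$pair_map)) {
    stop("recording container is missing the 'pair_map' dataset: ", path)
  }
  sensor_recording(x$data, x$sampling_rate, x$positions, x$pair_map)
}

#' Read and validate a subject label table
#'
#' The CSV must have columns `subject_id` and `group`; rows with missing or
#' blank entries are reported by row number.
#'
#' @param path CSV path.
#' @return Data frame with character `subject_id` and `group`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("label table must have columns subject_id, group: ", path)
  }
  bad <- which(is.na(df$subject_id) | df$subject_id == "" |
                 is.na(df$group) | df$group == "")
  if (length(bad)) {
    stop("malformed label rows: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id values: ",
         paste(df$subject_id[duplicated(df$subject_id)], collapse = ", "))
  }
  df[c("subject_id", "group")]
}

#' @rdname read_labels
#' @param labels data frame with `subject_id`, `group`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("subject_id", "group") %in% names(labels)))
  utils::write.csv(labels[c("subject_id", "group")], path, row.names = FALSE)
  invisible(path)
}

#' Save and load an efficiency map
#'
#' `save_efficiency_map` writes both the RDS container and, when `csv` is
#' `TRUE`, a long-format CSV (`node`, `frequency_hz`, `efficiency`).
#'
#' @param efficiency_map an `efficiency_map`.
#' @param path RDS path.
#' @param csv also write `<path>.csv` in long format.
#' @export
save_efficiency_map <- function(efficiency_map, path, csv = FALSE) {
  stopifnot(inherits(efficiency_map, "efficiency_map"))
  saveRDS(efficiency_map, path)
  if (csv) {
    utils::write.csv(efficiency_long(efficiency_map),
                     paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_efficiency_map
#' @export
load_efficiency_map <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "efficiency_map")) stop("not an efficiency map: ", path)
  x
}
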