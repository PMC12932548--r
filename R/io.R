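## File formats: spike CSV (well, electrode, time_s), plate maps, the trace
## container (JSON header + compressed CSV matrix), two-channel TIFF images
## and JSON ground-truth sidecars.

#' Write spike trains to CSV
#'
#' Columns `well`, `electrode`, `time_s`; timestamps are written as decimal
#' seconds with 6 fractional digits (1 microsecond, well beyond the 80
#' microsecond resolution of 12.5 kHz sampling), so a write/read round trip
#' is lossless at that precision.
#'
#' @param sts A [spike_train_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(sts, path) {
  stop_if(!inherits(sts, "spike_train_set"), "`sts` must be a spike_train_set")
  df <- sts$spikes
  df$time_s <- sprintf("%.6f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path CSV file with columns `well`, `electrode`, `time_s`.
#' @param duration Recording duration in seconds (not stored in the CSV).
#' @return A [spike_train_set()]; rows are sorted on read.
#' @export
read_spike_csv <- function(path, duration) {
  df <- utils::read.csv(path, colClasses = c(well = "character"))
  need <- c("well", "electrode", "time_s")
  stop_if(!all(need %in% names(df)), "%s: expected columns %s", path,
          paste(need, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 !is.finite(suppressWarnings(as.numeric(df$electrode))))
  stop_if(length(bad) > 0, "%s: malformed row(s) at line(s) %s", path,
          paste(bad + 1L, collapse = ", "))
  df$time_s <- as.numeric(df$time_s)
  df$electrode <- as.integer(df$electrode)
  spike_train_set(df, duration)
}

#' Write a voltage recording to a trace container
#'
#' The container is a directory holding `header.json` (sampling rate,
#' duration, electrode keys, sample count) and `traces.csv`, a
#' CSV matrix with one column per electrode (named
#' `<well>.<electrode>`) and one row per sample, in microvolts.
#'
#' @param rec A [voltage_recording()].
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stop_if(!inherits(rec, "voltage_recording"),
          "`rec` must be a voltage_recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(sampling_rate = rec$sampling_rate, duration = rec$duration,
                 electrodes = names(rec$traces),
                 n_samples = if (length(rec$traces)) length(rec$traces[[1]])
                             else 0L)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(as.data.frame(rec$traces, check.names = FALSE,
                                   optional = TRUE),
                     file.path(path, "traces.csv"))
  invisible(path)
}

#' Read a voltage recording from a trace container
#'
#' @param path Directory written by [write_recording()].
#' @return A [voltage_recording()].
#' @export
read_recording <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  df <- data.table::fread(file.path(path, "traces.csv"),
                          data.table = FALSE)
  traces <- as.list(df)
  names(traces) <- header$electrodes
  voltage_recording(traces, header$sampling_rate, header$duration)
}

#' Write / read a two-channel neuron image as TIFF
#'
#' Page 1 is the nuclei channel, page 2 the neurite-marker channel, both as
#' 32-bit float intensities in \[0, 1\].
#'
#' @param image A `neuron_image` (fields `nuclei`, `marker`).
#' @param path TIFF file path.
#' @return `path` invisibly ([write_neuron_tiff()]); a `neuron_image`
#'   ([read_neuron_tiff()]).
#' @export
write_neuron_tiff <- function(image, path) {
  tiff::writeTIFF(list(image$nuclei, image$marker), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_neuron_tiff
#' @export
read_neuron_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stop_if(length(pages) < 2, "%s: expected a 2-page TIFF", path)
  structure(list(nuclei = pages[[1]], marker = pages[[2]],
                 pixel_size = NA_real_), class = "neuron_image")
}

#' Write morphology ground truth as a JSON sidecar
#'
#' @param truth A `morphology_ground_truth` (from
#'   [generate_neuron_image()]).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a plate map
#'
#' @param path CSV with columns `well`, `compound`, `dose` and optionally
#'   `role` (`control`/`treated`; derived from `dose == 0` when absent).
#' @return `data.frame` of class `plate_map`.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, colClasses = c(well = "character"))
  plate_map(df)
}

#' Validate a plate map table
#'
#' @param df `data.frame` with columns `well`, `compound`, `dose`
#'   (micrograms/mL) and optionally `role`.
#' @return The validated `data.frame` with class `plate_map`.
#' @export
plate_map <- function(df) {
  need <- c("well", "compound", "dose")
  stop_if(!is.data.frame(df) || !all(need %in% names(df)),
          "plate map needs columns %s", paste(need, collapse = ", "))
  stop_if(anyDuplicated(df$well) > 0, "plate map wells must be unique")
  stop_if(any(df$dose < 0), "doses must be >= 0")
  if (!("role" %in% names(df))) {
    df$role <- ifelse(df$dose == 0, "control", "treated")
  }
  stop_if(any(df$role == "control" & df$dose != 0),
          "control wells must have dose 0")
  class(df) <- c("plate_map", class(df))
  df
}
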