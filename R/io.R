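#' Write / read a recording as raw binary plus JSON sidecar
#'
#' Voltages are stored channel-major (all samples of channel 1, then channel
#' 2, ...) as little-endian float32; acquisition metadata live in a JSON
#' sidecar (`fs_hz`, `n_channels`, `n_samples`, `unit`, `duration_s`).
#' Storage is 32-bit, so values not representable in float32 are rounded on
#' write; a write-read cycle of float32 data is lossless.
#'
#' @param rec an [recording()].
#' @param bin_path path of the binary voltage file.
#' @param sidecar_path path of the JSON sidecar (default `bin_path` +
#'   `.json`).
#' @return `bin_path`, invisibly.
#' @export
write_recording <- function(rec, bin_path,
                            sidecar_path = paste0(bin_path, ".json")) {
  stopifnot(inherits(rec, "ime_recording"))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$voltages)), con, size = 4, endian = "little")
  meta <- list(fs_hz = rec$fs, n_channels = nrow(rec$voltages),
               n_samples = ncol(rec$voltages), unit = "uV",
               duration_s = ncol(rec$voltages) / rec$fs,
               channel_ids = rec$channel_ids)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(bin_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(bin_path,
                           sidecar_path = paste0(bin_path, ".json")) {
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("fs_hz", "n_channels", "n_samples"))
    if (is.null(meta[[f]]))
      stop("sidecar missing field `", f, "`", call. = FALSE)
  if (meta$fs_hz <= 0) stop("sidecar `fs_hz` must be > 0", call. = FALSE)
  meta$fs_hz <- as.numeric(meta$fs_hz)
  expected <- meta$n_channels * meta$n_samples
  actual <- file.size(bin_path) / 4
  if (actual != expected)
    stop(sprintf("binary length mismatch: expected %d samples, found %g",
                 expected, actual), call. = FALSE)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = expected, size = 4, endian = "little")
  recording(matrix(v, nrow = meta$n_channels, byrow = TRUE), meta$fs_hz,
            meta$channel_ids %||% seq_len(meta$n_channels))
}

#' Write detected events as CSV plus raw snippet binary
#'
#' @param events a `spike_events` object.
#' @param dir output directory (created if needed).
#' @param flag optional per-event flag column (e.g. artifact class).
#' @return The directory, invisibly; writes `events.csv`, `snippets.bin`
#'   (float32, event-major) and `snippets.json`.
#' @export
write_events <- function(events, dir, flag = NULL) {
  stopifnot(inherits(events, "spike_events"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(events)
  df$flag <- flag %||% rep("kept", nrow(df))
  write.csv(df, file.path(dir, "events.csv"), row.names = FALSE)
  wf <- attr(events, "waveforms")
  con <- file(file.path(dir, "snippets.bin"), "wb")
  writeBin(as.vector(t(wf)), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(n_events = nrow(wf), snippet_samples = ncol(wf),
                            window_ms = as.list(attr(events, "window")),
                            fs_hz = attr(events, "fs")),
                       file.path(dir, "snippets.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize sorted units to JSON
#'
#' @param units an `ime_units` list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  stopifnot(inherits(units, "ime_units"))
  out <- lapply(units, function(u)
    list(channel = u$channel, n_spikes = u$n_spikes,
         verified = isTRUE(u$verified), spike_times_s = u$spike_times,
         mean_waveform_uv = u$mean_waveform))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a 16-bit grayscale TIFF image
#'
#' Intensities are stored as 16-bit counts (0-65535).
#'
#' @param image numeric matrix of counts.
#' @param path file path.
#' @return `path` invisibly, or the counts matrix for the reader.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  x <- round(tiff::readTIFF(path) * 65535)
  storage.mode(x) <- "integer"
  x
}

#' Write / read a binary mask as 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `path` invisibly, or the logical mask for the reader.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Read / write a channel activity CSV
#'
#' Columns: `group`, `animal`, `week`, `channel`, `n_units` (and optionally
#' `session`).
#'
#' @param df activity data.frame (writer) / `path` file path.
#' @param path file path.
#' @return The activity table (reader) or `path` invisibly (writer).
#' @export
read_activity_csv <- function(path) {
  channel_activity_table(read.csv(path))
}

#' @rdname read_activity_csv
#' @export
write_activity_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a release series CSV
#'
#' Columns `time_h`, `conc_mg_per_ml`; reservoir metadata may be supplied on
#' read.
#'
#' @param series a [release_series()] (writer) / `path` file path.
#' @param path file path.
#' @param v_reservoir,v_aliquot,loaded_mass metadata for the reader.
#' @return The series (reader) or `path` invisibly (writer).
#' @export
read_release_csv <- function(path, v_reservoir = 14, v_aliquot = 1,
                             loaded_mass = NA_real_) {
  df <- read.csv(path)
  release_series(df$time_h, df$conc_mg_per_ml, v_reservoir, v_aliquot,
                 loaded_mass)
}

#' @rdname read_release_csv
#' @export
write_release_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
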