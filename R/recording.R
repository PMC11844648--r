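#' Multichannel extracellular recording
#'
#' Container for a channels x samples voltage matrix in microvolts together
#' with its sampling rate and channel identifiers, mirroring a 16-channel
#' headstage acquisition.
#'
#' @param voltages numeric matrix, channels x samples, in uV.
#' @param fs sampling rate in Hz.
#' @param channel_ids optional channel identifiers (default `1:nrow`).
#' @return An object of class `ime_recording`.
#' @export
recording <- function(voltages, fs, channel_ids = NULL) {
  if (!is.matrix(voltages) || !is.numeric(voltages))
    stop("`voltages` must be a numeric channels x samples matrix", call. = FALSE)
  if (!.all_finite(voltages))   # streaming check; sessions are GB-scale
    stop("`voltages` must be finite", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  channel_ids <- channel_ids %||% seq_len(nrow(voltages))
  if (length(channel_ids) != nrow(voltages))
    stop("`channel_ids` length must match the number of channels", call. = FALSE)
  structure(list(voltages = voltages, fs = fs, channel_ids = channel_ids),
            class = "ime_recording")
}

#' @export
print.ime_recording <- function(x, ...) {
  cat(sprintf("<ime_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$voltages), ncol(x$voltages), x$fs,
              ncol(x$voltages) / x$fs))
  invisible(x)
}

#' @export
dim.ime_recording <- function(x) dim(x$voltages)

n_samples <- function(rec) ncol(rec$voltages)
n_channels <- function(rec) nrow(rec$voltages)
rec_duration <- function(rec) ncol(rec$voltages) / rec$fs
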