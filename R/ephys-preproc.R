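#' Spike detection and artifact-screening configuration
#'
#' Houses the study's detection rules: a -4 sigma negative threshold on the
#' referenced, band-passed signal, the +/-500 uV amplitude-abnormality rule,
#' and the >14-channel coincidence rule for motion artifacts.
#'
#' @param k_sigma threshold multiplier (default 4).
#' @param band band-pass edges in Hz (default `c(300, 3000)`).
#' @param lockout_ms detection lockout after a peak, ms (default 1).
#' @param snippet_pre_ms,snippet_post_ms snippet window around the peak, ms
#'   (defaults 0.5 / 1.0).
#' @param amp_limit_uv absolute amplitude limit, uV (default 500).
#' @param coincidence_channels channel-count threshold for the motion rule;
#'   groups spanning strictly more channels are removed (default 14).
#' @param coincidence_window_ms peak-coincidence window, ms (default 0.5).
#' @param sigma_method noise-scale estimator: `"mad"` (median(|x|)/0.6745,
#'   default) or `"sd"` (sample standard deviation).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(k_sigma = 4, band = c(300, 3000), lockout_ms = 1,
                             snippet_pre_ms = 0.5, snippet_post_ms = 1,
                             amp_limit_uv = 500, coincidence_channels = 14,
                             coincidence_window_ms = 0.5,
                             sigma_method = c("mad", "sd")) {
  stop_if_not_scalar_pos(k_sigma, "k_sigma")
  stop_if_not_scalar_pos(amp_limit_uv, "amp_limit_uv")
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  structure(list(k_sigma = k_sigma, band = band, lockout_ms = lockout_ms,
                 snippet_pre_ms = snippet_pre_ms,
                 snippet_post_ms = snippet_post_ms,
                 amp_limit_uv = amp_limit_uv,
                 coincidence_channels = coincidence_channels,
                 coincidence_window_ms = coincidence_window_ms,
                 sigma_method = match.arg(sigma_method)),
            class = "detection_config")
}

#' Common-median referencing
#'
#' Subtracts, sample by sample, the across-channel median from every channel,
#' removing common-mode signals (movement, line noise) while being robust to
#' large activity on a minority of channels. With an even channel count the
#' median is the mean of the two middle order statistics.
#'
#' @param rec an [recording()].
#' @return The referenced recording.
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "ime_recording"))
  if (nrow(rec$voltages) < 2)
    stop("common median reference requires >= 2 channels", call. = FALSE)
  v <- rec$voltages
  rec$voltages <- NULL
  # collect dead stage inputs before duplicating a GB-scale session matrix
  if (length(v) > 3e7) gc(FALSE)
  rec$voltages <- .subtract_col_medians(v)
  structure(rec[c("voltages", "fs", "channel_ids")], class = "ime_recording")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (default 300-3000 Hz, matching
#' the acquisition band) forward and backward (`filtfilt`) so the output is
#' zero-phase.
#'
#' @param rec an [recording()].
#' @param band band edges in Hz; both must lie inside `(0, fs/2)`.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, band = c(300, 3000)) {
  stopifnot(inherits(rec, "ime_recording"))
  if (band[1] <= 0 || band[2] <= band[1])
    stop("`band` must be an increasing positive pair", call. = FALSE)
  if (band[2] >= rec$fs / 2)
    stop("`band` upper edge must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(2, band / (rec$fs / 2), type = "pass")
  # detach the matrix so the row filter copies it at most once; collect any
  # dead upstream session matrix before that copy
  v <- rec$voltages
  rec$voltages <- NULL
  if (length(v) > 3e7) gc(FALSE)
  rec$voltages <- .filtfilt_rows(v, bf$b, bf$a)
  structure(rec[c("voltages", "fs", "channel_ids")], class = "ime_recording")
}

#' Robust per-channel noise scale
#'
#' `sigma_hat = median(|x|) / 0.6745`, the standard robust estimate of the
#' Gaussian noise SD, insensitive to spike contamination.
#'
#' @param x numeric signal vector.
#' @return Estimated noise SD.
#' @export
robust_sigma <- function(x) median(abs(x)) / 0.6745

#' Detect spikes by negative threshold crossing
#'
#' Per channel, estimates the noise scale, finds negative-going crossings of
#' `-k_sigma * sigma_hat`, takes the local minimum within the lockout window
#' as the event peak, enforces one event per lockout, and extracts
#' edge-padded waveform snippets around each peak.
#'
#' @param rec a referenced, band-limited [recording()].
#' @param cfg a [detection_config()].
#' @return An object of class `spike_events`: a data.frame with columns
#'   `channel`, `peak_sample` (0-based), `time_s`, `amplitude_uv`, and
#'   attributes `waveforms` (events x samples matrix), `window` (pre/post ms),
#'   `fs`, and `sigma` (per-channel noise scale).
#' @export
detect_spikes <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "ime_recording"), inherits(cfg, "detection_config"))
  fs <- rec$fs
  pre <- round(cfg$snippet_pre_ms * fs / 1000)
  post <- round(cfg$snippet_post_ms * fs / 1000)
  lock <- max(1L, round(cfg$lockout_ms * fs / 1000))
  nsmp <- ncol(rec$voltages)
  if (nsmp < pre + post + 1)
    stop("recording shorter than the snippet window", call. = FALSE)

  res <- vector("list", nrow(rec$voltages))
  sig_all <- numeric(nrow(rec$voltages))
  for (c in seq_len(nrow(rec$voltages))) {
    x <- rec$voltages[c, ]
    sig <- if (cfg$sigma_method == "mad") robust_sigma(x) else stats::sd(x)
    sig_all[c] <- sig
    thr <- -cfg$k_sigma * sig
    peaks <- integer(0)
    if (sig > 0) {
      below <- x < thr
      crossings <- which(below[-1] & !below[-nsmp]) + 1L
      last_end <- -Inf
      for (i in crossings) {
        if (i <= last_end) next
        w_end <- min(nsmp, i + lock - 1L)
        p <- i - 1L + which.min(x[i:w_end])
        peaks <- c(peaks, p)
        last_end <- p + lock
      }
    }
    if (length(peaks)) {
      wf <- t(vapply(peaks, function(p) {
        idx <- (p - pre):(p + post)
        x[pmin(pmax(idx, 1L), nsmp)]       # edge padding
      }, numeric(pre + post + 1)))
      res[[c]] <- list(df = data.frame(channel = rec$channel_ids[c],
                                       peak_sample = peaks - 1L,
                                       time_s = (peaks - 1L) / fs,
                                       amplitude_uv = x[peaks]),
                       wf = wf)
    }
    if (nsmp > 3e6 && c %% 4L == 0L) { rm(x); gc(FALSE) }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  df <- if (length(res)) do.call(rbind, lapply(res, `[[`, "df")) else
    data.frame(channel = integer(0), peak_sample = integer(0),
               time_s = numeric(0), amplitude_uv = numeric(0))
  wf <- if (length(res)) do.call(rbind, lapply(res, `[[`, "wf")) else
    matrix(0, 0, pre + post + 1)
  rownames(df) <- NULL
  structure(df, waveforms = wf,
            window = c(pre_ms = cfg$snippet_pre_ms,
                       post_ms = cfg$snippet_post_ms),
            fs = fs, sigma = setNames(sig_all, rec$channel_ids),
            class = c("spike_events", "data.frame"))
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events on %d channels\n",
              nrow(x), length(unique(x$channel))))
  invisible(x)
}

subset_events <- function(events, idx) {
  out <- events[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "waveforms") <- attr(events, "waveforms")[idx, , drop = FALSE]
  for (a in c("window", "fs", "sigma"))
    attr(out, a) <- attr(events, a)
  class(out) <- class(events)
  out
}

#' Screen detected events for amplitude and motion artifacts
#'
#' Events whose peak or any snippet sample exceeds `amp_limit_uv` in absolute
#' value are abnormal-amplitude artifacts. Among the remainder, events whose
#' peaks coincide within `coincidence_window_ms` across channels are grouped
#' (single-linkage in time) and any group spanning strictly more than
#' `coincidence_channels` distinct channels is removed as a motion artifact.
#' The three output sets partition the input.
#'
#' @param events a `spike_events` object from [detect_spikes()].
#' @param cfg a [detection_config()].
#' @return A list of `spike_events`: `kept`, `removed_amplitude`,
#'   `removed_motion`.
#' @export
reject_artifacts <- function(events, cfg = detection_config()) {
  stopifnot(inherits(events, "spike_events"))
  n <- nrow(events)
  if (n == 0)
    return(list(kept = events, removed_amplitude = events,
                removed_motion = events))
  wf <- attr(events, "waveforms")
  amp_bad <- apply(abs(wf), 1, max) > cfg$amp_limit_uv |
    abs(events$amplitude_uv) > cfg$amp_limit_uv

  motion_bad <- logical(n)
  cand <- which(!amp_bad)
  if (length(cand) > 1) {
    ord <- cand[order(events$time_s[cand])]
    tt <- events$time_s[ord]
    win <- cfg$coincidence_window_ms / 1000
    grp <- cumsum(c(1, diff(tt) > win))
    for (g in split(ord, grp)) {
      if (length(unique(events$channel[g])) > cfg$coincidence_channels)
        motion_bad[g] <- TRUE
    }
  }
  list(kept = subset_events(events, !amp_bad & !motion_bad),
       removed_amplitude = subset_events(events, amp_bad),
       removed_motion = subset_events(events, motion_bad))
}

#' Impedance quality control at 1 kHz
#'
#' A device passes when every electrode site's 1 kHz impedance lies in the
#' normal range 100 kOhm - 1 MOhm (inclusive).
#'
#' @param site_impedances numeric vector of per-site impedances, Ohm.
#' @param range acceptable range in Ohm (default `c(1e5, 1e6)`).
#' @return An `impedance_report`: data.frame of per-site impedance and
#'   in-range status, with attribute and element `pass` for the device.
#' @export
impedance_qc <- function(site_impedances, range = c(1e5, 1e6)) {
  if (!is.numeric(site_impedances) || length(site_impedances) < 1)
    stop("impedances must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(site_impedances)) || any(site_impedances <= 0))
    stop("impedances must be positive and finite", call. = FALSE)
  in_range <- site_impedances >= range[1] & site_impedances <= range[2]
  structure(list(sites = data.frame(site = seq_along(site_impedances),
                                    impedance_ohm = site_impedances,
                                    in_range = in_range),
                 pass = all(in_range)),
            class = "impedance_report")
}

#' @export
print.impedance_report <- function(x, ...) {
  cat(sprintf("<impedance_report> %d sites, %d in range: %s\n",
              nrow(x$sites), sum(x$sites$in_range),
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
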