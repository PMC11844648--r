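#' Peak-to-peak amplitude of a waveform
#'
#' @param waveform numeric vector, uV.
#' @return `max - min`, uV.
#' @export
unit_vpp <- function(waveform) {
  if (!length(waveform)) stop("empty waveform", call. = FALSE)
  max(waveform) - min(waveform)
}

#' Channel noise RMS after spike exclusion
#'
#' Root mean square of a referenced, filtered channel signal over the samples
#' lying outside every detected event's snippet window.
#'
#' @param x numeric channel signal, uV.
#' @param peak_samples 0-based peak samples of that channel's detected events.
#' @param fs sampling rate, Hz.
#' @param window snippet window `c(pre_ms, post_ms)` excised around each
#'   peak (default `c(0.5, 1)`).
#' @return Noise RMS, uV.
#' @export
channel_noise_rms <- function(x, peak_samples = integer(0), fs,
                              window = c(0.5, 1)) {
  stop_if_not_scalar_pos(fs, "fs")
  keep <- rep(TRUE, length(x))
  pre <- round(window[1] * fs / 1000)
  post <- round(window[2] * fs / 1000)
  for (p in peak_samples) {
    i0 <- max(1L, p + 1L - pre)
    i1 <- min(length(x), p + 1L + post)
    keep[i0:i1] <- FALSE
  }
  if (!any(keep)) stop("all samples excluded by spike windows", call. = FALSE)
  root_mean_square(x[keep])
}

#' Unit signal-to-noise ratio
#'
#' @param vpp unit peak-to-peak amplitude, uV.
#' @param noise_rms channel noise RMS, uV (> 0).
#' @return `vpp / noise_rms`.
#' @export
unit_snr <- function(vpp, noise_rms) {
  if (any(noise_rms <= 0)) stop("`noise_rms` must be > 0", call. = FALSE)
  vpp / noise_rms
}

#' Unit spike rate as the inverse median inter-spike interval
#'
#' With an even ISI count the median is the mean of the two middle intervals.
#' Units with fewer than 2 spikes have no defined rate and return `NA`
#' (they are flagged and excluded from rate means downstream).
#'
#' @param spike_times sorted spike times, seconds.
#' @return Rate in Hz, or `NA_real_`.
#' @export
unit_spike_rate <- function(spike_times) {
  if (length(spike_times) < 2) return(NA_real_)
  1 / median(diff(spike_times))
}

#' Putative-unit filter
#'
#' Units with a peak-to-peak amplitude below 40 uV are considered
#' non-putative; exactly 40 uV is retained.
#'
#' @param vpp numeric vector of unit Vpp values, uV.
#' @param threshold_uv threshold (default 40).
#' @return Logical vector: `TRUE` for putative units.
#' @export
filter_putative <- function(vpp, threshold_uv = 40) vpp >= threshold_uv

#' ROUT outlier detection (constant-model specialization)
#'
#' Robust outlier removal controlling a false-discovery rate `Q` among the
#' flagged points. Applied to a single metric column, the robust fit reduces
#' to the median; the residual scale is the robust standard deviation of the
#' residuals (RSDR), the 68.27th percentile of the absolute residuals with an
#' `n/(n-1)` small-sample correction. Residual t-ratios are tested
#' outermost-first against the FDR schedule `alpha_j = Q * j / n` (two-sided
#' t with `n - 1` degrees of freedom), stopping at the first non-significant
#' point.
#'
#' @param values numeric vector (>= 3 finite values for any flagging).
#' @param Q false-discovery rate (default 0.05).
#' @return Logical flags in input order.
#' @export
rout_outliers <- function(values, Q = 0.05) {
  stopifnot(is.numeric(values), Q > 0, Q < 1)
  n <- length(values)
  flags <- logical(n)
  if (n < 3) {
    warning("fewer than 3 values; no outliers flagged")
    return(flags)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  res <- values - median(values)
  rsdr <- quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) return(flags)                 # >68% of points identical
  tt <- abs(res) / rsdr
  ord <- order(tt, decreasing = TRUE)
  p <- 2 * pt(-tt[ord], df = n - 1)
  for (j in seq_len(n)) {
    if (p[j] < Q * j / n) flags[ord[j]] <- TRUE else break
  }
  flags
}

#' Assemble the per-unit metrics table
#'
#' Computes Vpp, channel noise RMS (spike-excised, shared by all units on a
#' channel), SNR, median-ISI spike rate, and the putative flag for every
#' sorted unit of one session.
#'
#' @param units an `ime_units` list (after [verify_units()]).
#' @param rec the referenced, filtered [recording()] the units came from.
#' @param events the `spike_events` retained after artifact screening (their
#'   snippet windows are excised from the noise estimate).
#' @param putative_threshold_uv putative-unit Vpp threshold (default 40).
#' @return A data.frame with one row per unit: `unit`, `channel`, `n_spikes`,
#'   `vpp_uv`, `noise_uv`, `snr`, `rate_hz`, `putative`, `verified`.
#' @export
unit_metrics_table <- function(units, rec, events,
                               putative_threshold_uv = 40) {
  stopifnot(inherits(units, "ime_units"), inherits(rec, "ime_recording"))
  win <- attr(events, "window") %||% c(pre_ms = 0.5, post_ms = 1)
  noise <- setNames(rep(NA_real_, length(rec$channel_ids)), rec$channel_ids)
  for (c in seq_along(rec$channel_ids)) {
    id <- rec$channel_ids[c]
    pk <- events$peak_sample[events$channel == id]
    noise[as.character(id)] <-
      channel_noise_rms(rec$voltages[c, ], pk, rec$fs, unname(win))
    if (ncol(rec$voltages) > 3e6 && c %% 4L == 0L) gc(FALSE)
  }
  vpp <- vapply(units, function(u) unit_vpp(u$mean_waveform), numeric(1))
  ch <- vapply(units, `[[`, numeric(1), "channel")
  data.frame(
    unit = seq_along(units),
    channel = ch,
    n_spikes = vapply(units, `[[`, numeric(1), "n_spikes"),
    vpp_uv = vpp,
    noise_uv = unname(noise[as.character(ch)]),
    snr = unit_snr(vpp, unname(noise[as.character(ch)])),
    rate_hz = vapply(units, function(u) unit_spike_rate(u$spike_times),
                     numeric(1)),
    putative = filter_putative(vpp, putative_threshold_uv),
    verified = vapply(units, function(u) isTRUE(u$verified), logical(1)))
}

#' Aggregate unit metrics to channel x phase summaries
#'
#' Averages per-unit metrics at the individual channel level within each time
#' phase (weeks 1-4 and 5-8 by default). Only qualifying units — putative,
#' verified, and not SNR outliers — contribute; channels with no qualifying
#' units in a phase produce no row (the active-channel definition).
#' `units_per_active_channel` divides the qualifying unit count by the number
#' of weeks in the phase. Units with an undefined spike rate still count but
#' are excluded from the rate mean.
#'
#' @param metrics data.frame with at least `channel`, `week`, `vpp_uv`,
#'   `noise_uv`, `snr`, `rate_hz`, `putative`, `verified`, and `snr_outlier`
#'   columns; optional `group` and `animal` columns join the grouping.
#' @param phases named list of week vectors
#'   (default `list(W1_4 = 1:4, W5_8 = 5:8)`).
#' @return A data.frame keyed by (optional group/animal,) channel and phase
#'   with `n_units`, `mean_vpp`, `mean_noise`, `mean_snr`, `mean_spike_rate`,
#'   `units_per_active_channel`.
#' @export
aggregate_channel_phase <- function(metrics,
                                    phases = list(W1_4 = 1:4, W5_8 = 5:8)) {
  need <- c("channel", "week", "vpp_uv", "noise_uv", "snr", "rate_hz",
            "putative", "verified", "snr_outlier")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!metrics$week %in% unlist(phases)))
    stop("unit week outside the defined phases", call. = FALSE)
  qual <- metrics[metrics$putative & metrics$verified & !metrics$snr_outlier,
                  , drop = FALSE]
  extra <- intersect(c("group", "animal"), names(metrics))
  out <- list()
  for (ph in names(phases)) {
    sub <- qual[qual$week %in% phases[[ph]], , drop = FALSE]
    if (!nrow(sub)) next
    key <- interaction(c(sub[extra], list(sub$channel)), drop = TRUE)
    for (k in levels(key)) {
      s <- sub[key == k, , drop = FALSE]
      row <- s[1, extra, drop = FALSE]
      row$channel <- s$channel[1]
      row$phase <- ph
      row$n_units <- nrow(s)
      row$mean_vpp <- mean(s$vpp_uv)
      row$mean_noise <- mean(s$noise_uv)
      row$mean_snr <- mean(s$snr)
      row$mean_spike_rate <- if (all(is.na(s$rate_hz))) NA_real_ else
        mean(s$rate_hz, na.rm = TRUE)
      row$units_per_active_channel <- nrow(s) / length(phases[[ph]])
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out))
    return(data.frame(channel = numeric(0), phase = character(0),
                      n_units = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
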