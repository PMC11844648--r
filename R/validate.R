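# Scoring of pipeline output against simulator ground truth.

match_counts <- function(det_times, true_times, tol_s) {
  if (!length(true_times))
    return(c(matched_true = 0, matched_det = 0))
  if (!length(det_times))
    return(c(matched_true = 0, matched_det = 0))
  near <- function(a, b) {
    # distance from each element of a to its nearest element of b
    i <- findInterval(a, b)
    lo <- pmax(i, 1); hi <- pmin(i + 1, length(b))
    pmin(abs(a - b[lo]), abs(a - b[hi]))
  }
  b <- sort(true_times)
  d <- sort(det_times)
  c(matched_true = sum(near(b, d) <= tol_s),
    matched_det = sum(near(d, b) <= tol_s))
}

#' Score detected events against simulator ground truth
#'
#' Event-level sensitivity (fraction of planted unit spikes matched by a
#' detected event within `tol_ms` on the same channel) and precision
#' (fraction of detected events matching a planted spike), pooled over
#' channels.
#'
#' @param events a `spike_events` object (typically the kept set after
#'   artifact screening).
#' @param truth an `ephys_ground_truth` from [simulate_recording()].
#' @param tol_ms matching tolerance in ms (default 0.2).
#' @return A list with `sensitivity`, `precision`, `n_true`, `n_detected`.
#' @export
score_detection <- function(events, truth, tol_ms = 0.2) {
  stopifnot(inherits(truth, "ephys_ground_truth"))
  tol <- tol_ms / 1000
  mt <- 0; md <- 0; n_true <- 0
  channels <- unique(c(vapply(truth$units, `[[`, numeric(1), "channel"),
                       events$channel))
  for (ch in channels) {
    tt <- sort(unlist(lapply(truth$units, function(u)
      if (u$channel == ch) u$spike_times else numeric(0))))
    dt <- events$time_s[events$channel == ch]
    m <- match_counts(dt, tt, tol)
    mt <- mt + m["matched_true"]; md <- md + m["matched_det"]
    n_true <- n_true + length(tt)
  }
  list(sensitivity = if (n_true) unname(mt) / n_true else NA_real_,
       precision = if (nrow(events)) unname(md) / nrow(events) else NA_real_,
       n_true = n_true, n_detected = nrow(events))
}

#' Score sorted units against planted units
#'
#' The standard sorting-benchmark agreement: each planted unit is matched to
#' the sorted unit on its channel sharing the most spikes (within `tol_ms`);
#' per planted unit the score reports event sensitivity (matched / planted),
#' event precision (matched / spikes in the matched sorted unit), the
#' recovered mean-waveform Vpp against the planted template Vpp, and the
#' recovered count-based rate (`n_spikes / duration`) against the planted
#' count-based rate.
#'
#' @param units an `ime_units` list.
#' @param truth an `ephys_ground_truth`.
#' @param tol_ms matching tolerance in ms (default 0.5).
#' @return A list with `per_unit` (data.frame) and pooled `sensitivity` and
#'   `precision` (spike-weighted over planted units).
#' @export
score_sorting <- function(units, truth, tol_ms = 0.5) {
  stopifnot(inherits(units, "ime_units"), inherits(truth, "ephys_ground_truth"))
  tol <- tol_ms / 1000
  dur <- truth$duration
  rows <- list()
  for (tu in truth$units) {
    if (!length(tu$spike_times)) next
    cand <- which(vapply(units, `[[`, numeric(1), "channel") == tu$channel)
    best <- NA_integer_; best_m <- -1
    for (i in cand) {
      m <- match_counts(units[[i]]$spike_times, tu$spike_times, tol)
      if (m["matched_det"] > best_m) { best_m <- m["matched_det"]; best <- i }
    }
    if (is.na(best)) {
      rows[[length(rows) + 1]] <- data.frame(
        channel = tu$channel, n_true = length(tu$spike_times),
        n_sorted = 0, matched = 0, sensitivity = 0, precision = NA_real_,
        true_vpp = unit_vpp(tu$template), est_vpp = NA_real_,
        true_rate = length(tu$spike_times) / dur, est_rate = NA_real_)
      next
    }
    u <- units[[best]]
    m <- match_counts(u$spike_times, tu$spike_times, tol)
    rows[[length(rows) + 1]] <- data.frame(
      channel = tu$channel, n_true = length(tu$spike_times),
      n_sorted = u$n_spikes, matched = unname(m["matched_true"]),
      sensitivity = unname(m["matched_true"]) / length(tu$spike_times),
      precision = unname(m["matched_det"]) / u$n_spikes,
      true_vpp = unit_vpp(tu$template), est_vpp = unit_vpp(u$mean_waveform),
      true_rate = length(tu$spike_times) / dur,
      est_rate = u$n_spikes / dur)
  }
  per_unit <- do.call(rbind, rows)
  list(per_unit = per_unit,
       sensitivity = sum(per_unit$matched) / sum(per_unit$n_true),
       precision = sum(per_unit$precision * per_unit$n_sorted, na.rm = TRUE) /
         sum(per_unit$n_sorted[!is.na(per_unit$precision)]))
}
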