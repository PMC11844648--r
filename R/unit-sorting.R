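#' Spike-sorting configuration
#'
#' Parameters of the k-means scan (an open analogue of the proprietary
#' "K-Means Scan": silhouette-selected, seeded k-means over PCA features) and
#' of the rule-based stand-in for manual unit verification.
#'
#' @param n_pcs number of principal components used as features (default 2).
#' @param k_max largest candidate cluster count (default 5).
#' @param silhouette_floor minimum mean silhouette required to accept a
#'   multi-cluster solution (default 0.5).
#' @param seed integer seed for the k-means restarts.
#' @param verify_min_spikes minimum spike count for a verified unit
#'   (default 30).
#' @param verify_max_isi_violation maximum tolerated fraction of inter-spike
#'   intervals below `isi_threshold_ms` (default 0.05).
#' @param isi_threshold_ms refractory criterion, ms (default 1).
#' @return An object of class `sort_config`.
#' @export
sort_config <- function(n_pcs = 2, k_max = 5, silhouette_floor = 0.5,
                        seed = 1, verify_min_spikes = 30,
                        verify_max_isi_violation = 0.05,
                        isi_threshold_ms = 1) {
  stopifnot(n_pcs >= 1, k_max >= 1,
            silhouette_floor > 0, silhouette_floor < 1,
            verify_max_isi_violation >= 0, verify_max_isi_violation < 1)
  structure(list(n_pcs = as.integer(n_pcs), k_max = as.integer(k_max),
                 silhouette_floor = silhouette_floor, seed = as.integer(seed),
                 verify_min_spikes = verify_min_spikes,
                 verify_max_isi_violation = verify_max_isi_violation,
                 isi_threshold_ms = isi_threshold_ms),
            class = "sort_config")
}

#' Project waveforms onto principal components
#'
#' Centers the (peak-aligned) waveforms and projects them onto the first
#' `n_pcs` principal components; feature rows correspond 1:1 to input rows.
#'
#' @param waveforms numeric matrix, events x samples (>= 2 rows).
#' @param n_pcs number of components (clamped to the available rank).
#' @return Feature matrix, events x `n_pcs`, with the `prcomp` fit attached
#'   as attribute `pca`.
#' @export
extract_features <- function(waveforms, n_pcs = 2) {
  if (!is.matrix(waveforms) || nrow(waveforms) < 2)
    stop("need at least 2 waveforms of equal length", call. = FALSE)
  pc <- prcomp(waveforms, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  structure(pc$x[, seq_len(k), drop = FALSE], pca = pc)
}

mean_silhouette <- function(d, labels) {
  mean(cluster::silhouette(labels, dist = d)[, "sil_width"])
}

#' Silhouette-selected seeded k-means ("k-means scan")
#'
#' For `k = 2..k_max` runs seeded k-means with 10 restarts and computes the
#' mean silhouette width; the chosen `k` maximizes the silhouette provided
#' the maximum reaches `silhouette_floor`, otherwise a single cluster is
#' returned. For large event counts the silhouette is estimated on a seeded
#' subsample of at most 1500 points (labels are still assigned to all
#' points). Deterministic given the seed.
#'
#' @param features numeric feature matrix (>= 2 rows).
#' @param cfg a [sort_config()].
#' @return A list with `labels` (integer vector), `k`, and `silhouette`
#'   (named mean silhouette per candidate `k`).
#' @export
kmeans_scan <- function(features, cfg = sort_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  n_distinct <- nrow(unique(features))
  k_max <- cfg$k_max
  if (k_max > n) {
    warning("k_max exceeds the number of points; clamping")
    k_max <- n
  }
  # every candidate k needs at least one spare point for a valid partition;
  # degenerate duplicate sets clamp silently
  k_max <- min(k_max, n - 1, n_distinct)
  if (k_max < 2 || n_distinct < 2)
    return(list(labels = rep(1L, n), k = 1L, silhouette = numeric(0)))

  set.seed(derive_seed(cfg$seed, "kmeans_scan"))
  sub <- if (n > 1500) sort(sample(n, 1500)) else seq_len(n)
  d_sub <- dist(features[sub, , drop = FALSE])
  sil <- setNames(rep(NA_real_, k_max - 1), paste0("k", 2:k_max))
  fits <- vector("list", k_max - 1)
  for (k in 2:k_max) {
    fit <- suppressWarnings(kmeans(features, centers = k, nstart = 10,
                                   iter.max = 50))
    fits[[k - 1]] <- fit
    lab_sub <- fit$cluster[sub]
    sil[k - 1] <- if (length(unique(lab_sub)) < 2) -1 else
      mean_silhouette(d_sub, lab_sub)
  }
  best <- which.max(sil)
  if (sil[best] >= cfg$silhouette_floor) {
    list(labels = unname(fits[[best]]$cluster), k = as.integer(best + 1),
         silhouette = sil)
  } else {
    list(labels = rep(1L, n), k = 1L, silhouette = sil)
  }
}

#' Cluster retained spike events into candidate single units
#'
#' Sorts per channel (unit counts in this design are reported per channel):
#' waveforms are projected onto principal components and clustered with
#' [kmeans_scan()]. Channels with a single event yield a single unit.
#'
#' @param events a `spike_events` object (after artifact screening).
#' @param cfg a [sort_config()].
#' @return An object of class `ime_units`: a list of units, each with
#'   `channel`, `spike_times` (s, sorted), `waveforms`, `mean_waveform`,
#'   `n_spikes`, and `verified` (`NA` until [verify_units()]).
#' @export
sort_units <- function(events, cfg = sort_config()) {
  stopifnot(inherits(events, "spike_events"))
  wf_all <- attr(events, "waveforms")
  units <- list()
  for (ch in sort(unique(events$channel))) {
    idx <- which(events$channel == ch)
    wf <- wf_all[idx, , drop = FALSE]
    labels <- if (length(idx) < 2) rep(1L, length(idx)) else
      kmeans_scan(extract_features(wf, cfg$n_pcs), cfg)$labels
    for (lab in sort(unique(labels))) {
      sel <- idx[labels == lab]
      ord <- sel[order(events$time_s[sel])]
      units[[length(units) + 1]] <- structure(
        list(channel = ch, spike_times = events$time_s[ord],
             waveforms = wf_all[ord, , drop = FALSE],
             mean_waveform = colMeans(wf_all[ord, , drop = FALSE]),
             n_spikes = length(ord), verified = NA),
        class = "ime_unit")
    }
  }
  structure(units, class = "ime_units")
}

#' Rule-based stand-in for manual unit verification
#'
#' Replaces manual true-positive verification with explicit rules so the
#' pipeline is automatable: a unit is verified when it has at least
#' `verify_min_spikes` spikes and its fraction of inter-spike intervals
#' shorter than `isi_threshold_ms` does not exceed
#' `verify_max_isi_violation`.
#'
#' @param units an `ime_units` list from [sort_units()].
#' @param cfg a [sort_config()].
#' @return The units with their `verified` flags set.
#' @export
verify_units <- function(units, cfg = sort_config()) {
  stopifnot(inherits(units, "ime_units"))
  for (i in seq_along(units)) {
    u <- units[[i]]
    isi <- diff(u$spike_times)
    viol <- if (length(isi)) mean(isi < cfg$isi_threshold_ms / 1000) else 0
    units[[i]]$verified <- u$n_spikes >= cfg$verify_min_spikes &&
      viol <= cfg$verify_max_isi_violation
  }
  units
}

#' @export
print.ime_units <- function(x, ...) {
  cat(sprintf("<ime_units> %d units on %d channels (%s verified)\n",
              length(x),
              length(unique(vapply(x, `[[`, numeric(1), "channel"))),
              sum(vapply(x, function(u) isTRUE(u$verified), logical(1)))))
  invisible(x)
}
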