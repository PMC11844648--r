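# Shared fixture builders. Everything is generated in code under fixed seeds.

# Fabricate a spike_events object directly (for artifact-screening tests).
make_events <- function(channel, time_s, amplitude_uv, fs = 24414,
                        waveforms = NULL) {
  n <- length(channel)
  if (is.null(waveforms))
    waveforms <- matrix(rep(amplitude_uv, each = 3), nrow = n, byrow = FALSE)
  df <- data.frame(channel = channel, peak_sample = round(time_s * fs),
                   time_s = time_s, amplitude_uv = amplitude_uv)
  structure(df, waveforms = waveforms,
            window = c(pre_ms = 0.5, post_ms = 1), fs = fs,
            sigma = NULL, class = c("spike_events", "data.frame"))
}

# Small band-limited scene without artifacts: `n_units_per_channel` planted
# units per channel with the given Vpps and rates.
small_scene <- function(seed, n_channels = 2, duration = 30, vpp = c(150),
                        rates = c(8), noise_sd = 10, fs = 24414) {
  units <- list()
  for (c in seq_len(n_channels)) {
    for (k in seq_along(vpp)) {
      units[[length(units) + 1]] <- list(
        channel = c, template = spike_template(vpp[k], fs), rate_hz = rates[k])
    }
  }
  ephys_sim_config(n_channels = n_channels, duration = duration, fs = fs,
                   noise_sd = noise_sd, units = units, seed = seed)
}

# Independent brute-force AEY recount used as the oracle for yield tests:
# written against the raw table rows, without reusing package internals.
brute_force_aey <- function(df) {
  df <- aggregate(n_units ~ group + animal + week + channel, data = df, sum)
  out <- NULL
  for (g in unique(df$group)) {
    rows <- df[df$group == g, ]
    ever <- list()
    for (i in seq_len(nrow(rows))) {
      key <- paste(rows$animal[i], rows$channel[i])
      if (rows$n_units[i] > 0) ever[[key]] <- TRUE
    }
    for (w in sort(unique(rows$week))) {
      wk <- rows[rows$week == w, ]
      n_tot <- 0; n_act <- 0
      for (i in seq_len(nrow(wk))) {
        key <- paste(wk$animal[i], wk$channel[i])
        if (isTRUE(ever[[key]])) {
          n_tot <- n_tot + 1
          if (wk$n_units[i] > 0) n_act <- n_act + 1
        }
      }
      out <- rbind(out, data.frame(group = g, week = w, n_active = n_act,
                                   n_total = n_tot))
    }
  }
  out
}

# Random activity table generator for oracle-equivalence tests.
random_activity <- function(seed, n_groups = 2, n_animals = 3, n_weeks = 8,
                            n_channels = 6) {
  set.seed(seed)
  expand <- expand.grid(group = LETTERS[seq_len(n_groups)],
                        animal = seq_len(n_animals),
                        week = seq_len(n_weeks),
                        channel = seq_len(n_channels),
                        stringsAsFactors = FALSE)
  expand$n_units <- rpois(nrow(expand), 0.6)
  expand
}

# Activity table reproducing the study's weekly channel totals: per group,
# `n_animals * 16` implanted channels of which `n_never` are never active.
study_activity_table <- function(groups = c(SPPINDEX = 107, PIN = 104,
                                            TH = 104, `Free DEXSP` = 118),
                                 n_weeks = 8, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (g in names(groups)) {
    n_animals <- ceiling(groups[[g]] / 16)
    n_never <- n_animals * 16 - groups[[g]]
    grid <- expand.grid(animal = seq_len(n_animals), channel = 1:16)
    never <- seq_len(n_never)            # first channels of animal 1 silent
    for (w in seq_len(n_weeks)) {
      n_units <- rpois(nrow(grid), 1.2)
      n_units[never] <- 0
      idx <- setdiff(seq_len(nrow(grid)), never)
      # guarantee every non-excluded channel fires at least once in week 1
      if (w == 1) n_units[idx] <- pmax(n_units[idx], 1)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, animal = grid$animal, week = w, channel = grid$channel,
        n_units = n_units)
    }
  }
  do.call(rbind, rows)
}
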