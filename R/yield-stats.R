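#' Channel activity table
#'
#' Validates and normalizes the per (group, animal, week, channel) active-unit
#' counts feeding the yield statistics. If a `session` column is present,
#' biweekly sessions are collapsed to the week level by summing counts (a
#' channel is active in a week iff it is active in at least one session of
#' that week).
#'
#' @param df data.frame with columns `group`, `animal`, `week`, `channel`,
#'   `n_units` (and optionally `session`). A row with `n_units = 0` records
#'   that the channel was recorded but silent; absent animal-weeks are
#'   treated as not recorded.
#' @return A `channel_activity` data.frame collapsed to week level.
#' @export
channel_activity_table <- function(df) {
  need <- c("group", "animal", "week", "channel", "n_units")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$n_units < 0)) stop("`n_units` must be >= 0", call. = FALSE)
  if (any(!df$week %in% 1:8))
    stop("weeks must lie in 1-8", call. = FALSE)
  agg <- aggregate(n_units ~ group + animal + week + channel, data = df, sum)
  class(agg) <- c("channel_activity", "data.frame")
  agg
}

as_activity <- function(table) {
  if (!inherits(table, "channel_activity")) table <- channel_activity_table(table)
  table
}

# Channels (animal x channel) with at least one active unit in any week of
# the whole study, per group: the "ever-active" denominator rule.
ever_active_keys <- function(tab, group) {
  sub <- tab[tab$group == group, , drop = FALSE]
  tot <- aggregate(n_units ~ animal + channel, data = sub, sum)
  paste(tot$animal[tot$n_units > 0], tot$channel[tot$n_units > 0])
}

#' Weekly active electrode yield
#'
#' For each group and week, the yield is the number of active channels (those
#' with at least one active unit that week) divided by the total number of
#' channels recorded that week, excluding channels that never have any active
#' unit over the whole study.
#'
#' @param table a [channel_activity_table()] (or coercible data.frame)
#'   spanning the full study (needed for the ever-active exclusion).
#' @return A data.frame with `group`, `week`, `n_active`, `n_total`,
#'   `proportion`.
#' @export
weekly_aey <- function(table) {
  tab <- as_activity(table)
  if (!nrow(tab)) stop("empty activity table", call. = FALSE)
  out <- list()
  for (g in unique(tab$group)) {
    ever <- ever_active_keys(tab, g)
    sub <- tab[tab$group == g, , drop = FALSE]
    for (w in sort(unique(sub$week))) {
      sw <- sub[sub$week == w, , drop = FALSE]
      keys <- paste(sw$animal, sw$channel)
      in_denom <- keys %in% ever
      n_total <- sum(in_denom)
      n_active <- sum(in_denom & sw$n_units > 0)
      out[[length(out) + 1]] <- data.frame(
        group = g, week = w, n_active = n_active, n_total = n_total,
        proportion = if (n_total > 0) n_active / n_total else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phase-pooled proportion of active electrodes
#'
#' Sums the weekly active and total channel counts across all weeks of a time
#' phase, per group.
#'
#' @param table a [channel_activity_table()] (or coercible data.frame).
#' @param weeks weeks making up the phase (subset of 1-8).
#' @param phase_label optional label stored in the output.
#' @return A data.frame with `group`, `phase`, `n_active`, `n_total`,
#'   `proportion`.
#' @export
phase_proportion <- function(table, weeks, phase_label = NULL) {
  if (!length(weeks)) stop("empty week set", call. = FALSE)
  if (any(!weeks %in% 1:8)) stop("weeks must lie in 1-8", call. = FALSE)
  wk <- weekly_aey(table)
  wk <- wk[wk$week %in% weeks, , drop = FALSE]
  out <- list()
  for (g in unique(wk$group)) {
    sub <- wk[wk$group == g, , drop = FALSE]
    n_total <- sum(sub$n_total)
    n_active <- sum(sub$n_active)
    out[[length(out) + 1]] <- data.frame(
      group = g,
      phase = phase_label %||% paste0("W", min(weeks), "_", max(weeks)),
      n_active = n_active, n_total = n_total,
      proportion = if (n_total > 0) n_active / n_total else NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided two-proportion z-test
#'
#' Pooled-variance z statistic
#' `z = (p1 - p2) / sqrt(p*(1-p)*(1/n1 + 1/n2))` with `p` the pooled
#' proportion, and a two-sided p-value from the standard normal. When the
#' pooled proportion is 0 or 1 the statistic is undefined; `z = 0`, `p = 1`
#' is returned with a warning.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @return A list with `z`, `p_value`, and the two sample proportions.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is 0 or 1; z set to 0")
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}
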