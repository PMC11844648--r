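#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the package flows from one user-supplied integer seed;
#' each pipeline stage draws from a seed derived deterministically from the
#' global seed and a stage label, so stages can be re-run in isolation and
#' still reproduce the pipeline run bit for bit.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

root_mean_square <- function(x) sqrt(mean(x^2))
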