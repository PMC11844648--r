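#' Encapsulation efficiency
#'
#' `EE(%) = (total - unencapsulated) / total * 100`: the percentage of the
#' drug mass used in manufacture that ends up inside the particles.
#'
#' @param total_mg total drug used, mg (> 0).
#' @param unencapsulated_mg unencapsulated (free) drug, mg, in
#'   `[0, total_mg]`.
#' @return Encapsulation efficiency, percent.
#' @export
encapsulation_efficiency <- function(total_mg, unencapsulated_mg) {
  if (any(total_mg <= 0)) stop("`total_mg` must be > 0", call. = FALSE)
  if (any(unencapsulated_mg < 0) || any(unencapsulated_mg > total_mg))
    stop("`unencapsulated_mg` must lie in [0, total_mg]", call. = FALSE)
  (total_mg - unencapsulated_mg) / total_mg * 100
}

#' Internal-standard calibration curve
#'
#' Ordinary least-squares line of HPLC peak-area ratio (analyte / internal
#' standard) on concentration ratio, used to determine unknown analyte
#' concentrations.
#'
#' @param conc_ratio known concentration ratios (>= 2 distinct values).
#' @param area_ratio measured peak-area ratios (same length).
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `residuals`, and the input points.
#' @export
fit_calibration <- function(conc_ratio, area_ratio) {
  stopifnot(length(conc_ratio) == length(area_ratio), length(conc_ratio) >= 2)
  if (length(unique(conc_ratio)) < 2)
    stop("all concentration ratios identical; cannot fit a line", call. = FALSE)
  fit <- lm(area_ratio ~ conc_ratio)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 residuals = unname(residuals(fit)),
                 points = data.frame(conc_ratio = conc_ratio,
                                     area_ratio = area_ratio)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> area = %.6g * conc %+.6g (n = %d)\n",
              x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}

#' Invert a calibration curve
#'
#' @param curve a [fit_calibration()] result.
#' @param area_ratio measured peak-area ratio(s).
#' @return Estimated concentration ratio(s): `(a - intercept) / slope`.
#' @export
invert_calibration <- function(curve, area_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope; curve not invertible", call. = FALSE)
  (area_ratio - curve$intercept) / curve$slope
}

#' Replacement-corrected cumulative release
#'
#' Mass balance for a sample-and-replace dialysis assay: at sampling time
#' `t_i` the cumulative released mass is the mass currently in the reservoir
#' plus the mass carried away by all previous aliquots,
#' `M_cum(t_i) = C_i * V_reservoir + sum_{j<i} C_j * V_aliquot`.
#' The uncorrected (naive) estimate `C_i * V_reservoir` is also reported for
#' comparison. Monotonicity violations (possible with measurement noise) are
#' flagged, not silently fixed.
#'
#' @param series a [release_series()].
#' @param tolerance allowed excess of the released fraction over 1 before a
#'   mass-balance error is raised (default 0.05, covering measurement noise).
#' @return A data.frame with `time_h`, `conc_mg_per_ml`, `mass_cum_mg`,
#'   `fraction` (of loaded mass; `NA` if the load is unknown),
#'   `mass_naive_mg`, `fraction_naive`, `monotone_violation`.
#' @export
cumulative_release <- function(series, tolerance = 0.05) {
  stopifnot(inherits(series, "release_series"))
  v_res <- attr(series, "v_reservoir")
  v_ali <- attr(series, "v_aliquot")
  loaded <- attr(series, "loaded_mass")
  conc <- series$conc_mg_per_ml
  removed_before <- c(0, cumsum(conc * v_ali))[seq_along(conc)]
  mass_cum <- conc * v_res + removed_before
  frac <- if (is.na(loaded)) rep(NA_real_, length(conc)) else mass_cum / loaded
  if (!is.na(loaded) && any(frac > 1 + tolerance))
    stop("mass balance violated: released fraction exceeds 1 + tolerance",
         call. = FALSE)
  data.frame(time_h = series$time_h, conc_mg_per_ml = conc,
             mass_cum_mg = mass_cum, fraction = frac,
             mass_naive_mg = conc * v_res,
             fraction_naive = if (is.na(loaded)) NA_real_ else
               conc * v_res / loaded,
             monotone_violation = c(FALSE, diff(mass_cum) < 0))
}
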