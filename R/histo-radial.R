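#' Concentric-ring bin labels around an implant hole
#'
#' Labels every pixel by its distance bin from the outer edge of the implant
#' hole. Distance is the Euclidean distance (exact distance transform) from
#' the pixel center to the nearest hole pixel, in microns; bins are half-open
#' `[k*w, (k+1)*w)` intervals of width `w` starting at the hole edge, so a
#' pixel at exactly 50 um falls in bin 1. Supports irregular holes; for a
#' circular hole the distance reduces to `r - r0`.
#'
#' @param hole_mask logical matrix, `TRUE` inside the (single, connected,
#'   non-empty) implant hole.
#' @param um_per_pixel microns per pixel.
#' @param bin_width_um ring width in um (default 50).
#' @param max_distance_um outer limit of the last bin in um (default 650);
#'   pixels at or beyond it are labeled "beyond".
#' @return An object of class `radial_bins`: an integer matrix with bin
#'   indices `0..n_bins-1`, `-1` for hole pixels and `-2` for pixels beyond
#'   `max_distance_um`, with attributes `edges_um` (bin edges),
#'   `um_per_pixel`, and `distance_um` (the distance map).
#' @export
radial_bins <- function(hole_mask, um_per_pixel, bin_width_um = 50,
                        max_distance_um = 650) {
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  stop_if_not_scalar_pos(bin_width_um, "bin_width_um")
  if (!any(hole_mask)) stop("empty hole mask", call. = FALSE)
  lab <- EBImage::bwlabel(hole_mask * 1)
  if (max(lab) > 1)
    stop("hole mask must be a single connected region", call. = FALSE)
  d_px <- EBImage::distmap(1 - hole_mask * 1, metric = "euclidean")
  d_um <- as.matrix(EBImage::imageData(d_px)) * um_per_pixel
  bins <- matrix(-1L, nrow(hole_mask), ncol(hole_mask))
  outside <- !hole_mask
  bins[outside] <- as.integer(floor(d_um[outside] / bin_width_um))
  n_bins <- floor(max_distance_um / bin_width_um)
  bins[outside & d_um >= n_bins * bin_width_um] <- -2L
  structure(bins, edges_um = seq(0, n_bins * bin_width_um, by = bin_width_um),
            um_per_pixel = um_per_pixel, distance_um = d_um,
            class = "radial_bins")
}

bin_frame <- function(bins) {
  edges <- attr(bins, "edges_um")
  data.frame(bin = seq_len(length(edges) - 1) - 1L,
             inner_um = edges[-length(edges)], outer_um = edges[-1])
}

#' Mean fluorescence intensity per concentric bin
#'
#' Averages pixel intensities within each ring, excluding masked artifact
#' pixels; rings whose unmasked pixel count is zero are reported as missing.
#'
#' @param image numeric intensity matrix (counts).
#' @param bins a [radial_bins()] label matrix of the same shape.
#' @param artifact_mask optional logical matrix; `TRUE` pixels are excluded.
#' @return A `radial_profile` data.frame: `bin`, `inner_um`, `outer_um`,
#'   `n_pixels`, `mean_intensity`.
#' @export
bin_intensity <- function(image, bins, artifact_mask = NULL) {
  stopifnot(inherits(bins, "radial_bins"))
  if (!all(dim(image) == dim(bins)))
    stop("image and bin labels must have the same shape", call. = FALSE)
  use <- bins >= 0
  if (!is.null(artifact_mask)) {
    if (!all(dim(artifact_mask) == dim(bins)))
      stop("artifact mask shape mismatch", call. = FALSE)
    use <- use & !artifact_mask
  }
  prof <- bin_frame(bins)
  b <- bins[use]
  v <- image[use]
  cnt <- tabulate(b + 1L, nbins = nrow(prof))
  sums <- vapply(seq_len(nrow(prof)) - 1L,
                 function(k) sum(v[b == k]), numeric(1))
  prof$n_pixels <- cnt
  prof$mean_intensity <- ifelse(cnt > 0, sums / cnt, NA_real_)
  if (all(cnt == 0)) stop("all bins are empty", call. = FALSE)
  structure(prof, class = c("radial_profile", "data.frame"))
}

#' Normalize a radial intensity profile to the background bin
#'
#' Normalizes each ring's mean intensity to the background intensity in the
#' 600-650 um bin with a marker-specific factor `f`:
#' `N_k = I_k / I_bg - (1 - f)`, the unique affine map that preserves ratio
#' scaling and sends the background bin to `f` exactly. `f = 1` (markers
#' present in healthy parenchyma, e.g. astrocytes/GFAP) gives the plain
#' ratio; `f = 0` (markers absent from healthy parenchyma, e.g. CD68, IgG)
#' gives the relative excess over background.
#'
#' @param profile a `radial_profile` from [bin_intensity()] (or any
#'   data.frame with `inner_um` and a value column).
#' @param f normalization factor, 0 or 1 (any value in `[0, 1]` accepted).
#' @param background_um inner edge of the background bin (default 600).
#' @param value_col column to normalize (default `"mean_intensity"`).
#' @return The profile with a `normalized` column and attribute `f`.
#' @export
normalize_profile <- function(profile, f, background_um = 600,
                              value_col = "mean_intensity") {
  stopifnot(f >= 0, f <= 1)
  bg_row <- which(profile$inner_um == background_um)
  if (!length(bg_row))
    stop("no background bin starting at ", background_um, " um", call. = FALSE)
  bg <- profile[[value_col]][bg_row]
  if (is.na(bg) || bg <= 0)
    stop("background-bin intensity must be > 0", call. = FALSE)
  profile$normalized <- profile[[value_col]] / bg - (1 - f)
  attr(profile, "f") <- f
  profile
}

#' Marker-specific normalization factor
#'
#' @param marker one of `"GFAP"`, `"NeuN"` (factor 1: present in healthy
#'   parenchyma) or `"CD68"`, `"IgG"` (factor 0: absent from healthy
#'   parenchyma).
#' @return 0 or 1.
#' @export
marker_factor <- function(marker) {
  switch(toupper(marker),
         GFAP = 1, NEUN = 1, CD68 = 0, IGG = 0,
         stop("unknown marker: ", marker, call. = FALSE))
}

#' Neuron density per concentric bin
#'
#' Counts segmented-neuron centroids per ring (a centroid belongs to the bin
#' containing its pixel; cells straddling borders are not split), divides by
#' the unmasked ring area in mm^2, and normalizes to the density in the
#' background bin.
#'
#' @param centroids data.frame with `x_px`, `y_px` centroid coordinates
#'   (from external segmentation).
#' @param bins a [radial_bins()] label matrix.
#' @param um_per_pixel microns per pixel.
#' @param artifact_mask optional logical exclusion mask; centroids on masked
#'   pixels are dropped and masked pixels do not count toward ring areas.
#' @param background_um inner edge of the background bin (default 600).
#' @return A `radial_profile` data.frame: `bin`, `inner_um`, `outer_um`,
#'   `n_neurons`, `area_mm2`, `density_per_mm2`, `normalized`. If the
#'   background density is zero, `normalized` is `NA` with a warning.
#' @export
neuron_density <- function(centroids, bins, um_per_pixel,
                           artifact_mask = NULL, background_um = 600) {
  stopifnot(inherits(bins, "radial_bins"))
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  use <- bins >= 0
  if (!is.null(artifact_mask)) use <- use & !artifact_mask
  prof <- bin_frame(bins)
  cnt_px <- tabulate(bins[use] + 1L, nbins = nrow(prof))
  prof$area_mm2 <- cnt_px * um_per_pixel^2 / 1e6

  n_neu <- rep(0L, nrow(prof))
  if (nrow(centroids)) {
    i <- pmin(pmax(round(centroids$y_px), 1), nrow(bins))
    j <- pmin(pmax(round(centroids$x_px), 1), ncol(bins))
    idx <- cbind(i, j)
    ok <- use[idx]
    b <- bins[idx][ok]
    n_neu <- tabulate(b + 1L, nbins = nrow(prof))
  }
  prof$n_neurons <- n_neu
  prof$density_per_mm2 <- ifelse(prof$area_mm2 > 0,
                                 n_neu / prof$area_mm2, NA_real_)
  bg <- prof$density_per_mm2[prof$inner_um == background_um]
  if (!length(bg) || is.na(bg) || bg <= 0) {
    warning("background-bin density is zero or undefined; ",
            "returning unnormalized densities")
    prof$normalized <- NA_real_
  } else {
    prof$normalized <- prof$density_per_mm2 / bg
  }
  structure(prof, class = c("radial_profile", "data.frame"))
}
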