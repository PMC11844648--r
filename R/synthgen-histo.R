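#' Configuration for the implant-site histology simulator
#'
#' Describes a single-channel 16-bit fluorescence image containing a circular
#' implant hole, a radially structured marker-intensity field, an optional
#' inhomogeneous-Poisson neuron point process, and optional rectangular
#' artifact regions.
#'
#' @param shape image size in pixels, `c(rows, cols)`.
#' @param um_per_pixel microns per pixel (> 0).
#' @param hole list with `center_px` (`c(x, y)`, pixel coordinates) and
#'   `radius_um`; the hole must lie fully inside the image.
#' @param marker_profile function mapping distance from the hole edge (um) to
#'   mean intensity (counts >= 0). Default: flat 1000 counts.
#' @param neuron_density_profile `NULL`, or a function mapping distance (um)
#'   to neuron density (neurons per mm^2).
#' @param artifact_regions list of rectangles, each
#'   `list(x0=, x1=, y0=, y1=)` in pixel coordinates, masked out downstream.
#' @param hole_fill intensity used inside the hole (default 0).
#' @param noise_sd Gaussian intensity noise SD in counts (default 0).
#' @param seed integer seed.
#' @return An object of class `histo_sim_config`.
#' @export
histo_sim_config <- function(shape = c(900, 900), um_per_pixel = 2,
                             hole = list(center_px = c(450, 450),
                                         radius_um = 200),
                             marker_profile = function(d) rep(1000, length(d)),
                             neuron_density_profile = NULL,
                             artifact_regions = list(), hole_fill = 0,
                             noise_sd = 0, seed = 1) {
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  stopifnot(length(shape) == 2, all(shape >= 3))
  r_px <- hole$radius_um / um_per_pixel
  cx <- hole$center_px[1]; cy <- hole$center_px[2]
  if (cx - r_px < 1 || cx + r_px > shape[2] ||
      cy - r_px < 1 || cy + r_px > shape[1])
    stop("implant hole must lie fully inside the image", call. = FALSE)
  d_chk <- seq(0, 1000, by = 50)
  if (any(marker_profile(d_chk) < 0))
    stop("`marker_profile` must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), um_per_pixel = um_per_pixel,
                 hole = hole, marker_profile = marker_profile,
                 neuron_density_profile = neuron_density_profile,
                 artifact_regions = artifact_regions, hole_fill = hole_fill,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "histo_sim_config")
}

#' Simulate an implant-site fluorescence image with ground truth
#'
#' Pixel mean intensity at distance `d` from the hole edge equals
#' `marker_profile(d)` before noise (distance computed analytically as
#' `r - r0` for the circular hole, independent of the analysis path); neuron
#' centroids are drawn from an inhomogeneous Poisson process with intensity
#' `neuron_density_profile(d)` by thinning; intensities are rounded and
#' clipped to the 16-bit range.
#'
#' @param config a [histo_sim_config()].
#' @return A list with `image` (numeric matrix, counts), `hole_mask` and
#'   `artifact_mask` (logical matrices), and `centroids`
#'   (data.frame `x_px`, `y_px`; empty if no density profile).
#' @export
simulate_histology <- function(config) {
  stopifnot(inherits(config, "histo_sim_config"))
  set.seed(derive_seed(config$seed, "histo"))
  nr <- config$shape[1]; nc <- config$shape[2]
  upp <- config$um_per_pixel
  cx <- config$hole$center_px[1]; cy <- config$hole$center_px[2]
  r0_px <- config$hole$radius_um / upp

  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  r_px <- sqrt((xs - cx)^2 + (ys - cy)^2)
  hole_mask <- r_px <= r0_px
  d_um <- pmax(0, r_px - r0_px) * upp

  img <- matrix(config$marker_profile(as.vector(d_um)), nr, nc)
  img[hole_mask] <- config$hole_fill
  if (config$noise_sd > 0)
    img <- img + rnorm(length(img), 0, config$noise_sd)
  img <- pmin(pmax(round(img), 0), 65535)

  artifact_mask <- matrix(FALSE, nr, nc)
  for (a in config$artifact_regions)
    artifact_mask[max(1, a$y0):min(nr, a$y1), max(1, a$x0):min(nc, a$x1)] <- TRUE

  centroids <- data.frame(x_px = numeric(0), y_px = numeric(0))
  if (!is.null(config$neuron_density_profile)) {
    lam <- config$neuron_density_profile
    d_grid <- seq(0, sqrt(nr^2 + nc^2) * upp, length.out = 2048)
    lam_max <- max(lam(d_grid))
    if (lam_max > 0) {
      area_mm2 <- nr * nc * upp^2 / 1e6
      n <- rpois(1, lam_max * area_mm2)
      if (n > 0) {
        x <- runif(n, 0.5, nc + 0.5)
        y <- runif(n, 0.5, nr + 0.5)
        r <- sqrt((x - cx)^2 + (y - cy)^2)
        d <- pmax(0, r - r0_px) * upp
        keep <- r > r0_px & runif(n) < lam(d) / lam_max
        centroids <- data.frame(x_px = x[keep], y_px = y[keep])
      }
    }
  }
  list(image = img, hole_mask = hole_mask, artifact_mask = artifact_mask,
       centroids = centroids)
}
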