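#' Configure a synthetic lesion image
#'
#' Describes a radially symmetric stand-in for a stained lesion section: a
#' core disk, an annular border (the astroglial border around a lesion core)
#' and background, each at a constant intensity, plus optional Gaussian noise.
#'
#' @param size image size in pixels, `c(rows, cols)` (a scalar is square).
#' @param center lesion center `c(x, y)` in pixel units (x = column,
#'   y = row); defaults to the image center.
#' @param core_radius radius of the core disk in pixels.
#' @param border_width width of the border annulus in pixels.
#' @param core_intensity,border_intensity,background_intensity intensities in
#'   arbitrary units, all >= 0.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed for the noise.
#' @return Object of class `lesion_image_config`.
#' @export
lesion_image_config <- function(size = 256,
                                center = NULL,
                                core_radius = 40,
                                border_width = 12,
                                core_intensity = 50,
                                border_intensity = 200,
                                background_intensity = 20,
                                noise_sd = 0,
                                seed = 1L) {
  size <- rep_len(as.integer(size), 2L)
  if (is.null(center)) center <- (size[c(2, 1)] + 1) / 2
  stopifnot(core_radius > 0, core_radius < min(size) / 2,
            border_width >= 0, noise_sd >= 0,
            core_intensity >= 0, border_intensity >= 0,
            background_intensity >= 0)
  structure(list(size = size, center = center,
                 core_radius = core_radius, border_width = border_width,
                 core_intensity = core_intensity,
                 border_intensity = border_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "lesion_image_config")
}

#' Generate a synthetic lesion image
#'
#' Renders the configured core/border/background geometry (pixel-center
#' coordinates, Euclidean distance from the lesion center) and adds Gaussian
#' noise; negative noisy intensities are clamped to zero so the image stays a
#' valid non-negative intensity array.
#'
#' @param config a [lesion_image_config()].
#' @return List with `image` (numeric matrix, rows x cols), `config`, and
#'   `truth` (list with `border_radii = c(inner, outer)` and `center`).
#' @export
generate_lesion_image <- function(config) {
  stopifnot(inherits(config, "lesion_image_config"))
  nr <- config$size[1]; nc <- config$size[2]
  x <- matrix(rep(seq_len(nc), each = nr), nr)
  y <- matrix(rep(seq_len(nr), times = nc), nr)
  d <- sqrt((x - config$center[1])^2 + (y - config$center[2])^2)
  r0 <- config$core_radius
  r1 <- r0 + config$border_width
  img <- matrix(config$background_intensity, nr, nc)
  img[d < r1] <- config$border_intensity
  img[d < r0] <- config$core_intensity
  if (config$noise_sd > 0) {
    set.seed(stream_seed(config$seed, "lesion_noise"))
    img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr)
    img[img < 0] <- 0
  }
  list(image = img, config = config,
       truth = list(border_radii = c(r0, r1), center = config$center))
}
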