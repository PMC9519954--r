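#' Radial intensity profile
#'
#' Mean staining intensity as a function of Euclidean distance from a center
#' point (pixel-center coordinates). Pixels are binned into half-open annuli
#' `[r, r + bin_width)`; empty annuli are recorded as `NA`, not zero. The
#' profile's area under the curve is its trapezoidal integral (NA bins
#' bridged linearly).
#'
#' @param image 2-D non-negative numeric matrix (rows = y, cols = x).
#' @param center `c(x, y)` center in pixel units; must lie inside the image.
#' @param bin_width annulus width in pixels.
#' @param max_radius outer radius (> 0); defaults to the largest distance of
#'   any pixel from the center.
#' @return Object of class `radial_profile`: data.frame with `r` (bin
#'   centers), `mean_intensity`, `n_pixels`, plus an `auc` attribute.
#' @export
radial_profile <- function(image, center, bin_width = 5, max_radius = NULL) {
  image <- as.matrix(image)
  stopifnot(length(center) == 2)
  if (center[1] < 1 || center[1] > ncol(image) ||
      center[2] < 1 || center[2] > nrow(image))
    stop("center must lie inside the image")
  nr <- nrow(image); nc <- ncol(image)
  x <- rep(seq_len(nc), each = nr)
  y <- rep(seq_len(nr), times = nc)
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  if (is.null(max_radius)) max_radius <- max(d)
  if (max_radius <= 0) stop("max_radius must be positive")

  breaks <- seq(0, max_radius + bin_width, by = bin_width)
  inside <- d < breaks[length(breaks)]
  bin <- findInterval(d[inside], breaks, rightmost.closed = FALSE)
  sums <- rowsum_vec(as.vector(image)[inside], bin, length(breaks) - 1)
  npx <- rowsum_vec(rep(1, sum(inside)), bin, length(breaks) - 1)
  meanint <- ifelse(npx > 0, sums / npx, NA_real_)

  prof <- data.frame(r = breaks[-length(breaks)] + bin_width / 2,
                     mean_intensity = meanint,
                     n_pixels = as.integer(npx))
  class(prof) <- c("radial_profile", "data.frame")
  attr(prof, "auc") <- profile_auc(prof)
  prof
}

#' Line intensity profile
#'
#' Mean intensity along one image axis, averaged across a band of the
#' perpendicular axis (the plot-profile quantification used for spinal cord
#' sections).
#'
#' @param image 2-D numeric matrix.
#' @param axis `"x"` (profile along columns, averaging rows) or `"y"`.
#' @param band integer range of rows (for `axis = "x"`) or columns (for
#'   `axis = "y"`) to average over; default the full extent.
#' @return Data.frame with `pos` (pixel position along the axis) and
#'   `mean_intensity`.
#' @export
line_profile <- function(image, axis = c("x", "y"), band = NULL) {
  image <- as.matrix(image)
  axis <- match.arg(axis)
  n_perp <- if (axis == "x") nrow(image) else ncol(image)
  if (is.null(band)) band <- seq_len(n_perp)
  if (length(band) == 0 || any(band < 1) || any(band > n_perp))
    stop("band must be a non-empty range within the image")
  vals <- if (axis == "x") colMeans(image[band, , drop = FALSE])
          else rowMeans(image[, band, drop = FALSE])
  data.frame(pos = seq_along(vals), mean_intensity = vals)
}

#' Area under an intensity profile
#'
#' Trapezoidal integral of a profile over a stated range. Missing bins are
#' bridged linearly (and a message says how many).
#'
#' @param profile a [radial_profile()], [line_profile()] result, or any
#'   data.frame whose first column is position and second is intensity.
#' @param range optional `c(lo, hi)` position range; default full profile.
#' @return Numeric scalar (intensity x distance units).
#' @export
profile_auc <- function(profile, range = NULL) {
  pos <- profile[[1]]; val <- profile[[2]]
  if (!is.null(range)) {
    if (range[1] < min(pos) || range[2] > max(pos))
      stop("range outside profile")
    keep <- pos >= range[1] & pos <= range[2]
    pos <- pos[keep]; val <- val[keep]
  }
  if (length(pos) < 2) stop("need at least 2 bins in range")
  if (anyNA(val)) {
    n_missing <- sum(is.na(val))
    ok <- !is.na(val)
    if (sum(ok) < 2) stop("too few non-missing bins")
    val <- stats::approx(pos[ok], val[ok], xout = pos, rule = 2)$y
    message(sprintf("profile_auc: bridged %d missing bins", n_missing))
  }
  sum(diff(pos) * (utils::head(val, -1) + utils::tail(val, -1)) / 2)
}

#' Two-channel colocalization (RG2B-style)
#'
#' Pixel-wise min-combine colocalization: where both channels exceed their
#' thresholds, the colocalized intensity is `min(a, b)`, elsewhere 0. The
#' summary fraction is colocalized pixels over channel-A-positive pixels.
#'
#' @param channel_a,channel_b same-shape numeric matrices.
#' @param threshold_a,threshold_b strict intensity thresholds (default 0).
#' @return List with `mask` (logical matrix), `intensity` (numeric matrix)
#'   and `fraction` in `[0, 1]`.
#' @export
colocalize_rg2b <- function(channel_a, channel_b,
                            threshold_a = 0, threshold_b = 0) {
  a <- as.matrix(channel_a); b <- as.matrix(channel_b)
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  pos_a <- a > threshold_a
  mask <- pos_a & (b > threshold_b)
  inten <- matrix(0, nrow(a), ncol(a))
  inten[mask] <- pmin(a[mask], b[mask])
  fraction <- if (sum(pos_a) == 0) 0 else sum(mask) / sum(pos_a)
  list(mask = mask, intensity = inten, fraction = fraction)
}

#' Read / write single-channel intensity images
#'
#' 16-bit single-channel TIFF (and PNG via the png package) support for the
#' image module. Intensities are stored scaled to the 16-bit range; `scale`
#' maps arbitrary units to `[0, 1]` on write and back on read.
#'
#' @param path file path (`.tif`/`.tiff` or `.png`).
#' @param scale full-scale intensity in arbitrary units corresponding to the
#'   maximum representable pixel value (default 2^16 - 1, i.e. raw 16-bit
#'   levels).
#' @return `read_image` returns a numeric matrix in arbitrary units.
#' @export
read_image <- function(path, scale = 65535) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("png package required for PNG images")
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]   # first channel
  img * scale
}

#' @rdname read_image
#' @param image numeric matrix in arbitrary units; values above `scale` are
#'   clipped.
#' @export
write_image <- function(image, path, scale = 65535) {
  img <- pmin(pmax(as.matrix(image) / scale, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("png package required for PNG images")
      png::writePNG(img, path)
    },
    stop("unsupported image format: .", ext))
  invisible(path)
}
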