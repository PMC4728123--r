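#' Gaussian-smooth an 8-bit image
#'
#' Standard noise-removal preprocessing before profile extraction: a
#' Gaussian blur of `sigma_px` pixels (default 0.6), re-quantized to the
#' 0-255 range. `sigma_px = 0` returns the input unchanged.
#'
#' @param image numeric/integer matrix, values 0-255.
#' @param sigma_px Gaussian sigma in pixels.
#' @return Integer matrix, 0-255.
#' @export
gaussian_smooth <- function(image, sigma_px = 0.6) {
  stop_if_not_scalar_num(sigma_px, "sigma_px", nonneg = TRUE)
  image <- as.matrix(image)
  if (sigma_px == 0) return(quantize_8bit(image))
  quantize_8bit(EBImage::gblur(image, sigma = sigma_px))
}

#' Sample an intensity profile along a line
#'
#' Intensities at `n_samples` evenly spaced points along the segment from
#' `p0` to `p1`, by bilinear interpolation, rounded to the 8-bit scale.
#' Coordinates are continuous 0-based pixel positions `(x, y)` with x
#' along columns and pixel centres at integer coordinates.
#'
#' @param image numeric matrix, 0-255.
#' @param p0,p1 length-2 numeric `(x, y)` endpoints; must differ and lie
#'   within the image.
#' @param n_samples number of samples (>= 2).
#' @return Integer vector of length `n_samples`.
#' @export
extract_profile <- function(image, p0, p1, n_samples = 50L) {
  image <- as.matrix(image)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("'n_samples' must be >= 2", call. = FALSE)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (isTRUE(all.equal(p0, p1)))
    stop("degenerate line: endpoints coincide", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > nc - 1 || p[2] < 0 || p[2] > nr - 1)
      stop("line endpoint outside image", call. = FALSE)
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  v <- bilinear_sample(image, xs, ys)
  as.integer(pmin(255, pmax(0, round(v))))
}

bilinear_sample <- function(image, xs, ys) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(xs), 0), nc - 1L)
  y0 <- pmin(pmax(floor(ys), 0), nr - 1L)
  x1 <- pmin(x0 + 1L, nc - 1L)
  y1 <- pmin(y0 + 1L, nr - 1L)
  fx <- xs - x0
  fy <- ys - y0
  v00 <- image[cbind(y0 + 1L, x0 + 1L)]
  v01 <- image[cbind(y0 + 1L, x1 + 1L)]
  v10 <- image[cbind(y1 + 1L, x0 + 1L)]
  v11 <- image[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
}

#' Reflection-regression colocalization index
#'
#' Quantifies the similarity of two intensity profiles sampled at the same
#' coordinates. Each sample pair `(a_k, b_k)` is plotted as a point; points
#' above the identity line (`b_k > a_k`) are reflected across `y = x`,
#' which preserves each point's distance from the identity line and folds
#' the cloud into the half-plane `y <= x`. The index is the magnitude of
#' the slope of the least-squares regression line through the origin,
#' `sum(x*y) / sum(x^2)`. It lies in `[0, 1]`: identical non-constant
#' profiles give exactly 1, and larger values mean stronger colocalization.
#'
#' The through-origin fit (rather than a free-intercept line) is what keeps
#' the index bounded in `[0, 1]` and makes 1 attainable only by identical
#' profiles; a free-intercept fit would score perfectly anti-correlated
#' profiles as 1.
#'
#' @param channel_a,channel_b equal-length numeric vectors of 8-bit
#'   intensities (0-255).
#' @return An object of class `"coloc_index"`: list with `slope` and
#'   `n_points`.
#' @examples
#' colocalization_index(c(10, 20), c(10, 10))$slope  # 0.6
#' @export
colocalization_index <- function(channel_a, channel_b) {
  a <- as.numeric(channel_a); b <- as.numeric(channel_b)
  if (length(a) != length(b)) stop("profile lengths differ", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(a < 0 | a > 255 | b < 0 | b > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  # reflect points with b > a across y = x
  x <- pmax(a, b)
  y <- pmin(a, b)
  sxx <- sum(x * x)
  if (sxx == 0)
    stop("all-zero profiles: slope undefined", call. = FALSE)
  structure(list(slope = abs(sum(x * y) / sxx), n_points = length(a)),
            class = "coloc_index")
}

#' @export
print.coloc_index <- function(x, ...) {
  cat(sprintf("colocalization index %.4f (n = %d points)\n",
              x$slope, x$n_points))
  invisible(x)
}

#' Colocalization indices for a set of lines over two images
#'
#' Convenience wrapper: optionally smooths both channels, extracts paired
#' profiles along each line and computes the index per line.
#'
#' @param image_a,image_b 8-bit matrices of the two channels.
#' @param lines data frame with columns `x0, y0, x1, y1` and optionally
#'   `n_samples` (default 50).
#' @param smooth_sigma Gaussian sigma applied to both channels first
#'   (0 = none).
#' @return Data frame with one row per line: endpoints, `n_samples`,
#'   `slope`.
#' @export
colocalization_profile_set <- function(image_a, image_b, lines,
                                       smooth_sigma = 0.6) {
  if (smooth_sigma > 0) {
    image_a <- gaussian_smooth(image_a, smooth_sigma)
    image_b <- gaussian_smooth(image_b, smooth_sigma)
  }
  ns <- lines$n_samples %||% rep(50L, nrow(lines))
  slopes <- vapply(seq_len(nrow(lines)), function(i) {
    p0 <- c(lines$x0[i], lines$y0[i])
    p1 <- c(lines$x1[i], lines$y1[i])
    pa <- extract_profile(image_a, p0, p1, ns[i])
    pb <- extract_profile(image_b, p0, p1, ns[i])
    colocalization_index(pa, pb)$slope
  }, numeric(1))
  cbind(lines[, c("x0", "y0", "x1", "y1")],
        data.frame(n_samples = ns, slope = slopes))
}
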