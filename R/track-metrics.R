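#' Filter trajectories by duration
#'
#' Retains only tracks whose frame count lies in
#' `[min_frames, max_frames]`, both inclusive. With the defaults (5 and 20
#' frames at 10 fps, i.e. 0.5-2 s) this reproduces the standard sptPALM
#' selection that discards tracks too short to fit an MSD line and too long
#' to be single fluorophores. Order is preserved.
#'
#' @param tracks list of [trajectory()] objects.
#' @param min_frames,max_frames inclusive bounds; `min_frames >= 2`.
#' @return The retained sublist.
#' @export
filter_by_duration <- function(tracks, min_frames = 5L, max_frames = 20L) {
  if (min_frames < 2L) stop("'min_frames' must be >= 2", call. = FALSE)
  if (max_frames < min_frames)
    stop("'max_frames' must be >= 'min_frames'", call. = FALSE)
  keep <- vapply(tracks, function(tr) {
    n <- n_frames(tr)
    n >= min_frames && n <= max_frames
  }, logical(1))
  tracks[keep]
}

#' Mean squared displacement of one trajectory
#'
#' For each lag `tau = n*dt`, `n = 1..N-1`, averages the squared
#' displacement over all `N - n` overlapping position pairs separated by
#' `n` frames:
#' \deqn{MSD(n\Delta t) = \frac{1}{N-n}\sum_{i=1}^{N-n}
#'   (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2.}
#'
#' @param traj a [trajectory()].
#' @return An object of class `"msd_curve"`: list with `lags` (seconds),
#'   `values` (um^2) and `pair_counts` (`N - n` per lag).
#' @examples
#' tr <- trajectory(cbind(0:2, 0), dt = 0.1)
#' compute_msd(tr)$values  # 1, 4
#' @export
compute_msd <- function(traj) {
  pos <- traj$positions
  N <- nrow(pos)
  if (N < 2L) stop("need at least 2 frames", call. = FALSE)
  ns <- seq_len(N - 1L)
  values <- vapply(ns, function(n) {
    d <- pos[(1L + n):N, , drop = FALSE] - pos[1L:(N - n), , drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1))
  structure(list(lags = ns * traj$dt, values = values,
                 pair_counts = N - ns),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve: %d lags, dt = %g s>\n", length(x$lags),
              x$lags[1]))
  print(data.frame(lag_s = x$lags, msd_um2 = x$values,
                   n_pairs = x$pair_counts))
  invisible(x)
}

#' Diffusion coefficient from the short-lag MSD slope
#'
#' Fits an ordinary least-squares line (with free intercept) to the first
#' `n_lags` points of the MSD curve and returns one-fourth of its slope,
#' the 2D diffusion coefficient implied by `MSD(tau) = 4 D tau`. The free
#' intercept absorbs the constant offset that localization noise adds to
#' every lag. On noisy input the fitted slope, and hence D, can be
#' negative; the value is reported as computed.
#'
#' @param msd an `"msd_curve"`.
#' @param n_lags number of initial lags to fit (default 4).
#' @return Diffusion coefficient in um^2/s.
#' @export
estimate_diffusion_coefficient <- function(msd, n_lags = 4L) {
  if (length(msd$lags) < n_lags)
    stop(sprintf("need at least %d MSD lags (track too short)", n_lags),
         call. = FALSE)
  x <- msd$lags[seq_len(n_lags)]
  y <- msd$values[seq_len(n_lags)]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  slope / 4
}

#' Radius of confinement: exact minimum enclosing circle
#'
#' The radius of the smallest circle that encloses every point of the
#' track, computed exactly with Welzl's move-to-front algorithm (the point
#' order is internally randomized under a fixed seed; the minimum enclosing
#' circle is unique, so the result is deterministic).
#'
#' @param traj a [trajectory()], or an n x 2 numeric matrix of points.
#' @return The radius in um. Use `attr(, "center")` for the circle centre.
#' @examples
#' radius_of_confinement(rbind(c(0, 0), c(1, 0), c(0, 1)))  # sqrt(2)/2
#' @export
radius_of_confinement <- function(traj) {
  pts <- if (inherits(traj, "trajectory")) traj$positions else as.matrix(traj)
  if (nrow(pts) < 1L) stop("need at least one point", call. = FALSE)
  circ <- min_enclosing_circle(pts)
  structure(circ$radius, center = circ$center)
}

# ---- Welzl minimum enclosing circle ------------------------------------
# Move-to-front formulation; exact for point sets in any position,
# including collinear and duplicated points.

min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1L, ], radius = 0))
  ord <- with_seed(0L, sample.int(n))
  pts <- pts[ord, , drop = FALSE]
  circ <- NULL
  for (i in seq_len(n)) {
    p <- pts[i, ]
    if (is.null(circ) || !circle_contains(circ, p))
      circ <- mec_one_point(pts[seq_len(i), , drop = FALSE], p)
  }
  circ
}

mec_one_point <- function(pts, p) {
  circ <- list(center = p, radius = 0)
  for (j in seq_len(nrow(pts))) {
    q <- pts[j, ]
    if (!circle_contains(circ, q)) {
      circ <- if (circ$radius == 0) circle_diameter(p, q)
              else mec_two_points(pts[seq_len(j), , drop = FALSE], p, q)
    }
  }
  circ
}

mec_two_points <- function(pts, p, q) {
  circ <- circle_diameter(p, q)
  left <- NULL; right <- NULL
  pq <- q - p
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, ]
    if (circle_contains(circ, r)) next
    cr <- cross2(pq, r - p)
    cc <- circumcircle(p, q, r)
    if (is.null(cc)) next
    d <- cross2(pq, cc$center - p)
    if (cr > 0 && (is.null(left) || d > cross2(pq, left$center - p)))
      left <- cc
    else if (cr < 0 && (is.null(right) || d < cross2(pq, right$center - p)))
      right <- cc
  }
  if (is.null(left) && is.null(right)) circ
  else if (is.null(left)) right
  else if (is.null(right)) left
  else if (left$radius <= right$radius) left else right
}

circle_contains <- function(circ, p, eps = 1e-12) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + eps) + eps
}

circle_diameter <- function(p, q) {
  center <- (p + q) / 2
  list(center = center, radius = sqrt(sum((p - center)^2)))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
            c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(NULL)  # collinear
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
         sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
         sum(c^2) * (b[1] - a[1])) / d
  center <- c(ux, uy)
  list(center = center,
       radius = max(sqrt(sum((a - center)^2)), sqrt(sum((b - center)^2)),
                    sqrt(sum((c - center)^2))))
}

#' Three-way mobility classification
#'
#' A track is immobile when its radius of confinement is smaller than one
#' pixel (`r_conf < immobile_radius`, strict); otherwise confined when its
#' diffusion coefficient is below `confined_D` (strict; a negative fitted D
#' is clamped to 0 for this comparison only); otherwise freely diffusive.
#'
#' @param D diffusion coefficient, um^2/s (may be negative on noisy fits).
#' @param r_conf radius of confinement, um.
#' @param immobile_radius pixel-size threshold on r_conf, um (default
#'   0.166).
#' @param confined_D diffusion threshold, um^2/s (default 0.2).
#' @return One of `"immobile"`, `"confined"`, `"free"`.
#' @export
classify_mobility <- function(D, r_conf, immobile_radius = 0.166,
                              confined_D = 0.2) {
  stop_if_not_scalar_num(immobile_radius, "immobile_radius", positive = TRUE)
  stop_if_not_scalar_num(confined_D, "confined_D", positive = TRUE)
  if (r_conf < immobile_radius) return("immobile")
  if (max(D, 0) < confined_D) return("confined")
  "free"
}
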