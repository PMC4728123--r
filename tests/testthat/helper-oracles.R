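# Independent oracles and small fixture builders used across the suite.

# Naive O(N^2) MSD: literal double loop over the defining sum.
msd_naive <- function(pos, dt) {
  N <- nrow(pos)
  vapply(seq_len(N - 1L), function(n) {
    s <- 0
    for (i in seq_len(N - n))
      s <- s + (pos[i + n, 1] - pos[i, 1])^2 + (pos[i + n, 2] - pos[i, 2])^2
    s / (N - n)
  }, numeric(1))
}

# Brute-force minimum enclosing circle: enumerate every pair (diameter
# circle) and every triple (circumcircle from the perpendicular-bisector
# linear system), then take the smallest candidate that encloses all
# points. Exhaustive by construction; vectorized only for speed.
mec_brute <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  ij <- utils::combn(n, 2L)
  cx <- (x[ij[1, ]] + x[ij[2, ]]) / 2
  cy <- (y[ij[1, ]] + y[ij[2, ]]) / 2
  r <- sqrt((x[ij[1, ]] - cx)^2 + (y[ij[1, ]] - cy)^2)
  if (n >= 3L) {
    t3 <- utils::combn(n, 3L)
    ax <- x[t3[1, ]]; ay <- y[t3[1, ]]
    bx <- x[t3[2, ]]; by <- y[t3[2, ]]
    gx <- x[t3[3, ]]; gy <- y[t3[3, ]]
    a11 <- 2 * (bx - ax); a12 <- 2 * (by - ay)
    a21 <- 2 * (gx - ax); a22 <- 2 * (gy - ay)
    det <- a11 * a22 - a12 * a21
    ok <- abs(det) > 1e-12
    r1 <- (bx^2 + by^2) - (ax^2 + ay^2)
    r2 <- (gx^2 + gy^2) - (ax^2 + ay^2)
    ux <- (a22 * r1 - a12 * r2) / det
    uy <- (-a21 * r1 + a11 * r2) / det
    rr <- sqrt((ax - ux)^2 + (ay - uy)^2)
    cx <- c(cx, ux[ok]); cy <- c(cy, uy[ok]); r <- c(r, rr[ok])
  }
  # enclosure check: candidate-by-point distance matrix
  d <- sqrt(outer(cx, x, `-`)^2 + outer(cy, y, `-`)^2)
  encl <- rowSums(d > r + 1e-9) == 0L
  min(r[encl])
}

random_track <- function(n, scale = 1) {
  matrix(stats::rnorm(2 * n, sd = scale), ncol = 2)
}

# A small two-ellipse mask shared by adhesion/coloc tests.
demo_mask_spec <- function(shape = c(48, 48)) {
  mask_spec(shape, list(
    list(center = c(14, 14), semi_axes = c(9, 5), angle = 0.4),
    list(center = c(33, 31), semi_axes = c(10, 6), angle = -0.7)))
}

make_traj <- function(xy, dt = 0.1, id = "t")
  trajectory(as.matrix(xy), dt = dt, track_id = id)
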