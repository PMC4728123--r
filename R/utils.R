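# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Map physical coordinates (x right along columns, y down along rows, in um)
# to 0-based pixel indices on the half-open grid: pixel (r, c) covers
# [c*ps, (c+1)*ps) x [r*ps, (r+1)*ps).
point_to_pixel <- function(x, y, pixel_size) {
  cbind(row = floor(y / pixel_size), col = floor(x / pixel_size))
}

# Physical coordinates (um) of the centre of 0-based pixel (row, col).
pixel_center <- function(row, col, pixel_size) {
  cbind(x = (col + 0.5) * pixel_size, y = (row + 0.5) * pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, positive = FALSE,
                                   nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
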