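#' Construct a single-molecule trajectory
#'
#' A trajectory is one molecule's time-ordered 2D positions, in micrometres,
#' at a fixed frame interval. This is the unit of analysis for MSD, diffusion
#' coefficient and radius-of-confinement calculations.
#'
#' @param positions numeric matrix with columns `x`, `y` (micrometres), one
#'   row per retained frame.
#' @param dt frame interval in seconds.
#' @param track_id identifier (coerced to character).
#' @return An object of class `"trajectory"`: a list with elements
#'   `track_id`, `dt` and `positions`.
#' @export
trajectory <- function(positions, dt, track_id = "track") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("'positions' must have two columns (x, y)", call. = FALSE)
  if (nrow(positions) < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  colnames(positions) <- c("x", "y")
  structure(
    list(track_id = as.character(track_id), dt = dt, positions = positions),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, dt = %g s>\n",
              x$track_id, nrow(x$positions), x$dt))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$positions)

#' Convert a list of trajectories to a long-format data frame
#'
#' Columns `track_id`, `frame` (0-based, contiguous), `x_um`, `y_um` --
#' the on-disk track-table dialect used throughout the package.
#'
#' @param tracks list of [trajectory()] objects.
#' @return A data frame.
#' @export
tracks_to_df <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = character(), frame = integer(),
                      x_um = numeric(), y_um = numeric()))
  do.call(rbind, lapply(tracks, function(tr) {
    n <- n_frames(tr)
    data.frame(track_id = tr$track_id, frame = 0:(n - 1L),
               x_um = tr$positions[, "x"], y_um = tr$positions[, "y"],
               row.names = NULL)
  }))
}
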