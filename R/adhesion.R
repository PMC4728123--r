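#' Adhesion mask
#'
#' Binary pixel grid marking focal-adhesion footprints (e.g. thresholded
#' vinculin signal), with its physical pixel size. Pixels follow the
#' half-open convention of the package: 0-based pixel (r, c) covers
#' `[c*ps, (c+1)*ps) x [r*ps, (r+1)*ps)` in um, x along columns.
#'
#' @param grid logical matrix, TRUE = adhesion.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `"adhesion_mask"`.
#' @export
adhesion_mask <- function(grid, pixel_size = 0.166) {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("empty mask grid", call. = FALSE)
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  storage.mode(grid) <- "logical"
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "adhesion_mask")
}

#' @export
print.adhesion_mask <- function(x, ...) {
  cat(sprintf("<adhesion_mask %dx%d px (%.3f um/px), coverage %.1f%%>\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              100 * mean(x$grid)))
  invisible(x)
}

#' Assign a track to inside/outside an adhesion mask
#'
#' A track is `"inside"` only if every localization falls in a mask-true
#' pixel, `"outside"` only if every localization falls in a mask-false
#' pixel; tracks that straddle the boundary are `"discarded"` and excluded
#' from quantitative adhesion statistics.
#'
#' @param traj a [trajectory()].
#' @param mask an [adhesion_mask()].
#' @return `"inside"`, `"outside"` or `"discarded"`.
#' @export
assign_track_region <- function(traj, mask) {
  px <- point_to_pixel(traj$positions[, "x"], traj$positions[, "y"],
                       mask$pixel_size)
  dims <- dim(mask$grid)
  if (any(px[, "row"] < 0 | px[, "row"] >= dims[1] |
          px[, "col"] < 0 | px[, "col"] >= dims[2]))
    stop("track position outside image bounds", call. = FALSE)
  inside <- mask$grid[cbind(px[, "row"] + 1L, px[, "col"] + 1L)]
  if (all(inside)) "inside" else if (!any(inside)) "outside" else "discarded"
}

#' Rectangular region of interest, 0-based half-open pixel bounds
#'
#' @param row0,col0,row1,col1 integer bounds; the ROI covers rows
#'   `row0..row1-1` and columns `col0..col1-1`.
#' @return A list of class `"roi"`.
#' @export
roi <- function(row0, col0, row1, col1) {
  if (row1 <= row0 || col1 <= col0)
    stop("degenerate ROI", call. = FALSE)
  if (row0 < 0 || col0 < 0)
    stop("ROI bounds must be non-negative", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "roi")
}

roi_submask <- function(mask, r) {
  dims <- dim(mask$grid)
  if (r$row1 > dims[1] || r$col1 > dims[2])
    stop("ROI exceeds mask bounds", call. = FALSE)
  mask$grid[(r$row0 + 1L):r$row1, (r$col0 + 1L):r$col1, drop = FALSE]
}

#' Does an ROI qualify as adhesion-rich?
#'
#' TRUE iff the mask covers strictly more than `min_coverage` (default
#' 25%) of the ROI area -- the selection rule for regions over which the
#' enrichment ratio is computed.
#'
#' @param mask an [adhesion_mask()].
#' @param r an [roi()].
#' @param min_coverage strict coverage threshold, fraction of ROI area.
#' @return Logical.
#' @export
qualify_adhesion_rich_roi <- function(mask, r, min_coverage = 0.25) {
  sub <- roi_submask(mask, r)
  mean(sub) > min_coverage
}

#' Track-density enrichment ratio inside vs outside adhesions
#'
#' Within one adhesion-rich ROI, the ratio of track density (tracks/um^2)
#' over mask-true pixels to track density over mask-false pixels. A track
#' is counted once, by the pixel of its first localization; only tracks
#' whose first pixel lies in the ROI and whose region label is `"inside"`
#' or `"outside"` contribute.
#'
#' @param tracks list of trajectories.
#' @param regions character vector of region labels parallel to `tracks`
#'   (from [assign_track_region()]).
#' @param mask an [adhesion_mask()].
#' @param r an [roi()]; must qualify as adhesion-rich (see
#'   [qualify_adhesion_rich_roi()]) unless `check_roi = FALSE`.
#' @param check_roi enforce the 25% coverage rule.
#' @return An object of class `"enrichment_result"`: list with
#'   `density_inside`, `density_outside` (tracks/um^2), `ratio`,
#'   `n_inside`, `n_outside`, `area_inside_um2`, `area_outside_um2`.
#' @export
enrichment_ratio <- function(tracks, regions, mask, r, check_roi = TRUE) {
  if (length(tracks) != length(regions))
    stop("'tracks' and 'regions' lengths differ", call. = FALSE)
  if (check_roi && !qualify_adhesion_rich_roi(mask, r))
    stop("ROI does not qualify as adhesion-rich (coverage <= 25%)",
         call. = FALSE)
  sub <- roi_submask(mask, r)
  ps2 <- mask$pixel_size^2
  area_in <- sum(sub) * ps2
  area_out <- sum(!sub) * ps2
  if (area_in == 0 || area_out == 0)
    stop("ROI must contain both mask and non-mask pixels", call. = FALSE)
  n_in <- 0L; n_out <- 0L
  for (i in seq_along(tracks)) {
    if (!regions[i] %in% c("inside", "outside")) next
    p <- point_to_pixel(tracks[[i]]$positions[1L, "x"],
                        tracks[[i]]$positions[1L, "y"], mask$pixel_size)
    if (p[1L, "row"] < r$row0 || p[1L, "row"] >= r$row1 ||
        p[1L, "col"] < r$col0 || p[1L, "col"] >= r$col1) next
    if (regions[i] == "inside") n_in <- n_in + 1L else n_out <- n_out + 1L
  }
  if (n_out == 0L)
    stop("no outside tracks in ROI: enrichment ratio undefined",
         call. = FALSE)
  di <- n_in / area_in
  do <- n_out / area_out
  structure(list(density_inside = di, density_outside = do,
                 ratio = di / do, n_inside = n_in, n_outside = n_out,
                 area_inside_um2 = area_in, area_outside_um2 = area_out),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("enrichment ratio %.3f ",
                     "(inside %.3f tracks/um^2 [n=%d], ",
                     "outside %.3f tracks/um^2 [n=%d])\n"),
              x$ratio, x$density_inside, x$n_inside,
              x$density_outside, x$n_outside))
  invisible(x)
}

#' Mobility-class fractions of a set of tracks
#'
#' @param mobility character or factor vector of classes
#'   (`"immobile"`, `"confined"`, `"free"`).
#' @return Named numeric vector `(f_immobile, f_confined, f_free)` summing
#'   to 1.
#' @export
mobility_fractions <- function(mobility) {
  mobility <- as.character(mobility)
  if (length(mobility) == 0L)
    stop("no tracks in region", call. = FALSE)
  bad <- setdiff(unique(mobility), c("immobile", "confined", "free"))
  if (length(bad))
    stop("unknown mobility class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  c(f_immobile = mean(mobility == "immobile"),
    f_confined = mean(mobility == "confined"),
    f_free = mean(mobility == "free"))
}
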