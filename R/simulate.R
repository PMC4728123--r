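#' Acquisition parameters for simulated sptPALM data
#'
#' Frame interval, pixel size and localization noise of the emulated
#' acquisition. Defaults mirror a 10 fps EMCCD TIRF setup with 0.166 um
#' pixels; the localization noise (sigma of an i.i.d. Gaussian error added
#' to each true position) defaults to 0.02 um, typical for PALM and small
#' against the pixel size.
#'
#' @param dt seconds per frame.
#' @param pixel_size micrometres per pixel.
#' @param localization_noise_sigma micrometres; 0 disables noise.
#' @return A list of class `"acquisition_params"`.
#' @export
acquisition_params <- function(dt = 0.1, pixel_size = 0.166,
                               localization_noise_sigma = 0.02) {
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  stop_if_not_scalar_num(localization_noise_sigma,
                         "localization_noise_sigma", nonneg = TRUE)
  structure(list(dt = dt, pixel_size = pixel_size,
                 localization_noise_sigma = localization_noise_sigma),
            class = "acquisition_params")
}

#' Specification of one simulated diffusive population
#'
#' @param mode one of `"immobile"`, `"confined"`, `"free"`.
#' @param D diffusion coefficient in um^2/s (used for confined and free).
#' @param confinement_radius radius in um of the reflecting circular boundary
#'   (confined mode only).
#' @param count number of tracks to generate.
#' @param frames_min,frames_max track durations are drawn uniformly on this
#'   inclusive range so a downstream duration filter has both survivors and
#'   casualties by default.
#' @param placement where track origins are placed relative to the adhesion
#'   mask: `"inside_mask"`, `"outside_mask"` or `"uniform"`.
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(mode = c("free", "confined", "immobile"),
                            D = 0, confinement_radius = NULL, count = 1L,
                            frames_min = 5L, frames_max = 20L,
                            placement = c("uniform", "inside_mask",
                                          "outside_mask")) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  stop_if_not_scalar_num(D, "D", nonneg = TRUE)
  stop_if_not_scalar_num(count, "count", nonneg = TRUE)
  stop_if_not_scalar_num(frames_min, "frames_min")
  stop_if_not_scalar_num(frames_max, "frames_max")
  if (frames_min < 2) stop("'frames_min' must be >= 2", call. = FALSE)
  if (frames_max < frames_min)
    stop("'frames_max' must be >= 'frames_min'", call. = FALSE)
  if (mode == "confined") {
    if (is.null(confinement_radius) || confinement_radius <= 0)
      stop("confined mode needs a positive 'confinement_radius'",
           call. = FALSE)
  }
  structure(list(mode = mode, D = D,
                 confinement_radius = confinement_radius,
                 count = as.integer(count),
                 frames_min = as.integer(frames_min),
                 frames_max = as.integer(frames_max),
                 placement = placement),
            class = "population_spec")
}

#' Specification of an adhesion-mask geometry
#'
#' Elliptical adhesion footprints (a synthetic stand-in for vinculin- or
#' integrin-marked focal adhesions) rasterized onto a pixel grid.
#'
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param ellipses list of ellipses, each a list with `center = c(row, col)`
#'   (pixels, 0-based), `semi_axes = c(a, b)` (pixels, along/perpendicular to
#'   the major axis) and `angle` (radians, rotation of the major axis from
#'   the column direction).
#' @return A list of class `"mask_spec"`.
#' @export
mask_spec <- function(image_shape, ellipses) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop("'image_shape' must be two positive integers (rows, cols)",
         call. = FALSE)
  for (e in ellipses) {
    if (any(e$semi_axes <= 0))
      stop("ellipse semi-axes must be > 0", call. = FALSE)
    a <- max(e$semi_axes)
    if (e$center[1] - a < 0 || e$center[1] + a > image_shape[1] ||
        e$center[2] - a < 0 || e$center[2] + a > image_shape[2])
      stop("ellipse extends beyond image bounds", call. = FALSE)
  }
  structure(list(image_shape = image_shape, ellipses = ellipses),
            class = "mask_spec")
}

#' Specification of a rendered intensity pattern
#'
#' `"fill"` paints each ellipse interior at `peak_intensity`; `"ring"`
#' paints only an annulus of width `ring_width` just inside the ellipse
#' boundary, leaving the interior at `background` -- emulating a receptor
#' that rings adhesions rather than filling them.
#'
#' @param pattern `"fill"` or `"ring"`.
#' @param ring_width annulus width in pixels (ring pattern).
#' @param peak_intensity,background 8-bit intensities, 0-255 with
#'   `background < peak_intensity`.
#' @param noise_sigma Gaussian intensity noise added before quantization.
#' @return A list of class `"render_spec"`.
#' @export
render_spec <- function(pattern = c("fill", "ring"), ring_width = 2,
                        peak_intensity = 200, background = 10,
                        noise_sigma = 0) {
  pattern <- match.arg(pattern)
  stop_if_not_scalar_num(ring_width, "ring_width")
  if (ring_width < 1) stop("'ring_width' must be >= 1", call. = FALSE)
  stop_if_not_scalar_num(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (!(background >= 0 && background < peak_intensity &&
        peak_intensity <= 255))
    stop("need 0 <= background < peak_intensity <= 255", call. = FALSE)
  structure(list(pattern = pattern, ring_width = ring_width,
                 peak_intensity = peak_intensity, background = background,
                 noise_sigma = noise_sigma),
            class = "render_spec")
}

#' Simulate one single-molecule trajectory
#'
#' Generates the true 2D path of one molecule and overlays i.i.d. Gaussian
#' localization noise. Free diffusion uses independent Gaussian increments
#' of variance `2*D*dt` per axis. Confined diffusion uses the same Brownian
#' steps inside a reflecting circular boundary of radius
#' `confinement_radius` centred on the origin, so the true path never leaves
#' that disc. Immobile molecules stay at the origin.
#'
#' @param mode `"immobile"`, `"confined"` or `"free"`.
#' @param n_frames number of frames (>= 2).
#' @param D diffusion coefficient, um^2/s.
#' @param confinement_radius disc radius in um (confined mode).
#' @param origin length-2 numeric, starting position in um.
#' @param acq [acquisition_params()]; supplies `dt` and the localization
#'   noise sigma.
#' @param seed integer; the same seed reproduces the trajectory exactly.
#' @param track_id identifier for the returned trajectory.
#' @return A [trajectory()].
#' @examples
#' tr <- simulate_trajectory("free", n_frames = 10, D = 0.5, seed = 1)
#' compute_msd(tr)
#' @export
simulate_trajectory <- function(mode, n_frames, D = 0,
                                confinement_radius = NULL,
                                origin = c(0, 0),
                                acq = acquisition_params(),
                                seed = 1L, track_id = "track") {
  if (!mode %in% c("immobile", "confined", "free"))
    stop(sprintf("unknown mode '%s'", mode), call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  if (mode == "confined" &&
      (is.null(confinement_radius) || confinement_radius <= 0))
    stop("confined mode needs a positive 'confinement_radius'",
         call. = FALSE)
  with_seed(seed, {
    pos <- simulate_path(mode, n_frames, D, confinement_radius, origin,
                         acq$dt)
    sig <- acq$localization_noise_sigma
    if (sig > 0)
      pos <- pos + matrix(stats::rnorm(2L * n_frames, 0, sig), ncol = 2L)
    trajectory(pos, dt = acq$dt, track_id = track_id)
  })
}

# True (noise-free) path; consumes the active RNG stream.
simulate_path <- function(mode, n_frames, D, R, origin, dt) {
  origin <- as.numeric(origin)
  if (mode == "immobile" || D == 0)
    return(matrix(rep(origin, each = n_frames), ncol = 2L))
  step_sd <- sqrt(2 * D * dt)
  steps <- matrix(stats::rnorm(2L * (n_frames - 1L), 0, step_sd), ncol = 2L)
  if (mode == "free") {
    cs <- apply(steps, 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1L)
    return(rbind(origin, sweep(cs, 2L, origin, `+`), deparse.level = 0))
  }
  # confined: radial reflection at the disc boundary about the origin
  pos <- matrix(0, n_frames, 2L)
  p <- c(0, 0)
  for (i in seq_len(n_frames - 1L)) {
    p <- p + steps[i, ]
    r <- sqrt(sum(p^2))
    while (r > R) {
      p <- p * (2 * R - r) / r
      r <- abs(2 * R - r)
    }
    pos[i + 1L, ] <- p
  }
  sweep(pos, 2L, origin, `+`)
}

#' Rasterize an adhesion-mask specification
#'
#' A pixel belongs to the mask iff its centre lies inside at least one
#' ellipse. Pixels follow the half-open convention: pixel (r, c), 0-based,
#' covers `[c, c+1) x [r, r+1)` in pixel units.
#'
#' @param spec a [mask_spec()].
#' @param pixel_size micrometres per pixel.
#' @return An [adhesion_mask()].
#' @export
rasterize_mask <- function(spec, pixel_size = 0.166) {
  dims <- spec$image_shape
  grid <- matrix(FALSE, dims[1], dims[2])
  xc <- matrix(rep(seq_len(dims[2]) - 0.5, each = dims[1]), dims[1])
  yc <- matrix(rep(seq_len(dims[1]) - 0.5, times = dims[2]), dims[1])
  for (e in spec$ellipses)
    grid <- grid | (ellipse_level(xc, yc, e) <= 1)
  adhesion_mask(grid, pixel_size)
}

# Normalized ellipse level: <= 1 inside, 1 on the boundary.
# x, y in pixel units with x along columns; center is (row, col).
ellipse_level <- function(x, y, e) {
  dx <- x - e$center[2]
  dy <- y - e$center[1]
  ang <- e$angle %||% 0
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  (u / e$semi_axes[1])^2 + (v / e$semi_axes[2])^2
}

#' Simulate a field of trajectories over an adhesion mask
#'
#' Generates the configured number of tracks per population, placing origins
#' inside the mask (at mask-true pixel centres), outside it (mask-false
#' pixel centres) or uniformly over the field, and rasterizes the mask.
#' Track durations are drawn uniformly on `[frames_min, frames_max]`.
#' This emulates an sptPALM experiment over vinculin-marked adhesions with
#' known ground-truth placement and mobility, so density-enrichment and
#' mobility-fraction estimates can be validated against what was programmed.
#'
#' @param spec a [mask_spec()].
#' @param populations list of [population_spec()].
#' @param acq [acquisition_params()].
#' @param seed integer seed; the full field is reproducible.
#' @return A list with `tracks` (list of trajectories, each carrying
#'   attributes `population` and `placement`) and `mask` (an
#'   [adhesion_mask()]).
#' @export
simulate_field <- function(spec, populations, acq = acquisition_params(),
                           seed = 1L) {
  if (length(populations) == 0L)
    stop("'populations' must be non-empty", call. = FALSE)
  mask <- rasterize_mask(spec, acq$pixel_size)
  dims <- dim(mask$grid)
  inside_px <- which(mask$grid, arr.ind = TRUE) - 1L   # 0-based (row, col)
  outside_px <- which(!mask$grid, arr.ind = TRUE) - 1L
  tracks <- with_seed(seed, {
    out <- list()
    for (pi in seq_along(populations)) {
      pop <- populations[[pi]]
      if (pop$count == 0L) next
      for (j in seq_len(pop$count)) {
        origin <- switch(pop$placement,
          inside_mask = {
            if (nrow(inside_px) == 0L)
              stop("placement 'inside_mask' with an empty mask",
                   call. = FALSE)
            k <- sample.int(nrow(inside_px), 1L)
            pixel_center(inside_px[k, 1L], inside_px[k, 2L],
                         acq$pixel_size)[1L, ]
          },
          outside_mask = {
            if (nrow(outside_px) == 0L)
              stop("placement 'outside_mask' with a full mask",
                   call. = FALSE)
            k <- sample.int(nrow(outside_px), 1L)
            pixel_center(outside_px[k, 1L], outside_px[k, 2L],
                         acq$pixel_size)[1L, ]
          },
          uniform = c(stats::runif(1, 0, dims[2] * acq$pixel_size),
                      stats::runif(1, 0, dims[1] * acq$pixel_size))
        )
        nf <- sample(pop$frames_min:pop$frames_max, 1L)
        pos <- simulate_path(pop$mode, nf, pop$D, pop$confinement_radius,
                             origin, acq$dt)
        sig <- acq$localization_noise_sigma
        if (sig > 0)
          pos <- pos + matrix(stats::rnorm(2L * nf, 0, sig), ncol = 2L)
        tr <- trajectory(pos, dt = acq$dt,
                         track_id = sprintf("pop%d_%04d", pi, j))
        attr(tr, "population") <- pi
        attr(tr, "placement") <- pop$placement
        out[[length(out) + 1L]] <- tr
      }
    }
    out
  })
  list(tracks = tracks, mask = mask)
}

#' Render a synthetic two-channel adhesion image
#'
#' Renders the same ellipse geometry twice, once per channel spec, as 8-bit
#' grayscale images. The fill/ring pair emulates the observed two-channel
#' pattern where one receptor fills integrin-rich adhesions while a second
#' receptor is enriched only in a peripheral ring around them.
#'
#' @param spec a [mask_spec()] giving the shared geometry.
#' @param spec_a,spec_b [render_spec()] for channels A and B.
#' @param seed integer seed for the intensity noise.
#' @return List of two integer matrices `A` and `B`, values in 0-255.
#' @export
render_two_channel_image <- function(spec, spec_a, spec_b, seed = 1L) {
  with_seed(seed, {
    list(A = render_channel(spec, spec_a),
         B = render_channel(spec, spec_b))
  })
}

render_channel <- function(spec, rs) {
  dims <- spec$image_shape
  img <- matrix(rs$background, dims[1], dims[2])
  xc <- matrix(rep(seq_len(dims[2]) - 0.5, each = dims[1]), dims[1])
  yc <- matrix(rep(seq_len(dims[1]) - 0.5, times = dims[2]), dims[1])
  for (e in spec$ellipses) {
    inside <- ellipse_level(xc, yc, e) <= 1
    if (rs$pattern == "fill") {
      img[inside] <- rs$peak_intensity
    } else {
      inner <- e
      inner$semi_axes <- pmax(e$semi_axes - rs$ring_width, 1e-6)
      ring <- inside & (ellipse_level(xc, yc, inner) > 1)
      img[ring] <- rs$peak_intensity
    }
  }
  if (rs$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, rs$noise_sigma),
                        nrow(img))
  quantize_8bit(img)
}

quantize_8bit <- function(img) {
  matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow(img), ncol(img))
}

#' Generate paired bait/mock peptide-count tables
#'
#' Draws spectral counts for a bait pulldown and a mock (untransfected
#' control) pulldown over a shared protein list. Mock counts for protein i
#' are Poisson with mean `depth * w_i`; bait counts are Poisson with mean
#' `depth * w_i * fold_i`, so the expected bait/mock count ratio equals the
#' programmed fold per protein.
#'
#' @param proteins data frame with columns `protein_id` and `mw_kda`.
#' @param bait_enrichment named numeric vector of fold enrichments
#'   (names = protein ids); proteins not named get fold 1. Folds must be
#'   >= 0 (0 means the protein never appears in the bait pulldown).
#' @param depth expected total mock counts.
#' @param weights optional baseline relative abundances (recycled to
#'   uniform); normalized internally.
#' @param seed integer seed.
#' @return List of two data frames `bait` and `mock`, each with columns
#'   `protein_id`, `mw_kda`, `count` and a `"sample"` attribute.
#' @export
generate_peptide_table <- function(proteins, bait_enrichment = numeric(),
                                   depth = 1e4, weights = NULL, seed = 1L) {
  if (nrow(proteins) == 0L)
    stop("'proteins' must be non-empty", call. = FALSE)
  stop_if_not_scalar_num(depth, "depth", positive = TRUE)
  if (any(bait_enrichment < 0))
    stop("folds must be >= 0", call. = FALSE)
  ids <- as.character(proteins$protein_id)
  if (anyDuplicated(ids)) stop("duplicate protein ids", call. = FALSE)
  w <- weights %||% rep(1, length(ids))
  w <- w / sum(w)
  fold <- rep(1, length(ids))
  hit <- match(names(bait_enrichment), ids)
  if (anyNA(hit)) stop("unknown protein id in 'bait_enrichment'",
                       call. = FALSE)
  fold[hit] <- unname(bait_enrichment)
  with_seed(seed, {
    mock_counts <- stats::rpois(length(ids), depth * w)
    bait_counts <- stats::rpois(length(ids), depth * w * fold)
    tab <- function(counts, label) {
      d <- data.frame(protein_id = ids, mw_kda = proteins$mw_kda,
                      count = counts)
      attr(d, "sample") <- label
      d
    }
    list(bait = tab(bait_counts, "bait"), mock = tab(mock_counts, "mock"))
  })
}
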