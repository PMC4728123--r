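#' Fit per-track mobility statistics to a trajectory set
#'
#' The central estimator of the package. Applies the duration filter, then
#' computes for every retained track the MSD curve, the diffusion
#' coefficient (one-fourth of the least-squares slope through the first
#' four MSD lags), the radius of confinement (exact minimum enclosing
#' circle) and the three-way mobility class. Optionally stratifies tracks
#' by an adhesion mask into inside / outside / discarded.
#'
#' @param tracks list of [trajectory()] objects (e.g. from [load_tracks()]
#'   or [simulate_field()]).
#' @param min_frames,max_frames duration filter bounds, inclusive
#'   (defaults 5 and 20 frames).
#' @param immobile_radius,confined_D classification thresholds; see
#'   [classify_mobility()].
#' @param n_lags number of initial MSD lags used for the D fit.
#' @param mask optional [adhesion_mask()]; when given, each track also gets
#'   a `region` label from [assign_track_region()].
#' @return An object of class `"spt_fit"` with elements `table` (one row
#'   per retained track: `track_id`, `n_frames`, `D_um2_s`, `r_conf_um`,
#'   `mobility`, and `region` when a mask was supplied), `msd` (list of
#'   MSD curves), `tracks`, `params`, `n_input`, `n_retained`.
#' @examples
#' trs <- lapply(1:20, function(i)
#'   simulate_trajectory("free", n_frames = 12, D = 0.5, seed = i,
#'                       track_id = i))
#' fit <- spt_fit(trs)
#' summary(fit)
#' @export
spt_fit <- function(tracks, min_frames = 5L, max_frames = 20L,
                    immobile_radius = 0.166, confined_D = 0.2,
                    n_lags = 4L, mask = NULL) {
  n_input <- length(tracks)
  kept <- filter_by_duration(tracks, min_frames, max_frames)
  msd <- lapply(kept, compute_msd)
  D <- vapply(msd, estimate_diffusion_coefficient, numeric(1),
              n_lags = n_lags)
  r_conf <- vapply(kept, function(tr) as.numeric(radius_of_confinement(tr)),
                   numeric(1))
  mobility <- mapply(classify_mobility, D, r_conf,
                     MoreArgs = list(immobile_radius = immobile_radius,
                                     confined_D = confined_D))
  tab <- data.frame(
    track_id = vapply(kept, function(tr) tr$track_id, character(1)),
    n_frames = vapply(kept, n_frames, integer(1)),
    D_um2_s = D,
    r_conf_um = r_conf,
    mobility = factor(if (length(kept)) mobility else character(),
                      levels = c("immobile", "confined", "free")),
    row.names = NULL
  )
  if (!is.null(mask))
    # tracks that wander beyond the imaged field cannot be attributed to
    # either side of the mask; treat them like boundary-straddling tracks
    tab$region <- factor(
      vapply(kept, function(tr)
        tryCatch(assign_track_region(tr, mask),
                 error = function(e) "discarded"),
        character(1)),
      levels = c("inside", "outside", "discarded"))
  structure(list(table = tab, msd = msd, tracks = kept,
                 params = list(min_frames = min_frames,
                               max_frames = max_frames,
                               immobile_radius = immobile_radius,
                               confined_D = confined_D, n_lags = n_lags),
                 n_input = n_input, n_retained = length(kept)),
            class = "spt_fit")
}

#' @export
print.spt_fit <- function(x, ...) {
  cat(sprintf("spt_fit: %d of %d tracks retained (%d-%d frames)\n",
              x$n_retained, x$n_input, x$params$min_frames,
              x$params$max_frames))
  if (x$n_retained > 0) {
    frac <- table(x$table$mobility) / x$n_retained
    cat(sprintf("mobility: immobile %.3f, confined %.3f, free %.3f\n",
                frac["immobile"], frac["confined"], frac["free"]))
  }
  invisible(x)
}

#' @export
coef.spt_fit <- function(object, ...) {
  stats::setNames(object$table$D_um2_s, object$table$track_id)
}

#' Summarize a trajectory-set fit
#'
#' Per-mobility-class counts and mean +/- SEM of D and r_conf; when a mask
#' was supplied, the same broken out by region.
#'
#' @param object an `"spt_fit"`.
#' @param ... unused.
#' @export
summary.spt_fit <- function(object, ...) {
  tab <- object$table
  by_class <- do.call(rbind, lapply(levels(tab$mobility), function(cl) {
    v <- tab$D_um2_s[tab$mobility == cl]
    data.frame(mobility = cl, n = length(v),
               fraction = length(v) / max(1L, nrow(tab)),
               mean_D = if (length(v)) mean(v) else NA_real_,
               sem_D = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_)
  }))
  out <- list(n_input = object$n_input, n_retained = object$n_retained,
              by_class = by_class, params = object$params)
  if (!is.null(tab$region)) {
    out$by_region <- do.call(rbind, lapply(c("inside", "outside"),
      function(rg) {
        sub <- tab[tab$region == rg, ]
        if (nrow(sub) == 0) return(NULL)
        data.frame(region = rg, n = nrow(sub),
                   f_immobile = mean(sub$mobility == "immobile"),
                   f_confined = mean(sub$mobility == "confined"),
                   f_free = mean(sub$mobility == "free"),
                   mean_D = mean(sub$D_um2_s),
                   sem_D = stats::sd(sub$D_um2_s) / sqrt(nrow(sub)))
      }))
  }
  structure(out, class = "summary.spt_fit")
}

#' @export
print.summary.spt_fit <- function(x, ...) {
  cat(sprintf("Tracks: %d retained of %d input\n", x$n_retained, x$n_input))
  cat("\nBy mobility class (D in um^2/s):\n")
  print(x$by_class, row.names = FALSE, digits = 4)
  if (!is.null(x$by_region)) {
    cat("\nBy adhesion region:\n")
    print(x$by_region, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot MSD curves of a fit, coloured by mobility class
#'
#' @param x an `"spt_fit"`.
#' @param max_tracks cap on the number of curves drawn.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spt_fit <- function(x, max_tracks = 200L, ...) {
  if (x$n_retained == 0L) stop("nothing to plot", call. = FALSE)
  idx <- seq_len(min(max_tracks, x$n_retained))
  cols <- c(immobile = "firebrick", confined = "forestgreen",
            free = "royalblue")
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$msd[idx],
                                                   `[[`, "lags")))),
                 ylim = c(0, stats::quantile(unlist(lapply(x$msd[idx],
                                                           `[[`, "values")),
                                             0.98)),
                 xlab = "lag tau (s)", ylab = "MSD (um^2)", ...)
  for (i in idx)
    graphics::lines(x$msd[[i]]$lags, x$msd[[i]]$values,
                    col = cols[as.character(x$table$mobility[i])])
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
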