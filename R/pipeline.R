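#' Run the full analysis pipeline from a configuration
#'
#' Chains the two headline analyses over file-based inputs:
#' the trajectory branch (load tracks, duration-filter, MSD / D / r_conf,
#' mobility classification, adhesion stratification, per-ROI enrichment
#' ratios, mobility fractions and an inside-vs-outside comparison of D)
#' and the colocalization branch (smooth, extract paired line profiles,
#' reflection-regression slopes), plus the optional bait-vs-mock abundance
#' screen. The report is deterministic given the inputs.
#'
#' @param config a named list or path to a YAML file with (all optional
#'   except `tracks` for the trajectory branch):
#' \describe{
#'   \item{acquisition}{`dt` (s, default 0.1), `pixel_size` (um, 0.166).}
#'   \item{tracks}{track CSV path.}
#'   \item{filter}{`min_frames` (5), `max_frames` (20).}
#'   \item{classify}{`immobile_radius` (0.166), `confined_d` (0.2).}
#'   \item{mask}{mask image path (png/tiff).}
#'   \item{rois}{list of `(row0, col0, row1, col1)` rectangles.}
#'   \item{coloc}{`image_a`, `image_b` (paths), `lines` (CSV path with
#'     header `x0,y0,x1,y1[,n_samples]`), `smooth_sigma` (0.6).}
#'   \item{screen}{`bait`, `mock` (CSV paths), `pseudocount` (1),
#'     `ratio_cutoff` (3), `total_mode` ("counts").}
#'   \item{alpha}{significance level, default 0.01.}
#' }
#' @param out_dir optional directory; when given, the per-track table,
#'   per-ROI enrichment, colocalization slopes and screen are written as
#'   CSV and the full report as `report.json`.
#' @return A list of class `"spt_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  acq <- config$acquisition %||% list()
  dt <- acq$dt %||% 0.1
  pixel_size <- acq$pixel_size %||% 0.166
  alpha <- config$alpha %||% 0.01
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  report <- list(params = list(dt = dt, pixel_size = pixel_size,
                               alpha = alpha))

  # ---- trajectory branch -------------------------------------------------
  if (!is.null(config$tracks)) {
    tracks <- load_tracks(config$tracks, dt = dt)
    note("loaded %d tracks from %s", length(tracks), config$tracks)
    flt <- config$filter %||% list()
    cls <- config$classify %||% list()
    min_frames <- flt$min_frames %||% 5L
    max_frames <- flt$max_frames %||% 20L
    immobile_radius <- cls$immobile_radius %||% 0.166
    confined_d <- cls$confined_d %||% 0.2
    mask <- if (!is.null(config$mask))
      read_mask(config$mask, pixel_size) else NULL
    fit <- spt_fit(tracks, min_frames = min_frames,
                   max_frames = max_frames,
                   immobile_radius = immobile_radius,
                   confined_D = confined_d, mask = mask)
    note("duration filter [%d, %d] frames: %d of %d tracks retained",
         min_frames, max_frames, fit$n_retained, fit$n_input)
    note("thresholds: immobile r_conf < %g um, confined D < %g um^2/s",
         immobile_radius, confined_d)
    report$tracks <- list(n_input = fit$n_input,
                          n_retained = fit$n_retained,
                          per_track = fit$table)

    if (!is.null(mask)) {
      tab <- fit$table
      note("region assignment: %d inside, %d outside, %d discarded",
           sum(tab$region == "inside"), sum(tab$region == "outside"),
           sum(tab$region == "discarded"))
      fractions <- lapply(c(inside = "inside", outside = "outside"),
        function(rg) {
          m <- tab$mobility[tab$region == rg]
          if (length(m) == 0L) NULL else as.list(mobility_fractions(m))
        })
      report$adhesion <- list(fractions = fractions)
      if (!is.null(config$rois)) {
        rois <- lapply(config$rois, function(r)
          roi(r$row0 %||% r[[1]], r$col0 %||% r[[2]],
              r$row1 %||% r[[3]], r$col1 %||% r[[4]]))
        enr <- do.call(rbind, lapply(seq_along(rois), function(i) {
          r <- rois[[i]]
          qual <- qualify_adhesion_rich_roi(mask, r)
          if (!qual) {
            note("ROI %d rejected: adhesion coverage <= 25%%", i)
            return(data.frame(roi = i, qualifies = FALSE,
                              ratio = NA_real_, n_inside = NA_integer_,
                              n_outside = NA_integer_))
          }
          er <- tryCatch(
            enrichment_ratio(fit$tracks, as.character(tab$region), mask, r),
            error = function(e) {
              note("ROI %d: %s", i, conditionMessage(e))
              NULL
            })
          if (is.null(er))
            return(data.frame(roi = i, qualifies = TRUE, ratio = NA_real_,
                              n_inside = NA_integer_,
                              n_outside = NA_integer_))
          data.frame(roi = i, qualifies = TRUE, ratio = er$ratio,
                     n_inside = er$n_inside, n_outside = er$n_outside)
        }))
        report$adhesion$enrichment <- enr
      }
      d_in <- tab$D_um2_s[tab$region == "inside"]
      d_out <- tab$D_um2_s[tab$region == "outside"]
      if (length(d_in) >= 2L && length(d_out) >= 2L &&
          (stats::var(d_in) > 0 || stats::var(d_out) > 0)) {
        cmp <- compare_groups(list(inside = d_in, outside = d_out),
                              method = "t_test", alpha = alpha)
        report$adhesion$D_comparison <- cmp$pairwise
      }
    }
  }

  # ---- colocalization branch --------------------------------------------
  if (!is.null(config$coloc)) {
    cc <- config$coloc
    img_a <- read_image_8bit(cc$image_a)
    img_b <- read_image_8bit(cc$image_b)
    lines <- utils::read.csv(cc$lines, stringsAsFactors = FALSE)
    sigma <- cc$smooth_sigma %||% 0.6
    slopes <- colocalization_profile_set(img_a, img_b, lines,
                                         smooth_sigma = sigma)
    note("colocalization: %d lines, smoothing sigma %g px",
         nrow(slopes), sigma)
    sm <- summarize_group(slopes$slope, "sd", label = "coloc_slope")
    report$coloc <- list(per_line = slopes,
                         summary = list(n = sm$n, mean = sm$mean,
                                        sd = sm$sd))
  }

  # ---- abundance screen --------------------------------------------------
  if (!is.null(config$screen)) {
    sc <- config$screen
    bait <- load_peptide_table(sc$bait, "bait")
    mock <- load_peptide_table(sc$mock, "mock")
    screen <- enrichment_screen(bait, mock,
                                pseudocount = sc$pseudocount %||% 1,
                                ratio_cutoff = sc$ratio_cutoff %||% 3,
                                total_mode = sc$total_mode %||% "counts")
    note("screen: %d proteins, %d candidates", nrow(screen),
         sum(screen$candidate))
    report$screen <- screen
  }

  report$log <- log
  class(report) <- "spt_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$tracks))
      utils::write.csv(report$tracks$per_track,
                       file.path(out_dir, "per_track.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(report$adhesion$enrichment))
      utils::write.csv(report$adhesion$enrichment,
                       file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(report$coloc))
      utils::write.csv(report$coloc$per_line,
                       file.path(out_dir, "coloc_slopes.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(report$screen))
      utils::write.csv(report$screen,
                       file.path(out_dir, "screen.csv"),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.spt_report <- function(x, ...) {
  cat("spt pipeline report\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
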