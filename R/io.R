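# Readers and writers for the plain-text and image formats the pipeline
# touches. Track tables are CSV with header track_id,frame,x_um,y_um;
# masks and 8-bit images are single-channel PNG or TIFF.

#' Load a trajectory set from a track CSV
#'
#' Expects the exact header `track_id,frame,x_um,y_um`. Frames must be
#' strictly increasing and contiguous within each track (a trajectory is a
#' run of consecutive frames; gapped or duplicated frames are rejected).
#'
#' @param path CSV file path.
#' @param dt frame interval in seconds assigned to the loaded tracks.
#' @return List of [trajectory()] objects, in order of first appearance.
#' @export
load_tracks <- function(path, dt = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!identical(names(df), req))
    stop("malformed header: expected ", paste(req, collapse = ","),
         call. = FALSE)
  if (nrow(df) == 0L) return(list())
  if (!is.numeric(df$frame) || !is.numeric(df$x_um) || !is.numeric(df$y_um))
    stop("non-numeric frame or coordinate column", call. = FALSE)
  if (anyNA(df)) stop("missing values in track table", call. = FALSE)
  ids <- unique(as.character(df$track_id))
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    d <- diff(sub$frame)
    if (any(d == 0))
      stop(sprintf("duplicated (track_id, frame) in track '%s'", id),
           call. = FALSE)
    if (any(d != 1))
      stop(sprintf("track '%s' has non-contiguous or non-increasing frames",
                   id), call. = FALSE)
    trajectory(cbind(sub$x_um, sub$y_um), dt = dt, track_id = id)
  })
}

#' Write a trajectory set as a track CSV
#'
#' @param tracks list of trajectories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks_to_df(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

img_writer <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG,
         tif = , tiff = tiff::writeTIFF,
         stop("unsupported image extension '", ext, "' (use png/tiff)",
              call. = FALSE))
}

img_reader <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::readPNG,
         tif = , tiff = tiff::readTIFF,
         stop("unsupported image extension '", ext, "' (use png/tiff)",
              call. = FALSE))
}

#' Read / write 8-bit single-channel images
#'
#' Images are stored as PNG or TIFF with intensities scaled to `[0, 1]` on
#' disk; in memory the package works on integer matrices in 0-255. Multi-
#' channel files are reduced to their first channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `read_image_8bit`: integer matrix 0-255.
#' @export
read_image_8bit <- function(path) {
  arr <- img_reader(path)(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  quantize_8bit(arr * 255)
}

#' @rdname read_image_8bit
#' @param image integer/numeric matrix, 0-255.
#' @export
write_image_8bit <- function(image, path) {
  m <- as.matrix(image) / 255
  m[] <- pmin(1, pmax(0, m))
  img_writer(path)(m, path)
  invisible(path)
}

#' Read / write adhesion masks
#'
#' On disk a mask is a single-channel image where any nonzero pixel is
#' adhesion.
#'
#' @param path image path (png/tiff).
#' @param pixel_size micrometres per pixel of the stored grid.
#' @return `read_mask`: an [adhesion_mask()].
#' @export
read_mask <- function(path, pixel_size = 0.166) {
  arr <- img_reader(path)(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  adhesion_mask(arr > 0, pixel_size)
}

#' @rdname read_mask
#' @param mask an [adhesion_mask()].
#' @export
write_mask <- function(mask, path) {
  img_writer(path)(mask$grid * 1.0, path)
  invisible(path)
}

#' Load a peptide-count table
#'
#' CSV with header `protein_id,mw_kda,count`.
#'
#' @param path CSV path.
#' @param sample label attached to the table.
#' @return Data frame with a `"sample"` attribute.
#' @export
load_peptide_table <- function(path, sample = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "mw_kda", "count")
  if (!identical(names(df), req))
    stop("malformed header: expected ", paste(req, collapse = ","),
         call. = FALSE)
  attr(df, "sample") <- sample
  df
}

#' Load a pipeline configuration from YAML
#'
#' See [run_pipeline()] for the recognized fields.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}
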