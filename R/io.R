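# Frame-stack container and plain-text / PNG interchange formats.

#' Frame stack container
#'
#' An ordered stack of RGB frames with frame-rate metadata. Intensities
#' are float in `[0, 1]`; values are only clipped when exported to PNG.
#'
#' @param frames Numeric array `H x W x 3 x T`.
#' @param fps Frame rate in frames/second.
#' @param segment Segment index (metadata).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 50, segment = 1L) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 4 || d[3] != 3) {
    stop_rube("`frames` must be an H x W x 3 x T array.", "input")
  }
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, fps = fps, segment = as.integer(segment)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d RGB at %g fps (segment %d)\n",
              d[4], d[1], d[2], x$fps, x$segment))
  invisible(x)
}

#' Number of frames in a frame stack
#' @param stack A [frame_stack].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[4]

#' Write a frame stack as a directory of PNG frames
#'
#' Frames are written as zero-padded PNGs (`frame_000001.png`, ...) with a
#' sidecar `stack.json` carrying fps and segment index. Intensities are
#' clipped to `[0, 1]` at export.
#'
#' @param stack A [frame_stack].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T_len <- n_frames(stack)
  for (t in seq_len(T_len)) {
    img <- pmin(pmax(stack$frames[, , , t], 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%06d.png", t)))
  }
  jsonlite::write_json(
    list(fps = stack$fps, segment = stack$segment, n_frames = T_len),
    file.path(dir, "stack.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a frame stack from a directory of PNG frames
#'
#' @param dir Directory produced by [write_frame_stack()].
#' @return A [frame_stack].
#' @export
read_frame_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path)) {
    stop_rube("No stack.json sidecar found in the directory.", "input")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop_rube("No PNG frames found.", "input")
  first <- png::readPNG(files[1])
  frames <- array(0, c(dim(first)[1], dim(first)[2], 3, length(files)))
  for (t in seq_along(files)) {
    img <- png::readPNG(files[t])
    frames[, , , t] <- img[, , 1:3]
  }
  frame_stack(frames, fps = meta$fps, segment = meta$segment %||% 1L)
}

#' Write a patch manifest as JSON
#'
#' The manifest is the external contract replacing facial-landmark
#' detection: a list of `{role, x, y, w, h}` boxes in 0-based pixel
#' coordinates with origin at the top-left (x = column, y = row).
#'
#' @param manifest A tibble with columns `role`, `x`, `y`, `w`, `h`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a patch manifest from JSON
#' @param path JSON path written by [write_manifest()].
#' @return A tibble with columns `role`, `x`, `y`, `w`, `h`.
#' @export
read_manifest <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write an eigenvalue sample as single-column CSV
#' @param sample An [eigen_sample] or numeric vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eigen_csv <- function(sample, path) {
  utils::write.csv(data.frame(value = as_esd_values(sample)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an eigenvalue sample from single-column CSV
#' @param path CSV with a `value` column.
#' @return An [eigen_sample].
#' @export
read_eigen_csv <- function(path) {
  eigen_sample(utils::read.csv(path)$value)
}

#' Write segment features (subject, segment, k, sigma, label) as CSV
#' @param features A tibble of per-segment tail features.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Read segment features from CSV
#' @param path CSV written by [write_features_csv()].
#' @return A tibble.
#' @export
read_features_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a tail-fit report as JSON
#' @param report A `tail_fit` row (or tibble of them) from [fit_tails()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tail_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}
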