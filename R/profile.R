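# Facial patch extraction and the normalized spatio-temporal tensor
# expression profile: the pixelwise difference between the reddest and
# palest patches, row-standardized.

#' Extract facial patches from a frame stack
#'
#' Pulls the Red-channel intensities of the eight manifest patches out of
#' every frame. Patch locations come from the manifest (0-based pixel
#' coordinates, origin top-left); patch tracking across frames is the
#' manifest producer's job — boxes are static here.
#'
#' @param stack A [frame_stack].
#' @param manifest Patch-box tibble with columns `role`, `x`, `y`, `w`,
#'   `h` (exactly 8 rows, equal square sizes), e.g. from [scene_layout()]
#'   or [read_manifest()].
#' @return An object of class `patch_series`: per-patch `pixels` matrices
#'   (w*h x T), `roles`, per-frame patch `means` (T x 8), and the boxes.
#' @export
extract_patches <- function(stack, manifest) {
  stopifnot(inherits(stack, "frame_stack"))
  manifest <- as_tibble(manifest)
  if (nrow(manifest) != 8) {
    stop_rube("The patch manifest must contain exactly 8 boxes.", "manifest")
  }
  d <- dim(stack$frames)
  if (any(manifest$x < 0 | manifest$y < 0 |
          manifest$x + manifest$w > d[2] | manifest$y + manifest$h > d[1])) {
    stop_rube("A patch box lies outside the frame bounds.", "geometry")
  }
  if (length(unique(manifest$w)) != 1 || length(unique(manifest$h)) != 1) {
    stop_rube("All patch boxes must share the same size.", "manifest")
  }
  T_len <- d[4]
  pixels <- purrr::map(seq_len(8), function(b) {
    rows <- (manifest$y[b] + 1):(manifest$y[b] + manifest$h[b])
    cols <- (manifest$x[b] + 1):(manifest$x[b] + manifest$w[b])
    m <- matrix(stack$frames[rows, cols, 1, ], nrow = length(rows) * length(cols),
                ncol = T_len)
    m
  })
  means <- vapply(pixels, colMeans, numeric(T_len))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  structure(
    list(pixels = pixels, roles = manifest$role, boxes = manifest,
         means = means, fps = stack$fps, segment = stack$segment),
    class = "patch_series"
  )
}

#' Per-frame patch means in tidy form
#'
#' @param ps A `patch_series` from [extract_patches()].
#' @return A tibble with columns `frame`, `patch`, `role`, `mean`.
#' @export
patch_means <- function(ps) {
  stopifnot(inherits(ps, "patch_series"))
  T_len <- nrow(ps$means)
  tibble(
    frame = rep(seq_len(T_len), times = 8),
    patch = rep(seq_len(8), each = T_len),
    role = rep(ps$roles, each = T_len),
    mean = as.numeric(ps$means)
  )
}

#' Normalized spatio-temporal tensor expression profile
#'
#' Identifies the patches with the highest and lowest time-averaged mean
#' Red intensity (fixed once per segment, so patch identities cannot
#' switch frame to frame), forms the pixelwise difference matrix between
#' them, and z-scores every pixel row (zero mean, unit variance).
#' Zero-variance rows are flagged degenerate, imputed to zero, and counted
#' in a warning. The profile is invariant to patch order in the manifest
#' and to adding a constant to every pixel of every frame.
#'
#' @param ps A `patch_series` from [extract_patches()].
#' @param keep_raw Keep the raw (unstandardized) difference matrix
#'   (default FALSE).
#' @return An object of class `tensor_profile` with elements `P`
#'   (standardized pixels x frames matrix), `hi`/`lo` (patch indices),
#'   `row_mean`, `row_sd`, `degenerate` (logical per row),
#'   `mean_abs_diff` (mean absolute raw difference, the group-contrast
#'   summary), and `mean_series` (per-frame difference of patch means).
#' @export
tensor_profile <- function(ps, keep_raw = FALSE) {
  stopifnot(inherits(ps, "patch_series"))
  avg <- colMeans(ps$means)
  if (diff(range(avg)) == 0) {
    stop_rube("All patches have identical mean intensity.", "input")
  }
  hi <- which.max(avg)
  lo <- which.min(avg)
  D <- ps$pixels[[hi]] - ps$pixels[[lo]]
  row_mean <- rowMeans(D)
  row_sd <- apply(D, 1, sd)
  tol <- 1e-12 * max(1, max(abs(D)))
  degenerate <- row_sd <= tol
  P <- (D - row_mean) / ifelse(degenerate, 1, row_sd)
  if (any(degenerate)) {
    P[degenerate, ] <- 0
    warn(sprintf("%d degenerate (zero-variance) pixel rows imputed to zero.",
                 sum(degenerate)))
  }
  structure(
    list(P = P, hi = hi, lo = lo, row_mean = row_mean, row_sd = row_sd,
         degenerate = degenerate, mean_abs_diff = mean(abs(D)),
         mean_series = ps$means[, hi] - ps$means[, lo],
         raw = if (keep_raw) D else NULL,
         fps = ps$fps, segment = ps$segment),
    class = "tensor_profile"
  )
}

#' @export
print.tensor_profile <- function(x, ...) {
  cat(sprintf(
    "<tensor_profile> %d pixels x %d frames (hi patch %d, lo patch %d, %d degenerate rows)\n",
    nrow(x$P), ncol(x$P), x$hi, x$lo, sum(x$degenerate)
  ))
  invisible(x)
}

#' Write a tensor profile as CSV (pixels x frames)
#' @param tp A [tensor_profile].
#' @param path Output CSV path; a JSON sidecar `<path>.json` records
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(tp, path) {
  utils::write.table(tp$P, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(n_pixels = nrow(tp$P), n_frames = ncol(tp$P), fps = tp$fps,
         segment = tp$segment, hi = tp$hi, lo = tp$lo,
         mean_abs_diff = tp$mean_abs_diff),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a tensor profile from CSV
#' @param path CSV written by [write_profile_csv()].
#' @return A [tensor_profile] (metadata from the sidecar if present).
#' @export
read_profile_csv <- function(path) {
  P <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(P) <- NULL
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(
    list(P = P, hi = meta$hi %||% NA, lo = meta$lo %||% NA,
         row_mean = rowMeans(P), row_sd = apply(P, 1, sd),
         degenerate = apply(P, 1, sd) == 0,
         mean_abs_diff = meta$mean_abs_diff %||% NA_real_,
         mean_series = colMeans(P), raw = NULL,
         fps = meta$fps %||% NA, segment = meta$segment %||% NA),
    class = "tensor_profile"
  )
}
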