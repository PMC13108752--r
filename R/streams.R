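#' Keypoint stream containers
#'
#' Streams are tidy tibbles, one row per (frame, keypoint) observation, with
#' stream-level metadata stored in attributes.
#'
#' * `stream2d`: columns `frame` (0-based integer), `keypoint`, `u`, `v`
#'   (pixels; the origin is the top-left image corner, u rightward, v
#'   downward), `confidence` in \[0, 1\], `missing` (logical). Attributes:
#'   `camera_id`, `fps`, `resolution` (width, height in px).
#' * `stream3d`: columns `frame`, `keypoint`, `x`, `y`, `z` (mm),
#'   `confidence` (may be `NA` throughout, e.g. MoCap), `missing`.
#'   Attributes: `fps`, `coordinate_frame` (one of `"mocap"`, `"camera1"`,
#'   `"mono_raw"`, `"aligned"`).
#'
#' Missingness is always explicit via the `missing` flag; coordinates of
#' missing observations are `NA`, never sentinel values.
#'
#' @param df A data frame with the columns above.
#' @param camera_id Camera identifier.
#' @param fps Frame rate in Hz.
#' @param resolution Integer vector `c(width, height)` in pixels.
#' @param coordinate_frame Coordinate-frame tag for 3D streams.
#' @return A `stream2d` or `stream3d` tibble.
#' @export
stream2d <- function(df, camera_id, fps, resolution) {
  df <- as_tibble(df)
  need <- c("frame", "keypoint", "u", "v", "confidence", "missing")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("stream2d is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  stopifnot_scalar_num(fps, "fps", positive = TRUE)
  bad <- !df$missing & !is.na(df$confidence) &
    (df$confidence < 0 | df$confidence > 1)
  if (any(bad)) abort("Confidence values must lie in [0, 1].")
  df$missing <- as.logical(df$missing)
  df$frame <- as.integer(df$frame)
  out <- df[order(df$frame, df$keypoint), need]
  structure(out,
            camera_id = camera_id, fps = fps,
            resolution = as.integer(resolution),
            class = c("stream2d", class(tibble())))
}

#' @rdname stream2d
#' @export
stream3d <- function(df, fps, coordinate_frame = c("mocap", "camera1", "mono_raw", "aligned")) {
  coordinate_frame <- match.arg(coordinate_frame)
  df <- as_tibble(df)
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  need <- c("frame", "keypoint", "x", "y", "z", "confidence", "missing")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("stream3d is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  stopifnot_scalar_num(fps, "fps", positive = TRUE)
  present <- !df$missing
  if (any(present & (!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))) {
    abort("Non-missing 3D coordinates must be finite.")
  }
  df$missing <- as.logical(df$missing)
  df$frame <- as.integer(df$frame)
  out <- df[order(df$frame, df$keypoint), need]
  structure(out,
            fps = fps, coordinate_frame = coordinate_frame,
            class = c("stream3d", class(tibble())))
}

stream_meta <- function(stream) {
  attributes(stream)[intersect(names(attributes(stream)),
                               c("camera_id", "fps", "resolution", "coordinate_frame"))]
}

# Rebuild `df` as a stream carrying `template`'s metadata/class.
restore_stream_attrs <- function(df, template) {
  m <- stream_meta(template)
  if (inherits(template, "stream2d")) {
    stream2d(df, camera_id = m$camera_id, fps = m$fps, resolution = m$resolution)
  } else {
    stream3d(df, fps = m$fps, coordinate_frame = m$coordinate_frame)
  }
}

#' @export
print.stream2d <- function(x, ...) {
  cat(sprintf("<stream2d> camera %s, %d frames x %d keypoints @ %g fps, %dx%d px\n",
              format(attr(x, "camera_id")), stream_n_frames(x),
              stream_n_keypoints(x), attr(x, "fps"),
              attr(x, "resolution")[1], attr(x, "resolution")[2]))
  NextMethod()
}

#' @export
print.stream3d <- function(x, ...) {
  cat(sprintf("<stream3d> frame '%s', %d frames x %d keypoints @ %g fps\n",
              attr(x, "coordinate_frame"), stream_n_frames(x),
              stream_n_keypoints(x), attr(x, "fps")))
  NextMethod()
}

#' Stream dimensions
#' @param stream A `stream2d` or `stream3d`.
#' @return Integer count.
#' @export
stream_n_frames <- function(stream) {
  if (nrow(stream) == 0L) return(0L)
  length(unique(stream$frame))
}

#' @rdname stream_n_frames
#' @export
stream_n_keypoints <- function(stream) {
  if (nrow(stream) == 0L) return(0L)
  length(unique(stream$keypoint))
}

canonicalize_stream <- function(stream) {
  df <- as_tibble(stream)
  df$keypoint <- factor(as.character(df$keypoint), levels = target_keypoints())
  if (anyNA(df$keypoint)) abort("Stream contains keypoints outside the target set.")
  restore_stream_attrs(df, stream)
}

# frames x keypoints matrix of one stream column; assumes canonical sorting
# (frame-major, keypoint within frame) enforced by the constructors.
st_mat <- function(stream, col) {
  nk <- stream_n_keypoints(stream)
  nf <- stream_n_frames(stream)
  m <- matrix(stream[[col]], nrow = nk, ncol = nf)
  t(m)
}

# Inverse of st_mat for building target-keypoint streams from per-coordinate
# frame x 13 matrices.
stream3d_from_mats <- function(x, y, z, fps, coordinate_frame,
                               confidence = NULL, missing = NULL) {
  nf <- nrow(x); nk <- ncol(x)
  kp <- factor(rep(target_keypoints()[seq_len(nk)], times = nf),
               levels = target_keypoints())
  if (is.null(missing)) missing <- matrix(FALSE, nf, nk)
  df <- tibble(
    frame = rep(seq_len(nf) - 1L, each = nk),
    keypoint = kp,
    x = as.vector(t(x)), y = as.vector(t(y)), z = as.vector(t(z)),
    confidence = if (is.null(confidence)) NA_real_ else as.vector(t(confidence)),
    missing = as.vector(t(missing))
  )
  df$x[df$missing] <- NA_real_
  df$y[df$missing] <- NA_real_
  df$z[df$missing] <- NA_real_
  stream3d(df, fps = fps, coordinate_frame = coordinate_frame)
}

stream2d_from_mats <- function(u, v, confidence, missing, camera_id, fps, resolution) {
  nf <- nrow(u); nk <- ncol(u)
  df <- tibble(
    frame = rep(seq_len(nf) - 1L, each = nk),
    keypoint = factor(rep(target_keypoints()[seq_len(nk)], times = nf),
                      levels = target_keypoints()),
    u = as.vector(t(u)), v = as.vector(t(v)),
    confidence = as.vector(t(confidence)),
    missing = as.vector(t(missing))
  )
  df$u[df$missing] <- NA_real_
  df$v[df$missing] <- NA_real_
  df$confidence[df$missing] <- NA_real_
  stream2d(df, camera_id = camera_id, fps = fps, resolution = resolution)
}

fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "null"
  out
}

#' Read and write keypoint stream files
#'
#' Two plain-text interchange formats are supported:
#'
#' * `json2d`: a JSON array with one object per frame; keys are keypoint
#'   names (or 0-based source indices as strings), values are
#'   `[u, v, confidence]`, with `null` for a missing observation. This
#'   mirrors common pose-estimator JSON exports; camera metadata travels
#'   separately (reader arguments / `meta.json` side files).
#' * `csv3d`: long-format CSV with columns
#'   `frame, keypoint, x_mm, y_mm, z_mm, confidence, missing`.
#'
#' Writing then reading reproduces the stream exactly (integers bit-exact,
#' floats to within 1e-9 relative).
#'
#' @param path File path.
#' @param stream Stream to write.
#' @param camera_id,fps,resolution Metadata attached on read (`json2d`).
#' @param coordinate_frame Coordinate-frame tag attached on read (`csv3d`).
#' @return The read stream, or (invisibly) `path` for writers.
#' @export
read_stream2d <- function(path, camera_id = "cam", fps = 30,
                          resolution = c(1920L, 1080L)) {
  frames <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(frames) == 0L) {
    return(stream2d(tibble(frame = integer(), keypoint = character(),
                           u = double(), v = double(),
                           confidence = double(), missing = logical()),
                    camera_id = camera_id, fps = fps, resolution = resolution))
  }
  kp_names <- names(frames[[1]])
  rows <- purrr::imap(frames, function(fr, i) {
    if (!identical(sort(names(fr)), sort(kp_names))) {
      abort(sprintf("Frame %d has inconsistent keypoint names.", i - 1L))
    }
    vals <- lapply(kp_names, function(k) {
      v <- fr[[k]]
      if (is.null(v) || length(v) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      if (length(v) != 3L) {
        abort(sprintf("Frame %d keypoint '%s': expected [u, v, confidence].",
                      i - 1L, k))
      }
      vapply(v, function(el) if (is.null(el)) NA_real_ else as.numeric(el), 0)
    })
    m <- do.call(rbind, vals)
    tibble(frame = i - 1L, keypoint = kp_names,
           u = m[, 1], v = m[, 2], confidence = m[, 3],
           missing = is.na(m[, 1]))
  })
  df <- bind_rows(rows)
  if (all(df$keypoint %in% target_keypoints())) {
    df$keypoint <- factor(df$keypoint, levels = target_keypoints())
  }
  stream2d(df, camera_id = camera_id, fps = fps, resolution = resolution)
}

#' @rdname read_stream2d
#' @export
write_stream2d <- function(stream, path) {
  nf <- stream_n_frames(stream)
  if (nf == 0L) {
    writeLines("[]", path)
    return(invisible(path))
  }
  kp <- as.character(stream$keypoint[seq_len(stream_n_keypoints(stream))])
  entry <- ifelse(
    stream$missing,
    paste0("\"", as.character(stream$keypoint), "\":null"),
    paste0("\"", as.character(stream$keypoint), "\":[",
           fmt_num(stream$u), ",", fmt_num(stream$v), ",",
           fmt_num(stream$confidence), "]")
  )
  nk <- length(kp)
  per_frame <- vapply(split(entry, rep(seq_len(nf), each = nk)),
                      paste, character(1), collapse = ",")
  body <- paste0("{", per_frame, "}")
  writeLines(c("[", paste0(body, c(rep(",", nf - 1L), "")), "]"), path)
  invisible(path)
}

#' @rdname read_stream2d
#' @export
read_stream3d <- function(path, fps = 100,
                          coordinate_frame = c("mocap", "camera1", "mono_raw", "aligned")) {
  coordinate_frame <- match.arg(coordinate_frame)
  df <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), keypoint = readr::col_character(),
    x_mm = readr::col_double(), y_mm = readr::col_double(),
    z_mm = readr::col_double(), confidence = readr::col_double(),
    missing = readr::col_logical()
  ))
  bad <- !df$missing & (is.na(df$x_mm) | is.na(df$y_mm) | is.na(df$z_mm))
  if (any(bad)) {
    abort(sprintf("Malformed csv3d record: missing coordinate at frame %d (row %d).",
                  df$frame[which(bad)[1]], which(bad)[1]))
  }
  counts <- table(df$frame)
  if (length(unique(counts)) > 1L) {
    abort(sprintf("Inconsistent keypoint count across frames (first offender: frame %s).",
                  names(counts)[which(counts != counts[1])[1]]))
  }
  df <- rename(df, x = "x_mm", y = "y_mm", z = "z_mm")
  if (all(df$keypoint %in% target_keypoints())) {
    df$keypoint <- factor(df$keypoint, levels = target_keypoints())
  }
  stream3d(df, fps = fps, coordinate_frame = coordinate_frame)
}

#' @rdname read_stream2d
#' @export
write_stream3d <- function(stream, path) {
  df <- tibble(
    frame = stream$frame,
    keypoint = as.character(stream$keypoint),
    x_mm = stream$x, y_mm = stream$y, z_mm = stream$z,
    confidence = stream$confidence, missing = stream$missing
  )
  lines <- paste(df$frame, df$keypoint, fmt_num(df$x_mm), fmt_num(df$y_mm),
                 fmt_num(df$z_mm), fmt_num(df$confidence),
                 ifelse(df$missing, "TRUE", "FALSE"), sep = ",")
  lines <- gsub("null", "", lines, fixed = TRUE)
  writeLines(c("frame,keypoint,x_mm,y_mm,z_mm,confidence,missing", lines), path)
  invisible(path)
}
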