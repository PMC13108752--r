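#' Validity configuration
#'
#' A (frame, keypoint) observation counts as valid only when the MoCap
#' reference detected it AND every participating HPE method reports a
#' confidence at or above the threshold `tau` (ties at exactly `tau` are
#' valid).
#'
#' @param confidence_threshold Threshold `tau` in \[0, 1\]; 0.3 by default.
#' @return A `validity_config`.
#' @export
validity_config <- function(confidence_threshold = 0.3) {
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    abort("`confidence_threshold` must lie in [0, 1].")
  }
  structure(list(confidence_threshold = confidence_threshold),
            class = "validity_config")
}

#' Trim a stream to its clapperboard span and analysis margins
#'
#' Keeps the content strictly between the two clap frames (the clap frames
#' themselves are excluded), then removes `margin_s` seconds from each end of
#' the retained span, since the experimenter is visible near the claps. Clap
#' frames in the metadata are video-frame indices; for streams at other rates
#' (MoCap) they are rescaled by the frame-rate ratio. Frame indices are
#' re-zeroed in the output.
#'
#' @param stream A `stream2d` or `stream3d`.
#' @param meta A `session_meta`.
#' @return The trimmed stream.
#' @export
trim_to_claps <- function(stream, meta) {
  fps <- attr(stream, "fps")
  scale <- fps / meta$video_fps
  cs <- round(meta$clap_start_frame * scale)
  ce <- round(meta$clap_end_frame * scale)
  nf <- stream_n_frames(stream)
  if (cs < 0 || ce > nf - 1L) abort("Clap frames fall outside the stream.")
  m <- round(meta$margin_s * fps)
  lo <- cs + 1L + m
  hi <- ce - 1L - m
  if (lo > hi) abort("Empty sequence: margins exhaust the clap-to-clap span.")
  df <- as_tibble(stream)
  df <- df[df$frame >= lo & df$frame <= hi, , drop = FALSE]
  df$frame <- df$frame - lo
  restore_stream_attrs(df, stream)
}

#' Uniformly downsample a stream to a target frame count
#'
#' Nearest-index selection: frame `i` of the output (0-based, `i = 0..T-1`)
#' is source frame `round(i * (N - 1) / (T - 1))`, so both endpoints are
#' preserved and no interpolation is invented. Missing flags are carried
#' through. An interpolating variant is available for sensitivity checks.
#'
#' @param stream A `stream3d` (typically the 100 fps MoCap reference).
#' @param target_frames Output frame count `T` (`2 <= T <= N`).
#' @param target_fps Frame rate recorded on the output (default: scaled).
#' @param method `"nearest"` (default) or `"linear"` interpolation in time.
#' @return A `stream3d` with `target_frames` frames.
#' @export
downsample_uniform <- function(stream, target_frames, target_fps = NULL,
                               method = c("nearest", "linear")) {
  method <- match.arg(method)
  N <- stream_n_frames(stream)
  T_ <- as.integer(target_frames)
  if (T_ > N) abort("Cannot downsample: target exceeds source frame count.")
  if (T_ < 2L) abort("Need at least 2 target frames.")
  fps_out <- target_fps %||% (attr(stream, "fps") * (T_ - 1) / (N - 1))
  if (method == "nearest") {
    idx <- round((seq_len(T_) - 1) * (N - 1) / (T_ - 1))
    df <- as_tibble(stream)
    df <- df[df$frame %in% idx, , drop = FALSE]
    df$frame <- match(df$frame, idx) - 1L
  } else {
    pos <- (seq_len(T_) - 1) * (N - 1) / (T_ - 1)
    lo <- pmin(floor(pos), N - 2); w <- pos - lo
    dfs <- as_tibble(stream)
    get <- function(col, fr) {
      m <- matrix(dfs[[col]], nrow = stream_n_keypoints(stream))
      t(m)[fr + 1L, , drop = FALSE]
    }
    interp <- function(col) (1 - w) * get(col, lo) + w * get(col, lo + 1L)
    missing <- get("missing", round(pos)) |
      (get("missing", lo) | get("missing", lo + 1L)) & (w > 0 & w < 1)
    return(stream3d_from_mats(interp("x"), interp("y"), interp("z"),
                              fps = fps_out,
                              coordinate_frame = attr(stream, "coordinate_frame"),
                              missing = missing))
  }
  out <- restore_stream_attrs(df, stream)
  attr(out, "fps") <- fps_out
  out
}

#' Build the joint validity mask
#'
#' Conjunction over streams sharing a frame grid: a (frame, keypoint) cell is
#' valid iff the MoCap keypoint is present (not lost) and every method stream
#' is present with confidence at or above the threshold. Streams without
#' confidence values (e.g. a noiseless reference) only contribute their
#' missing flags.
#'
#' @param mocap The reference `stream3d`, already downsampled to the shared
#'   frame grid.
#' @param methods Named list of method `stream3d`s on the same grid.
#' @param cfg A `validity_config`.
#' @return A `validity_mask` tibble `(frame, keypoint, valid)` with a
#'   `provenance` attribute naming the intersected streams.
#' @export
build_validity_mask <- function(mocap, methods, cfg = validity_config()) {
  nf <- stream_n_frames(mocap)
  for (m in methods) {
    if (stream_n_frames(m) != nf || nrow(m) != nrow(mocap)) {
      abort("Frame-count mismatch between MoCap and a method stream.")
    }
  }
  tau <- cfg$confidence_threshold
  valid <- !mocap$missing
  for (m in methods) {
    ok <- !m$missing
    conf_ok <- is.na(m$confidence) | m$confidence >= tau
    valid <- valid & ok & conf_ok
  }
  structure(tibble(frame = mocap$frame, keypoint = mocap$keypoint,
                   valid = valid),
            provenance = c("mocap", names(methods) %||% rep("", length(methods))),
            class = c("validity_mask", class(tibble())))
}

#' Estimate the monocular scale from the tape-measured arm segment
#'
#' Monocular 3D streams have no absolute scale, so the participant's right
#' elbow-shoulder distance, measured physically with a tape measure, anchors
#' it: `s = tape_length_mm / mean(valid per-frame ||elbow_R - shoulder_R||)`.
#' Only frames where both keypoints are valid contribute.
#'
#' @param mono A `stream3d` (or list of them, pooled) in the raw monocular
#'   frame.
#' @param mask Matching `validity_mask` (or list).
#' @param tape_length_mm Physical segment length, mm.
#' @return Scalar scale `s`.
#' @export
estimate_scale <- function(mono, mask, tape_length_mm) {
  monos <- if (inherits(mono, "stream3d")) list(mono) else mono
  masks <- if (inherits(mask, "validity_mask")) list(mask) else mask
  lens <- unlist(purrr::map2(monos, masks, function(st, mk) {
    E <- st[st$keypoint == "elbow_right", ]
    S <- st[st$keypoint == "shoulder_right", ]
    vE <- mk$valid[mk$keypoint == "elbow_right"]
    vS <- mk$valid[mk$keypoint == "shoulder_right"]
    ok <- vE & vS
    sqrt((E$x[ok] - S$x[ok])^2 + (E$y[ok] - S$y[ok])^2 + (E$z[ok] - S$z[ok])^2)
  }))
  if (length(lens) == 0L) {
    abort("Scale estimation failed: no frame has both right elbow and shoulder valid.")
  }
  tape_length_mm / mean(lens)
}

#' Alignment parameters for one (participant, method)
#'
#' @param participant_id,method_id Identifiers.
#' @param transform A `rigid_transform` mapping the (scaled) method frame
#'   into the MoCap frame.
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(participant_id, method_id, transform) {
  structure(list(participant_id = participant_id, method_id = method_id,
                 transform = transform), class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf("<alignment_params> participant %s, method %s\n",
              format(x$participant_id), format(x$method_id)))
  print(x$transform)
  invisible(x)
}

#' Read or write alignment parameters as JSON
#' @param path File path.
#' @param params An `alignment_params`.
#' @export
write_alignment <- function(params, path) {
  jsonlite::write_json(list(
    participant = params$participant_id, method = params$method_id,
    s = params$transform$s, R = as.vector(t(params$transform$R)),
    t = params$transform$t
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  o <- jsonlite::fromJSON(path)
  alignment_params(o$participant, o$method,
                   rigid_transform(R = matrix(o$R, 3, 3, byrow = TRUE),
                                   t = o$t, s = o$s))
}

#' Fit the spatial alignment of a method stream onto MoCap
#'
#' Applies the scale `s`, stacks every valid (frame, keypoint) pair across
#' the supplied sequences as one 3D correspondence (all pairs weighted
#' equally), and solves for the least-squares rigid transform with
#' [rigid_fit()]. One transform is estimated per (participant, method) from
#' all of that participant's sequences jointly.
#'
#' @param method A `stream3d` or list of them (one per sequence).
#' @param mocap Matching reference `stream3d`(s) on the same frame grids.
#' @param mask Matching `validity_mask`(s).
#' @param s Scale applied to the method stream before fitting (1 for stereo
#'   methods; tape-measure estimate for monocular).
#' @param participant_id,method_id Recorded on the result.
#' @return An `alignment_params`.
#' @export
fit_alignment <- function(method, mocap, mask, s = 1,
                          participant_id = NA, method_id = NA) {
  ms <- if (inherits(method, "stream3d")) list(method) else method
  rs <- if (inherits(mocap, "stream3d")) list(mocap) else mocap
  ks <- if (inherits(mask, "validity_mask")) list(mask) else mask
  P <- list(); Q <- list()
  for (i in seq_along(ms)) {
    v <- ks[[i]]$valid
    P[[i]] <- cbind(ms[[i]]$x[v], ms[[i]]$y[v], ms[[i]]$z[v])
    Q[[i]] <- cbind(rs[[i]]$x[v], rs[[i]]$y[v], rs[[i]]$z[v])
  }
  P <- do.call(rbind, P); Q <- do.call(rbind, Q)
  keep <- stats::complete.cases(P) & stats::complete.cases(Q)
  P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
  if (nrow(P) < 3L) abort("Degenerate fit: fewer than 3 valid correspondences.")
  tf <- rigid_fit(s * P, Q)
  alignment_params(participant_id, method_id,
                   rigid_transform(R = tf$R, t = tf$t, s = s))
}

#' Apply alignment parameters to a stream
#'
#' Maps each point as `x -> R (s x) + t`; confidence and missing flags are
#' preserved. The result is tagged with the `"aligned"` coordinate frame.
#'
#' @param method A `stream3d`.
#' @param params An `alignment_params` (or bare `rigid_transform`).
#' @return A `stream3d` in the aligned (MoCap) frame.
#' @export
apply_alignment <- function(method, params) {
  tf <- if (inherits(params, "alignment_params")) params$transform else params
  df <- as_tibble(method)
  ok <- !df$missing
  pts <- apply_rigid(cbind(df$x[ok], df$y[ok], df$z[ok]), tf)
  df$x[ok] <- pts[, 1]; df$y[ok] <- pts[, 2]; df$z[ok] <- pts[, 3]
  stream3d(df, fps = attr(method, "fps"), coordinate_frame = "aligned")
}
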