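#' Pinhole camera parameters
#'
#' Standard pinhole model with the 5-coefficient radial–tangential distortion
#' (k1, k2, p1, p2, k3). Extrinsics map world coordinates into the camera
#' frame: `x_cam = R %*% x_world + t`. The world frame is the reference
#' camera's frame (right-handed, z forward, units mm), so a reference camera
#' has `R = I`, `t = 0`.
#'
#' @param camera_id Identifier.
#' @param fx,fy Focal lengths in px (> 0).
#' @param cx,cy Principal point in px.
#' @param dist Length-5 numeric `(k1, k2, p1, p2, k3)`.
#' @param R 3x3 orthonormal rotation, det +1 (tolerance 1e-9).
#' @param t Length-3 translation, mm.
#' @param width,height Image size in px.
#' @return A `camera_params` object.
#' @export
camera_params <- function(camera_id, fx, fy, cx, cy,
                          dist = rep(0, 5), R = diag(3), t = c(0, 0, 0),
                          width = 1920L, height = 1080L) {
  stopifnot_scalar_num(fx, "fx", positive = TRUE)
  stopifnot_scalar_num(fy, "fy", positive = TRUE)
  if (length(dist) != 5L) abort("`dist` must be (k1, k2, p1, p2, k3).")
  R <- matrix(as.numeric(R), 3, 3)
  check_rotation(R)
  structure(list(camera_id = camera_id, fx = fx, fy = fy, cx = cx, cy = cy,
                 dist = as.numeric(dist), R = R, t = as.numeric(t),
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_params")
}

check_rotation <- function(R, tol = 1e-9) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("Rotation must be orthonormal with determinant +1.")
  }
  invisible(R)
}

#' @export
print.camera_params <- function(x, ...) {
  cat(sprintf("<camera_params> %s: f=(%.1f, %.1f) c=(%.1f, %.1f) %dx%d px\n",
              format(x$camera_id), x$fx, x$fy, x$cx, x$cy, x$width, x$height))
  invisible(x)
}

#' Read or write a camera parameter file
#'
#' JSON layout: `{camera_id, fx, fy, cx, cy, dist: [k1,k2,p1,p2,k3],
#' R: 9 floats row-major, t: [mm,mm,mm], width, height}`.
#'
#' @param path File path.
#' @param cam A `camera_params`.
#' @export
read_camera <- function(path) {
  o <- jsonlite::fromJSON(path)
  camera_params(o$camera_id, o$fx, o$fy, o$cx, o$cy, dist = o$dist,
                R = matrix(o$R, 3, 3, byrow = TRUE), t = o$t,
                width = o$width, height = o$height)
}

#' @rdname read_camera
#' @export
write_camera <- function(cam, path) {
  o <- list(camera_id = cam$camera_id, fx = cam$fx, fy = cam$fy,
            cx = cam$cx, cy = cam$cy, dist = cam$dist,
            R = as.vector(t(cam$R)), t = cam$t,
            width = cam$width, height = cam$height)
  jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

camera_center <- function(cam) as.vector(-crossprod(cam$R, cam$t))

# Forward distortion on normalized coordinates (n x 2 matrix).
distort_normalized <- function(xy, dist) {
  x <- xy[, 1]; y <- xy[, 2]
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- x * x + y * y
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
  yd <- y * radial + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
  cbind(xd, yd)
}

# Inverse distortion by fixed-point iteration: 20 iterations or
# max-change < 1e-12, whichever first.
undistort_normalized <- function(xyd, dist) {
  if (all(dist == 0)) return(xyd)
  x <- xyd[, 1]; y <- xyd[, 2]
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  for (i in seq_len(20L)) {
    r2 <- x * x + y * y
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
    dy <- p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
    x_new <- (xyd[, 1] - dx) / radial
    y_new <- (xyd[, 2] - dy) / radial
    delta <- suppressWarnings(max(abs(x_new - x), abs(y_new - y), na.rm = TRUE))
    x <- x_new; y <- y_new
    if (!is.finite(delta) || delta < 1e-12) break
  }
  cbind(x, y)
}

#' Project 3D world points through a camera
#'
#' Full pinhole model: world-to-camera rigid transform, perspective divide,
#' radial + tangential distortion, then intrinsic mapping to pixels.
#'
#' @param points An n x 3 matrix (or length-3 vector) of world points, mm.
#' @param cam A `camera_params`.
#' @param behind One of `"error"` (points with camera-frame depth z <= 0 are
#'   an error) or `"na"` (they project to `NA`, for vectorised rendering).
#' @return An n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
#' @examples
#' cam <- camera_params("ref", 1000, 1000, 960, 540)
#' project_points(c(0, 0, 1000), cam)  # on the optical axis -> (960, 540)
project_points <- function(points, cam, behind = c("error", "na")) {
  behind <- match.arg(behind)
  P <- to_mat3(points)
  Xc <- P %*% t(cam$R) + matrix(cam$t, nrow(P), 3, byrow = TRUE)
  z <- Xc[, 3]
  bad <- z <= 0 | !is.finite(z)
  if (any(bad, na.rm = TRUE) && behind == "error") {
    abort("Point(s) at or behind the camera plane (z <= 0).")
  }
  z[bad] <- NA_real_
  xy <- cbind(Xc[, 1] / z, Xc[, 2] / z)
  xyd <- distort_normalized(xy, cam$dist)
  cbind(u = cam$fx * xyd[, 1] + cam$cx,
        v = cam$fy * xyd[, 2] + cam$cy)
}

to_mat3 <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) abort("Expected a 3-vector or n x 3 matrix.")
    matrix(points, 1, 3)
  } else {
    if (ncol(points) != 3L) abort("Expected an n x 3 matrix.")
    as.matrix(points)
  }
}

# Undistorted normalized coordinates from pixel observations (n x 2).
pixels_to_normalized <- function(uv, cam) {
  xyd <- cbind((uv[, 1] - cam$cx) / cam$fx, (uv[, 2] - cam$cy) / cam$fy)
  undistort_normalized(xyd, cam$dist)
}

# Vectorised two-view DLT triangulation in the w = 1 least-squares gauge.
# x1, y1, x2, y2: undistorted normalized coordinates (vectors). Returns list
# with n x 3 matrix `X` (reference frame) and logical `degenerate`.
triangulate_normalized <- function(x1, y1, x2, y2, cam1, cam2,
                                   cond_tol = 1e-10) {
  # Rows of A X = b, from x ~ P X with P = [R | t] on normalized coords:
  #   (x * R3 - R1) X = t1 - x * t3   (and same for y, per camera)
  make_row <- function(s, R, t, i) {
    list(a1 = s * R[3, 1] - R[i, 1],
         a2 = s * R[3, 2] - R[i, 2],
         a3 = s * R[3, 3] - R[i, 3],
         b = t[i] - s * t[3])
  }
  r1 <- make_row(x1, cam1$R, cam1$t, 1L)
  r2 <- make_row(y1, cam1$R, cam1$t, 2L)
  r3 <- make_row(x2, cam2$R, cam2$t, 1L)
  r4 <- make_row(y2, cam2$R, cam2$t, 2L)
  # Normal equations M X = rhs with M = A'A (3x3 symmetric per point).
  m11 <- r1$a1^2 + r2$a1^2 + r3$a1^2 + r4$a1^2
  m12 <- r1$a1 * r1$a2 + r2$a1 * r2$a2 + r3$a1 * r3$a2 + r4$a1 * r4$a2
  m13 <- r1$a1 * r1$a3 + r2$a1 * r2$a3 + r3$a1 * r3$a3 + r4$a1 * r4$a3
  m22 <- r1$a2^2 + r2$a2^2 + r3$a2^2 + r4$a2^2
  m23 <- r1$a2 * r1$a3 + r2$a2 * r2$a3 + r3$a2 * r3$a3 + r4$a2 * r4$a3
  m33 <- r1$a3^2 + r2$a3^2 + r3$a3^2 + r4$a3^2
  b1 <- r1$a1 * r1$b + r2$a1 * r2$b + r3$a1 * r3$b + r4$a1 * r4$b
  b2 <- r1$a2 * r1$b + r2$a2 * r2$b + r3$a2 * r3$b + r4$a2 * r4$b
  b3 <- r1$a3 * r1$b + r2$a3 * r2$b + r3$a3 * r3$b + r4$a3 * r4$b
  det3 <- m11 * (m22 * m33 - m23^2) -
    m12 * (m12 * m33 - m23 * m13) +
    m13 * (m12 * m23 - m22 * m13)
  scale3 <- pmax(m11, m22, m33)^3
  degenerate <- !is.finite(det3) | abs(det3) <= cond_tol * scale3
  inv_det <- ifelse(degenerate, NA_real_, 1 / det3)
  # Cramer's rule on the symmetric system.
  X <- ((m22 * m33 - m23^2) * b1 + (m13 * m23 - m12 * m33) * b2 +
          (m12 * m23 - m13 * m22) * b3) * inv_det
  Y <- ((m13 * m23 - m12 * m33) * b1 + (m11 * m33 - m13^2) * b2 +
          (m12 * m13 - m11 * m23) * b3) * inv_det
  Z <- ((m12 * m23 - m13 * m22) * b1 + (m12 * m13 - m11 * m23) * b2 +
          (m11 * m22 - m12^2) * b3) * inv_det
  list(X = cbind(X, Y, Z), degenerate = degenerate)
}

#' Triangulate one stereo observation pair
#'
#' Undistorts the two pixel observations to normalized coordinates and solves
#' the two-view DLT linear system by least squares. The fused confidence is
#' the lower of the two per-camera confidences, reflecting that a keypoint
#' poorly seen by either camera yields an unreliable 3D estimate.
#'
#' @param obs1,obs2 Length-3 vectors `(u, v, confidence)`, or `NULL`/`NA` for
#'   a missing observation.
#' @param cam1,cam2 `camera_params` with distinct centers.
#' @return A list with `point` (3-vector, mm, reference-camera frame),
#'   `confidence`, and `missing` (TRUE when either observation is absent).
#' @export
triangulate_pair <- function(obs1, obs2, cam1, cam2) {
  if (is.null(obs1) || is.null(obs2) || anyNA(obs1[1:2]) || anyNA(obs2[1:2])) {
    return(list(point = c(NA_real_, NA_real_, NA_real_),
                confidence = NA_real_, missing = TRUE))
  }
  if (sqrt(sum((camera_center(cam1) - camera_center(cam2))^2)) < 1e-9) {
    abort("Degenerate geometry: coincident camera centers.")
  }
  n1 <- pixels_to_normalized(matrix(obs1[1:2], 1, 2), cam1)
  n2 <- pixels_to_normalized(matrix(obs2[1:2], 1, 2), cam2)
  tri <- triangulate_normalized(n1[, 1], n1[, 2], n2[, 1], n2[, 2], cam1, cam2)
  if (tri$degenerate[1]) {
    abort("Degenerate geometry: rays numerically parallel.")
  }
  list(point = as.vector(tri$X[1, ]),
       confidence = min(obs1[3], obs2[3]),
       missing = FALSE)
}

#' Triangulate two calibrated 2D streams into a 3D stream
#'
#' Applies [triangulate_pair()]'s model to every (frame, keypoint) pair in one
#' vectorised pass. Observations missing in either camera, or with degenerate
#' geometry, are flagged missing in the output; fused confidence is the
#' per-pair minimum.
#'
#' @param s1,s2 `stream2d` objects with identical frames and keypoints.
#' @param cam1,cam2 Their `camera_params`.
#' @return A `stream3d` in the reference-camera frame (`"camera1"`), at the
#'   video frame rate.
#' @export
triangulate_streams <- function(s1, s2, cam1, cam2) {
  if (nrow(s1) != nrow(s2) || !all(s1$frame == s2$frame)) {
    abort("Streams must share frames and keypoints for triangulation.")
  }
  if (sqrt(sum((camera_center(cam1) - camera_center(cam2))^2)) < 1e-9) {
    abort("Degenerate geometry: coincident camera centers.")
  }
  ok <- !s1$missing & !s2$missing
  n1 <- pixels_to_normalized(cbind(s1$u, s1$v), cam1)
  n2 <- pixels_to_normalized(cbind(s2$u, s2$v), cam2)
  tri <- triangulate_normalized(n1[, 1], n1[, 2], n2[, 1], n2[, 2], cam1, cam2)
  missing <- !ok | tri$degenerate
  df <- tibble(
    frame = s1$frame, keypoint = s1$keypoint,
    x = ifelse(missing, NA_real_, tri$X[, 1]),
    y = ifelse(missing, NA_real_, tri$X[, 2]),
    z = ifelse(missing, NA_real_, tri$X[, 3]),
    confidence = ifelse(missing, NA_real_, pmin(s1$confidence, s2$confidence)),
    missing = missing
  )
  stream3d(df, fps = attr(s1, "fps"), coordinate_frame = "camera1")
}

#' Midpoint-method triangulation (cross-check)
#'
#' Independent geometric alternative to the DLT solve: intersects the two
#' back-projected rays by taking the midpoint of their common perpendicular.
#' Intended for validating the DLT path, not as the primary method.
#'
#' @inheritParams triangulate_pair
#' @return 3-vector, mm, reference-camera frame.
#' @export
triangulate_midpoint <- function(obs1, obs2, cam1, cam2) {
  n1 <- pixels_to_normalized(matrix(obs1[1:2], 1, 2), cam1)
  n2 <- pixels_to_normalized(matrix(obs2[1:2], 1, 2), cam2)
  c1 <- camera_center(cam1); c2 <- camera_center(cam2)
  d1 <- as.vector(crossprod(cam1$R, c(n1[1, ], 1)))
  d2 <- as.vector(crossprod(cam2$R, c(n2[1, ], 1)))
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  w0 <- c1 - c2
  a <- 1; b <- sum(d1 * d2); cc <- 1
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  denom <- a * cc - b * b
  if (abs(denom) < 1e-15) abort("Degenerate geometry: parallel rays.")
  s <- (b * e - cc * d) / denom
  tt <- (a * e - b * d) / denom
  (c1 + s * d1 + c2 + tt * d2) / 2
}

#' Root-mean-square re-projection error
#'
#' Quality metric for calibration and triangulation: RMS pixel distance
#' between observed 2D points and the projections of their 3D counterparts.
#'
#' @param points n x 3 matrix of 3D points, mm.
#' @param obs n x 2 matrix of observed pixel coordinates.
#' @param cam A `camera_params`.
#' @return RMS error in px.
#' @export
reprojection_rms <- function(points, obs, cam) {
  P <- to_mat3(points)
  obs <- as.matrix(obs)
  if (nrow(P) < 1L) abort("Need at least one point.")
  if (nrow(P) != nrow(obs)) abort("`points` and `obs` lengths differ.")
  proj <- project_points(P, cam)
  sqrt(mean((proj[, 1] - obs[, 1])^2 + (proj[, 2] - obs[, 2])^2))
}
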