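# Small deterministic fixtures shared across test files. All data are built
# in code; nothing is read from disk except what a test itself writes.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2L, n_sequences = 2L, duration_s = 16,
         margin_s = 2, seed = 42L),
    list(...)
  )
  do.call(sim_config, args)
}

# A convergent stereo pair: reference camera plus a second camera translated
# along x by `baseline` mm and toed in by `toe_deg`.
test_cam_pair <- function(baseline = 200, toe_deg = 0, dist2 = rep(0, 5)) {
  cam1 <- camera_params("c1", 1000, 1000, 960, 540)
  ang <- toe_deg * pi / 180
  R2 <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  cam2 <- camera_params("c2", 1000, 1000, 960, 540, dist = dist2,
                        R = R2, t = as.vector(-R2 %*% c(baseline, 0, 0)))
  list(cam1 = cam1, cam2 = cam2)
}

rand_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random 13-keypoint 3D stream on a canonical grid.
rand_stream3d <- function(nf = 5, fps = 30, frame_tag = "camera1",
                          conf = NA_real_) {
  stream3d(tibble::tibble(
    frame = rep(seq_len(nf) - 1L, each = 13L),
    keypoint = factor(rep(target_keypoints(), nf), levels = target_keypoints()),
    x = rnorm(nf * 13, 0, 500), y = rnorm(nf * 13, 0, 500),
    z = rnorm(nf * 13, 2000, 300),
    confidence = if (is.na(conf)) NA_real_ else conf,
    missing = FALSE
  ), fps = fps, coordinate_frame = frame_tag)
}

# Random 2D stream over arbitrary source indices (0-based), e.g. for schema
# mapping tests.
rand_stream2d <- function(nf = 3, nk = 13, fps = 30, kp = NULL) {
  kp <- kp %||% factor(target_keypoints(), levels = target_keypoints())
  stream2d(tibble::tibble(
    frame = rep(seq_len(nf) - 1L, each = nk),
    keypoint = rep(kp, nf),
    u = runif(nf * nk, 0, 1920), v = runif(nf * nk, 0, 1080),
    confidence = runif(nf * nk),
    missing = FALSE
  ), camera_id = "t", fps = fps, resolution = c(1920L, 1080L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_true_mask <- function(stream) {
  structure(tibble::tibble(frame = stream$frame, keypoint = stream$keypoint,
                           valid = TRUE),
            class = c("validity_mask", class(tibble::tibble())))
}
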