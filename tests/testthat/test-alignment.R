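make_meta <- function(cs, ce, margin_s = 5) {
  session_meta(1, 1, cs, ce, video_fps = 30, mocap_fps = 100,
               margin_s = margin_s)
}

const_stream <- function(nf, fps = 30, frame_tag = "camera1") {
  stream3d(tibble::tibble(
    frame = rep(seq_len(nf) - 1L, each = 13L),
    keypoint = factor(rep(target_keypoints(), nf), levels = target_keypoints()),
    x = 1, y = 2, z = 3, confidence = NA_real_, missing = FALSE
  ), fps = fps, coordinate_frame = frame_tag)
}

test_that("clap trimming follows the exclusive-clap + margin convention", {
  # 70 s at 30 fps: frames 0..2100; claps at 0 and 2100; exclusive claps
  # keep 1..2099 (2099 frames), minus 150-frame margins -> 1799 frames.
  s <- const_stream(2101)
  out <- trim_to_claps(s, make_meta(0, 2100))
  expect_equal(stream_n_frames(out), 2101 - 2 - 2 * 150)
  expect_equal(min(out$frame), 0L)  # re-zeroed
  # margin 0: clap-to-clap content unchanged
  out0 <- trim_to_claps(s, make_meta(0, 2100, margin_s = 0))
  expect_equal(stream_n_frames(out0), 2099)
  expect_error(trim_to_claps(const_stream(200), make_meta(0, 199)),
               "margins exhaust")
})

test_that("trimming the synthetic session recovers the analysed content span", {
  cfg <- tiny_cfg()
  b <- simulate_session(cfg, 1, 1)
  tr <- trim_to_claps(b$ground_truth, b$meta)
  expect_equal(stream_n_frames(tr),
               (cfg$duration_s - 2 * cfg$margin_s) * cfg$video_fps)
  # the retained values are exactly a contiguous slice of the source
  first <- b$meta$clap_start_frame + 1L + cfg$margin_s * cfg$video_fps
  src <- b$ground_truth[b$ground_truth$frame == first, c("x", "y", "z")]
  expect_equal(tr[tr$frame == 0L, c("x", "y", "z")], src, ignore_attr = TRUE)
  # MoCap trimming scales clap indices by the frame-rate ratio
  trm <- trim_to_claps(b$mocap, b$meta)
  expect_equal(stream_n_frames(trm) / stream_n_frames(tr), 100 / 30,
               tolerance = 0.01)
})

test_that("uniform downsampling selects round(i(N-1)/(T-1)) with endpoints kept", {
  s <- const_stream(7)
  df <- tibble::as_tibble(s)
  df$x <- df$frame  # tag coordinates by source frame
  s <- stream3d(df, fps = 100, coordinate_frame = "mocap")
  out <- downsample_uniform(s, 3)
  expect_equal(unique(out$x), c(0, 3, 6))
  big <- const_stream(1000, fps = 100, frame_tag = "mocap")
  out2 <- downsample_uniform(big, 300, target_fps = 30)
  expect_equal(stream_n_frames(out2), 300L)
  expect_equal(attr(out2, "fps"), 30)
  same <- downsample_uniform(big, 1000)
  expect_equal(stream_n_frames(same), 1000L)
  expect_error(downsample_uniform(big, 2000), "exceeds")
})

test_that("downsampling carries missing flags through", {
  s <- const_stream(7, fps = 100, frame_tag = "mocap")
  df <- tibble::as_tibble(s)
  hit <- df$frame == 3L & df$keypoint == "chin"
  df$missing[hit] <- TRUE; df$x[hit] <- NA; df$y[hit] <- NA; df$z[hit] <- NA
  s <- stream3d(df, fps = 100, coordinate_frame = "mocap")
  out <- downsample_uniform(s, 3)
  expect_true(out$missing[out$frame == 1L & out$keypoint == "chin"])
})

test_that("validity requires MoCap presence and every method at or above tau", {
  set.seed(31)
  mocap <- rand_stream3d(nf = 4, frame_tag = "mocap")
  m1 <- rand_stream3d(nf = 4, conf = 1)
  df <- tibble::as_tibble(m1)
  df$confidence[1] <- 0.3     # exactly tau: valid
  df$confidence[2] <- 0.2999  # just below: invalid
  m1 <- stream3d(df, fps = 30, coordinate_frame = "camera1")
  dm <- tibble::as_tibble(mocap)
  dm$missing[3] <- TRUE; dm$x[3] <- NA; dm$y[3] <- NA; dm$z[3] <- NA
  mocap <- stream3d(dm, fps = 30, coordinate_frame = "mocap")
  mask <- build_validity_mask(mocap, list(m1 = m1), validity_config(0.3))
  expect_true(mask$valid[1])
  expect_false(mask$valid[2])
  expect_false(mask$valid[3])
  expect_true(all(mask$valid[-(1:3)]))
  # all confidences 1, no gaps -> all true
  full <- build_validity_mask(rand_stream3d(4, frame_tag = "mocap"),
                              list(a = rand_stream3d(4, conf = 1)))
  expect_true(all(full$valid))
  short <- rand_stream3d(nf = 3)
  expect_error(build_validity_mask(mocap, list(short)), "mismatch")
})

test_that("tape-measure scaling is the ratio of tape to mean valid segment length", {
  nf <- 5
  df <- tibble::tibble(
    frame = rep(seq_len(nf) - 1L, each = 13L),
    keypoint = factor(rep(target_keypoints(), nf), levels = target_keypoints()),
    x = 0, y = 0, z = 0, confidence = NA_real_, missing = FALSE
  )
  df$x[df$keypoint == "elbow_right"] <- 300  # constant 300 mm segment
  mono <- stream3d(df, fps = 30, coordinate_frame = "mono_raw")
  mask <- all_true_mask(mono)
  expect_equal(estimate_scale(mono, mask, 330), 1.1)
  # hidden premultiplied scale cancels exactly at zero noise
  k <- 0.83
  df2 <- df; df2$x <- df2$x * k
  mono2 <- stream3d(df2, fps = 30, coordinate_frame = "mono_raw")
  expect_equal(estimate_scale(mono2, mask, 300) * k, 1, tolerance = 1e-12)
  dead <- mask; dead$valid <- FALSE
  expect_error(estimate_scale(mono, dead, 330), "no frame")
})

test_that("alignment fitting recovers exact transforms and improves noisy ones", {
  set.seed(32)
  mocap <- rand_stream3d(nf = 10, frame_tag = "mocap")
  mask <- all_true_mask(mocap)
  idp <- fit_alignment(mocap, mocap, mask, s = 1)
  expect_lt(max(abs(idp$transform$R - diag(3))), 1e-9)
  expect_lt(max(abs(idp$transform$t)), 1e-9)
  # method = R0 mocap + t0: fit maps method back onto mocap
  R0 <- rand_rotation(); t0 <- c(10, 20, 30)
  dm <- tibble::as_tibble(mocap)
  pts <- cbind(dm$x, dm$y, dm$z) %*% t(R0) +
    matrix(t0, nrow(dm), 3, byrow = TRUE)
  dm$x <- pts[, 1]; dm$y <- pts[, 2]; dm$z <- pts[, 3]
  method <- stream3d(dm, fps = 30, coordinate_frame = "mono_raw")
  par <- fit_alignment(method, mocap, mask, s = 1)
  expect_lt(max(abs(par$transform$R - t(R0))), 1e-9)
  back <- apply_alignment(method, par)
  expect_lt(max(abs(back$x - mocap$x)), 1e-9)
  # with noise, alignment beats the identity transform
  dn <- dm
  dn$x <- dn$x + rnorm(nrow(dn), 0, 5)
  noisy <- stream3d(dn, fps = 30, coordinate_frame = "mono_raw")
  parn <- fit_alignment(noisy, mocap, mask, s = 1)
  e_fit <- mean(euclid_errors(apply_alignment(noisy, parn), mocap, mask)$e)
  e_id <- mean(euclid_errors(apply_alignment(noisy, rigid_transform()),
                             mocap, mask)$e)
  expect_lt(e_fit, e_id)
})

test_that("masked-out entries never influence the fitted parameters", {
  set.seed(33)
  mocap <- rand_stream3d(nf = 8, frame_tag = "mocap")
  method <- rand_stream3d(nf = 8)
  mask <- all_true_mask(mocap)
  mask$valid[sample(nrow(mask), 30)] <- FALSE
  p1 <- fit_alignment(method, mocap, mask, s = 1)
  dm <- tibble::as_tibble(method)
  dm$x[!mask$valid] <- dm$x[!mask$valid] + 1e6  # arbitrary corruption
  p2 <- fit_alignment(stream3d(dm, fps = 30, coordinate_frame = "camera1"),
                      mocap, mask, s = 1)
  expect_identical(p1$transform, p2$transform)
})

test_that("hidden scale and rotation are recovered within 1% / 0.1 deg at zero noise", {
  # static pose: no temporal-resampling mismatch, recovery is exact
  cfg0 <- tiny_cfg(pixel_noise_sd = 0, dropout_prob = 0, marker_offset_mm = 0,
                   mocap_loss_hazard = 0, mono_depth_noise_mm = 0,
                   mono_jitter_mm = 0, motion_amplitude = 0)
  rig <- scene_rig(cfg0)
  b <- simulate_session(cfg0, 1, 1, rig = rig)
  pr <- prepare_session(b, cfg0, rig = rig)
  mask <- build_validity_mask(pr$mocap, pr$methods)
  s <- estimate_scale(pr$methods$mono_a, mask, b$tape_length_mm)
  expect_equal(s * b$hidden$mono_scale[["mono_a"]], 1, tolerance = 0.01)
  par <- fit_alignment(pr$methods$tri_13, pr$mocap, mask, s = 1)
  Rerr <- par$transform$R %*% t(b$hidden$mocap_tf$R)
  angle <- acos(pmin(1, (sum(diag(Rerr)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 0.1)
  expect_lt(max(abs(par$transform$t - b$hidden$mocap_tf$t)), 1)
})

test_that("with motion, recovery degrades only by the 100-to-30 fps resampling mismatch", {
  cfg <- tiny_cfg(pixel_noise_sd = 0, dropout_prob = 0, marker_offset_mm = 0,
                  mocap_loss_hazard = 0, mono_depth_noise_mm = 0,
                  mono_jitter_mm = 0)
  rig <- scene_rig(cfg)
  b <- simulate_session(cfg, 1, 1, rig = rig)
  pr <- prepare_session(b, cfg, rig = rig)
  mask <- build_validity_mask(pr$mocap, pr$methods)
  s <- estimate_scale(pr$methods$mono_a, mask, b$tape_length_mm)
  expect_equal(s * b$hidden$mono_scale[["mono_a"]], 1, tolerance = 0.01)
  par <- fit_alignment(pr$methods$tri_13, pr$mocap, mask, s = 1)
  Rerr <- par$transform$R %*% t(b$hidden$mocap_tf$R)
  angle <- acos(pmin(1, (sum(diag(Rerr)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 0.1)
  # nearest-index timestamps differ by up to 5 ms; wrists move ~1 m/s
  expect_lt(max(abs(par$transform$t - b$hidden$mocap_tf$t)), 5)
})

test_that("alignment parameters round-trip through JSON", {
  tf <- rigid_transform(R = rand_rotation(), t = c(1.5, -2, 3), s = 1.07)
  par <- alignment_params(3, "mono_a", tf)
  path <- withr::local_tempfile(fileext = ".json")
  write_alignment(par, path)
  got <- read_alignment(path)
  expect_equal(got$participant_id, 3)
  expect_equal(got$method_id, "mono_a")
  expect_equal(got$transform$R, tf$R, tolerance = 1e-12)
  expect_equal(got$transform$t, tf$t, tolerance = 1e-12)
  expect_equal(got$transform$s, tf$s, tolerance = 1e-12)
})
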