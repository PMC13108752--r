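#' Simulation configuration for synthetic gesture sessions
#'
#' Defines the study conditions the generator emulates: 10 participants each
#' describing 8 animated videos while recorded by three 1920x1080 @ 30 fps
#' cameras (one frontal, two diagonal) and a 100 fps optical MoCap system;
#' 13 upper-body keypoints; per-keypoint HPE confidence with occlusion-driven
#' degradation; a systematic anatomical marker-vs-keypoint offset; and
#' depth-degraded monocular 3D streams.
#'
#' @param n_participants,n_sequences,n_cameras Study design counts
#'   (defaults 10, 8, 3).
#' @param duration_s Gesture content per sequence, seconds (clap to clap,
#'   exclusive of padding).
#' @param video_fps,mocap_fps Frame rates, Hz.
#' @param pixel_noise_sd 2D detection noise, px.
#' @param conf_base,conf_noise_sd Baseline confidence level and jitter.
#' @param occlusion_penalty Confidence drop when a keypoint is geometrically
#'   occluded by the torso proxy.
#' @param dropout_prob Per (frame, keypoint) probability that an HPE detection
#'   is absent outright (independent dropout).
#' @param mocap_loss_hazard Per-frame hazard that a MoCap marker label is lost;
#'   once lost, the marker stays missing for the rest of the sequence
#'   (persistent dropout, emulating un-relabelled tracking failures).
#' @param marker_offset_mm Magnitude of the fixed outward anatomical offset
#'   between MoCap markers (on the skin, bone-referenced) and HPE keypoints
#'   (inside the body). A systematic bias, not noise: rigid alignment cannot
#'   fully remove it.
#' @param mono_depth_noise_mm SD of the shared per-frame depth wobble of
#'   monocular 3D streams along the frontal camera's optical axis.
#' @param mono_jitter_mm SD of the additional independent per-keypoint
#'   monocular noise (each axis).
#' @param bone_length_range_mm Range of the per-participant elbow-shoulder
#'   bone length, drawn uniformly.
#' @param motion_amplitude Scale factor on all motion harmonics (0 freezes the
#'   pose).
#' @param clap_pad_s Padding before the first and after the last clap, s.
#' @param margin_s Margin excluded from each end of the clap-to-clap span, s.
#' @param seed Base seed; every random draw derives deterministically from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 10L, n_sequences = 8L, n_cameras = 3L,
                       duration_s = 60, video_fps = 30, mocap_fps = 100,
                       pixel_noise_sd = 2, conf_base = 0.92,
                       conf_noise_sd = 0.04, occlusion_penalty = 0.7,
                       dropout_prob = 1e-3, mocap_loss_hazard = 2e-5,
                       marker_offset_mm = 10, mono_depth_noise_mm = 150,
                       mono_jitter_mm = 20,
                       bone_length_range_mm = c(260, 320),
                       motion_amplitude = 1,
                       clap_pad_s = 2, margin_s = 5, seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_sequences = as.integer(n_sequences),
    n_cameras = as.integer(n_cameras),
    duration_s = duration_s, video_fps = video_fps, mocap_fps = mocap_fps,
    pixel_noise_sd = pixel_noise_sd, conf_base = conf_base,
    conf_noise_sd = conf_noise_sd, occlusion_penalty = occlusion_penalty,
    dropout_prob = dropout_prob, mocap_loss_hazard = mocap_loss_hazard,
    marker_offset_mm = marker_offset_mm,
    mono_depth_noise_mm = mono_depth_noise_mm,
    mono_jitter_mm = mono_jitter_mm,
    bone_length_range_mm = bone_length_range_mm,
    motion_amplitude = motion_amplitude,
    clap_pad_s = clap_pad_s, margin_s = margin_s, seed = as.integer(seed)
  )
  rates <- c(cfg$dropout_prob, cfg$mocap_loss_hazard)
  if (any(rates < 0 | rates > 1)) abort("Rates must lie in [0, 1].")
  if (any(c(cfg$duration_s, cfg$video_fps, cfg$mocap_fps) <= 0)) {
    abort("Durations and frame rates must be > 0.")
  }
  if (cfg$n_cameras != 3L) abort("The camera rig is defined for 3 cameras.")
  structure(cfg, class = "sim_config")
}

#' Session metadata
#'
#' @param participant_id,sequence_id Identifiers (sequence in 1..8 for the
#'   default design).
#' @param clap_start_frame,clap_end_frame 0-based video frame indices of the
#'   two clapperboard strikes; content lies strictly between them.
#' @param video_fps,mocap_fps Frame rates.
#' @param margin_s Analysis margin excluded from each end.
#' @return A `session_meta` list.
#' @export
session_meta <- function(participant_id, sequence_id, clap_start_frame,
                         clap_end_frame, video_fps = 30, mocap_fps = 100,
                         margin_s = 5) {
  if (clap_start_frame >= clap_end_frame) abort("clap_start must precede clap_end.")
  structure(list(participant_id = participant_id, sequence_id = sequence_id,
                 clap_start_frame = as.integer(clap_start_frame),
                 clap_end_frame = as.integer(clap_end_frame),
                 video_fps = video_fps, mocap_fps = mocap_fps,
                 margin_s = margin_s),
            class = "session_meta")
}

# ---- camera rig and coordinate frames --------------------------------------

look_at_rotation <- function(pos, target) {
  f <- target - pos; f <- f / sqrt(sum(f^2))
  d0 <- c(0, -1, 0)  # desired image-down is world-down (scene y is up)
  r <- pracma_cross(d0, f); r <- r / sqrt(sum(r^2))
  d <- pracma_cross(f, r)
  rbind(r, d, f)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default three-camera rig and reference frames
#'
#' Builds the simulated recording geometry: camera 2 directly in front of the
#' participant and cameras 1 and 3 diagonally in front (+/- 35 degrees), all
#' 3 m away at shoulder height, focal length 1500 px at 1920x1080 with mild
#' radial-tangential distortion. Extrinsics are expressed relative to camera 1
#' (the reference: identity rotation, zero translation), and the returned
#' `scene_to_world` transform maps the body-centred scene frame into the
#' camera-1 world frame. `mocap_tf` is the hidden world-to-MoCap-frame rigid
#' transform that the alignment stage must recover.
#'
#' @param config A `sim_config`.
#' @return List with `cameras` (list of 3 `camera_params`), `scene_to_world`
#'   and `mocap_tf` (`rigid_transform`s).
#' @export
scene_rig <- function(config = sim_config()) {
  target <- c(0, 400, 0)
  dist <- 3000
  azimuths <- c(-35, 0, 35) * pi / 180  # cameras 1, 2, 3
  scene_cams <- lapply(azimuths, function(a) {
    pos <- c(dist * sin(a), 500, dist * cos(a))
    R <- look_at_rotation(pos, target)
    list(R = R, t = as.vector(-R %*% pos))
  })
  ref <- scene_cams[[1]]
  cameras <- lapply(seq_along(scene_cams), function(i) {
    sc <- scene_cams[[i]]
    Rrel <- sc$R %*% t(ref$R)
    trel <- sc$t - as.vector(Rrel %*% ref$t)
    camera_params(paste0("cam", i), fx = 1500, fy = 1500, cx = 960, cy = 540,
                  dist = c(-0.05, 0.01, 5e-4, -3e-4, 2e-3),
                  R = Rrel, t = trel, width = 1920L, height = 1080L)
  })
  ang <- 25 * pi / 180
  Rm <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)), 3, 3)
  list(
    cameras = cameras,
    scene_to_world = rigid_transform(R = ref$R, t = ref$t),
    mocap_tf = rigid_transform(R = Rm, t = c(400, -200, 600))
  )
}

# ---- motion synthesis ------------------------------------------------------

# Smooth random signal: sum of 2-5 harmonics in 0.2-2 Hz, peak ~ amp.
harmonic_signal <- function(t, amp) {
  if (amp == 0) return(rep(0, length(t)))
  nh <- sample(2:5, 1)
  f <- runif(nh, 0.2, 2)
  phi <- runif(nh, 0, 2 * pi)
  A <- runif(nh, 0.3, 1)
  A <- A / sum(A) * amp
  out <- numeric(length(t))
  for (i in seq_len(nh)) out <- out + A[i] * sin(2 * pi * f[i] * t + phi[i])
  out
}

participant_profile <- function(config, participant) {
  with_substream(config$seed, "participant", participant, expr = {
    L1 <- runif(1, config$bone_length_range_mm[1], config$bone_length_range_mm[2])
    list(
      upper_arm_mm = L1,
      forearm_mm = 0.92 * L1,
      thumb_mm = 80,
      middle_mm = 110,
      tape_length_mm = L1
    )
  })
}

#' Generate ground-truth skeletal motion for one session
#'
#' Synthesises smooth 13-keypoint upper-body motion: a static pelvis anchor
#' with small whole-body sway, near-rigid shoulders and face, and arms driven
#' through the shoulder-elbow-wrist-fingertip chain by sums of 2-5 random
#' harmonics (0.2-2 Hz) on the joint angles, so segment lengths are constant
#' by construction (the elbow-shoulder distance equals the participant's
#' drawn bone length exactly). Deterministic given (seed, participant,
#' sequence). Output covers the full recorded span including clap padding, at
#' video fps, in the camera-1 world frame.
#'
#' @param config A `sim_config`.
#' @param participant,sequence Ids.
#' @return A `stream3d` (coordinate frame `"camera1"`).
#' @export
generate_motion <- function(config, participant, sequence) {
  rig <- scene_rig(config)
  prof <- participant_profile(config, participant)
  fps <- config$video_fps
  nf <- round((2 * config$clap_pad_s + config$duration_s) * fps)
  t <- (seq_len(nf) - 1) / fps
  amp <- config$motion_amplitude

  kp <- target_keypoints()
  X <- matrix(0, nf, 13); Y <- matrix(0, nf, 13); Z <- matrix(0, nf, 13)
  colnames(X) <- colnames(Y) <- colnames(Z) <- kp
  set_kp <- function(name, m) {
    X[, name] <<- m[, 1]; Y[, name] <<- m[, 2]; Z[, name] <<- m[, 3]
  }

  with_substream(config$seed, "motion", participant, sequence, expr = {
    sway <- cbind(harmonic_signal(t, 15 * amp),
                  harmonic_signal(t, 6 * amp),
                  harmonic_signal(t, 15 * amp))
    bob <- cbind(harmonic_signal(t, 8 * amp),
                 harmonic_signal(t, 8 * amp),
                 harmonic_signal(t, 8 * amp))
    for (name in c("shoulder_right", "shoulder_left")) {
      off <- if (name == "shoulder_right") c(170, 480, 0) else c(-170, 480, 0)
      set_kp(name, sweep(sway, 2, off, "+"))
    }
    # face: rigid offsets from a head centre, rotated by a slow yaw so the
    # cheeks alternately face and turn away from the diagonal cameras
    yaw <- harmonic_signal(t, 0.45 * amp)
    head_ctr <- sweep(sway + bob, 2, c(0, 640, 60), "+")
    face_off <- list(cheek_right = c(55, 0, 0), cheek_left = c(-55, 0, 0),
                     chin = c(0, -50, 20))
    for (name in names(face_off)) {
      o <- face_off[[name]]
      rot <- cbind(o[1] * cos(yaw) + o[3] * sin(yaw),
                   rep(o[2], nf),
                   -o[1] * sin(yaw) + o[3] * cos(yaw))
      set_kp(name, head_ctr + rot)
    }
    for (side in c("right", "left")) {
      sgn <- if (side == "right") 1 else -1
      S <- cbind(X[, paste0("shoulder_", side)],
                 Y[, paste0("shoulder_", side)],
                 Z[, paste0("shoulder_", side)])
      el1 <- 0.95 + harmonic_signal(t, 0.55 * amp)
      az1 <- sgn * 0.30 + harmonic_signal(t, 0.70 * amp)
      u <- cbind(sin(el1) * sin(az1), -cos(el1), sin(el1) * cos(az1))
      E <- S + prof$upper_arm_mm * u
      el2 <- 1.35 + harmonic_signal(t, 0.50 * amp)
      az2 <- az1 + harmonic_signal(t, 0.60 * amp)
      v <- cbind(sin(el2) * sin(az2), cos(el2), sin(el2) * cos(az2))
      W <- E + prof$forearm_mm * v
      elm <- el2 + harmonic_signal(t, 0.30 * amp)
      azm <- az2 + harmonic_signal(t, 0.35 * amp)
      wm <- cbind(sin(elm) * sin(azm), cos(elm), sin(elm) * cos(azm))
      elt <- el2 + 0.35 + harmonic_signal(t, 0.30 * amp)
      azt <- az2 - sgn * 0.45 + harmonic_signal(t, 0.35 * amp)
      wt <- cbind(sin(elt) * sin(azt), cos(elt), sin(elt) * cos(azt))
      set_kp(paste0("elbow_", side), E)
      set_kp(paste0("wrist_", side), W)
      set_kp(paste0("thumb_", side), W + prof$thumb_mm * wt)
      set_kp(paste0("middle_", side), W + prof$middle_mm * wm)
    }
  })

  # scene -> camera-1 world frame
  pts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  w <- apply_rigid(pts, rig$scene_to_world)
  dim_w <- function(i) matrix(w[, i], nf, 13)
  stream3d_from_mats(dim_w(1), dim_w(2), dim_w(3),
                     fps = fps, coordinate_frame = "camera1")
}

# Geometric visibility proxies, per camera. Three mechanisms, all driven by
# pose so that low-confidence events correlate with what the participant is
# doing (as in real HPE), never drawn independently at random:
#   * torso capsule (pelvis-neck segment, sampled as spheres): hides arm and
#     hand keypoints that pass behind the body as seen from a diagonal view;
#   * hand self-occlusion: a fingertip pointing away from the camera is
#     hidden behind the hand itself;
#   * face orientation: a cheek whose outward normal points away from the
#     camera is on the far side of the head.
# Shoulders lie on the torso outline and are never occluded (they are
# detected in every frame). Returns an nf x 13 logical matrix.
occluded_from_camera <- function(Xw, Yw, Zw, sway_world, rig, cam) {
  nf <- nrow(Xw)
  kp <- target_keypoints()
  C <- camera_center(cam)
  occ <- matrix(FALSE, nf, 13)
  colnames(occ) <- kp
  dX <- Xw - C[1]; dY <- Yw - C[2]; dZ <- Zw - C[3]
  len2 <- dX^2 + dY^2 + dZ^2
  base <- apply_rigid(rbind(c(0, 80, 0), c(0, 480, 0)), rig$scene_to_world)
  radius <- 140
  arm_cols <- match(c("elbow_right", "elbow_left", "wrist_right", "wrist_left",
                      "thumb_right", "thumb_left", "middle_right", "middle_left"), kp)
  for (l in seq(0, 1, length.out = 5)) {
    ctr <- base[1, ] + l * (base[2, ] - base[1, ])
    sx <- sway_world[, 1] + ctr[1] - C[1]
    sy <- sway_world[, 2] + ctr[2] - C[2]
    sz <- sway_world[, 3] + ctr[3] - C[3]
    dot <- dX * sx + dY * sy + dZ * sz
    tt <- dot / len2
    d2 <- (tt * dX - sx)^2 + (tt * dY - sy)^2 + (tt * dZ - sz)^2
    s2 <- sx^2 + sy^2 + sz^2
    hit <- d2 < radius^2 & tt > 0 & tt < 1 & s2 < len2 - radius^2
    occ[, arm_cols] <- occ[, arm_cols] | hit[, arm_cols]
  }
  rayward <- function(col, nx, ny, nz) {
    # cos angle between the outward direction and the camera->point ray
    nl <- sqrt(nx^2 + ny^2 + nz^2)
    rl <- sqrt(len2[, col])
    (nx * dX[, col] + ny * dY[, col] + nz * dZ[, col]) / (nl * rl)
  }
  for (side in c("right", "left")) {
    w <- match(paste0("wrist_", side), kp)
    for (part in c("thumb", "middle")) {
      f <- match(paste0(part, "_", side), kp)
      ca <- rayward(f, Xw[, f] - Xw[, w], Yw[, f] - Yw[, w], Zw[, f] - Zw[, w])
      occ[, f] <- occ[, f] | ca > 0.4
    }
  }
  cR <- match("cheek_right", kp); cL <- match("cheek_left", kp)
  ch <- match("chin", kp)
  fcx <- (Xw[, cR] + Xw[, cL]) / 2
  fcy <- (Yw[, cR] + Yw[, cL]) / 2
  fcz <- (Zw[, cR] + Zw[, cL]) / 2
  for (col in c(cR, cL, ch)) {
    ca <- rayward(col, Xw[, col] - fcx, Yw[, col] - fcy, Zw[, col] - fcz)
    occ[, col] <- occ[, col] | ca > 0.65
  }
  occ
}

#' Render synthetic observations of a ground-truth motion stream
#'
#' Produces everything the real study recorded for one session:
#'
#' * `mocap`: the truth upsampled to MoCap fps (cubic spline in time),
#'   expressed in the MoCap system's own coordinate frame, with a fixed
#'   outward per-keypoint anatomical marker offset and persistent marker-loss
#'   dropout.
#' * `cam_streams`: per-camera 2D detections — exact projections plus
#'   Gaussian pixel noise, with confidence values that drop when the keypoint
#'   is geometrically occluded by a torso capsule, and occasional independent
#'   dropout. Keypoints behind a camera are flagged missing.
#' * `mono_streams`: two depth-degraded monocular 3D streams (`mono_a`,
#'   `mono_b`) in the frontal-camera frame, each multiplied by a hidden
#'   per-participant scale drawn from U(0.8, 1.25) and corrupted by a shared
#'   per-frame depth wobble plus small per-keypoint jitter.
#'
#' @param truth A `stream3d` from [generate_motion()].
#' @param config A `sim_config`.
#' @param participant,sequence Ids (select the deterministic substreams).
#' @param rig Optional `scene_rig()` result (rebuilt if omitted).
#' @return A `session_bundle` list with elements `ground_truth`, `mocap`,
#'   `cam_streams`, `mono_streams`, `meta`, `tape_length_mm`, and `hidden`
#'   (the simulation's concealed transforms/scales, for validation).
#' @export
render_observations <- function(truth, config, participant, sequence,
                                rig = NULL) {
  if (stream_n_frames(truth) == 0L) abort("`truth` must be nonempty.")
  rig <- rig %||% scene_rig(config)
  prof <- participant_profile(config, participant)
  nf <- stream_n_frames(truth)
  fps <- config$video_fps
  Xw <- st_mat(truth, "x"); Yw <- st_mat(truth, "y"); Zw <- st_mat(truth, "z")
  t_v <- (seq_len(nf) - 1) / fps

  # --- MoCap reference -------------------------------------------------------
  nm <- floor((nf - 1) * config$mocap_fps / fps) + 1L
  t_m <- (seq_len(nm) - 1) / config$mocap_fps
  up <- function(M) {
    apply(M, 2, function(col) splinefun(t_v, col, method = "natural")(t_m))
  }
  Xm <- up(Xw); Ym <- up(Yw); Zm <- up(Zw)
  torso_w <- apply_rigid(c(0, 280, 0), rig$scene_to_world)
  mean_pos <- cbind(colMeans(Xw), colMeans(Yw), colMeans(Zw))
  off_dir <- sweep(mean_pos, 2, torso_w)
  off_dir <- off_dir / sqrt(rowSums(off_dir^2))
  offsets <- config$marker_offset_mm * off_dir
  Xm <- sweep(Xm, 2, offsets[, 1], "+")
  Ym <- sweep(Ym, 2, offsets[, 2], "+")
  Zm <- sweep(Zm, 2, offsets[, 3], "+")
  pts_m <- apply_rigid(cbind(as.vector(Xm), as.vector(Ym), as.vector(Zm)),
                       rig$mocap_tf)
  miss_m <- with_substream(config$seed, "mocaploss", participant, sequence, expr = {
    m <- matrix(FALSE, nm, 13)
    if (config$mocap_loss_hazard > 0) {
      for (k in 1:13) {
        u <- runif(1)
        # first-loss frame from the geometric hazard
        first <- ceiling(log(u) / log(1 - config$mocap_loss_hazard))
        if (is.finite(first) && first <= nm) m[first:nm, k] <- TRUE
      }
    }
    m
  })
  mocap <- stream3d_from_mats(matrix(pts_m[, 1], nm, 13),
                              matrix(pts_m[, 2], nm, 13),
                              matrix(pts_m[, 3], nm, 13),
                              fps = config$mocap_fps, coordinate_frame = "mocap",
                              missing = miss_m)

  # --- per-camera 2D streams -------------------------------------------------
  sway_w <- matrix(0, nf, 3)  # sway is baked into keypoints; capsule follows
  # the torso: approximate its per-frame displacement by the shoulder
  # midpoint's deviation from its mean.
  shoulder_mid <- cbind((Xw[, 1] + Xw[, 2]) / 2, (Yw[, 1] + Yw[, 2]) / 2,
                        (Zw[, 1] + Zw[, 2]) / 2)
  sway_w <- sweep(shoulder_mid, 2, colMeans(shoulder_mid))
  pts_w <- cbind(as.vector(Xw), as.vector(Yw), as.vector(Zw))
  cam_streams <- lapply(seq_along(rig$cameras), function(ci) {
    cam <- rig$cameras[[ci]]
    uv <- project_points(pts_w, cam, behind = "na")
    U <- matrix(uv[, 1], nf, 13); V <- matrix(uv[, 2], nf, 13)
    occ <- occluded_from_camera(Xw, Yw, Zw, sway_w, rig, cam)
    with_substream(config$seed, "camera", ci, participant, sequence, expr = {
      U <- U + matrix(rnorm(nf * 13, 0, config$pixel_noise_sd), nf, 13)
      V <- V + matrix(rnorm(nf * 13, 0, config$pixel_noise_sd), nf, 13)
      conf <- config$conf_base +
        matrix(rnorm(nf * 13, 0, config$conf_noise_sd), nf, 13) -
        config$occlusion_penalty * occ
      conf <- pmin(pmax(conf, 0.01), 1)
      miss <- matrix(runif(nf * 13) < config$dropout_prob, nf, 13) | is.na(U)
      stream2d_from_mats(U, V, conf, miss, camera_id = paste0("cam", ci),
                         fps = fps, resolution = c(cam$width, cam$height))
    })
  })
  names(cam_streams) <- paste0("cam", seq_along(cam_streams))

  # --- monocular 3D streams --------------------------------------------------
  cam2 <- rig$cameras[[2]]
  pts_c2 <- pts_w %*% t(cam2$R) + matrix(cam2$t, nrow(pts_w), 3, byrow = TRUE)
  mono_streams <- lapply(c("mono_a", "mono_b"), function(m) {
    k <- with_substream(config$seed, "mono_scale", participant, m,
                        expr = runif(1, 0.8, 1.25))
    with_substream(config$seed, m, participant, sequence, expr = {
      P <- k * pts_c2
      Xc <- matrix(P[, 1], nf, 13); Yc <- matrix(P[, 2], nf, 13)
      Zc <- matrix(P[, 3], nf, 13)
      Zc <- Zc + rnorm(nf, 0, config$mono_depth_noise_mm)  # shared depth wobble
      if (config$mono_jitter_mm > 0) {
        Xc <- Xc + matrix(rnorm(nf * 13, 0, config$mono_jitter_mm), nf, 13)
        Yc <- Yc + matrix(rnorm(nf * 13, 0, config$mono_jitter_mm), nf, 13)
        Zc <- Zc + matrix(rnorm(nf * 13, 0, config$mono_jitter_mm), nf, 13)
      }
      conf <- config$conf_base +
        matrix(rnorm(nf * 13, 0, config$conf_noise_sd), nf, 13)
      conf <- pmin(pmax(conf, 0.01), 1)
      miss <- matrix(runif(nf * 13) < config$dropout_prob, nf, 13)
      stream3d_from_mats(Xc, Yc, Zc, fps = fps, coordinate_frame = "mono_raw",
                         confidence = conf, missing = miss)
    })
  })
  names(mono_streams) <- c("mono_a", "mono_b")

  pad_f <- round(config$clap_pad_s * fps)
  meta <- session_meta(participant, sequence,
                       clap_start_frame = pad_f - 1L,
                       clap_end_frame = nf - pad_f,
                       video_fps = fps, mocap_fps = config$mocap_fps,
                       margin_s = config$margin_s)
  structure(list(
    ground_truth = truth, mocap = mocap, cam_streams = cam_streams,
    mono_streams = mono_streams, meta = meta,
    tape_length_mm = prof$tape_length_mm,
    hidden = list(
      mocap_tf = rig$mocap_tf,
      mono_scale = vapply(c("mono_a", "mono_b"), function(m) {
        with_substream(config$seed, "mono_scale", participant, m,
                       expr = runif(1, 0.8, 1.25))
      }, 0),
      marker_offsets = offsets
    )
  ), class = "session_bundle")
}

#' Simulate one complete session
#'
#' Convenience wrapper: [generate_motion()] followed by
#' [render_observations()].
#'
#' @inheritParams render_observations
#' @inheritParams generate_motion
#' @return A `session_bundle`.
#' @export
simulate_session <- function(config, participant, sequence, rig = NULL) {
  rig <- rig %||% scene_rig(config)
  truth <- generate_motion(config, participant, sequence)
  render_observations(truth, config, participant, sequence, rig = rig)
}

#' Generate the full synthetic study
#'
#' Runs [simulate_session()] over every participant x sequence cell of the
#' design (10 x 8 = 80 sessions by default). Fully deterministic under the
#' config seed.
#'
#' @param config A `sim_config`.
#' @return A list of `session_bundle`s, named `"p<participant>_s<sequence>"`.
#' @export
generate_study <- function(config = sim_config()) {
  rig <- scene_rig(config)
  out <- list()
  for (p in seq_len(config$n_participants)) {
    for (q in seq_len(config$n_sequences)) {
      out[[sprintf("p%d_s%d", p, q)]] <- simulate_session(config, p, q, rig = rig)
    }
  }
  out
}

#' Export a study to disk
#'
#' Layout: `root/participant_P/sequence_S/{cam1.json, cam2.json, cam3.json,
#' mocap.csv, mono_a_cam2.csv, mono_b_cam2.csv, meta.json}` plus
#' `cameras.json` and `config.yaml` at the root. With the default design this
#' writes one 2D stream file per camera per sequence: 10 x 8 x 3 = 240 files.
#'
#' @param study Result of [generate_study()].
#' @param config The `sim_config` used to generate it.
#' @param dir Output directory (created).
#' @return Invisibly, a character vector of all written file paths.
#' @export
export_study <- function(study, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rig <- scene_rig(config)
  files <- character()
  campath <- file.path(dir, "cameras.json")
  jsonlite::write_json(lapply(rig$cameras, function(cm) {
    list(camera_id = cm$camera_id, fx = cm$fx, fy = cm$fy, cx = cm$cx,
         cy = cm$cy, dist = cm$dist, R = as.vector(t(cm$R)), t = cm$t,
         width = cm$width, height = cm$height)
  }), campath, auto_unbox = TRUE, digits = NA)
  files <- c(files, campath)
  cfgpath <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfgpath)
  files <- c(files, cfgpath)
  for (nm in names(study)) {
    b <- study[[nm]]
    sdir <- file.path(dir, sprintf("participant_%s", b$meta$participant_id),
                      sprintf("sequence_%s", b$meta$sequence_id))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (ci in names(b$cam_streams)) {
      p <- file.path(sdir, paste0(ci, ".json"))
      write_stream2d(b$cam_streams[[ci]], p)
      files <- c(files, p)
    }
    p <- file.path(sdir, "mocap.csv")
    write_stream3d(b$mocap, p); files <- c(files, p)
    for (mi in names(b$mono_streams)) {
      p <- file.path(sdir, paste0(mi, "_cam2.csv"))
      write_stream3d(b$mono_streams[[mi]], p); files <- c(files, p)
    }
    p <- file.path(sdir, "meta.json")
    jsonlite::write_json(unclass(b$meta)[c("participant_id", "sequence_id",
                                           "clap_start_frame", "clap_end_frame",
                                           "video_fps", "mocap_fps", "margin_s")],
                         p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  invisible(files)
}
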