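#' Prepare one session for evaluation
#'
#' Applies the temporal pipeline to a session bundle: clap trimming and
#' margin exclusion of every stream, confidence-gated stereo triangulation of
#' the camera pairs (the diagonal pair 1-3, `tri_13`, and pair 1-2,
#' `tri_12`), and uniform downsampling of the MoCap reference to the video
#' frame count.
#'
#' @param bundle A `session_bundle`.
#' @param config The `sim_config`.
#' @param rig A `scene_rig()` (rebuilt if omitted).
#' @return List with `mocap` (downsampled, trimmed) and `methods` (named list
#'   of method `stream3d`s: `tri_13`, `tri_12`, `mono_a`, `mono_b`).
#' @export
prepare_session <- function(bundle, config, rig = NULL) {
  rig <- rig %||% scene_rig(config)
  meta <- bundle$meta
  cams <- lapply(bundle$cam_streams, trim_to_claps, meta = meta)
  monos <- lapply(bundle$mono_streams, trim_to_claps, meta = meta)
  mocap <- trim_to_claps(bundle$mocap, meta)
  nf <- stream_n_frames(cams[[1]])
  mocap_ds <- downsample_uniform(mocap, nf, target_fps = meta$video_fps)
  methods <- list(
    tri_13 = triangulate_streams(cams[[1]], cams[[3]],
                                 rig$cameras[[1]], rig$cameras[[3]]),
    tri_12 = triangulate_streams(cams[[1]], cams[[2]],
                                 rig$cameras[[1]], rig$cameras[[2]]),
    mono_a = monos$mono_a,
    mono_b = monos$mono_b
  )
  list(mocap = mocap_ds, methods = methods)
}

method_is_mono <- function(m) grepl("^mono", m)

#' Run the full validation study in memory
#'
#' End-to-end evaluation under the configured study conditions: simulate
#' every session, triangulate the stereo pairs, build the joint validity mask
#' (MoCap present and every method at or above the confidence threshold),
#' estimate the monocular tape-measure scale and fit one rigid alignment per
#' (participant, method) pooled over all of that participant's sequences,
#' then compute the per-keypoint error table, per-group repeated-measures
#' ANOVAs with Bonferroni post-hoc comparisons, the stereo-vs-stereo
#' low-confidence breakdown, and the gesture-space Dice curve (first
#' participant, wrists, MoCap vs the diagonal stereo method).
#'
#' @param config A `sim_config`.
#' @param validity A `validity_config`.
#' @param voxel_sizes Voxel-size sweep for the Dice curve, mm.
#' @param alpha Significance level for post-hoc verdicts.
#' @return An `hpe_study` list: `errors`, `cell_means`, `participant_means`,
#'   `overall`, `anova`, `pairwise`, `breakdown`, `dice_curve`,
#'   `alignments`, `config`.
#' @export
run_validation_study <- function(config = sim_config(),
                                 validity = validity_config(),
                                 voxel_sizes = seq(10, 100, by = 10),
                                 alpha = 0.05) {
  rig <- scene_rig(config)
  err_rows <- list()
  align_rows <- list()
  conf_a <- list(); conf_b <- list()
  dice_mocap <- NULL; dice_method <- NULL
  for (p in seq_len(config$n_participants)) {
    preps <- lapply(seq_len(config$n_sequences), function(q) {
      b <- simulate_session(config, p, q, rig = rig)
      c(prepare_session(b, config, rig = rig),
        list(tape = b$tape_length_mm))
    })
    masks <- lapply(preps, function(pr) {
      build_validity_mask(pr$mocap, pr$methods, validity)
    })
    mocaps <- lapply(preps, `[[`, "mocap")
    tape <- preps[[1]]$tape
    for (m in names(preps[[1]]$methods)) {
      streams <- lapply(preps, function(pr) pr$methods[[m]])
      s <- if (method_is_mono(m)) estimate_scale(streams, masks, tape) else 1
      params <- fit_alignment(streams, mocaps, masks, s = s,
                              participant_id = p, method_id = m)
      align_rows[[paste(p, m)]] <- tibble(
        participant = p, method = m, s = params$transform$s,
        t_mm = sqrt(sum(params$transform$t^2))
      )
      for (q in seq_along(streams)) {
        aligned <- apply_alignment(streams[[q]], params)
        err_rows[[paste(p, m, q)]] <- euclid_errors(
          aligned, mocaps[[q]], masks[[q]],
          participant = p, method = m, sequence = q
        )
        if (p == 1L && m == "tri_13") {
          dice_mocap <- rbind(dice_mocap, wrist_points(mocaps[[q]], masks[[q]]))
          dice_method <- rbind(dice_method, wrist_points(aligned, masks[[q]]))
        }
      }
    }
    for (q in seq_along(preps)) {
      cols <- c("keypoint", "confidence", "missing")
      conf_a[[paste(p, q)]] <- as_tibble(preps[[q]]$methods$tri_13)[, cols]
      conf_b[[paste(p, q)]] <- as_tibble(preps[[q]]$methods$tri_12)[, cols]
    }
  }
  errors <- bind_rows(err_rows)
  class(errors) <- c("error_table", class(tibble()))
  dcurve <- dice_curve(dice_mocap, dice_method, voxel_sizes)
  report <- assemble_report(errors, dice_curve = dcurve, alpha = alpha)
  breakdown <- low_confidence_breakdown(bind_rows(conf_a), bind_rows(conf_b),
                                        tau = validity$confidence_threshold)
  structure(list(
    errors = errors,
    cell_means = report$cell_means,
    participant_means = aggregate_participant_means(errors)$participant_means,
    overall = report$overall,
    anova = report$anova,
    pairwise = report$pairwise,
    errors_summary = report$errors_summary,
    breakdown = breakdown,
    dice_curve = dcurve,
    alignments = bind_rows(align_rows),
    config = config
  ), class = "hpe_study")
}

#' @export
print.hpe_study <- function(x, ...) {
  cat(sprintf("<hpe_study> %d participants x %d sequences, %d error records\n",
              x$config$n_participants, x$config$n_sequences, nrow(x$errors)))
  cat("Overall mean error (mm) by method:\n")
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-8s %8.2f\n", ov$method[i], ov$mean_error_mm[i]))
  }
  d50 <- x$dice_curve$dice[x$dice_curve$voxel_size_mm == 50]
  if (length(d50)) cat(sprintf("Dice at 50 mm voxels: %.1f%%\n", 100 * d50))
  invisible(x)
}

#' @rdname hpeval-tidiers
#' @export
#' @method glance hpe_study
glance.hpe_study <- function(x, ...) {
  stereo <- x$overall$mean_error_mm[!method_is_mono(x$overall$method)]
  mono <- x$overall$mean_error_mm[method_is_mono(x$overall$method)]
  d50 <- x$dice_curve$dice[x$dice_curve$voxel_size_mm == 50]
  tibble(
    n_participants = x$config$n_participants,
    n_sequences = x$config$n_sequences,
    n_records = nrow(x$errors),
    mean_error_stereo_mm = mean(stereo),
    mean_error_mono_mm = mean(mono),
    dice_50mm = if (length(d50)) d50 else NA_real_
  )
}
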