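#' File-based pipeline stages
#'
#' The pipeline mirrors the analysis end to end with stages that communicate
#' only via files under one root directory, so every intermediate is
#' re-runnable and inspectable:
#'
#' 1. `pipeline_simulate()` — export the synthetic study
#'    (`root/study/`).
#' 2. `pipeline_triangulate()` — per-sequence confidence-gated stereo
#'    streams (`root/triangulated/`).
#' 3. `pipeline_align()` — per-(participant, method) alignment parameters and
#'    aligned streams (`root/aligned/`).
#' 4. `pipeline_evaluate()` — error table, low-confidence breakdown,
#'    occupancy sets and Dice curve (`root/evaluated/`).
#' 5. `pipeline_report()` — ANOVA/post-hoc CSVs and markdown report
#'    (`root/report/`).
#'
#' Every stage writes a `manifest.json` (config hash, seed, md5 of each
#' output) and refuses to run before its upstream stage, naming the stage to
#' run first. All outputs are deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @param root Pipeline root directory.
#' @param validity A `validity_config`.
#' @param voxel_sizes Dice-curve voxel sweep, mm.
#' @return Invisibly, the stage output directory.
#' @name pipeline
NULL

stage_dir <- function(root, stage) file.path(root, stage)

require_stage <- function(root, stage) {
  d <- stage_dir(root, stage)
  producer <- c(study = "simulate", triangulated = "triangulate",
                aligned = "align", evaluated = "evaluate",
                report = "report")[[stage]]
  if (!file.exists(file.path(d, "manifest.json"))) {
    abort(sprintf(
      "Missing upstream artifacts in '%s': run pipeline_%s() first.",
      d, producer))
  }
  d
}

write_manifest <- function(dir, config, files) {
  files <- files[file.exists(files)]
  md5 <- tools::md5sum(files)
  jsonlite::write_json(list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_files = length(files),
    files = as.list(setNames(unname(md5), basename(names(md5))))
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

seq_dirs <- function(dir) {
  list.files(dir, pattern = "^sequence_", recursive = TRUE,
             include.dirs = TRUE, full.names = TRUE)
}

rel_seq <- function(root_stage, sdir) {
  # participant_P/sequence_S relative path
  file.path(basename(dirname(sdir)), basename(sdir))
}

read_meta_file <- function(path) {
  o <- jsonlite::fromJSON(path)
  session_meta(o$participant_id, o$sequence_id, o$clap_start_frame,
               o$clap_end_frame, o$video_fps, o$mocap_fps, o$margin_s)
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, root) {
  d <- stage_dir(root, "study")
  study <- generate_study(config)
  files <- export_study(study, config, d)
  write_manifest(d, config, files)
  message(sprintf("[simulate] %d sessions, %d files -> %s",
                  length(study), length(files), d))
  invisible(d)
}

#' @rdname pipeline
#' @export
pipeline_triangulate <- function(config, root) {
  sd <- require_stage(root, "study")
  d <- stage_dir(root, "triangulated")
  cams <- lapply(jsonlite::fromJSON(file.path(sd, "cameras.json"),
                                    simplifyVector = FALSE),
                 function(o) camera_params(o$camera_id, o$fx, o$fy, o$cx, o$cy,
                                           dist = unlist(o$dist),
                                           R = matrix(unlist(o$R), 3, 3, byrow = TRUE),
                                           t = unlist(o$t),
                                           width = o$width, height = o$height))
  files <- character()
  for (sdir in seq_dirs(sd)) {
    rel <- rel_seq(sd, sdir)
    out <- file.path(d, rel)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    s1 <- read_stream2d(file.path(sdir, "cam1.json"), camera_id = "cam1",
                        fps = config$video_fps)
    s2 <- read_stream2d(file.path(sdir, "cam2.json"), camera_id = "cam2",
                        fps = config$video_fps)
    s3 <- read_stream2d(file.path(sdir, "cam3.json"), camera_id = "cam3",
                        fps = config$video_fps)
    for (pair in list(c("tri_13", 1, 3), c("tri_12", 1, 2))) {
      a <- list(s1, s2, s3)[[as.integer(pair[2])]]
      b <- list(s1, s2, s3)[[as.integer(pair[3])]]
      tri <- triangulate_streams(a, b, cams[[as.integer(pair[2])]],
                                 cams[[as.integer(pair[3])]])
      p <- file.path(out, paste0(pair[1], ".csv"))
      write_stream3d(tri, p)
      files <- c(files, p)
    }
  }
  write_manifest(d, config, files)
  message(sprintf("[triangulate] %d stereo streams -> %s", length(files), d))
  invisible(d)
}

load_prepared_participant <- function(config, root, pdir_name) {
  sd <- stage_dir(root, "study")
  td <- stage_dir(root, "triangulated")
  sdirs <- sort(list.files(file.path(sd, pdir_name), pattern = "^sequence_",
                           include.dirs = TRUE, full.names = TRUE))
  lapply(sdirs, function(sdir) {
    rel <- rel_seq(sd, sdir)
    meta <- read_meta_file(file.path(sdir, "meta.json"))
    mocap <- trim_to_claps(read_stream3d(file.path(sdir, "mocap.csv"),
                                         fps = meta$mocap_fps,
                                         coordinate_frame = "mocap"), meta)
    methods <- list(
      tri_13 = read_stream3d(file.path(td, rel, "tri_13.csv"),
                             fps = meta$video_fps, coordinate_frame = "camera1"),
      tri_12 = read_stream3d(file.path(td, rel, "tri_12.csv"),
                             fps = meta$video_fps, coordinate_frame = "camera1"),
      mono_a = read_stream3d(file.path(sdir, "mono_a_cam2.csv"),
                             fps = meta$video_fps, coordinate_frame = "mono_raw"),
      mono_b = read_stream3d(file.path(sdir, "mono_b_cam2.csv"),
                             fps = meta$video_fps, coordinate_frame = "mono_raw")
    )
    methods$tri_13 <- trim_to_claps(methods$tri_13, meta)
    methods$tri_12 <- trim_to_claps(methods$tri_12, meta)
    methods$mono_a <- trim_to_claps(methods$mono_a, meta)
    methods$mono_b <- trim_to_claps(methods$mono_b, meta)
    nf <- stream_n_frames(methods$tri_13)
    list(meta = meta, rel = rel,
         mocap = downsample_uniform(mocap, nf, target_fps = meta$video_fps),
         methods = methods)
  })
}

#' @rdname pipeline
#' @export
pipeline_align <- function(config, root, validity = validity_config()) {
  require_stage(root, "study")
  require_stage(root, "triangulated")
  d <- stage_dir(root, "aligned")
  sd <- stage_dir(root, "study")
  pdirs <- sort(list.files(sd, pattern = "^participant_", include.dirs = TRUE))
  files <- character()
  for (pn in pdirs) {
    preps <- load_prepared_participant(config, root, pn)
    p_id <- preps[[1]]$meta$participant_id
    tape <- participant_profile(config, p_id)$tape_length_mm
    masks <- lapply(preps, function(pr) {
      build_validity_mask(pr$mocap, pr$methods, validity)
    })
    mocaps <- lapply(preps, `[[`, "mocap")
    for (i in seq_along(preps)) {
      mdir <- file.path(d, preps[[i]]$rel)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      mp <- file.path(mdir, "mask.csv")
      readr::write_csv(as_tibble(masks[[i]]), mp)
      files <- c(files, mp)
    }
    for (m in names(preps[[1]]$methods)) {
      streams <- lapply(preps, function(pr) pr$methods[[m]])
      s <- if (method_is_mono(m)) estimate_scale(streams, masks, tape) else 1
      params <- fit_alignment(streams, mocaps, masks, s = s,
                              participant_id = p_id, method_id = m)
      ap <- file.path(d, pn, paste0("alignment_", m, ".json"))
      dir.create(dirname(ap), recursive = TRUE, showWarnings = FALSE)
      write_alignment(params, ap)
      files <- c(files, ap)
      for (i in seq_along(preps)) {
        aligned <- apply_alignment(streams[[i]], params)
        p <- file.path(d, preps[[i]]$rel, paste0("aligned_", m, ".csv"))
        write_stream3d(aligned, p)
        files <- c(files, p)
      }
    }
    for (i in seq_along(preps)) {
      p <- file.path(d, preps[[i]]$rel, "mocap_ds.csv")
      write_stream3d(mocaps[[i]], p)
      files <- c(files, p)
    }
  }
  write_manifest(d, config, files)
  message(sprintf("[align] alignment parameters + aligned streams -> %s", d))
  invisible(d)
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(config, root, validity = validity_config(),
                              voxel_sizes = seq(10, 100, by = 10)) {
  require_stage(root, "study")
  ad <- require_stage(root, "aligned")
  d <- stage_dir(root, "evaluated")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  err_rows <- list(); conf_a <- list(); conf_b <- list()
  dice_mocap <- NULL; dice_method <- NULL
  first_p <- NULL
  for (sdir in sort(seq_dirs(ad))) {
    rel <- rel_seq(ad, sdir)
    p_id <- sub("^participant_", "", basename(dirname(sdir)))
    q_id <- sub("^sequence_", "", basename(sdir))
    if (is.null(first_p)) first_p <- p_id
    mocap <- read_stream3d(file.path(sdir, "mocap_ds.csv"),
                           fps = config$video_fps, coordinate_frame = "mocap")
    mask_df <- readr::read_csv(file.path(sdir, "mask.csv"),
                               col_types = readr::cols())
    mask <- structure(
      tibble(frame = as.integer(mask_df$frame),
             keypoint = factor(mask_df$keypoint, levels = target_keypoints()),
             valid = as.logical(mask_df$valid)),
      class = c("validity_mask", class(tibble())))
    for (m in c("tri_13", "tri_12", "mono_a", "mono_b")) {
      aligned <- read_stream3d(file.path(sdir, paste0("aligned_", m, ".csv")),
                               fps = config$video_fps, coordinate_frame = "aligned")
      err_rows[[paste(rel, m)]] <- euclid_errors(
        aligned, mocap, mask, participant = p_id, method = m, sequence = q_id)
      if (m == "tri_13") {
        conf_a[[rel]] <- as_tibble(aligned)[, c("keypoint", "confidence", "missing")]
        if (p_id == first_p) {
          dice_mocap <- rbind(dice_mocap, wrist_points(mocap, mask))
          dice_method <- rbind(dice_method, wrist_points(aligned, mask))
        }
      }
      if (m == "tri_12") {
        conf_b[[rel]] <- as_tibble(aligned)[, c("keypoint", "confidence", "missing")]
      }
    }
  }
  errors <- bind_rows(err_rows)
  breakdown <- low_confidence_breakdown(bind_rows(conf_a), bind_rows(conf_b),
                                        tau = validity$confidence_threshold)
  dcurve <- dice_curve(dice_mocap, dice_method, voxel_sizes)
  occ <- voxelize(dice_method, 50)
  files <- c(
    errors = file.path(d, "errors.csv"),
    breakdown = file.path(d, "breakdown.csv"),
    dice_curve = file.path(d, "dice_curve.csv"),
    occupancy = file.path(d, "occupancy_50mm.csv")
  )
  readr::write_csv(errors, files[["errors"]])
  readr::write_csv(breakdown, files[["breakdown"]])
  readr::write_csv(as_tibble(dcurve), files[["dice_curve"]])
  readr::write_csv(as_tibble(occ), files[["occupancy"]])
  write_manifest(d, config, files)
  message(sprintf("[evaluate] %d error records -> %s", nrow(errors), d))
  invisible(d)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(config, root) {
  ed <- require_stage(root, "evaluated")
  d <- stage_dir(root, "report")
  errors <- readr::read_csv(file.path(ed, "errors.csv"),
                            col_types = readr::cols())
  errors$group <- factor(errors$group, levels = group_levels())
  class(errors) <- c("error_table", class(tibble()))
  dcurve <- readr::read_csv(file.path(ed, "dice_curve.csv"),
                            col_types = readr::cols())
  rep <- assemble_report(errors, dice_curve = dcurve, dir = d)
  write_manifest(d, config, unname(rep$files))
  message(sprintf("[report] -> %s", d))
  invisible(d)
}

#' @rdname pipeline
#' @export
pipeline_all <- function(config, root, validity = validity_config(),
                         voxel_sizes = seq(10, 100, by = 10)) {
  pipeline_simulate(config, root)
  pipeline_triangulate(config, root)
  pipeline_align(config, root, validity)
  pipeline_evaluate(config, root, validity, voxel_sizes)
  pipeline_report(config, root)
  invisible(root)
}
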