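#' Per-keypoint Euclidean error table
#'
#' Computes `e = ||a - m||` between an aligned method stream and the MoCap
#' reference for every valid (frame, keypoint) cell, folding the 13 keypoints
#' into the 10 analysis groups (the two shoulders together; the cheeks and
#' chin together as "face").
#'
#' @param aligned Method `stream3d` in the MoCap frame.
#' @param mocap Reference `stream3d` on the same frame grid.
#' @param mask A `validity_mask`.
#' @param participant,method Labels recorded in the table.
#' @param sequence Optional sequence label.
#' @return An `error_table` tibble with columns `participant, method,
#'   sequence, group, keypoint, frame, e` (mm); rows exist only where the
#'   mask is TRUE.
#' @export
euclid_errors <- function(aligned, mocap, mask, participant = NA,
                          method = NA, sequence = NA) {
  if (stream_n_frames(aligned) != stream_n_frames(mocap) ||
      nrow(aligned) != nrow(mocap)) {
    abort("Frame mismatch between aligned stream and MoCap.")
  }
  v <- mask$valid & !aligned$missing & !mocap$missing
  e <- sqrt((aligned$x - mocap$x)^2 + (aligned$y - mocap$y)^2 +
              (aligned$z - mocap$z)^2)
  grp <- keypoint_groups()
  lut <- setNames(grp$group, grp$keypoint)
  out <- tibble(
    participant = participant, method = method, sequence = sequence,
    group = factor(unname(lut[as.character(mocap$keypoint[v])]),
                   levels = group_levels()),
    keypoint = mocap$keypoint[v],
    frame = mocap$frame[v],
    e = e[v]
  )
  structure(out, class = c("error_table", class(tibble())))
}

#' Aggregate error tables to participant means
#'
#' Cell means are unweighted means of `e` within (participant, method,
#' group). The overall per-method mean is the mean over participants of each
#' participant's pooled mean error (participants are the experimental units,
#' matching the repeated-measures analysis), not a pooled-frame mean.
#'
#' @param table An `error_table` (rows from any number of sequences).
#' @return A list with `cell_means` (participant x method x group tibble;
#'   empty cells are absent, i.e. flagged by omission rather than zeroed)
#'   and `overall` (per-method tibble with `mean_error_mm`).
#' @export
aggregate_participant_means <- function(table) {
  if (nrow(table) == 0L) abort("Empty error table.")
  cell <- table |>
    group_by(.data$participant, .data$method, .data$group) |>
    summarise(mean_error_mm = mean(.data$e), n = dplyr::n(), .groups = "drop")
  per_part <- table |>
    group_by(.data$participant, .data$method) |>
    summarise(mean_error_mm = mean(.data$e), .groups = "drop")
  overall <- per_part |>
    group_by(.data$method) |>
    summarise(mean_error_mm = mean(.data$mean_error_mm),
              n_participants = dplyr::n(), .groups = "drop")
  list(cell_means = cell, participant_means = per_part, overall = overall)
}

#' Voxel grid specification
#'
#' Space is partitioned into half-open cubic cells `[i*v, (i+1)*v)` anchored
#' at the aligned-frame origin; the voxel index of a point is
#' `floor(p / v)` componentwise (so negative coordinates floor downward).
#'
#' @param voxel_size_mm Edge length `v` (> 0).
#' @return A `voxel_grid_spec`.
#' @export
voxel_grid_spec <- function(voxel_size_mm) {
  stopifnot_scalar_num(voxel_size_mm, "voxel_size_mm", positive = TRUE)
  structure(list(voxel_size_mm = voxel_size_mm), class = "voxel_grid_spec")
}

#' Voxelize a point cloud into an occupancy set
#'
#' Returns the set of voxel indices touched at least once by any point. For
#' gesture-space analysis, the points are typically the left and right wrist
#' positions pooled over all frames and sequences (handedness and time are
#' not distinguished).
#'
#' @param points n x 3 matrix of points, mm.
#' @param spec A `voxel_grid_spec` (or scalar voxel size).
#' @return An `occupancy_set` tibble of distinct integer triples
#'   `(ix, iy, iz)` with the voxel size as attribute.
#' @export
voxelize <- function(points, spec) {
  if (is.numeric(spec)) spec <- voxel_grid_spec(spec)
  P <- to_mat3(points)
  P <- P[stats::complete.cases(P), , drop = FALSE]
  idx <- floor(P / spec$voxel_size_mm)
  out <- distinct(tibble(ix = as.integer(idx[, 1]),
                         iy = as.integer(idx[, 2]),
                         iz = as.integer(idx[, 3])))
  structure(out, voxel_size_mm = spec$voxel_size_mm,
            class = c("occupancy_set", class(tibble())))
}

#' Dice similarity of two occupancy sets
#'
#' `2 |A intersect B| / (|A| + |B|)`, in \[0, 1\].
#'
#' @param A,B `occupancy_set`s.
#' @return Scalar Dice coefficient.
#' @export
dice <- function(A, B) {
  if (nrow(A) + nrow(B) == 0L) abort("Dice undefined: both sets are empty.")
  inter <- nrow(inner_join(as_tibble(A), as_tibble(B),
                           by = c("ix", "iy", "iz")))
  2 * inter / (nrow(A) + nrow(B))
}

#' Dice coefficient as a function of voxel size
#'
#' Re-voxelizes both point clouds at each requested size and computes the
#' Dice coefficient, tracing how spatial agreement grows with coarser grids.
#'
#' @param mocap_points,method_points n x 3 matrices, mm (same frame).
#' @param v_list Voxel sizes, mm (default 10 to 100 by 10).
#' @return A `dice_curve` tibble `(voxel_size_mm, dice)`.
#' @export
dice_curve <- function(mocap_points, method_points,
                       v_list = seq(10, 100, by = 10)) {
  if (any(v_list <= 0)) abort("Voxel sizes must be positive.")
  out <- tibble(
    voxel_size_mm = v_list,
    dice = vapply(v_list, function(v) {
      dice(voxelize(mocap_points, v), voxelize(method_points, v))
    }, 0)
  )
  structure(out, class = c("dice_curve", class(tibble())))
}

#' Low-confidence breakdown between two methods
#'
#' Among all (frame, keypoint) events where at least one of the two streams
#' falls below the confidence threshold (a missing observation counts as
#' below threshold), tabulates per analysis group the total count `N` and the
#' percentage falling in each category: below in `a` only, in `b` only, or in
#' both. Groups with no such event report `N = 0` and `NA` percentages.
#'
#' @param stream_a,stream_b Streams carrying confidences on the same grid
#'   (2D or 3D).
#' @param tau Confidence threshold.
#' @return A tibble `(group, N, pct_a_only, pct_b_only, pct_both)`.
#' @export
low_confidence_breakdown <- function(stream_a, stream_b, tau = 0.3) {
  if (nrow(stream_a) != nrow(stream_b)) abort("Streams must share the grid.")
  below <- function(s) s$missing | (!is.na(s$confidence) & s$confidence < tau)
  ba <- below(stream_a); bb <- below(stream_b)
  grp <- keypoint_groups()
  lut <- setNames(grp$group, grp$keypoint)
  df <- tibble(group = factor(unname(lut[as.character(stream_a$keypoint)]),
                              levels = group_levels()),
               a = ba, b = bb)
  df |>
    group_by(.data$group) |>
    summarise(
      N = sum(.data$a | .data$b),
      pct_a_only = ifelse(.data$N > 0, 100 * sum(.data$a & !.data$b) / .data$N, NA_real_),
      pct_b_only = ifelse(.data$N > 0, 100 * sum(!.data$a & .data$b) / .data$N, NA_real_),
      pct_both = ifelse(.data$N > 0, 100 * sum(.data$a & .data$b) / .data$N, NA_real_),
      .groups = "drop"
    ) |>
    tidyr::complete(group = factor(group_levels(), levels = group_levels()),
                    fill = list(N = 0L, pct_a_only = NA_real_,
                                pct_b_only = NA_real_, pct_both = NA_real_))
}

#' Extract pooled wrist points from a 3D stream
#'
#' Helper for gesture-space analysis: stacks the left and right wrist
#' positions of all (optionally mask-valid) frames into one point matrix.
#'
#' @param stream A `stream3d` in the aligned/MoCap frame.
#' @param mask Optional `validity_mask`.
#' @return n x 3 matrix, mm.
#' @export
wrist_points <- function(stream, mask = NULL) {
  sel <- stream$keypoint %in% c("wrist_right", "wrist_left") & !stream$missing
  if (!is.null(mask)) sel <- sel & mask$valid
  cbind(stream$x[sel], stream$y[sel], stream$z[sel])
}
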