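#' Canonical upper-body keypoint vocabulary
#'
#' The analysis targets 13 upper-body keypoints commonly used in gesture
#' research: the tips of the left and right thumbs and middle fingers, the
#' wrists, elbows, shoulders, cheeks, and the chin. Keypoint identifiers are
#' strings of the form `"part_side"` (`"chin"` has side `center` and carries
#' no suffix ambiguity: its id is `"chin"`).
#'
#' The canonical column order is fixed (right before left, proximal to distal,
#' chin last) so that exported CSV columns are stable across runs.
#'
#' @return `target_keypoints()` returns a character vector of the 13 canonical
#'   keypoint ids in canonical order. `keypoint_groups()` returns a tibble
#'   mapping each keypoint id to its analysis group (10 groups: the two
#'   shoulders are analysed together, as are the three face points).
#' @export
#' @examples
#' target_keypoints()
#' keypoint_groups()
target_keypoints <- function() {
  c(
    "shoulder_right", "shoulder_left",
    "elbow_right", "elbow_left",
    "wrist_right", "wrist_left",
    "thumb_right", "thumb_left",
    "middle_right", "middle_left",
    "cheek_right", "cheek_left",
    "chin"
  )
}

#' @rdname target_keypoints
#' @export
keypoint_groups <- function() {
  tibble(
    keypoint = target_keypoints(),
    group = c(
      "shoulder", "shoulder",
      "elbow_R", "elbow_L",
      "wrist_R", "wrist_L",
      "thumb_R", "thumb_L",
      "middle_R", "middle_L",
      "face", "face", "face"
    )
  )
}

group_levels <- function() {
  c("thumb_R", "thumb_L", "middle_R", "middle_L", "wrist_R", "wrist_L",
    "elbow_R", "elbow_L", "shoulder", "face")
}

#' Skeleton schemas: mapping source keypoint layouts onto the target set
#'
#' A schema names a source keypoint layout (its `size`) and an injective
#' mapping from 0-based source indices onto the 13 target keypoints. Where a
#' source layout has no keypoint at exactly the target position, the closest
#' available point is frozen into the table as a documented convention — in
#' particular the facial proxies: for the 133-point "wholebody" layout the
#' cheeks and chin are taken from the 68-point jaw contour (indices 26/36/31
#' of the face block), and for the 543-point "holistic" layout from the face
#' mesh (234/454 lateral cheek vertices, 152 chin vertex). These are package
#' conventions, not properties of the layouts themselves.
#'
#' @param name One of `"wholebody"` (133 keypoints), `"holistic"` (543),
#'   `"mocap-markers"` (19) or `"target"` (13, identity).
#' @return A `skeleton_schema` object: list with `name`, `size` and `mapping`
#'   (named integer vector: names are target keypoint ids, values 0-based
#'   source indices).
#' @export
#' @examples
#' builtin_schema("wholebody")
builtin_schema <- function(name = c("wholebody", "holistic", "mocap-markers", "target")) {
  name <- match.arg(name)
  mapping <- switch(name,
    "wholebody" = c(
      # COCO-wholebody layout: body 0-16, feet 17-22, face 23-90,
      # left hand 91-111, right hand 112-132 (0-based).
      shoulder_right = 6L, shoulder_left = 5L,
      elbow_right = 8L, elbow_left = 7L,
      wrist_right = 10L, wrist_left = 9L,
      thumb_right = 116L, thumb_left = 95L,
      middle_right = 124L, middle_left = 103L,
      cheek_right = 23L + 26L, cheek_left = 23L + 36L,
      chin = 23L + 31L
    ),
    "holistic" = c(
      # pose 0-32, face mesh 33-500, left hand 501-521, right hand 522-542.
      shoulder_right = 12L, shoulder_left = 11L,
      elbow_right = 14L, elbow_left = 13L,
      wrist_right = 16L, wrist_left = 15L,
      thumb_right = 526L, thumb_left = 505L,
      middle_right = 534L, middle_left = 513L,
      cheek_right = 33L + 234L, cheek_left = 33L + 454L,
      chin = 33L + 152L
    ),
    "mocap-markers" = c(
      # 19 markers: toes, knees, little-finger bases, thumbs, middle fingers,
      # wrists, elbows, shoulders, cheeks, chin (right before left).
      shoulder_right = 14L, shoulder_left = 15L,
      elbow_right = 12L, elbow_left = 13L,
      wrist_right = 10L, wrist_left = 11L,
      thumb_right = 6L, thumb_left = 7L,
      middle_right = 8L, middle_left = 9L,
      cheek_right = 16L, cheek_left = 17L,
      chin = 18L
    ),
    "target" = setNames(seq_along(target_keypoints()) - 1L, target_keypoints())
  )
  size <- switch(name, wholebody = 133L, holistic = 543L,
                 `mocap-markers` = 19L, target = 13L)
  new_schema(name, size, mapping)
}

new_schema <- function(name, size, mapping) {
  mapping <- mapping[target_keypoints()[target_keypoints() %in% names(mapping)]]
  if (anyDuplicated(mapping)) abort("Schema mapping must be injective.")
  if (any(mapping < 0L | mapping >= size)) {
    abort("Schema mapping indices must lie in [0, size).")
  }
  bad <- setdiff(names(mapping), target_keypoints())
  if (length(bad)) abort(paste0("Unknown target keypoint(s): ",
                                paste(bad, collapse = ", ")))
  structure(list(name = name, size = as.integer(size),
                 mapping = mapping), class = "skeleton_schema")
}

#' @export
print.skeleton_schema <- function(x, ...) {
  cat(sprintf("<skeleton_schema> %s: %d source keypoints, %d mapped\n",
              x$name, x$size, length(x$mapping)))
  invisible(x)
}

#' Read or write a skeleton schema file
#'
#' Schema files are JSON objects `{name, size, mapping}` where `mapping` maps
#' 0-based source index strings to target keypoint ids.
#'
#' @param path File path.
#' @param schema A `skeleton_schema`.
#' @return `read_schema()` returns a `skeleton_schema`.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::fromJSON(path)
  idx <- as.integer(names(obj$mapping))
  if (anyNA(idx)) abort("Schema mapping keys must be integer source indices.")
  mapping <- setNames(idx, unlist(obj$mapping, use.names = FALSE))
  new_schema(obj$name, obj$size, mapping)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  obj <- list(
    name = schema$name, size = schema$size,
    mapping = as.list(setNames(names(schema$mapping),
                               as.character(schema$mapping)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restrict a stream to the 13 target keypoints
#'
#' Applies a skeleton schema to a 2D or 3D keypoint stream, keeping only the
#' mapped source keypoints, renaming them to canonical target ids and ordering
#' them canonically. Confidence and missing flags are carried through
#' unchanged.
#'
#' @param stream A `stream2d` or `stream3d` whose keypoint column holds
#'   0-based source indices (or, for the identity schema, target ids).
#' @param schema A `skeleton_schema` whose `size` matches the stream's
#'   keypoint count.
#' @return A stream of the same kind with exactly 13 keypoints.
#' @export
map_to_target <- function(stream, schema) {
  if (!inherits(schema, "skeleton_schema")) abort("`schema` must be a skeleton_schema.")
  nk <- stream_n_keypoints(stream)
  if (nk != schema$size) {
    abort(sprintf("Schema '%s' expects %d source keypoints but stream has %d.",
                  schema$name, schema$size, nk))
  }
  kp <- stream$keypoint
  if (is.factor(kp)) kp <- as.character(kp)
  if (schema$name == "target" && all(kp %in% target_keypoints())) {
    return(canonicalize_stream(stream))
  }
  src <- as.integer(kp)
  lut <- setNames(names(schema$mapping), as.character(schema$mapping))
  keep <- as.character(src) %in% names(lut)
  out <- as_tibble(stream)[keep, , drop = FALSE]
  out$keypoint <- factor(unname(lut[as.character(src[keep])]),
                         levels = target_keypoints())
  restore_stream_attrs(out, stream)
}
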