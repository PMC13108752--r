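#' Rigid (similarity) transforms
#'
#' A rigid transform maps points as `x -> R %*% (s * x) + t` with `R`
#' orthonormal (det +1), translation `t` in mm, and an optional uniform scale
#' `s > 0` (default 1). Affine maps are deliberately excluded: shearing a
#' skeleton deforms it and would flatter the error metric.
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation, mm.
#' @param s Uniform scale (> 0).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), s = 1) {
  R <- matrix(as.numeric(R), 3, 3)
  check_rotation(R)
  stopifnot_scalar_num(s, "s", positive = TRUE)
  structure(list(R = R, t = as.numeric(t), s = s), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> s = %.6g, rotation %.3f deg, |t| = %.3f mm\n",
              x$s, ang, sqrt(sum(x$t^2))))
  invisible(x)
}

#' Apply, invert and compose rigid transforms
#'
#' @param tf,tf1,tf2 `rigid_transform` objects.
#' @param points n x 3 matrix or 3-vector.
#' @return `apply_rigid()` returns transformed points; `invert_rigid()` the
#'   inverse transform; `compose_rigid()` the transform equivalent to
#'   applying `tf2` first, then `tf1`.
#' @export
apply_rigid <- function(points, tf) {
  P <- to_mat3(points)
  out <- (tf$s * P) %*% t(tf$R) + matrix(tf$t, nrow(P), 3, byrow = TRUE)
  if (is.null(dim(points))) as.vector(out) else out
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(tf) {
  Rinv <- t(tf$R)
  rigid_transform(R = Rinv, t = -(Rinv %*% tf$t) / tf$s, s = 1 / tf$s)
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(tf1, tf2) {
  # (tf1 o tf2)(x) = R1 (s1 (R2 s2 x + t2)) + t1
  rigid_transform(R = tf1$R %*% tf2$R,
                  t = as.vector(tf1$R %*% (tf1$s * tf2$t)) + tf1$t,
                  s = tf1$s * tf2$s)
}

#' Least-squares rigid registration (Kabsch / SVD)
#'
#' Finds the rotation `R` and translation `t` minimising
#' `sum_i || R p_i + t - q_i ||^2` over paired point sets, via the SVD of the
#' cross-covariance with a reflection correction so `det(R) = +1`. Scale is
#' fixed to 1; any scaling is estimated separately upstream (tape-measure
#' scaling for monocular streams).
#'
#' @param P,Q n x 3 matrices of paired points (n >= 3, not all collinear).
#' @return A `rigid_transform` with `s = 1`.
#' @export
rigid_fit <- function(P, Q) {
  P <- to_mat3(P); Q <- to_mat3(Q)
  if (nrow(P) != nrow(Q)) abort("`P` and `Q` must pair up.")
  if (nrow(P) < 3L) abort("Degenerate fit: need at least 3 point pairs.")
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # Rank check: collinear configurations leave the rotation about the line
  # unconstrained.
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1)) {
    abort("Degenerate fit: point configuration is (near-)collinear.")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R = R, t = as.vector(qbar - R %*% pbar), s = 1)
}
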