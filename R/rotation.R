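#' Rigid transform from an axis-angle pose
#'
#' Converts a marker pose given as an axis-angle rotation vector plus a
#' translation (the native output of fiducial-marker detectors) into a
#' rigid transform: a 3x3 rotation matrix built with the Rodrigues formula
#' and a translation vector. A zero rotation vector yields the identity
#' rotation.
#'
#' @param rvec length-3 axis-angle rotation vector in radians (direction =
#'   axis, norm = angle).
#' @param tvec length-3 translation in metres.
#' @return An object of class `rigid_transform`: a list with `R` (3x3
#'   rotation) and `p` (length-3 translation).
#' @export
to_homogeneous <- function(rvec, tvec) {
  rvec <- as.numeric(rvec); tvec <- as.numeric(tvec)
  if (length(rvec) != 3L || length(tvec) != 3L)
    stop("`rvec` and `tvec` must have length 3")
  if (any(!is.finite(rvec)) || any(!is.finite(tvec)))
    stop("non-finite pose input")
  structure(list(R = rodrigues(rvec), p = tvec), class = "rigid_transform")
}

#' Rodrigues rotation matrix
#'
#' R = I + sin(theta) K + (1 - cos(theta)) K^2, with theta = |rvec| and K
#' the skew-symmetric matrix of the unit axis.
#'
#' @param rvec length-3 axis-angle vector, radians.
#' @return 3x3 rotation matrix.
#' @export
rodrigues <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < .Machine$double.eps) return(diag(3))
  k <- rvec / theta
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Axis-angle vector of a rotation matrix
#'
#' Inverse of [rodrigues()] for angles in `[0, pi)`; near pi the axis is
#' recovered from the symmetric part.
#'
#' @param R 3x3 rotation matrix.
#' @return length-3 axis-angle vector.
#' @export
rotation_to_rvec <- function(R) {
  tr <- sum(diag(R))
  theta <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta < pi - 1e-6) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(theta * v / (2 * sin(theta)))
  }
  # theta ~ pi: axis from the dominant column of R + I
  B <- R + diag(3)
  j <- which.max(colSums(B^2))
  axis <- B[, j] / sqrt(sum(B[, j]^2))
  theta * axis
}

#' Rebase a pose into a reference frame
#'
#' Given the pose `h_ref` of a fixed reference marker and the pose `h_k` of
#' a moving marker, both expressed in the (possibly wobbling) camera frame,
#' returns the moving marker's pose in the reference-marker frame:
#' `h_ref^-1 o h_k`. The result is independent of camera motion, which is
#' the whole point of carrying a fixed reference marker in the scene.
#'
#' @param h_ref,h_k `rigid_transform` objects.
#' @return A `rigid_transform` such that `h_ref` composed with it equals
#'   `h_k`.
#' @export
rebase <- function(h_ref, h_k) {
  stopifnot(inherits(h_ref, "rigid_transform"), inherits(h_k, "rigid_transform"))
  Rt <- t(h_ref$R)  # inverse of a rotation
  structure(list(R = Rt %*% h_k$R, p = drop(Rt %*% (h_k$p - h_ref$p))),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' @param a,b `rigid_transform` objects; returns `a o b`.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  structure(list(R = a$R %*% b$R, p = drop(a$R %*% b$p) + a$p),
            class = "rigid_transform")
}

# ---- vectorised internals ------------------------------------------------
# Rotations for N frames are carried as an N x 9 matrix holding the 3x3
# rotation in column-major order (r11, r21, r31, r12, ...). These helpers
# keep per-frame work out of R-level loops; they are exercised against the
# scalar API in the test suite.

# N x 3 axis-angle matrix -> N x 9 rotation rows
rodrigues_many <- function(rvecs) {
  rvecs <- matrix(rvecs, ncol = 3)
  th <- sqrt(rowSums(rvecs^2))
  safe <- pmax(th, .Machine$double.eps)
  kx <- rvecs[, 1] / safe; ky <- rvecs[, 2] / safe; kz <- rvecs[, 3] / safe
  s <- sin(th); c1 <- 1 - cos(th)
  zero <- th < .Machine$double.eps
  kx[zero] <- 0; ky[zero] <- 0; kz[zero] <- 0
  cbind(
    1 + c1 * (kx * kx - 1),           # r11
    kz * s + c1 * kx * ky,            # r21
    -ky * s + c1 * kx * kz,           # r31
    -kz * s + c1 * kx * ky,           # r12
    1 + c1 * (ky * ky - 1),           # r22
    kx * s + c1 * ky * kz,            # r32
    ky * s + c1 * kx * kz,            # r13
    -kx * s + c1 * ky * kz,           # r23
    1 + c1 * (kz * kz - 1)            # r33
  )
}

# N x 9 rotation rows -> N x 3 axis-angle matrix (angles in [0, pi - eps])
rvec_many <- function(R9) {
  tr <- R9[, 1] + R9[, 5] + R9[, 9]
  th <- acos(pmax(-1, pmin(1, (tr - 1) / 2)))
  # vee(R - R^T) = 2 sin(theta) * axis
  vx <- R9[, 6] - R9[, 8]
  vy <- R9[, 7] - R9[, 3]
  vz <- R9[, 2] - R9[, 4]
  f <- ifelse(th < 1e-8, 0.5 + th^2 / 12, th / (2 * sin(th)))
  cbind(f * vx, f * vy, f * vz)
}

# rowwise rotation composition: (A %*% B) per frame
rot_compose_many <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (j in 0:2) {      # output column j of the 3x3
    b <- B[, (3 * j + 1):(3 * j + 3), drop = FALSE]
    for (i in 0:2) {    # output row i
      a <- A[, c(i + 1, i + 4, i + 7), drop = FALSE]
      out[, 3 * j + i + 1] <- rowSums(a * b)
    }
  }
  out
}

# rowwise R %*% p for N frames: R9 N x 9, P N x 3
rotate_points_many <- function(R9, P) {
  cbind(
    R9[, 1] * P[, 1] + R9[, 4] * P[, 2] + R9[, 7] * P[, 3],
    R9[, 2] * P[, 1] + R9[, 5] * P[, 2] + R9[, 8] * P[, 3],
    R9[, 3] * P[, 1] + R9[, 6] * P[, 2] + R9[, 9] * P[, 3]
  )
}

# rowwise transpose: N x 9 -> N x 9
rot_transpose_many <- function(R9) {
  R9[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
}
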