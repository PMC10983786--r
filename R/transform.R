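#' Rigid-body transforms
#'
#' A rigid transform pairs a translation vector `t` (Angstrom) with a proper
#' rotation matrix `R`. It acts on an n x 3 coordinate matrix `X` as
#' \deqn{Y = (X - 1_n t^T) R,}
#' i.e. translate first, then right-multiply by the rotation. All fitters in
#' the package report transforms in this orientation, so `apply_transform()`
#' maps raw coordinates into the common (superposed) frame.
#'
#' @param t Numeric length-3 translation, Angstrom.
#' @param R 3 x 3 proper rotation matrix (`t(R) %*% R = I`, `det(R) = 1`).
#' @return An object of class `rigid_transform`.
#' @examples
#' tr <- rigid_transform(c(1, 0, 0), diag(3))
#' apply_transform(matrix(rnorm(9), 3), tr)
#' @export
rigid_transform <- function(t = c(0, 0, 0), R = diag(3)) {
  t <- as.numeric(t)
  R <- as.matrix(R)
  stopifnot(length(t) == 3L, all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stopf("R is not a proper rotation (orthogonality/det tolerance 1e-9)")
  structure(list(t = t, R = R), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param X n x 3 coordinate matrix.
#' @param transform A `rigid_transform`.
#' @export
apply_transform <- function(X, transform) {
  shift_rotate(as.matrix(X), transform$t, transform$R)
}

#' @rdname rigid_transform
#' @details `invert_transform()` returns the transform mapping the superposed
#' frame back to the raw frame: if `Y = (X - 1 t^T) R`, the inverse in the
#' same convention is `X = (Y - 1 s^T) Q` with `Q = t(R)` and `s = -t %*% R`.
#' @export
invert_transform <- function(transform) {
  # Y = (X - 1 t^T) R  =>  X = Y R^T + 1 t^T = (Y - 1 (- t R)^T ... ) ;
  # in the same convention: X = (Y - 1 s^T) Q with Q = t(R), s = -t %*% R.
  rigid_transform(-as.numeric(transform$t %*% transform$R), t(transform$R))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: t = (", paste(sprintf("%.3f", x$t), collapse = ", "),
      ") Angstrom\n", sep = "")
  print(round(x$R, 6))
  invisible(x)
}

#' Optimal weighted rigid superposition (weighted Kabsch)
#'
#' Finds the rigid transform minimizing the weighted residual sum of squares
#' \deqn{\sum_a w_a \| \mathrm{row}_a((X - 1 t^T) R) - \mathrm{row}_a(M) \|^2}
#' between a mobile structure `X` and a fixed target `M`. The rotation is the
#' classical SVD solution of the weighted cross-covariance with a sign flip of
#' the smallest singular direction when needed to enforce a proper rotation;
#' the translation aligns the weighted centroids.
#'
#' @param X n x 3 mobile coordinates, Angstrom.
#' @param M n x 3 target coordinates, Angstrom.
#' @param w Optional length-n positive atom weights (default: uniform).
#' @return A [rigid_transform()].
#' @examples
#' M <- matrix(rnorm(15), 5)
#' tr <- optimal_transform(M, M)   # identity
#' max(abs(tr$R - diag(3)))
#' @export
optimal_transform <- function(X, M, w = NULL) {
  X <- as.matrix(X); M <- as.matrix(M)
  n <- nrow(X)
  if (n < 3L) stopf("at least 3 atoms are required for superposition")
  stopifnot(all(dim(X) == dim(M)))
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stopf("weights must be %d finite positive values", n)

  sw <- sum(w)
  xbar <- colSums(X * w) / sw
  mbar <- colSums(M * w) / sw
  Xc <- sweep(X, 2L, xbar)
  Mc <- sweep(M, 2L, mbar)
  # 3x3 weighted cross-covariance A = sum_a w_a x_a m_a^T
  A <- crossprod(Xc * w, Mc)
  sv <- svd(A)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stopf("ill-conditioned superposition (rank < 2 cross-covariance)")
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  # row y_a = t(R) (x_a - t); centroid condition t(R)(xbar - t) = mbar
  t_vec <- xbar - as.numeric(R %*% mbar)
  rigid_transform(t_vec, R)
}

# Lean weighted Procrustes for hot loops: same mathematics as
# optimal_transform() but no validation and no class construction; returns
# the transformed coordinates and the bare (t, R). `w` must be positive and
# finite; callers guarantee non-degeneracy.
fast_transform <- function(X, target, w, sw) {
  xbar <- colSums(X * w) / sw
  mbar <- colSums(target * w) / sw
  Xc <- X - rep(xbar, each = nrow(X))
  Mc <- target - rep(mbar, each = nrow(X))
  sv <- svd(crossprod(Xc * w, Mc))
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% (c(1, 1, s) * t(sv$v))
  t_vec <- xbar - as.numeric(R %*% mbar)
  list(t = t_vec, R = R, Y = Xc %*% R + rep(mbar, each = nrow(X)))
}

# Uniform random rotation on SO(3) via a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}
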