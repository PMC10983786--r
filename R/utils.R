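# Internal numerical helpers shared across the fitters.
#
# Index convention for 3n-vectors and 3n x 3n covariance matrices:
# coordinate (atom a, axis k in {x, y, z}) maps to row 3*(a-1) + k,
# i.e. the vectorization vec(t(Y)) of an n x 3 coordinate matrix Y.

# n x 3 matrix -> 3n vector under the vec(t(Y)) convention
vec3n <- function(Y) as.vector(t(Y))

# 3n vector -> n x 3 matrix (inverse of vec3n)
unvec3n <- function(y) matrix(y, ncol = 3L, byrow = TRUE)

# Force exact symmetry (covariance updates accumulate tiny asymmetries).
symmetrize <- function(C) (C + t(C)) / 2

# Ridge-stabilized copy: C + eps * (tr(C)/p) * I, the relative ridge used
# before every inversion of an estimated covariance matrix. Rank-deficient
# estimates are routine when nu or sum(m_i) is below 3n.
ridge_stabilize <- function(C, ridge) {
  if (ridge <= 0) return(C)
  p <- nrow(C)
  scale <- sum(diag(C)) / p
  if (!is.finite(scale) || scale <= 0) scale <- 1
  C + diag(ridge * scale, p)
}

# Cholesky-based solve of C x = B with symmetric positive definite C;
# falls back to an escalated ridge when the factorization fails.
chol_solve <- function(C, B, ridge = 0) {
  Cs <- ridge_stabilize(symmetrize(C), ridge)
  R <- tryCatch(chol(Cs), error = function(e) NULL)
  attempt <- ridge
  while (is.null(R)) {
    attempt <- max(attempt * 10, 1e-10)
    if (attempt > 1) stop("covariance matrix is numerically singular")
    Cs <- ridge_stabilize(symmetrize(C), attempt)
    R <- tryCatch(chol(Cs), error = function(e) NULL)
  }
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

# Cholesky factor with the same escalation policy; also returns log|C|.
chol_logdet <- function(C, ridge = 0) {
  Cs <- ridge_stabilize(symmetrize(C), ridge)
  R <- tryCatch(chol(Cs), error = function(e) NULL)
  attempt <- ridge
  while (is.null(R)) {
    attempt <- max(attempt * 10, 1e-10)
    if (attempt > 1) stop("covariance matrix is numerically singular")
    Cs <- ridge_stabilize(symmetrize(C), attempt)
    R <- tryCatch(chol(Cs), error = function(e) NULL)
  }
  list(R = R, logdet = 2 * sum(log(diag(R))))
}

# Per-atom mean variances: average of the three diagonal entries of each
# 3x3 atom block of a 3n x 3n covariance matrix.
atom_variances <- function(C) {
  d <- diag(C)
  n <- length(d) / 3L
  colMeans(matrix(d, nrow = 3L, ncol = n))
}

# Conjugate a 3n x 3n covariance by a global rotation applied as Y -> Y %*% R:
# y -> (I_n (x) t(R)) y, so C -> (I_n (x) t(R)) C (I_n (x) R).
rotate_cov3n <- function(C, R) {
  n <- nrow(C) / 3L
  K <- kronecker(diag(n), t(R))
  symmetrize(K %*% C %*% t(K))
}

# Apply a global rigid motion (translate by t then rotate by R) to an n x 3
# coordinate matrix, the gauge action Y -> (Y - 1 t(t)) R.
shift_rotate <- function(Y, t_vec, R) {
  sweep(Y, 2L, t_vec) %*% R
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
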