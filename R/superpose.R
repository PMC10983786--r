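#' Sample covariance of aligned structures
#'
#' Accumulates the 3n x 3n scatter of vectorized aligned structures around a
#' given mean, \eqn{C = d^{-1} \sum_j (y_j - \mu)(y_j - \mu)^T} with
#' `y = vec(t(Y))`, using divisor `d = m` (`"ml"`) or `d = m - 1`
#' (`"unbiased"`, the standalone default).
#'
#' @param aligned List of n x 3 aligned coordinate matrices.
#' @param M n x 3 mean structure.
#' @param divisor `"unbiased"` or `"ml"`.
#' @return Symmetric PSD 3n x 3n matrix (Angstrom^2).
#' @export
sample_covariance <- function(aligned, M, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  m <- length(aligned)
  if (m < 2L) stopf("at least 2 structures are required")
  mu <- vec3n(as.matrix(M))
  D <- vapply(aligned, function(Y) vec3n(as.matrix(Y)) - mu,
              numeric(length(mu)))
  d <- if (divisor == "ml") m else m - 1L
  symmetrize(tcrossprod(D) / d)
}

# --- shared internals -------------------------------------------------------

as_coord_list <- function(members) {
  if (inherits(members, "ensemble_set")) members <- set_members(members)$coords
  lapply(members, function(x) {
    if (inherits(x, "conformation")) {
      if (!all(x$present)) stopf("superposition requires complete conformations")
      x$coords
    } else as.matrix(x)
  })
}

# Gauge-fix a converged single-ensemble fit: anchor the mean's orientation to
# the (centered) first input conformation's frame and its centroid to the
# origin; transforms and the covariance are rotated consistently.
gauge_anchor_single <- function(M, aligned, transforms, Sigma, anchor_X) {
  anchor <- sweep(anchor_X, 2L, colMeans(anchor_X))
  g <- optimal_transform(M, anchor)
  Mg <- apply_transform(M, g)
  Mg <- sweep(Mg, 2L, colMeans(Mg))
  alignedg <- lapply(aligned, function(Y) apply_transform(Y, g))
  transformsg <- lapply(transforms, function(tr)
    rigid_transform(tr$t + as.numeric(tr$R %*% g$t), tr$R %*% g$R))
  Sigmag <- if (is.null(Sigma)) NULL else rotate_cov3n(Sigma, g$R)
  list(M = Mg, aligned = alignedg, transforms = transformsg, Sigma = Sigmag)
}

new_single_fit <- function(method, M, Sigma, transforms, weights,
                           n_iter, converged, trace, objective) {
  structure(list(
    method = method, M_hat = M, Sigma_hat = Sigma, transforms = transforms,
    weights = weights, n_iter = n_iter, converged = converged,
    objective_trace = trace, objective = objective
  ), class = c(paste0(method, "_fit"), "single_fit"))
}

#' @export
print.single_fit <- function(x, ...) {
  cat(sprintf("%s superposition: %d structures, %d atoms, %d iteration(s)%s\n",
              toupper(x$method), length(x$transforms), nrow(x$M_hat),
              x$n_iter, if (x$converged) "" else " (not converged)"))
  cat(sprintf("  final %s: %.6g\n", x$objective,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# --- OLS --------------------------------------------------------------------

#' Single-ensemble superposition
#'
#' `ols_superpose()` alternates mean and rigid-transform updates with uniform
#' atom weights (homoscedastic errors) until the relative change in the
#' residual sum of squares falls below `tol`. `iwls_superpose()` additionally
#' re-estimates per-atom variances from the aligned residuals after each
#' sweep and uses their inverses as atom weights, so that weakly fluctuating
#' regions dominate the superposition; its trace records the per-atom
#' heteroscedastic Gaussian log-likelihood, which each sweep cannot decrease.
#'
#' The mean structure is centered at the origin and its orientation anchored
#' to the first input conformation's initial frame, which removes the global
#' rigid indeterminacy and makes the fit deterministic given the input order.
#'
#' @param members List of [conformation()]s (complete) or n x 3 matrices, or
#'   an [ensemble_set()] (members pooled).
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Maximum number of outer sweeps; on exhaustion the best fit
#'   so far is returned with `converged = FALSE`.
#' @return A `single_fit` with mean structure `M_hat`, full 3n x 3n
#'   `Sigma_hat` estimated from the final aligned residuals (ML divisor),
#'   per-conformation `transforms`, final atom `weights`, and the objective
#'   trace.
#' @examples
#' Ms <- replicate(4, matrix(rnorm(30), 10) , simplify = FALSE)
#' fit <- ols_superpose(lapply(Ms, function(x) x + matrix(rnorm(30), 10)))
#' @export
ols_superpose <- function(members, tol = 1e-8, max_iter = 200) {
  Xs <- as_coord_list(members)
  m <- length(Xs)
  if (m < 2L) stopf("at least 2 conformations are required")
  n <- nrow(Xs[[1L]])
  M <- sweep(Xs[[1L]], 2L, colMeans(Xs[[1L]]))
  trace <- numeric(0)
  converged <- FALSE
  aligned <- NULL; transforms <- NULL
  for (it in seq_len(max_iter)) {
    transforms <- lapply(Xs, optimal_transform, M = M)
    aligned <- Map(apply_transform, Xs, transforms)
    M <- Reduce(`+`, aligned) / m
    rss <- sum(vapply(aligned, function(Y) sum((Y - M)^2), numeric(1)))
    trace <- c(trace, rss)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(prev - rss) <= tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  g <- gauge_anchor_single(M, aligned, transforms,
                           Sigma = sample_covariance(aligned, M, "ml"),
                           anchor_X = Xs[[1L]])
  new_single_fit("ols", g$M, g$Sigma, g$transforms, rep(1, n),
                 length(trace), converged, trace, "rss")
}

# --- IWLS -------------------------------------------------------------------

#' @rdname ols_superpose
#' @param variance_floor Lower clamp (Angstrom^2) applied to per-atom
#'   variances before inversion to weights; prevents weight blow-up on
#'   (nearly) noiseless atoms.
#' @param prior_df Strength (pseudo-observations) of the empirical-Bayes
#'   smoothing of the per-atom variances toward their pooled mean before
#'   inversion to weights. Pure maximum-likelihood weighting (`prior_df =
#'   0`) is degenerate: the quietest atom acquires an unbounded weight and
#'   the transforms collapse onto it, zeroing its residual and reinforcing
#'   the weight — the divergence that motivates the inverse-gamma variance
#'   priors of heteroscedastic superposition methods. The default smooths
#'   each variance as if 4 pooled-mean pseudo-observations were added.
#' @param min_rel_variance Relative variance floor: no atom's working
#'   variance may fall below this fraction of the mean atom variance
#'   (default 0.05, i.e. the weight ratio is capped at 20). The smoothing
#'   prior alone vanishes as m grows, while the degenerate fixed point (a
#'   pinned atom with an unbounded weight) persists at any m; the relative
#'   floor removes it at every sample size.
#' @export
iwls_superpose <- function(members, tol = 1e-8, max_iter = 200,
                           variance_floor = 1e-6, prior_df = 4,
                           min_rel_variance = 0.05) {
  Xs <- as_coord_list(members)
  m <- length(Xs)
  if (m < 2L) stopf("at least 2 conformations are required")
  n <- nrow(Xs[[1L]])
  M <- sweep(Xs[[1L]], 2L, colMeans(Xs[[1L]]))
  w <- rep(1, n)
  sigma2 <- rep(1, n)
  trace <- numeric(0)
  converged <- FALSE
  aligned <- NULL; transforms <- NULL
  for (it in seq_len(max_iter)) {
    transforms <- lapply(Xs, optimal_transform, M = M, w = w)
    aligned <- Map(apply_transform, Xs, transforms)
    M <- Reduce(`+`, aligned) / m
    # per-atom ML variances of the isotropic-per-atom error model,
    # smoothed toward their pooled mean (moderated weights)
    ss <- Reduce(`+`, lapply(aligned, function(Y) rowSums((Y - M)^2)))
    s2_raw <- ss / (3 * m)
    sigma2 <- pmax((3 * m * s2_raw + prior_df * mean(s2_raw)) /
                     (3 * m + prior_df),
                   min_rel_variance * mean(s2_raw), variance_floor)
    w <- 1 / sigma2
    ll <- -(3 * n * m / 2) * log(2 * pi) -
      (3 * m / 2) * sum(log(sigma2)) - sum(ss / (2 * sigma2))
    trace <- c(trace, ll)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(ll - prev) <= tol * max(abs(prev), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  g <- gauge_anchor_single(M, aligned, transforms,
                           Sigma = sample_covariance(aligned, M, "ml"),
                           anchor_X = Xs[[1L]])
  fit <- new_single_fit("iwls", g$M, g$Sigma, g$transforms, w,
                        length(trace), converged, trace, "loglik")
  fit$atom_variances <- sigma2
  fit$variance_floor <- variance_floor
  fit
}
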