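#' Configuration for the random-effects (REM) fitter
#'
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM sweeps (EM convergence is slow; the default is
#'   generous).
#' @param ridge Relative ridge `eps`: every covariance inversion uses
#'   `C + eps * (tr(C)/3n) * I`. Rank-deficient ML covariance estimates are
#'   the norm when `nu` or `sum(m_i)` is below `3n`, so a small ridge keeps
#'   the E-step solvable; the value used is reported in the fit.
#' @param covariance_structure `"full"` (default) or `"atom_block"`, which
#'   restricts W and Sigma to block-diagonal 3 x 3 atom blocks during the EM
#'   iterations (full-rank much sooner) and recomputes full matrices from the
#'   final residuals and posteriors.
#' @param init `"ts_warm"` (default; warm start from a two-stage fit, whose
#'   stage-1 per-ensemble superpositions preserve the ensemble deviations),
#'   `"ols_pool"` (pooled OLS superposition start; simpler, but aligning
#'   every conformation to the pooled mean pushes part of each ensemble
#'   deviation into the initial transforms, a poorer basin that EM does not
#'   leave) or `"identity"` (take the input frames as already superposed;
#'   identity initial transforms and moment-based starting covariances).
#' @param seed Optional integer; when set, the initial superposition is
#'   anchored to a randomly chosen conformation instead of the first one,
#'   giving cheap random restarts (the converged superposition can depend on
#'   the initial one).
#' @param update_transforms Set `FALSE` to freeze the input frames (no
#'   transform step); mainly for validating the EM updates in a fixed frame.
#' @param variance_floor Lower clamp (Angstrom^2) on per-atom variances used
#'   for superposition weights.
#' @return A list of class `rem_config`.
#' @export
rem_config <- function(tol = 1e-8, max_iter = 5000, ridge = 1e-6,
                       covariance_structure = c("full", "atom_block"),
                       init = c("ts_warm", "ols_pool", "identity"), seed = NULL,
                       update_transforms = TRUE, variance_floor = 1e-6) {
  stopifnot(tol > 0, ridge >= 0, max_iter >= 1)
  structure(list(
    tol = tol, max_iter = max_iter, ridge = ridge,
    covariance_structure = match.arg(covariance_structure),
    init = match.arg(init), seed = seed,
    update_transforms = isTRUE(update_transforms),
    variance_floor = variance_floor
  ), class = "rem_config")
}

# Zero all off-diagonal 3x3 atom blocks (atom_block covariance structure).
project_atom_block <- function(C) {
  n <- nrow(C) / 3L
  out <- matrix(0, nrow(C), ncol(C))
  for (a in seq_len(n)) {
    idx <- (3L * (a - 1L) + 1L):(3L * a)
    out[idx, idx] <- C[idx, idx]
  }
  out
}

# Superposition weights from a covariance: inverse mean per-atom variance,
# w_a = 3 / tr(Sigma_aa), clamped at the variance floor and at a relative
# floor (5% of the mean atom variance) that bounds the weight ratio.
weights_from_cov <- function(Sigma, floor) {
  av <- atom_variances(Sigma)
  1 / pmax(av, 0.05 * mean(av), floor)
}

# E-step: posterior covariance V_i = (Wbar^-1 + m_i Sbar^-1)^-1 and mean
# b_i = V_i Sbar^-1 sum_j (y_ij - mu). Y is the 3n x N matrix of vectorized
# transformed coordinates; ens/sizes index ensembles.
rem_e_step <- function(Y, mu, W, Sigma, ens, sizes, ridge) {
  p <- nrow(Y)
  Winv <- chol_solve(W, diag(p), ridge)
  Sinv <- chol_solve(Sigma, diag(p), ridge)
  nu <- length(sizes)
  V <- vector("list", nu)
  B <- matrix(0, p, nu)
  Vm <- list()  # cache per unique ensemble size
  S <- Y - mu
  for (i in seq_len(nu)) {
    key <- as.character(sizes[i])
    if (is.null(Vm[[key]]))
      Vm[[key]] <- chol_solve(Winv + sizes[i] * Sinv, diag(p), ridge = 0)
    V[[i]] <- symmetrize(Vm[[key]])
    si <- rowSums(S[, ens == i, drop = FALSE])
    B[, i] <- V[[i]] %*% (Sinv %*% si)
  }
  list(V = V, B = B)
}

# M-step (Laird-Ware updates) given the E-step posteriors.
rem_m_step <- function(Y, ens, sizes, E) {
  N <- ncol(Y)
  nu <- length(sizes)
  mu <- (rowSums(Y) - as.numeric(E$B %*% sizes)) / N
  W <- Reduce(`+`, lapply(seq_len(nu), function(i)
    tcrossprod(E$B[, i]) + E$V[[i]])) / nu
  R <- Y - mu - E$B[, ens, drop = FALSE]
  SigV <- Reduce(`+`, lapply(seq_len(nu), function(i) sizes[i] * E$V[[i]]))
  Sigma <- (tcrossprod(R) + SigV) / N
  list(mu = mu, W = symmetrize(W), Sigma = symmetrize(Sigma))
}

#' Marginal log-likelihood of the random-effects superposition model
#'
#' Evaluates the exact marginal Gaussian log-likelihood of the transformed
#' coordinates: within ensemble i the stacked vectors `y_i1..y_im` are
#' jointly normal with mean `1 (x) mu` and covariance
#' `I_m (x) Sigma + J_m (x) W`. The evaluation reduces to one 3n x 3n solve
#' in `Sigma` and one in `Sigma + m_i W` per distinct ensemble size (never a
#' 3nm-dimensional factorization), via the orthogonal split of each ensemble
#' into its mean and within-ensemble contrasts.
#'
#' @param set An [ensemble_set()].
#' @param M n x 3 mean structure.
#' @param W,Sigma 3n x 3n inter-/intra-ensemble covariance matrices.
#' @param transforms List of [rigid_transform()]s, one per conformation in
#'   set order.
#' @param ridge Relative ridge applied to `Sigma` and `Sigma + m W` before
#'   factorization (0 = exact).
#' @return Scalar log-likelihood.
#' @export
rem_loglik <- function(set, M, W, Sigma, transforms, ridge = 0) {
  mem <- set_members(set)
  N <- length(mem$coords)
  if (length(transforms) != N) stopf("need one transform per conformation")
  p <- 3L * set$n_atoms
  Y <- vapply(seq_len(N), function(k)
    vec3n(apply_transform(mem$coords[[k]], transforms[[k]])), numeric(p))
  rem_loglik_core(Y, vec3n(as.matrix(M)), W, Sigma,
                  mem$ens_index, unname(set$sizes), ridge)
}

# loglik on a precomputed 3n x N matrix of transformed coordinates
rem_loglik_core <- function(Y, mu, W, Sigma, ens, sizes, ridge = 0) {
  p <- nrow(Y)
  cS <- chol_logdet(Sigma, ridge)
  ll <- 0
  Gm <- list()
  for (i in seq_along(sizes)) {
    m <- sizes[i]
    Yi <- Y[, ens == i, drop = FALSE]
    ybar <- rowMeans(Yi)
    key <- as.character(m)
    if (is.null(Gm[[key]])) Gm[[key]] <- chol_logdet(Sigma + m * W, ridge)
    cG <- Gm[[key]]
    dbar <- ybar - mu
    qmean <- m * sum(backsolve(cG$R, dbar, transpose = TRUE)^2)
    qwithin <- 0
    if (m > 1L) {
      D <- Yi - ybar
      qwithin <- sum(backsolve(cS$R, D, transpose = TRUE)^2)
    }
    ll <- ll - 0.5 * (p * m * log(2 * pi) +
                        (m - 1) * cS$logdet + cG$logdet + qmean + qwithin)
  }
  if (!is.finite(ll)) stopf("non-finite log-likelihood")
  ll
}

#' Fit the two-level random-effects superposition model by EM
#'
#' Jointly estimates per-conformation rigid transforms, the population mean
#' structure M, the inter-ensemble covariance W, the intra-ensemble
#' covariance Sigma and empirical-Bayes posterior ensemble deviations Z_i
#' under the model `Y_ij = M + Z_i + E_ij` with `vec(t(Z_i)) ~ N(0, W)` and
#' `vec(t(E_ij)) ~ N(0, Sigma)`. Each EM sweep cycles: (1) re-superpose each
#' conformation onto its tentative ensemble mean `M + Z_i` with atom weights
#' from the current Sigma; (2) E-step — Gaussian posterior of each `Z_i`
#' under the current `(W, Sigma)` prior; (3) M-step — Laird–Ware updates of
#' `mu`, W and Sigma; (4) gauge step — recenter the mean at the origin
#' (absorbed into the transforms, likelihood-invariant).
#'
#' A sweep is only accepted if the marginal log-likelihood does not
#' decrease: the scalar-weight transform step is not an exact ascent step
#' under a full Sigma, so a proposed transform update that lowers the
#' likelihood is discarded, and a sweep with no monotone progress (the
#' numerically flat region around the optimum) terminates the fit. The
#' recorded `loglik_trace` is therefore non-decreasing.
#'
#' @param set An [ensemble_set()] with at least 2 ensembles and
#'   `sum(m_i) >= nu + 1` (otherwise W and Sigma are confounded).
#' @param config A [rem_config()].
#' @return An object of class `rem_fit`: `M_hat` (centered mean structure),
#'   `W_hat`, `Sigma_hat`, `Z_hat` (list of posterior-mean n x 3 ensemble
#'   deviations), `V` (posterior covariances), `transforms`, `loglik_trace`,
#'   `n_iter`, `converged`, plus bookkeeping (`ens_ids`, `conf_ids`,
#'   `sizes`, `config`).
#' @seealso [ts_fit()], [spe_fit()], [covariance_pca()]
#' @export
rem_fit <- function(set, config = rem_config()) {
  if (set$n_ensembles < 2L)
    stopf("inter-ensemble variance unidentifiable: need at least 2 ensembles")
  if (sum(set$sizes) < set$n_ensembles + 1L)
    stopf("W and Sigma are confounded: need sum(m_i) >= nu + 1")
  mem <- set_members(set)
  n <- set$n_atoms
  p <- 3L * n
  N <- length(mem$coords)
  sizes <- set$sizes
  ens <- mem$ens_index
  block <- config$covariance_structure == "atom_block"

  # ---- initialization ------------------------------------------------------
  pool <- mem$coords
  if (!is.null(config$seed)) {
    set.seed(config$seed)
    anchor <- sample.int(N, 1L)
    pool <- c(pool[anchor], pool[-anchor])
  }
  if (config$init == "ts_warm") {
    # the warm start needs a consistent configuration, not a converged one
    warm <- ts_fit(set, first_stage = "iwls", tol = 1e-6, max_iter = 60)
    M <- warm$M_hat
    transforms <- warm$transforms
    # ensembles whose stage-1 fit failed have no warm transforms; superpose
    # them directly onto the warm mean
    for (k in seq_len(N)) if (is.null(transforms[[k]]))
      transforms[[k]] <- optimal_transform(mem$coords[[k]], M)
    W <- warm$W_hat
    Sigma <- warm$Sigma_pooled
    Y <- vapply(seq_len(N), function(k)
      vec3n(apply_transform(mem$coords[[k]], transforms[[k]])), numeric(p))
    mu <- vec3n(M)
  } else {
    transforms <- if (config$init == "identity") {
      replicate(N, rigid_transform(), simplify = FALSE)
    } else {
      init_fit <- ols_superpose(pool)
      # re-derive transforms in original member order against the pooled mean
      lapply(mem$coords, optimal_transform, M = init_fit$M_hat)
    }
    Y <- vapply(seq_len(N), function(k)
      vec3n(apply_transform(mem$coords[[k]], transforms[[k]])), numeric(p))
    mu <- rowMeans(Y)
    ybar_i <- vapply(seq_along(sizes), function(i)
      rowMeans(Y[, ens == i, drop = FALSE]), numeric(p))
    W <- symmetrize(tcrossprod(ybar_i - mu) / length(sizes))
    Rw <- Y - ybar_i[, ens, drop = FALSE]
    Sigma <- symmetrize(tcrossprod(Rw) / N)
  }
  if (block) { W <- project_atom_block(W); Sigma <- project_atom_block(Sigma) }
  # overdispersed PD start: the raw moment estimates are rank-deficient
  # whenever nu - 1 < 3n, which makes their (ridged) likelihood a degenerate
  # spike; a 10% isotropic inflation yields a strictly PD start from which
  # EM ascends
  eps0 <- 0.1 * (sum(diag(W)) + sum(diag(Sigma))) / (2 * p) + 1e-10
  W <- W + diag(eps0, p)
  Sigma <- Sigma + diag(eps0, p)
  M <- unvec3n(mu)
  M0 <- M  # orientation anchor: the initial pooled-mean frame

  sizes <- unname(sizes)
  loglik <- rem_loglik_core(Y, mu, W, Sigma, ens, sizes, config$ridge)
  trace <- loglik
  E <- rem_e_step(Y, mu, W, Sigma, ens, sizes, config$ridge)
  converged <- FALSE

  for (it in seq_len(config$max_iter)) {
    # (1) transform step: superpose onto M + Z_i, weights from Sigma diag
    if (config$update_transforms) {
      w <- weights_from_cov(Sigma, config$variance_floor)
      sw <- sum(w)
      targets <- lapply(seq_along(sizes), function(i) M + unvec3n(E$B[, i]))
      prop <- vector("list", N)
      Yprop <- Y
      for (k in seq_len(N)) {
        ft <- fast_transform(mem$coords[[k]], targets[[ens[k]]], w, sw)
        prop[[k]] <- ft
        Yprop[, k] <- vec3n(ft$Y)
      }
      ll_prop <- rem_loglik_core(Yprop, mu, W, Sigma, ens, sizes, config$ridge)
      if (ll_prop >= loglik) {
        transforms <- lapply(prop, function(ft)
          structure(list(t = ft$t, R = ft$R), class = "rigid_transform"))
        loglik <- ll_prop
        Y <- Yprop
      }
    }

    # (2)-(3) E-step and M-step
    E <- rem_e_step(Y, mu, W, Sigma, ens, sizes, config$ridge)
    Mstep <- rem_m_step(Y, ens, sizes, E)
    mu_new <- Mstep$mu
    W_new <- Mstep$W
    Sigma_new <- Mstep$Sigma
    if (block) {
      W_new <- project_atom_block(W_new)
      Sigma_new <- project_atom_block(Sigma_new)
    }

    # (4) gauge step: recenter the mean; the shift is absorbed into the
    # transforms, leaving the likelihood unchanged
    cshift <- colMeans(unvec3n(mu_new))
    if (max(abs(cshift)) > 0) {
      mu_new <- mu_new - vec3n(matrix(cshift, n, 3L, byrow = TRUE))
      transforms_new <- lapply(transforms, function(tr)
        rigid_transform(tr$t + as.numeric(tr$R %*% cshift), tr$R))
      Y <- Y - vec3n(matrix(cshift, n, 3L, byrow = TRUE))
    } else transforms_new <- transforms

    ll_new <- rem_loglik_core(Y, mu_new, W_new, Sigma_new, ens, sizes,
                              config$ridge)
    if (ll_new < loglik) {
      # numerically flat region: no monotone progress available; stop here
      converged <- TRUE
      break
    }
    mu <- mu_new; W <- W_new; Sigma <- Sigma_new
    transforms <- transforms_new
    M <- unvec3n(mu)
    delta <- ll_new - loglik
    loglik <- ll_new
    trace <- c(trace, loglik)
    if (delta <= config$tol * abs(loglik)) {
      converged <- TRUE
      break
    }
  }

  # refresh posteriors at the accepted parameters
  E <- rem_e_step(Y, mu, W, Sigma, ens, sizes, config$ridge)
  if (block) {
    # full covariance matrices recomputed from residuals and posteriors
    full <- rem_m_step(Y, ens, sizes, E)
    W_full <- full$W
    Sigma_full <- full$Sigma
  } else {
    W_full <- W
    Sigma_full <- Sigma
  }

  # final orientation gauge: anchor M_hat to the initial pooled-mean frame
  g <- optimal_transform(M, M0)
  Mg <- apply_transform(M, g)
  Mg <- sweep(Mg, 2L, colMeans(Mg))
  transforms <- lapply(transforms, function(tr)
    rigid_transform(tr$t + as.numeric(tr$R %*% g$t), tr$R %*% g$R))
  W_full <- rotate_cov3n(W_full, g$R)
  Sigma_full <- rotate_cov3n(Sigma_full, g$R)
  K <- kronecker(diag(n), t(g$R))
  Z_hat <- lapply(seq_along(sizes), function(i)
    unvec3n(as.numeric(K %*% E$B[, i])))
  V <- lapply(E$V, function(v) symmetrize(K %*% v %*% t(K)))

  structure(list(
    M_hat = Mg, W_hat = W_full, Sigma_hat = Sigma_full,
    Z_hat = setNames(Z_hat, names(set$ensembles)),
    V = setNames(V, names(set$ensembles)),
    transforms = transforms,
    loglik_trace = trace, n_iter = length(trace) - 1L,
    converged = converged,
    ens_ids = mem$ens_id, conf_ids = mem$conf_id, sizes = sizes,
    config = config, method = "rem"
  ), class = "rem_fit")
}

#' @export
print.rem_fit <- function(x, ...) {
  cat(sprintf(
    "REM fit: %d ensembles, %d conformations, %d atoms\n",
    length(x$sizes), length(x$transforms), nrow(x$M_hat)))
  cat(sprintf("  EM sweeps: %d (%s), log-likelihood %.4f\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$loglik_trace[length(x$loglik_trace)]))
  cat(sprintf("  tr(W_hat) = %.4g, tr(Sigma_hat) = %.4g (Angstrom^2)\n",
              sum(diag(x$W_hat)), sum(diag(x$Sigma_hat))))
  invisible(x)
}

#' Posterior (empirical Bayes) ensemble mean structures
#'
#' Returns `M_hat + Z_hat_i` for every ensemble. The posterior deviations
#' shrink each raw ensemble-mean deviation toward the population mean, the
#' more strongly the smaller the ensemble.
#'
#' @param fit A [rem_fit()] result.
#' @return Named list of n x 3 structures, Angstrom.
#' @export
posterior_ensemble_means <- function(fit) {
  stopifnot(inherits(fit, "rem_fit"))
  lapply(fit$Z_hat, function(Z) fit$M_hat + Z)
}
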