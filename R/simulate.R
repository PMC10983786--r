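#' Synthetic ground truth for recovery experiments
#'
#' Builds a smooth helix-like mean chain and a pair of symmetric positive
#' definite 3n x 3n covariance matrices to act as simulation truth. Three
#' covariance styles are available:
#' \describe{
#'   \item{`low_rank_plus_diag`}{a few smooth, spatially coherent modes with
#'     decaying eigenvalues on top of an isotropic floor,
#'     `C = sum_k lambda_k v_k v_k^T + d I` — the generic "essential
#'     dynamics" shape of protein covariances, with strong per-atom
#'     heteroscedasticity;}
#'   \item{`hinge`}{a single two-domain hinge mode (the two halves of the
#'     chain move oppositely) plus the isotropic floor;}
#'   \item{`isotropic`}{`sigma^2 I`.}
#' }
#' Both matrices are rescaled so their mean per-coordinate standard
#' deviation `mean(sqrt(diag(C)))` equals `scale`.
#'
#' @param n Number of atoms.
#' @param style Covariance style (see above).
#' @param scale Target mean per-coordinate standard deviation, Angstrom.
#' @param rank Number of smooth modes for `low_rank_plus_diag`.
#' @param diag_frac Fraction of the total variance carried by the local
#'   (diagonal) floor under the collective modes; the default 0.3 leaves the
#'   top modes with ~70% of the variance, the usual essential-dynamics
#'   picture.
#' @param seed Optional seed fixing the construction.
#' @return List with `M_true` (n x 3, centered), `W_true`, `Sigma_true`
#'   (3n x 3n SPD).
#' @export
make_truth <- function(n, style = c("low_rank_plus_diag", "hinge", "isotropic"),
                       scale = 0.5, rank = 3L, diag_frac = 0.3, seed = NULL) {
  style <- match.arg(style)
  if (!is.null(seed)) set.seed(seed)
  p <- 3L * n
  # globular smooth backbone: a 3D Lissajous curve (comparable extent along
  # all three axes, like a folded chain) scaled to a protein-like radius of
  # gyration, Rg ~ 2.2 n^0.38 A; the lever arm for rotation estimation, not
  # the exact inter-atom spacing, is what conditions the recovery problem
  s <- seq_len(n)
  tt <- 2 * pi * (s - 1) / n
  M <- cbind(sin(tt), sin(2 * tt + 1), sin(3 * tt + 2))
  M <- sweep(M, 2L, colMeans(M))
  M <- M * 2.2 * n^0.38 / sqrt(mean(rowSums(M^2)))

  # orthonormal basis of the rigid-body subspace of M (3 translations and
  # 3 infinitesimal rotations): variance along these directions is pure
  # gauge and would be absorbed by any superposition, so truth modes are
  # built orthogonal to it (as post-superposition covariance estimates are)
  rigid <- matrix(0, p, 6L)
  for (k in 1:3) rigid[seq(k, p, by = 3L), k] <- 1
  gens <- list(c(2, 3), c(3, 1), c(1, 2))
  for (k in 1:3) {
    field <- matrix(0, n, 3L)
    ax <- gens[[k]]
    field[, ax[1]] <- -M[, ax[2]]
    field[, ax[2]] <- M[, ax[1]]
    rigid[, 3L + k] <- vec3n(field)
  }
  rigid <- qr.Q(qr(rigid))
  deflate <- function(V) {
    V <- V - rigid %*% crossprod(rigid, V)
    qr.Q(qr(V))
  }
  # Remove the rigid-body subspace from a built covariance in the metric of
  # its own inverse atom variances (oblique projection). A heteroscedastic
  # superposition quotients out rigid motions orthogonally under the
  # inverse-variance metric, so a truth produced by such a pipeline (as an
  # MD-derived reference covariance is) has its null space there; building
  # the truth the same way makes recovery well-posed for weighted fitters.
  deflate_weighted <- function(C) {
    av <- atom_variances(C)
    wv <- rep(1 / pmax(av, 0.05 * mean(av)), each = 3L)
    Bw <- rigid * wv
    Q <- diag(p) - rigid %*% solve(crossprod(rigid, Bw), t(Bw))
    symmetrize(Q %*% C %*% t(Q))
  }

  # terminal-flexibility envelope: chain ends fluctuate several-fold more
  # than the core, the strong per-atom heteroscedasticity characteristic of
  # protein ensembles
  u <- 2 * (s - 0.5) / n - 1
  envelope <- 1 + 3 * u^4

  build <- function(mode_phase) {
    if (style == "isotropic") return(diag(1, p))
    if (style == "hinge") {
      dir <- matrix(rnorm(3), n, 3L, byrow = TRUE)
      amp <- tanh((s - (n + 1) / 2) / (n / 10))  # opposite signs per domain
      V <- deflate(cbind(vec3n(dir * amp)))
      lam <- 1
    } else {
      if (3L * rank > p) stopf("rank must not exceed 3n")
      V <- vapply(seq_len(rank), function(k) {
        phase <- mode_phase + k
        field <- envelope * cbind(sin(pi * k * (s - 0.5) / n + phase),
                                  cos(pi * k * (s - 0.5) / n + 0.7 * phase),
                                  sin(pi * (k + 0.5) * (s - 0.5) / n + 1.3 * phase))
        vec3n(field)
      }, numeric(p))
      V <- deflate(V)
      lam <- 1 / seq_len(rank)^2
    }
    denv <- if (style == "hinge") rep(1, n) else envelope^2
    d <- rep(denv, each = 3L)
    # floor carries diag_frac of the total trace, modes the rest
    d <- d * (diag_frac / (1 - diag_frac)) * sum(lam) / sum(d)
    C <- V %*% (lam * t(V)) + diag(d, p)
    symmetrize(C)
  }
  scale_to <- function(C) {
    f <- scale / mean(sqrt(diag(C)))
    C * f^2
  }
  finish <- function(C) {
    if (style != "isotropic") C <- deflate_weighted(C)
    scale_to(C)
  }
  W <- build(stats::runif(1, 0, 2 * pi))
  S <- build(stats::runif(1, 0, 2 * pi))
  list(M_true = M, W_true = finish(W), Sigma_true = finish(S))
}

#' Pass a synthetic truth through the estimation pipeline once
#'
#' Replaces each truth covariance with the (registered, rescaled)
#' heteroscedastic-superposition estimate obtained from a large sample drawn
#' from it. Reference covariances for recovery studies are in practice
#' themselves estimates from trajectory data, i.e. images of the estimation
#' pipeline; a truth constructed purely analytically is not exactly on that
#' image manifold, and the small mismatch becomes the dominant error at
#' large ensemble sizes, flattening or inverting accuracy-vs-size curves.
#' Calibration removes it: large-sample fits then converge to the truth.
#'
#' @param truth A list from [make_truth()].
#' @param m_cal Calibration sample size (default 300).
#' @param seed Seed for the calibration draw.
#' @return The truth list with `W_true` and `Sigma_true` replaced; the mean
#'   per-coordinate standard deviation of each matrix is preserved.
#' @export
calibrate_truth <- function(truth, m_cal = 300, seed = 1) {
  set.seed(seed)
  M <- truth$M_true
  p <- 3L * nrow(M)
  refit <- function(C) {
    scale <- mean(sqrt(diag(C)))
    L <- chol(C + diag(1e-10 * max(diag(C), 1), p))
    draws <- lapply(seq_len(m_cal), function(j)
      M + unvec3n(as.numeric(crossprod(L, rnorm(p)))))
    fit <- iwls_superpose(draws, tol = 1e-8, max_iter = 100)
    g <- optimal_transform(fit$M_hat, M)
    S <- rotate_cov3n(fit$Sigma_hat, g$R)
    S * (scale / mean(sqrt(diag(S))))^2
  }
  truth$W_true <- refit(truth$W_true)
  truth$Sigma_true <- refit(truth$Sigma_true)
  truth
}

#' Generate a synthetic multi-ensemble dataset
#'
#' Draws conformations from the two-level model: per ensemble a deviation
#' `vec(t(Z_i)) ~ N(0, W_true)`, per conformation an error
#' `vec(t(E_ij)) ~ N(0, Sigma_true)`, giving `Y_ij = M + Z_i + E_ij`; each
#' `Y_ij` is then (optionally) displaced by a random rigid motion — a
#' uniform SO(3) rotation and a Gaussian translation — producing the raw
#' coordinates `X_ij` from which a fitter must recover the common frame.
#' The generating deviations and transforms are retained as ground truth.
#'
#' @param truth A list from [make_truth()] (or with the same fields).
#' @param nu Number of ensembles.
#' @param m Ensemble size, scalar or length-`nu` vector.
#' @param rigid_scramble Displace each conformation by a random rigid motion
#'   (default `TRUE`).
#' @param translation_scale SD of each translation component, Angstrom.
#' @param seed Seed fixing the full stream.
#' @return A list of class `sim_ensembles`: `set` (an [ensemble_set()] of
#'   the raw `X_ij`), `truth`, `Z` (true ensemble deviations), `transforms`
#'   (the rigid motions whose application to `X_ij` recovers `Y_ij`), and
#'   `Y` (the generation-frame coordinates).
#' @export
simulate_ensembles <- function(truth, nu, m, rigid_scramble = TRUE,
                               translation_scale = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (length(m) == 1L) rep(m, nu) else m
  stopifnot(length(sizes) == nu)
  M <- truth$M_true
  n <- nrow(M)
  p <- 3L * n
  Lw <- chol(ridge_stabilize(truth$W_true, 1e-12))
  Ls <- chol(ridge_stabilize(truth$Sigma_true, 1e-12))
  ens <- list()
  Z <- list()
  transforms <- list()
  Ys <- list()
  for (i in seq_len(nu)) {
    zi <- unvec3n(as.numeric(crossprod(Lw, rnorm(p))))
    Z[[i]] <- zi
    members <- vector("list", sizes[i])
    for (j in seq_len(sizes[i])) {
      eij <- unvec3n(as.numeric(crossprod(Ls, rnorm(p))))
      Yij <- M + zi + eij
      if (rigid_scramble) {
        R <- random_rotation()
        t_vec <- rnorm(3, sd = translation_scale)
        # X = Y R^T + 1 t^T, so that (X - 1 t^T) R recovers Y
        Xij <- Yij %*% t(R) + matrix(t_vec, n, 3L, byrow = TRUE)
        tr <- rigid_transform(t_vec, R)
      } else {
        Xij <- Yij
        tr <- rigid_transform()
      }
      id <- sprintf("e%02d_c%03d", i, j)
      members[[j]] <- conformation(id, Xij)
      transforms[[length(transforms) + 1L]] <- tr
      Ys[[length(Ys) + 1L]] <- Yij
    }
    ens[[sprintf("e%02d", i)]] <- members
  }
  structure(list(set = ensemble_set(ens), truth = truth, Z = Z,
                 transforms = transforms, Y = Ys,
                 nu = nu, m = sizes,
                 rigid_scramble = rigid_scramble), class = "sim_ensembles")
}

#' @export
print.sim_ensembles <- function(x, ...) {
  cat("Synthetic ensembles:", x$nu, "ensembles, sizes",
      paste(unique(x$m), collapse = "/"), "-",
      nrow(x$truth$M_true), "atoms",
      if (x$rigid_scramble) "(rigid-scrambled)" else "(generation frame)", "\n")
  invisible(x)
}

# Fit one method to a simulated dataset with moderate iteration budgets
# (the recovery harness runs many fits).
fit_method <- function(set, method, rem_cfg = NULL) {
  switch(method,
    "rem" = rem_fit(set, rem_cfg %||% rem_config(tol = 1e-6, max_iter = 100)),
    "ts-iwls" = ts_fit(set, first_stage = "iwls", tol = 1e-7, max_iter = 100),
    "ts-ols" = ts_fit(set, first_stage = "ols", tol = 1e-7, max_iter = 100),
    "spe" = spe_fit(set, tol = 1e-7, max_iter = 100),
    stopf("unknown method '%s'", method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# W- and Sigma-type covariance estimates of a fit (NULL when not estimated).
fit_covariances <- function(fit) {
  switch(fit$method %||% class(fit)[1],
    "rem" = list(W = fit$W_hat, Sigma = fit$Sigma_hat),
    "spe" = list(W = NULL, Sigma = NULL, Delta = fit$Delta_hat),
    list(W = fit$W_hat, Sigma = fit$Sigma_pooled))
}

#' Covariance-recovery experiment on synthetic data
#'
#' For every grid cell `(nu, m)` and replicate: generate a dataset from the
#' supplied truth, fit each requested method, register the fit onto the
#' truth frame, and score the recovered covariance matrices by the MAE of
#' per-coordinate standard deviations ([mae_sqrt_diag()]) and the RMSIP of
#' the top-k eigenvector subspaces against the truth. Individual fit
#' failures are recorded and excluded from the averages.
#'
#' @param truth A list from [make_truth()].
#' @param nu_grid,m_grid Integer vectors of ensemble counts/sizes.
#' @param replicates Replicates per cell.
#' @param methods Subset of `c("rem", "ts-iwls", "ts-ols", "spe")`.
#' @param k_rmsip Subspace sizes for RMSIP (default `c(2, 8)`).
#' @param seed Base seed; every (cell, replicate) derives its own stream.
#' @param rem_cfg Optional [rem_config()] override for the REM fits.
#' @param ... Passed to [simulate_ensembles()].
#' @return A list of class `recovery_report`: `results` (tibble, one row per
#'   method x cell x replicate) and `summary` (tibble of means over
#'   successful replicates).
#' @export
recovery_experiment <- function(truth, nu_grid, m_grid, replicates = 10,
                                methods = c("rem", "ts-iwls", "ts-ols"),
                                k_rmsip = c(2L, 8L), seed = 1L,
                                rem_cfg = NULL, ...) {
  p <- 3L * nrow(truth$M_true)
  k_rmsip <- k_rmsip[k_rmsip <= p]
  pcaW <- covariance_pca(truth$W_true, max(k_rmsip), source = "W")
  pcaS <- covariance_pca(truth$Sigma_true, max(k_rmsip), source = "Sigma")
  rows <- list()
  for (nu in nu_grid) for (m in m_grid) for (r in seq_len(replicates)) {
    cell_seed <- (seed * 1000L + nu * 97L + m * 13L + r) %% .Machine$integer.max
    sim <- simulate_ensembles(truth, nu = nu, m = m, seed = cell_seed, ...)
    for (method in methods) {
      fit <- tryCatch(fit_method(sim$set, method, rem_cfg),
                      error = function(e) e)
      row <- tibble::tibble(method = method, nu = nu, m = m, replicate = r,
                            failed = FALSE,
                            mae_W = NA_real_, mae_Sigma = NA_real_)
      for (k in k_rmsip) {
        row[[paste0("rmsip_W_", k)]] <- NA_real_
        row[[paste0("rmsip_Sigma_", k)]] <- NA_real_
      }
      if (inherits(fit, "error")) {
        row$failed <- TRUE
        rows[[length(rows) + 1L]] <- row
        next
      }
      fit <- register_to_reference(fit, truth$M_true)
      cov <- fit_covariances(fit)
      W_hat <- cov$W %||% cov$Delta
      Sigma_hat <- cov$Sigma %||% cov$Delta
      row$mae_W <- mae_sqrt_diag(W_hat, truth$W_true)
      row$mae_Sigma <- mae_sqrt_diag(Sigma_hat, truth$Sigma_true)
      for (k in k_rmsip) {
        eW <- covariance_pca(W_hat, k, source = "W")
        eS <- covariance_pca(Sigma_hat, k, source = "Sigma")
        row[[paste0("rmsip_W_", k)]] <-
          rmsip(eW$vectors, pcaW$vectors[, seq_len(k), drop = FALSE])
        row[[paste0("rmsip_Sigma_", k)]] <-
          rmsip(eS$vectors, pcaS$vectors[, seq_len(k), drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- setdiff(names(results),
                         c("method", "nu", "m", "replicate", "failed"))
  keys <- unique(results[, c("method", "nu", "m")])
  summ <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$method == keys$method[i] & results$nu == keys$nu[i] &
      results$m == keys$m[i]
    ok <- sel & !results$failed
    out <- keys[i, ]
    out$n_ok <- sum(ok)
    out$n_failed <- sum(sel & results$failed)
    for (cl in metric_cols) out[[cl]] <- mean(results[[cl]][ok])
    out
  })
  structure(list(results = tibble::as_tibble(results),
                 summary = tibble::as_tibble(do.call(rbind, summ)),
                 truth = truth, k_rmsip = k_rmsip),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Covariance-recovery experiment\n")
  print(x$summary)
  invisible(x)
}
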