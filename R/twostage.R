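#' Two-stage (fixed-effects) covariance estimation
#'
#' The two-stage (TS) baseline treats ensemble deviations as fixed effects:
#' stage 1 superposes each ensemble on its own (IWLS by default, OLS for the
#' TS/OLS variant) to obtain the ensemble mean structures and per-ensemble
#' covariances; stage 2 superposes the ensemble means by IWLS to obtain the
#' population mean `M_hat` and the inter-ensemble covariance `W_hat` (sample
#' covariance of the aligned means, ML divisor over `nu`). The intra-ensemble
#' covariance is estimated as the degrees-of-freedom-weighted pooled variance
#' \deqn{\Sigma_{pooled} = \sum_i (m_i - 1)\,\hat\Sigma_i / \sum_i (m_i - 1),}
#' with each stage-1 covariance rotated into the common stage-2 frame.
#'
#' Singleton ensembles (`m_i = 1`) contribute a mean structure only and are
#' flagged; a stage-1 failure (IWLS occasionally diverges at tiny `m_i`)
#' excludes that ensemble and is recorded in `$flags` rather than aborting,
#' unless every ensemble fails.
#'
#' @param set An [ensemble_set()] with at least 2 ensembles.
#' @param first_stage `"iwls"` (default) or `"ols"`.
#' @param tol,max_iter Passed to the stage fitters.
#' @param w_divisor Divisor for `W_hat`: `"ml"` (`nu`, default) or
#'   `"unbiased"` (`nu - 1`).
#' @param pool_weights Pooling weights for `Sigma_pooled`: `"df"`
#'   (`m_i - 1`, default) or `"size"` (`m_i`).
#' @return An object of class `ts_fit`: `M_hat`, `W_hat`, `Sigma_pooled`,
#'   `stage1` (per-ensemble `single_fit`s), `stage2` (the mean-structure
#'   fit), per-conformation `transforms` (stage-1 composed with stage-2),
#'   `ensemble_means` (aligned), and a `flags` tibble.
#' @seealso [rem_fit()], [spe_fit()]
#' @export
ts_fit <- function(set, first_stage = c("iwls", "ols"), tol = 1e-8,
                   max_iter = 200, w_divisor = c("ml", "unbiased"),
                   pool_weights = c("df", "size")) {
  first_stage <- match.arg(first_stage)
  w_divisor <- match.arg(w_divisor)
  pool_weights <- match.arg(pool_weights)
  if (set$n_ensembles < 2L)
    stopf("two-stage estimation needs at least 2 ensembles")
  nu <- set$n_ensembles
  eids <- names(set$ensembles)
  stage_fun <- if (first_stage == "iwls") iwls_superpose else ols_superpose

  stage1 <- vector("list", nu)
  means <- vector("list", nu)
  flags <- tibble::tibble(ensemble = eids, m = unname(set$sizes),
                          mean_only = FALSE, failed = FALSE, converged = NA)
  for (i in seq_len(nu)) {
    members <- set$ensembles[[i]]
    if (length(members) == 1L) {
      X <- members[[1L]]$coords
      means[[i]] <- sweep(X, 2L, colMeans(X))
      flags$mean_only[i] <- TRUE
      next
    }
    fit <- tryCatch(stage_fun(members, tol = tol, max_iter = max_iter),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      flags$failed[i] <- TRUE
      next
    }
    stage1[[i]] <- fit
    means[[i]] <- fit$M_hat
    flags$converged[i] <- fit$converged
  }
  ok <- !flags$failed
  if (!any(ok)) stopf("all stage-1 superpositions failed")
  keep <- which(ok)

  stage2 <- iwls_superpose(means[keep], tol = tol, max_iter = max_iter)
  aligned_means <- Map(apply_transform, means[keep], stage2$transforms)
  M_hat <- stage2$M_hat
  W_hat <- sample_covariance(aligned_means, M_hat, "ml")
  if (w_divisor == "unbiased" && length(keep) > 1L)
    W_hat <- W_hat * length(keep) / (length(keep) - 1L)

  # pooled intra-ensemble covariance in the common frame
  num <- 0; den <- 0
  for (k in seq_along(keep)) {
    i <- keep[k]
    if (is.null(stage1[[i]])) next  # singleton: mean only
    m <- set$sizes[i]
    R2 <- stage2$transforms[[k]]$R
    Sig_i <- rotate_cov3n(stage1[[i]]$Sigma_hat, R2)  # ML divisor (m)
    wgt <- if (pool_weights == "df") m - 1L else m
    num <- num + wgt * Sig_i * if (pool_weights == "df") m / (m - 1) else 1
    den <- den + wgt
  }
  if (den == 0) stopf("no ensemble with m_i >= 2: Sigma_pooled unavailable")
  Sigma_pooled <- symmetrize(num / den)

  # per-conformation transforms: stage 1 composed with the ensemble's
  # stage-2 transform ((t1 + R1 t2, R1 R2) in the translate-then-rotate
  # convention); failed ensembles get NULL entries
  mem <- set_members(set)
  transforms <- vector("list", length(mem$coords))
  for (k in seq_along(keep)) {
    i <- keep[k]
    t2 <- stage2$transforms[[k]]
    idx <- which(mem$ens_index == i)
    for (j in seq_along(idx)) {
      t1 <- if (is.null(stage1[[i]])) {
        X <- set$ensembles[[i]][[1L]]$coords
        rigid_transform(colMeans(X), diag(3))
      } else stage1[[i]]$transforms[[j]]
      transforms[[idx[j]]] <- rigid_transform(
        t1$t + as.numeric(t1$R %*% t2$t), t1$R %*% t2$R)
    }
  }

  Z_hat <- lapply(seq_along(keep), function(k) aligned_means[[k]] - M_hat)
  structure(list(
    M_hat = M_hat, W_hat = W_hat, Sigma_pooled = Sigma_pooled,
    Sigma_hat = Sigma_pooled,
    Z_hat = setNames(Z_hat, eids[keep]),
    stage1 = setNames(stage1, eids), stage2 = stage2,
    ensemble_means = setNames(aligned_means, eids[keep]),
    transforms = transforms, flags = flags,
    ens_ids = mem$ens_id, conf_ids = mem$conf_id,
    sizes = set$sizes,
    method = paste0("ts-", first_stage)
  ), class = "ts_fit")
}

#' @export
print.ts_fit <- function(x, ...) {
  cat(sprintf("Two-stage fit (%s): %d ensembles, %d atoms\n",
              x$method, nrow(x$flags), nrow(x$M_hat)))
  if (any(x$flags$failed))
    cat("  stage-1 failures:",
        paste(x$flags$ensemble[x$flags$failed], collapse = ", "), "\n")
  cat(sprintf("  tr(W_hat) = %.4g, tr(Sigma_pooled) = %.4g (Angstrom^2)\n",
              sum(diag(x$W_hat)), sum(diag(x$Sigma_pooled))))
  invisible(x)
}

#' Single pooled ensemble (SPE) estimation
#'
#' Ignores the ensemble grouping entirely: all conformations are merged into
#' one pool and superposed by IWLS under `Y_ij = M + E_ij`,
#' `vec(t(E_ij)) ~ N(0, Delta)`. The pooled covariance approximately equals
#' the sum of the inter- and intra-ensemble covariances,
#' `Delta ~ W + Sigma`.
#'
#' @param set An [ensemble_set()] (a single ensemble is allowed; the result
#'   then coincides with [iwls_superpose()] on that ensemble).
#' @param tol,max_iter Passed to [iwls_superpose()].
#' @return An object of class `spe_fit`: `M_hat`, `Delta_hat`, `transforms`,
#'   and the underlying `single_fit` as `$iwls`.
#' @export
spe_fit <- function(set, tol = 1e-8, max_iter = 200) {
  mem <- set_members(set)
  if (length(mem$coords) < 2L)
    stopf("at least 2 conformations are required")
  fit <- iwls_superpose(mem$coords, tol = tol, max_iter = max_iter)
  structure(list(
    M_hat = fit$M_hat, Delta_hat = fit$Sigma_hat, Sigma_hat = fit$Sigma_hat,
    transforms = fit$transforms, iwls = fit,
    ens_ids = mem$ens_id, conf_ids = mem$conf_id,
    converged = fit$converged, method = "spe"
  ), class = "spe_fit")
}

#' @export
print.spe_fit <- function(x, ...) {
  cat(sprintf("SPE fit: %d conformations, %d atoms\n",
              length(x$transforms), nrow(x$M_hat)))
  cat(sprintf("  tr(Delta_hat) = %.4g (Angstrom^2)\n", sum(diag(x$Delta_hat))))
  invisible(x)
}
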