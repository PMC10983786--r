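#' Principal component analysis of a 3n x 3n covariance matrix
#'
#' Eigen-decomposes an estimated covariance matrix (W, Sigma or Delta) into
#' its top-K conformational modes. Eigenvalues (Angstrom^2) are sorted
#' descending and clipped at zero when within numerical tolerance of zero;
#' eigenvector signs are fixed so that each column's largest-magnitude entry
#' is positive (ties broken at the lowest index), making the decomposition
#' deterministic.
#'
#' @param C Symmetric 3n x 3n covariance matrix.
#' @param K Number of components to keep (default all).
#' @param source Tag recording which matrix was decomposed
#'   (e.g. `"W"`, `"Sigma"`, `"Delta"`).
#' @return An object of class `covariance_pca`: `values` (length K),
#'   `vectors` (3n x K orthonormal), `n`, `K`, `source`, `trace`.
#' @export
covariance_pca <- function(C, K = NULL, source = "Sigma") {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stopf("covariance matrix must be symmetric")
  p <- nrow(C)
  if (is.null(K)) K <- p
  if (K > p) stopf("K must not exceed 3n = %d", p)
  e <- eigen(symmetrize(C), symmetric = TRUE)
  vals <- e$values
  tol <- 1e-8 * max(sum(diag(C)), .Machine$double.eps)
  vals[vals < 0 & vals > -tol] <- 0
  vals <- pmax(vals, 0)
  vecs <- e$vectors
  for (k in seq_len(K)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(values = vals[seq_len(K)],
                 vectors = vecs[, seq_len(K), drop = FALSE],
                 n = p / 3L, K = K, source = source, trace = sum(diag(C))),
            class = "covariance_pca")
}

#' @export
print.covariance_pca <- function(x, ...) {
  cat(sprintf("PCA of %s (%d atoms): top %d of %d modes\n",
              x$source, x$n, min(x$K, 8L), x$K))
  v <- x$values[seq_len(min(x$K, 8L))]
  cat("  eigenvalues (A^2):", paste(sprintf("%.4g", v), collapse = " "), "\n")
  cat(sprintf("  variance explained by shown modes: %.1f%%\n",
              100 * sum(v) / max(x$trace, .Machine$double.eps)))
  invisible(x)
}

# mean vector of a fit in the vec(t(M)) convention
fit_mu <- function(fit) vec3n(fit$M_hat)

#' Project conformations onto principal components
#'
#' Computes PC scores (Angstrom) of every conformation of a fitted dataset.
#' With `mode = "total"` the projected residual is `y_ij - mu` (appropriate
#' for Delta- and W-derived modes); with `mode = "within"` it is
#' `y_ij - mu - z_i`, the intra-ensemble residual (appropriate for
#' Sigma-derived modes, and the default for them when the fit provides
#' ensemble deviations). Coordinates come from the fit's stored transforms.
#'
#' @param set The [ensemble_set()] the fit was computed from.
#' @param fit A [rem_fit()], [ts_fit()] or [spe_fit()].
#' @param model A [covariance_pca()].
#' @param mode `"auto"`, `"total"` or `"within"`.
#' @return A tibble with columns `conformation`, `ensemble`, `PC1..PCK`.
#' @export
project_structures <- function(set, fit, model, mode = c("auto", "total", "within")) {
  mode <- match.arg(mode)
  if (3L * set$n_atoms != 3L * model$n || nrow(fit$M_hat) != model$n)
    stopf("fit, set and PCA model must share the same atom count")
  if (mode == "auto")
    mode <- if (identical(model$source, "Sigma") && !is.null(fit$Z_hat))
      "within" else "total"
  if (mode == "within" && is.null(fit$Z_hat))
    stopf("fit has no ensemble deviations: within-mode unavailable")
  mem <- set_members(set)
  mu <- fit_mu(fit)
  keep <- !vapply(fit$transforms, is.null, logical(1))
  scores <- matrix(NA_real_, length(mem$coords), model$K)
  for (k in which(keep)) {
    y <- vec3n(apply_transform(mem$coords[[k]], fit$transforms[[k]]))
    r <- y - mu
    if (mode == "within") {
      Z <- fit$Z_hat[[mem$ens_id[k]]]
      if (is.null(Z)) next
      r <- r - vec3n(Z)
    }
    scores[k, ] <- crossprod(model$vectors, r)
  }
  out <- tibble::tibble(conformation = mem$conf_id, ensemble = mem$ens_id)
  colnames(scores) <- paste0("PC", seq_len(model$K))
  cbind(out, tibble::as_tibble(scores))
}

#' Per-residue displacement profile of a principal component
#'
#' Converts a PC and the observed scores into the root-mean-square Cartesian
#' displacement it produces at each residue:
#' `d_a = sqrt(mean(s^2)) * ||u_a||`, where `u_a` is the atom's 3-subvector
#' of the eigenvector.
#'
#' @param model A [covariance_pca()].
#' @param pc Component index.
#' @param scores Numeric vector of per-structure scores on that component.
#' @return Length-n numeric vector, Angstrom.
#' @export
per_residue_displacement <- function(model, pc, scores) {
  if (pc > model$K) stopf("component %d not available (K = %d)", pc, model$K)
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stopf("no scores supplied")
  u <- matrix(model$vectors[, pc], ncol = 3L, byrow = TRUE)
  sqrt(mean(scores^2)) * sqrt(rowSums(u^2))
}

#' Reconstruct structures along a principal component
#'
#' `reconstruct_extreme()` displaces the mean structure along one mode:
#' `vec(t(S)) = vec(t(M)) + score * u_pc`. Used with the maximum/minimum
#' observed scores it yields the "open"/"closed" endpoint structures;
#' `reconstruct_path()` emits a linear interpolation series between two
#' scores (e.g. for animation).
#'
#' @param M_hat n x 3 mean structure.
#' @param model A [covariance_pca()].
#' @param pc Component index.
#' @param score Displacement along the component, Angstrom.
#' @return `reconstruct_extreme()`: an n x 3 matrix. `reconstruct_path()`:
#'   a list of n x 3 matrices.
#' @export
reconstruct_extreme <- function(M_hat, model, pc, score) {
  if (pc > model$K) stopf("component %d not available (K = %d)", pc, model$K)
  M_hat + score * unvec3n(model$vectors[, pc])
}

#' @rdname reconstruct_extreme
#' @param from,to Score endpoints of the interpolation.
#' @param n_frames Number of frames (endpoints included).
#' @export
reconstruct_path <- function(M_hat, model, pc, from, to, n_frames = 11L) {
  lapply(seq(from, to, length.out = n_frames),
         function(s) reconstruct_extreme(M_hat, model, pc, s))
}

#' Root mean squared inner product between two eigenvector sets
#'
#' \deqn{\mathrm{RMSIP} = \sqrt{\frac{1}{k}\sum_{i\le k}\sum_{j\le k}
#' (u_i^T v_j)^2} \in [0, 1],} the standard overlap measure between two
#' k-dimensional essential subspaces (1 = identical subspaces).
#'
#' @param U,V 3n x k matrices with orthonormal columns.
#' @return Scalar in `[0, 1]`.
#' @export
rmsip <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (!all(dim(U) == dim(V))) stopf("U and V must have matching dimensions")
  for (A in list(U, V))
    if (max(abs(crossprod(A) - diag(ncol(A)))) > 1e-6)
      stopf("columns must be orthonormal (tolerance 1e-6)")
  sqrt(sum(crossprod(U, V)^2) / ncol(U))
}

#' Mean absolute error of per-coordinate standard deviations
#'
#' Compares two covariance matrices through the mean over all 3n coordinates
#' of `|sqrt(C_hat_kk) - sqrt(C_true_kk)|` (Angstrom) — the accuracy measure
#' for recovered variances.
#'
#' @param C_hat,C_true Same-shape covariance matrices.
#' @return Scalar MAE, Angstrom.
#' @export
mae_sqrt_diag <- function(C_hat, C_true) {
  if (!all(dim(C_hat) == dim(C_true))) stopf("matrices must have equal shape")
  dh <- diag(as.matrix(C_hat)); dt <- diag(as.matrix(C_true))
  tol <- 1e-8 * max(sum(dh), sum(dt), .Machine$double.eps)
  if (any(dh < -tol) || any(dt < -tol))
    stopf("negative diagonal beyond tolerance")
  mean(abs(sqrt(pmax(dh, 0)) - sqrt(pmax(dt, 0))))
}

#' Pairwise distances between atom selections
#'
#' Computes, per conformation, the Euclidean distance between the centroids
#' of two atom selections (a single-atom selection is its own centroid), for
#' any number of named selection pairs — e.g. active-site cavity dimensions.
#' Distances are rigid-motion invariant, so no superposition is needed.
#'
#' @param set An [ensemble_set()].
#' @param pairs Named list; each element `list(a = <indices>, b = <indices>)`
#'   of 1-based atom (alignment column) indices.
#' @param summarize If `TRUE`, return per-ensemble averages instead of
#'   per-conformation values.
#' @return A tibble: `conformation`, `ensemble` and one column per pair
#'   (Angstrom), or the per-ensemble means when `summarize = TRUE`.
#' @export
pairwise_distance_metrics <- function(set, pairs, summarize = FALSE) {
  mem <- set_members(set)
  n <- set$n_atoms
  for (nm in names(pairs)) for (side in c("a", "b")) {
    idx <- pairs[[nm]][[side]]
    if (is.null(idx) || any(idx < 1L | idx > n))
      stopf("selection '%s$%s' does not resolve to atoms in 1..%d", nm, side, n)
  }
  vals <- vapply(names(pairs), function(nm) {
    a <- pairs[[nm]]$a; b <- pairs[[nm]]$b
    vapply(mem$coords, function(X) {
      ca <- colMeans(X[a, , drop = FALSE])
      cb <- colMeans(X[b, , drop = FALSE])
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
  }, numeric(length(mem$coords)))
  vals <- matrix(vals, nrow = length(mem$coords),
                 dimnames = list(NULL, names(pairs)))
  out <- cbind(tibble::tibble(conformation = mem$conf_id,
                              ensemble = mem$ens_id),
               tibble::as_tibble(vals))
  if (!summarize) return(tibble::as_tibble(out))
  ens <- unique(out$ensemble)
  agg <- lapply(ens, function(e) {
    sub <- out[out$ensemble == e, names(pairs), drop = FALSE]
    c(list(ensemble = e, n = sum(out$ensemble == e)), colMeans(sub))
  })
  tibble::as_tibble(do.call(rbind, lapply(agg, as.data.frame)))
}

#' Register a fit onto a reference frame
#'
#' Superposes the fitted mean structure onto a reference structure
#' (unweighted) and carries the whole fit along: covariance matrices are
#' conjugated by the gauge rotation and ensemble deviations and transforms
#' are rotated consistently. Needed before comparing covariance diagonals or
#' eigenvectors across fits (or against a simulation truth), since those are
#' not invariant under the arbitrary global rotation of the fitted frame.
#'
#' @param fit A [rem_fit()], [ts_fit()] or [spe_fit()].
#' @param M_ref n x 3 reference structure.
#' @return The fit, expressed in the reference frame.
#' @export
register_to_reference <- function(fit, M_ref) {
  g <- optimal_transform(fit$M_hat, sweep(M_ref, 2L, colMeans(M_ref)))
  R <- g$R
  K <- kronecker(diag(nrow(fit$M_hat)), t(R))
  fit$M_hat <- apply_transform(fit$M_hat, g)
  for (f in intersect(c("W_hat", "Sigma_hat", "Sigma_pooled", "Delta_hat"),
                      names(fit)))
    fit[[f]] <- rotate_cov3n(fit[[f]], R)
  if (!is.null(fit$Z_hat))
    fit$Z_hat <- lapply(fit$Z_hat, function(Z) Z %*% R)
  if (!is.null(fit$V))
    fit$V <- lapply(fit$V, function(v) symmetrize(K %*% v %*% t(K)))
  if (!is.null(fit$transforms))
    fit$transforms <- lapply(fit$transforms, function(tr) {
      if (is.null(tr)) return(NULL)
      rigid_transform(tr$t + as.numeric(tr$R %*% g$t), tr$R %*% R)
    })
  fit
}
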