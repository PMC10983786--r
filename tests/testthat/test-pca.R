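test_that("covariance_pca recovers simple spectra deterministically", {
  C <- diag(c(4, 1, rep(0, 10)))
  p <- covariance_pca(C, 3)
  expect_equal(p$values, c(4, 1, 0))
  expect_equal(abs(p$vectors[1, 1]), 1)
  expect_equal(abs(p$vectors[2, 2]), 1)

  v <- c(3, 0, 0, 4, rep(0, 8))
  p1 <- covariance_pca(tcrossprod(v), 1)
  expect_equal(p1$values[1], sum(v^2))
  expect_equal(p1$vectors[, 1], v / sqrt(sum(v^2)))  # sign rule: largest > 0

  # sign convention: flipping the input mode leaves the output fixed
  p2 <- covariance_pca(tcrossprod(-v), 1)
  expect_equal(p2$vectors, p1$vectors)

  expect_error(covariance_pca(matrix(rnorm(16), 4)), "symmetric")
})

test_that("full-rank spectral reconstruction is exact", {
  set.seed(40)
  A <- matrix(rnorm(144), 12)
  C <- crossprod(A) / 12
  p <- covariance_pca(C, 12)
  rec <- p$vectors %*% (p$values * t(p$vectors))
  expect_lt(max(abs(rec - C)), 1e-8)
  expect_lt(max(abs(crossprod(p$vectors) - diag(12))), 1e-8)
  expect_true(all(diff(p$values) <= 1e-12))
})

test_that("projections vanish at the mean and read off injected modes", {
  set.seed(41)
  truth <- make_truth(8, scale = 0.4, seed = 41)
  sim <- simulate_ensembles(truth, nu = 3, m = 4, seed = 410)
  fit <- ts_fit(sim$set)
  model <- covariance_pca(fit$Sigma_pooled, 3, source = "Sigma")

  # a structure equal to the fitted mean scores 0 on every component
  mu_set <- ensemble_set(list(e0 = list(conformation("mu", fit$M_hat))))
  mu_fit <- list(M_hat = fit$M_hat, transforms = list(rigid_transform()),
                 Z_hat = NULL)
  sc0 <- project_structures(mu_set, mu_fit, model, mode = "total")
  expect_lt(max(abs(as.matrix(sc0[, 3:5]))), 1e-10)

  # injecting c * u1 on top of the mean returns score c on PC1 only
  cc <- 2.5
  y <- fit$M_hat + cc * matrix(model$vectors[, 1], ncol = 3, byrow = TRUE)
  inj_set <- ensemble_set(list(e0 = list(conformation("inj", y))))
  sc1 <- project_structures(inj_set, mu_fit, model, mode = "total")
  expect_equal(sc1$PC1, cc, tolerance = 1e-10)
  expect_lt(max(abs(c(sc1$PC2, sc1$PC3))), 1e-10)
})

test_that("within-mode scores of a fixed-effects fit sum to zero per
           ensemble", {
  set.seed(42)
  truth <- make_truth(10, scale = 0.5, seed = 42)
  sim <- simulate_ensembles(truth, nu = 4, m = 5, seed = 420)
  fit <- ts_fit(sim$set)
  model <- covariance_pca(fit$Sigma_pooled, 4, source = "Sigma")
  sc <- project_structures(sim$set, fit, model, mode = "within")
  for (e in unique(sc$ensemble)) {
    sums <- colSums(as.matrix(sc[sc$ensemble == e, -(1:2)]))
    expect_lt(max(abs(sums)), 1e-6)
  }
})

test_that("per-residue displacement localizes concentrated and uniform
           modes", {
  p <- 30  # 10 atoms
  u <- rep(0, p); u[13:15] <- c(0.6, 0.8, 0)  # atom 5 only
  model <- structure(list(values = 1, vectors = cbind(u), n = 10, K = 1,
                          source = "Sigma", trace = 1),
                     class = "covariance_pca")
  d <- per_residue_displacement(model, 1, scores = c(1, 1, 1))
  expect_equal(which(d > 0), 5)
  expect_equal(d[5], 1)

  uu <- rep(1 / sqrt(p), p)
  model$vectors <- cbind(uu)
  d2 <- per_residue_displacement(model, 1, scores = c(-1, 1))
  expect_equal(d2, rep(sqrt(3 / p), 10), tolerance = 1e-12)

  # a hinge-style truth concentrates PC1 displacement away from the pivot
  truth <- make_truth(30, style = "hinge", scale = 0.5, seed = 43)
  hp <- covariance_pca(truth$W_true, 1, source = "W")
  prof <- per_residue_displacement(hp, 1, scores = 1)
  mid <- mean(prof[14:17])
  expect_gt(mean(prof[c(1:4, 27:30)]), 2 * mid)
})

test_that("extreme-structure reconstruction is linear and round-trips", {
  set.seed(44)
  A <- matrix(rnorm(15 * 15), 15)
  model <- covariance_pca(crossprod(A) / 15, 5)
  M <- matrix(rnorm(15), 5)
  expect_equal(reconstruct_extreme(M, model, 1, 0), M)
  up <- reconstruct_extreme(M, model, 2, 1.7)
  dn <- reconstruct_extreme(M, model, 2, -1.7)
  expect_equal((up + dn) / 2, M, tolerance = 1e-12)

  # projecting the reconstruction returns the score exactly
  dvec <- remsuper:::vec3n(up) - remsuper:::vec3n(M)
  expect_equal(as.numeric(crossprod(model$vectors, dvec)),
               c(0, 1.7, 0, 0, 0), tolerance = 1e-10)

  path <- reconstruct_path(M, model, 1, -1, 1, n_frames = 5)
  expect_length(path, 5)
  expect_equal(path[[3]], M, tolerance = 1e-12)
})

test_that("rmsip matches its closed-form cases and is symmetric", {
  set.seed(45)
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  U <- Q[, 1:3]
  expect_equal(rmsip(U, U), 1)
  expect_equal(rmsip(U, Q[, 4:6]), 0)

  # k = 1 at 60 degrees: RMSIP equals cos(60) = 0.5
  a <- Q[, 1]
  b <- cos(pi / 3) * Q[, 1] + sin(pi / 3) * Q[, 2]
  expect_equal(rmsip(cbind(a), cbind(b)), 0.5, tolerance = 1e-12)

  V <- Q[, c(2, 5, 7)]
  expect_equal(rmsip(U, V), rmsip(V, U))
  # invariant under rotations within each subspace
  G <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(rmsip(U %*% G, V), rmsip(U, V), tolerance = 1e-10)
  expect_error(rmsip(U, 2 * V), "orthonormal")
})

test_that("mae_sqrt_diag matches direct computation and rejects bad input", {
  C <- diag(4, 6)
  expect_equal(mae_sqrt_diag(C, C), 0)
  expect_equal(mae_sqrt_diag(diag(4, 6), diag(1, 6)), 1)

  set.seed(46)
  A <- matrix(rnorm(36), 6); B <- matrix(rnorm(36), 6)
  C1 <- crossprod(A); C2 <- crossprod(B)
  expect_equal(mae_sqrt_diag(C1, C2),
               mean(abs(sqrt(diag(C1)) - sqrt(diag(C2)))))
  bad <- C1; bad[1, 1] <- -1
  expect_error(mae_sqrt_diag(bad, C2), "negative diagonal")
})

test_that("pairwise distances follow geometry and rigid invariance", {
  X <- rbind(c(0, 0, 0), c(3, 4, 0), c(2, 0, 0), c(1, 4, 0))
  set <- set_from_matrices(list(list(X)))
  d <- pairwise_distance_metrics(set, list(d1 = list(a = 1, b = 2)))
  expect_equal(d$d1, 5)

  # centroid of atoms {1,3} = (1,0,0) to atom 4 at (1,4,0): distance 4
  d2 <- pairwise_distance_metrics(set, list(dc = list(a = c(1, 3), b = 4)))
  expect_equal(d2$dc, 4)

  R <- remsuper:::random_rotation()
  Xr <- X %*% t(R) + matrix(c(5, -2, 9), 4, 3, byrow = TRUE)
  setr <- set_from_matrices(list(list(Xr)))
  dr <- pairwise_distance_metrics(setr, list(d1 = list(a = 1, b = 2),
                                             dc = list(a = c(1, 3), b = 4)))
  expect_equal(c(dr$d1, dr$dc), c(5, 4), tolerance = 1e-9)

  expect_error(pairwise_distance_metrics(set, list(x = list(a = 1, b = 9))),
               "resolve")

  # per-ensemble averages
  set2 <- set_from_matrices(list(list(X, X), list(X + 1)))
  avg <- pairwise_distance_metrics(set2, list(d1 = list(a = 1, b = 2)),
                                   summarize = TRUE)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$d1, c(5, 5), tolerance = 1e-9)
  expect_equal(avg$n, c(2L, 1L))
})
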