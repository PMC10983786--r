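test_that("rem_loglik reproduces the single-observation closed form", {
  n <- 6
  M <- matrix(rnorm(3 * n), n)
  set <- set_from_matrices(list(list(M)))
  ll <- rem_loglik(set, M, W = matrix(0, 3 * n, 3 * n), Sigma = diag(3 * n),
                   transforms = list(rigid_transform()))
  expect_equal(ll, -(3 * n / 2) * log(2 * pi), tolerance = 1e-12)
})

test_that("rem_loglik equals the dense multivariate normal oracle", {
  set.seed(20)
  n <- 4; p <- 3 * n
  for (rep in 1:3) {
    A <- matrix(rnorm(p * p), p); W <- crossprod(A) / p + diag(0.5, p)
    B <- matrix(rnorm(p * p), p); Sigma <- crossprod(B) / p + diag(0.5, p)
    M <- matrix(rnorm(p), n)
    groups <- lapply(1:2, function(i) lapply(1:3, function(j) matrix(rnorm(p, sd = 2), n)))
    set <- set_from_matrices(groups)
    transforms <- replicate(6, rigid_transform(), simplify = FALSE)
    ll <- rem_loglik(set, M, W, Sigma, transforms)
    ll_dense <- dense_rem_loglik(groups, M, W, Sigma)
    expect_equal(ll, ll_dense, tolerance = 1e-8)
  }
})

test_that("E-step and M-step match the hand-coded Laird-Ware oracle", {
  set.seed(21)
  n <- 4; p <- 3 * n
  A <- matrix(rnorm(p * p), p); W <- crossprod(A) / p + diag(0.4, p)
  B <- matrix(rnorm(p * p), p); Sigma <- crossprod(B) / p + diag(0.4, p)
  groups <- lapply(1:3, function(i)
    lapply(seq_len(i + 1), function(j) matrix(rnorm(p, sd = 2), n)))
  mu <- rnorm(p)
  sizes <- vapply(groups, length, integer(1))
  Y <- do.call(cbind, lapply(unlist(groups, recursive = FALSE),
                             function(Yij) as.vector(t(Yij))))
  ens <- rep(seq_along(sizes), sizes)

  E <- remsuper:::rem_e_step(Y, mu, W, Sigma, ens, sizes, ridge = 0)
  Mstep <- remsuper:::rem_m_step(Y, ens, sizes, E)
  oracle <- laird_ware_onepass(groups, mu, W, Sigma)

  for (i in seq_along(sizes)) {
    expect_equal(E$V[[i]], oracle$V[[i]], tolerance = 1e-8)
    expect_equal(E$B[, i], oracle$b[[i]], tolerance = 1e-8)
  }
  expect_equal(Mstep$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(Mstep$W, oracle$W, tolerance = 1e-8)
  expect_equal(Mstep$Sigma, oracle$Sigma, tolerance = 1e-8)

  # conservation: weighted posterior residuals sum to zero after the M-step
  resid_sum <- rowSums(Y - Mstep$mu - E$B[, ens, drop = FALSE])
  expect_lt(max(abs(resid_sum)), 1e-8)
})

test_that("identifiability preconditions are enforced", {
  M <- matrix(rnorm(12), 4)
  one_ens <- set_from_matrices(list(list(M, M + 1)))
  expect_error(rem_fit(one_ens), "at least 2 ensembles")
  singletons <- set_from_matrices(list(list(M), list(M + 1)))
  expect_error(rem_fit(singletons), "confounded")
})

test_that("data generated with W = 0 yields a near-zero inter-ensemble
           covariance", {
  set.seed(22)
  truth <- make_truth(20, style = "low_rank_plus_diag", scale = 0.5, seed = 22)
  truth$W_true <- matrix(0, 60, 60)
  sim <- simulate_ensembles(truth, nu = 20, m = 10, seed = 220)
  fit <- rem_fit(sim$set, rem_config(tol = 1e-6, max_iter = 150))
  expect_lt(sum(diag(fit$W_hat)) / sum(diag(fit$Sigma_hat)), 0.15)
})

test_that("the EM log-likelihood trace is non-decreasing and the fit frame
           invariant", {
  set.seed(23)
  truth <- make_truth(12, style = "low_rank_plus_diag", scale = 0.5, seed = 23)
  sim <- simulate_ensembles(truth, nu = 8, m = 5, seed = 230)
  fit <- rem_fit(sim$set, rem_config(tol = 1e-8, max_iter = 200))
  expect_true(is_nondecreasing(fit$loglik_trace, slack = 1e-6))
  expect_gt(fit$n_iter, 10)

  # scramble every input by a fresh rigid motion: eigenvalues must not move
  scrambled <- lapply(sim$set$ensembles, function(e) lapply(e, function(cf) {
    R <- remsuper:::random_rotation()
    conformation(cf$id, cf$coords %*% t(R) +
                   matrix(rnorm(3, sd = 20), nrow(cf$coords), 3, byrow = TRUE))
  }))
  fit2 <- rem_fit(ensemble_set(scrambled), rem_config(tol = 1e-8, max_iter = 200))
  for (f in c("W_hat", "Sigma_hat")) {
    e1 <- eigen(fit[[f]], symmetric = TRUE, only.values = TRUE)$values
    e2 <- eigen(fit2[[f]], symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(e1 - e2)) / max(e1), 1e-5)
  }
})

test_that("posterior ensemble deviations shrink toward the population mean", {
  set.seed(24)
  truth <- make_truth(10, style = "low_rank_plus_diag", scale = 0.5, seed = 24)
  sim <- simulate_ensembles(truth, nu = 9, m = c(1, rep(5, 8)), seed = 240)
  fit <- rem_fit(sim$set, rem_config(tol = 1e-7, max_iter = 150))
  means <- posterior_ensemble_means(fit)
  expect_length(means, 9)

  # the singleton ensemble's posterior mean lies strictly between the
  # population mean and its lone aligned observation
  mem <- remsuper:::set_members(sim$set)
  k <- which(mem$ens_index == 1)[1]
  y1 <- apply_transform(mem$coords[[k]], fit$transforms[[k]])
  raw_dev <- sqrt(sum((y1 - fit$M_hat)^2))
  shrunk_dev <- sqrt(sum(fit$Z_hat[[1]]^2))
  expect_gt(shrunk_dev, 0)
  expect_lt(shrunk_dev, raw_dev)

  # W = 0 prior forces all deviations to (numerically) vanish
  p <- 30
  E0 <- remsuper:::rem_e_step(
    vapply(seq_along(mem$coords), function(k)
      remsuper:::vec3n(apply_transform(mem$coords[[k]], fit$transforms[[k]])),
      numeric(p)),
    remsuper:::vec3n(fit$M_hat), matrix(0, p, p), diag(p),
    mem$ens_index, sim$set$sizes, ridge = 0)
  expect_lt(max(abs(E0$B)), 1e-6)
})

test_that("a huge prior variance leaves deviations at the raw ensemble
           means", {
  set.seed(25)
  n <- 5; p <- 15
  groups <- lapply(1:3, function(i) lapply(1:4, function(j)
    matrix(rnorm(p), n)))
  Y <- do.call(cbind, lapply(unlist(groups, recursive = FALSE),
                             function(Yij) as.vector(t(Yij))))
  sizes <- c(4L, 4L, 4L); ens <- rep(1:3, each = 4)
  mu <- rowMeans(Y)
  Sigma <- diag(0.5, p)
  E <- remsuper:::rem_e_step(Y, mu, W = diag(1e8, p), Sigma, ens, sizes,
                             ridge = 0)
  for (i in 1:3) {
    raw <- rowMeans(Y[, ens == i, drop = FALSE]) - mu
    expect_equal(E$B[, i], raw, tolerance = 1e-5)
  }
})

test_that("atom_block covariance structure still recovers full matrices", {
  set.seed(26)
  truth <- make_truth(10, style = "low_rank_plus_diag", scale = 0.5, seed = 26)
  sim <- simulate_ensembles(truth, nu = 10, m = 6, seed = 260)
  fit <- rem_fit(sim$set, rem_config(tol = 1e-6, max_iter = 80,
                                     covariance_structure = "atom_block"))
  expect_true(is_nondecreasing(fit$loglik_trace, slack = 1e-6))
  # returned matrices are full (off-block entries generally nonzero)
  off <- fit$Sigma_hat
  for (a in 1:10) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    off[idx, idx] <- 0
  }
  expect_gt(max(abs(off)), 0)
})
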