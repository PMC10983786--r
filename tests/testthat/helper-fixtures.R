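# Fixture builders and independent oracles used across the suite.

# --- tiny PDB fixtures ------------------------------------------------------

pdb_atom_line <- function(serial, resno, x, y, z, alt = " ", chain = "A",
                          occ = 1.00, elety = " CA ", resid = "ALA") {
  sprintf("ATOM  %5d %s%s%s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          serial, elety, alt, resid, chain, resno, x, y, z, occ)
}

# write a one-chain C-alpha-only PDB; coords is an n x 3 matrix
write_toy_pdb <- function(path, coords, chain = "A", resno = seq_len(nrow(coords))) {
  lines <- vapply(seq_len(nrow(coords)), function(i)
    pdb_atom_line(i, resno[i], coords[i, 1], coords[i, 2], coords[i, 3],
                  chain = chain), character(1))
  writeLines(c(lines, "END"), path)
  path
}

# --- small random ensembles -------------------------------------------------

# quick multivariate normal draw: chol factor of C applied to iid normals
rmvn3n <- function(C) {
  L <- chol(C + diag(1e-12 * max(diag(C), 1), nrow(C)))
  matrix(as.numeric(crossprod(L, rnorm(nrow(C)))), ncol = 3, byrow = TRUE)
}

# build an ensemble_set directly from lists of coordinate matrices
set_from_matrices <- function(groups) {
  ens <- lapply(seq_along(groups), function(i)
    lapply(seq_along(groups[[i]]), function(j)
      conformation(sprintf("g%d_%d", i, j), groups[[i]][[j]])))
  names(ens) <- sprintf("g%d", seq_along(groups))
  ensemble_set(ens)
}

# --- independent oracles ----------------------------------------------------

# dense-covariance Gaussian log-likelihood: builds the full 3nm-dimensional
# covariance I_m (x) Sigma + J_m (x) W per ensemble and evaluates the joint
# normal density directly (no Woodbury-style reduction)
dense_rem_loglik <- function(Ylist_by_ens, M, W, Sigma) {
  mu <- as.vector(t(M))
  ll <- 0
  for (Ys in Ylist_by_ens) {
    m <- length(Ys)
    p <- length(mu)
    y <- unlist(lapply(Ys, function(Y) as.vector(t(Y))))
    big_mu <- rep(mu, m)
    C <- kronecker(diag(m), Sigma) + kronecker(matrix(1, m, m), W)
    R <- chol(C)
    d <- y - big_mu
    q <- sum(backsolve(R, d, transpose = TRUE)^2)
    ll <- ll - 0.5 * (m * p * log(2 * pi) + 2 * sum(log(diag(R))) + q)
  }
  ll
}

# hand-coded single-pass Laird-Ware EM step with explicit loops and solve()
laird_ware_onepass <- function(Ylist_by_ens, mu, W, Sigma) {
  p <- length(mu)
  Winv <- solve(W)
  Sinv <- solve(Sigma)
  nu <- length(Ylist_by_ens)
  V <- list(); b <- list()
  for (i in seq_len(nu)) {
    m <- length(Ylist_by_ens[[i]])
    V[[i]] <- solve(Winv + m * Sinv)
    s <- rep(0, p)
    for (Y in Ylist_by_ens[[i]]) s <- s + (as.vector(t(Y)) - mu)
    b[[i]] <- as.numeric(V[[i]] %*% Sinv %*% s)
  }
  N <- sum(vapply(Ylist_by_ens, length, integer(1)))
  mu_new <- rep(0, p)
  for (i in seq_len(nu)) for (Y in Ylist_by_ens[[i]])
    mu_new <- mu_new + (as.vector(t(Y)) - b[[i]])
  mu_new <- mu_new / N
  W_new <- matrix(0, p, p)
  for (i in seq_len(nu)) W_new <- W_new + tcrossprod(b[[i]]) + V[[i]]
  W_new <- W_new / nu
  S_new <- matrix(0, p, p)
  for (i in seq_len(nu)) for (Y in Ylist_by_ens[[i]]) {
    r <- as.vector(t(Y)) - mu_new - b[[i]]
    S_new <- S_new + tcrossprod(r) + V[[i]]
  }
  S_new <- S_new / N
  list(mu = mu_new, W = W_new, Sigma = S_new, b = b, V = V)
}

# axis-angle numerical oracle for the weighted rigid superposition: coarse
# grid over rotation space refined by Nelder-Mead; translation solved
# analytically at each rotation
rotation_from_axis_angle <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

procrustes_objective <- function(R, X, M, w) {
  sw <- sum(w)
  xbar <- colSums(X * w) / sw
  mbar <- colSums(M * w) / sw
  t_vec <- xbar - as.numeric(R %*% mbar)
  Y <- sweep(X, 2, t_vec) %*% R
  sum(w * rowSums((Y - M)^2))
}

procrustes_grid_oracle <- function(X, M, w) {
  f <- function(v) procrustes_objective(rotation_from_axis_angle(v), X, M, w)
  # Fibonacci-sphere axes x angle grid, then local refinement
  i <- seq_len(80)
  phi <- pi * (3 - sqrt(5)) * i
  zc <- 1 - 2 * (i - 0.5) / 80
  rc <- sqrt(pmax(0, 1 - zc^2))
  axes <- cbind(rc * cos(phi), rc * sin(phi), zc)
  angles <- seq(0.1, pi, length.out = 18)
  best <- c(0, 0, 0); best_val <- f(best)
  for (a in seq_len(nrow(axes))) for (th in angles) {
    v <- axes[a, ] * th
    val <- f(v)
    if (val < best_val) { best <- v; best_val <- val }
  }
  opt <- optim(best, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# fraction-free helper: check a numeric vector is non-increasing within slack
is_nonincreasing <- function(x, slack = 0) all(diff(x) <= slack)
is_nondecreasing <- function(x, slack = 0) all(diff(x) >= -slack)
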