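# Independent reference solvers and fixtures used across tests.
#
# The reference solver below minimizes the same penalized likelihood
# with a completely different method: quasi-Newton (L-BFGS-B) with
# finite-difference gradients on a smoothed |x| ~ sqrt(x^2 + eps)
# surrogate of the L1 terms, an explicit eigenvalue barrier instead of
# Cholesky rejection, and an explicit-inverse likelihood evaluation.
# It shares no code path with the package's proximal-gradient fit.

# penalized objective evaluated from first principles (explicit inverse
# and determinant), smoothed L1; Lambda packed as its upper triangle
oracle_pack <- function(Lambda, Theta) {
  c(Lambda[upper.tri(Lambda, diag = TRUE)], as.vector(Theta))
}

oracle_unpack <- function(par, p, q) {
  L <- matrix(0, p, p)
  L[upper.tri(L, diag = TRUE)] <- par[seq_len(p * (p + 1) / 2)]
  L <- L + t(L) - diag(diag(L))
  Theta <- matrix(par[-seq_len(p * (p + 1) / 2)], q, p)
  list(Lambda = L, Theta = Theta)
}

oracle_objective <- function(par, pdim, qdim, suff, lam_net,
                             lam_perturb, smooth_eps = 1e-10,
                             theta_zero = FALSE) {
  if (theta_zero) par <- c(par, rep(0, qdim * pdim))
  pk <- oracle_unpack(par, pdim, qdim)
  L <- pk$Lambda; Th <- pk$Theta
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) return(1e8 * (1 + abs(min(ev))))
  Li <- solve(L)
  nll <- 0.5 * sum(diag(L %*% suff$Syy)) + sum(Th * suff$Sxy) +
    0.5 * sum(diag(Th %*% Li %*% t(Th) %*% suff$Sxx)) -
    0.5 * sum(log(ev)) + 0.5 * pdim * log(2 * pi)
  off <- L; diag(off) <- 0
  nll + lam_net * (sum(sqrt(off^2 + smooth_eps)) - pdim * sqrt(smooth_eps)) +
    lam_perturb * sum(sqrt(Th^2 + smooth_eps))
}

# reference solution by quasi-Newton on the smoothed objective,
# restarted from the identity model
oracle_solve <- function(suff, lam_net, lam_perturb,
                         theta_zero = FALSE, smooth_eps = 1e-10,
                         maxit = 5000) {
  p <- nrow(suff$Syy); q <- nrow(suff$Sxx)
  init <- if (theta_zero) oracle_pack(diag(p), matrix(0, q, p))[
    seq_len(p * (p + 1) / 2)] else oracle_pack(diag(p), matrix(0, q, p))
  res <- stats::optim(init, oracle_objective, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14,
                                     ndeps = rep(1e-6, length(init))),
                      pdim = p, qdim = q, suff = suff,
                      lam_net = lam_net, lam_perturb = lam_perturb,
                      smooth_eps = smooth_eps, theta_zero = theta_zero)
  par <- res$par
  if (theta_zero) par <- c(par, rep(0, q * p))
  pk <- oracle_unpack(par, p, q)
  # true (unsmoothed) objective at the reference solution
  off <- pk$Lambda; diag(off) <- 0
  ev <- eigen(pk$Lambda, symmetric = TRUE, only.values = TRUE)$values
  Li <- solve(pk$Lambda)
  nll <- 0.5 * sum(diag(pk$Lambda %*% suff$Syy)) +
    sum(pk$Theta * suff$Sxy) +
    0.5 * sum(diag(pk$Theta %*% Li %*% t(pk$Theta) %*% suff$Sxx)) -
    0.5 * sum(log(ev)) + 0.5 * p * log(2 * pi)
  list(Lambda = pk$Lambda, Theta = pk$Theta,
       objective = nll + lam_net * sum(abs(off)) +
         lam_perturb * sum(abs(pk$Theta)),
       convergence = res$convergence)
}

# dense-grid quadrature of the unnormalized conditional density for
# p <= 3; integrates exp(-y'Ly/2 - x'Th y) on a cube
quadrature_log_partition <- function(Lambda, Theta, x, half_width = 12,
                                     n_grid = 241) {
  p <- nrow(Lambda)
  mu <- -solve(Lambda, as.vector(t(Theta) %*% x))  # mode of the density
  gs <- lapply(seq_len(p), function(j)
    seq(mu[j] - half_width, mu[j] + half_width, length.out = n_grid))
  h <- vapply(gs, function(g) g[2] - g[1], numeric(1))
  pts <- as.matrix(expand.grid(gs))
  expo <- -0.5 * rowSums((pts %*% Lambda) * pts) -
    as.vector(pts %*% (t(Theta) %*% x))
  m <- max(expo)
  log(sum(exp(expo - m))) + m + sum(log(h))
}

# random small PD instance builders
random_pd_matrix <- function(p, jitter = 0.5) {
  A <- matrix(stats::rnorm(p * p), p, p)
  S <- crossprod(A) / p
  S + jitter * diag(p)
}

random_model <- function(p, q, sparsity = 0.5) {
  Lambda <- random_pd_matrix(p)
  Theta <- matrix(stats::rnorm(q * p) *
                    (stats::runif(q * p) < sparsity), q, p)
  scggm_model(Lambda, Theta)
}

random_stats <- function(n, p, q) {
  X <- matrix(stats::rnorm(n * q), n, q)
  Y <- matrix(stats::rnorm(n * p), n, p)
  sufficient_stats(scale(X), scale(Y, scale = FALSE))
}
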