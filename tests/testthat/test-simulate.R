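test_that("module networks are jittered graph Laplacians", {
  # closed form for a forced single edge: connect 2 genes in 1 module
  # with p_within = 1
  L <- sim_module_network(2, n_modules = 1, p_within = 1,
                          weight_range = c(0.4, 0.8),
                          diag_jitter = 0.1, seed = 3)
  w <- -L[1, 2]
  expect_gt(w, 0.4); expect_lt(w, 0.8)
  expect_equal(L, matrix(c(w + 0.1, -w, -w, w + 0.1), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sort(eigen(L)$values), c(0.1, 2 * w + 0.1))

  # no edges: pure jitter diagonal
  L0 <- sim_module_network(6, 2, p_within = 0, p_between = 0,
                           diag_jitter = 0.1, seed = 4)
  expect_equal(L0, 0.1 * diag(6), ignore_attr = TRUE)

  # Laplacian row-sum identity and positive definiteness
  for (seed in 1:5) {
    L <- sim_module_network(30, 3, seed = seed)
    expect_equal(as.vector(L %*% rep(1, 30)), rep(0.1, 30),
                 tolerance = 1e-12)
    expect_silent(chol(L))
    expect_length(attr(L, "modules"), 30)
  }
  expect_error(sim_module_network(10, 2, p_within = 1.2), "probabilities")
})

test_that("scale-free networks have heavy-tailed decreasing degrees", {
  for (seed in 1:10) {
    L <- sim_scalefree_network(200, degree_exponent = 2.5, seed = seed)
    expect_silent(chol(L))
    expect_lt(max(abs(L - t(L))), 1e-12)
    deg <- attr(L, "degrees")
    # heavy tail: spans at least a decade across seeds of this size
    expect_gte(max(deg), 10 * max(1, min(deg[deg > 0])))
    # cumulative distribution decreasing in degree
    xs <- sort(unique(deg[deg > 0]))
    frac <- vapply(xs, function(v) mean(deg >= v), numeric(1))
    expect_true(all(diff(frac) < 0))
  }
  # Laplacian row sums equal the jitter
  L <- sim_scalefree_network(50, seed = 2)
  expect_equal(as.vector(L %*% rep(1, 50)), rep(0.1, 50),
               tolerance = 1e-12)
})

test_that("perturbation patterns respect their sparsity designs", {
  modules <- rep(1:3, each = 10)
  # zero probability: zero matrix
  Th0 <- sim_direct_perturbations(30, 40, perturb_prob = 0,
                                  modules = modules, seed = 1)
  expect_true(all(Th0 == 0))

  # per-module single gene: at most 3 nonzero columns
  Th <- sim_direct_perturbations(30, 40, "per_module_single_gene",
                                 perturb_prob = 0.2, modules = modules,
                                 seed = 7)
  expect_lte(sum(colSums(abs(Th)) > 0), 3L)
  # the targeted column of each module lies inside it
  nz_cols <- which(colSums(abs(Th)) > 0)
  expect_equal(length(unique(modules[nz_cols])), length(nz_cols))
  # effect sizes in range, mixed random signs over a larger draw
  vals <- Th[Th != 0]
  expect_true(all(abs(vals) >= 0.6 & abs(vals) <= 1.0))

  # uniform design: binomial count bound (4 SD)
  ThU <- sim_direct_perturbations(500, 1000, "uniform",
                                  perturb_prob = 0.01, seed = 11)
  nz <- sum(ThU != 0)
  expn <- 1000 * 500 * 0.01
  sd4 <- 4 * sqrt(expn * 0.99)
  expect_gt(nz, expn - sd4); expect_lt(nz, expn + sd4)

  # hub_extra adds eQTLs for high-degree genes
  degrees <- c(rep(25, 2), rep(1, 8))
  ThH <- sim_direct_perturbations(10, 20, "hub_extra",
                                  perturb_prob = 0, degrees = degrees,
                                  seed = 13)
  expect_true(all(colSums(ThH != 0)[1:2] >= 1))
  expect_true(all(ThH[, 3:10] == 0))

  expect_error(sim_direct_perturbations(10, 5, "per_module_single_gene"),
               "module")
})

test_that("genotype simulator produces valid LD-structured allele counts", {
  X <- sim_genotypes(2000, 30, seed = 17)
  expect_true(all(X %in% c(0, 1, 2)))
  expect_false(any(apply(X, 2, function(v) length(unique(v)) == 1)))

  # no LD: adjacent columns nearly uncorrelated
  X0 <- sim_genotypes(2000, 20, ld_decay = 0, seed = 19)
  r0 <- vapply(1:19, function(j) stats::cor(X0[, j], X0[, j + 1]),
               numeric(1))
  expect_lt(max(abs(r0)), 0.1)

  # strong LD: adjacent columns clearly correlated
  X9 <- sim_genotypes(2000, 20, ld_decay = 0.9, seed = 19)
  r9 <- vapply(1:19, function(j) stats::cor(X9[, j], X9[, j + 1]),
               numeric(1))
  expect_gt(mean(r9), 0.5)

  # allele frequency control
  Xf <- sim_genotypes(2000, 10, maf_lo = 0.5, maf_hi = 0.5, seed = 23)
  expect_lt(abs(mean(Xf) / 2 - 0.5), 0.03)

  expect_error(sim_genotypes(10, 5, maf_lo = 0), "maf")
  expect_error(sim_genotypes(10, 5, ld_decay = 1), "ld_decay")
})

test_that("expression sampling follows the conditional Gaussian model", {
  # identity model: empirical covariance near identity
  truth <- scggm_truth(diag(6), matrix(0, 4, 6))
  X <- standardize_genotypes(sim_genotypes(5000, 4, seed = 29))
  Y <- sim_expressions(truth, X, seed = 31)
  S <- crossprod(Y) / nrow(Y)
  expect_lt(max(abs(S - diag(6))), 0.1)

  # determinism: same seed, same bits
  Y2 <- sim_expressions(truth, X, seed = 31)
  expect_identical(Y, Y2)

  # residual precision approximates the true Lambda
  L <- sim_module_network(10, 2, p_within = 0.5, seed = 37)
  Th <- sim_direct_perturbations(10, 4, "uniform", perturb_prob = 0.2,
                                 seed = 41)
  tr2 <- scggm_truth(L, Th)
  Y3 <- sim_expressions(tr2, X, seed = 43)
  R <- Y3 - X %*% tr2$B
  Prec <- solve(crossprod(R) / nrow(R))
  expect_lt(norm(Prec - L, "F") / norm(L, "F"), 0.15)
})

test_that("ground truth objects are internally consistent", {
  L <- sim_module_network(8, 2, seed = 47)
  Th <- sim_direct_perturbations(8, 5, "uniform", perturb_prob = 0.2,
                                 seed = 53)
  tr <- scggm_truth(L, Th)
  expect_lt(max(abs(tr$B %*% tr$Lambda + tr$Theta)), 1e-10)
})

test_that("regression design has module-shared eQTL support", {
  L <- sim_module_network(12, 2, p_within = 0.4, seed = 59)
  X <- standardize_genotypes(sim_genotypes(5000, 8, seed = 61))
  reg <- sim_regression_design(L, q = 8, eqtl_prob = 0.3, X = X,
                               seed = 67)
  modules <- attr(L, "modules")
  Bstar <- reg$truth$B
  # support shared within each module
  for (m in unique(modules)) {
    genes <- which(modules == m)
    supp <- Bstar[, genes] != 0
    if (length(genes) > 1)
      expect_true(all(apply(supp, 1, function(r) all(r) || !any(r))))
  }
  # least-squares recovery at large n
  Bhat <- solve(crossprod(X), crossprod(X, reg$Y))
  expect_lt(max(abs(Bhat - Bstar)), 0.1)

  # zero effect range: Y is pure noise with precision Lambda
  regz <- sim_regression_design(L, q = 8, eqtl_prob = 0, X = X, seed = 71)
  expect_true(all(regz$truth$B == 0))
})

test_that("generators are pure functions of parameters and seed", {
  a <- sim_eqtl_dataset(n = 40, p = 10, q = 15, seed = 73)
  b <- sim_eqtl_dataset(n = 40, p = 10, q = 15, seed = 73)
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)
  expect_identical(a$truth$Lambda, b$truth$Lambda)
  c <- sim_eqtl_dataset(n = 40, p = 10, q = 15, seed = 74)
  expect_false(identical(a$Y, c$Y))
})
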