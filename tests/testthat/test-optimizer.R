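test_that("soft-thresholding operator matches hand computation", {
  M <- matrix(c(3, 0.5, -2, 1), 2, 2)
  expect_equal(prox_l1(M, 1), matrix(c(2, 0, -1, 0), 2, 2))
  expect_equal(prox_l1(M, 0), M)
  D <- diag(c(2, -3))
  expect_equal(prox_l1(D, 10, skip_diagonal = TRUE), D)
  expect_error(prox_l1(M, -1), "nonnegative")
})

test_that("objective separates into likelihood plus penalties", {
  set.seed(1)
  st <- random_stats(30, 4, 3)
  m <- random_model(4, 3)
  nll <- neg_log_likelihood(m, st)
  expect_equal(scggm_objective(m, st, 0, 0), nll)

  off <- abs(m$Lambda); diag(off) <- 0
  expect_equal(scggm_objective(m, st, 0.3, 0.7) - nll,
               0.3 * sum(off) + 0.7 * sum(abs(m$Theta)),
               tolerance = 1e-12)

  # diagonal unpenalized
  mI <- scggm_model(diag(4), matrix(0, 3, 4))
  expect_equal(scggm_objective(mI, st, 5, 5),
               neg_log_likelihood(mI, st))
  expect_error(scggm_objective(m, st, -0.1, 0), "nonnegative")
})

test_that("fit matches the independent reference solver", {
  set.seed(7)
  st <- random_stats(50, 4, 3)
  or <- oracle_solve(st, 0.1, 0.1)
  fit <- scggm(NULL, NULL, 0.1, 0.1, stats = st,
               control = scggm_control(tol = 1e-9, max_iter = 10000))
  expect_lte(fit$fit_info$objective, or$objective + 1e-4)
  expect_lt(max(abs(fit$Lambda - or$Lambda)), 1e-3)
  expect_lt(max(abs(fit$Theta - or$Theta)), 1e-3)
})

test_that("fitted models satisfy the subgradient optimality condition", {
  set.seed(17)
  st <- random_stats(80, 5, 4)
  fit <- scggm(NULL, NULL, 0.08, 0.12, stats = st,
               control = scggm_control(tol = 1e-10, max_iter = 20000))
  expect_lt(scggm_kkt_residual(fit, st), 1e-3)
})

test_that("objective trace is non-increasing and Lambda stays PD", {
  set.seed(3)
  d <- sim_eqtl_dataset(n = 120, p = 8, q = 12, seed = 33)
  fit <- scggm(d$X, d$Y, 0.05, 0.05)
  tr <- fit$fit_info$objective_trace
  expect_true(all(diff(tr) <= 1e-9))
  expect_silent(chol(fit$Lambda))
  expect_true(fit$fit_info$converged)
})

test_that("large perturbation penalty reduces to network-only estimation", {
  set.seed(9)
  d <- sim_eqtl_dataset(n = 150, p = 4, q = 3, seed = 29)
  st <- sufficient_stats(standardize_genotypes(d$X),
                         center_expressions(d$Y))
  fit <- scggm(NULL, NULL, 0.1, 1e3, stats = st,
               control = scggm_control(tol = 1e-9, max_iter = 10000))
  expect_true(all(fit$Theta == 0))
  # reference: graphical-lasso-style solution of the Theta = 0 problem
  or <- oracle_solve(st, 0.1, 0, theta_zero = TRUE)
  expect_lt(norm(fit$Lambda - or$Lambda, "F"), 1e-4)
})

test_that("large network penalty drives off-diagonal Lambda to zero", {
  set.seed(19)
  d <- sim_eqtl_dataset(n = 150, p = 5, q = 4, seed = 31)
  fit <- scggm(d$X, d$Y, 1e3, 0.05,
               control = scggm_control(tol = 1e-9, max_iter = 10000))
  off <- fit$Lambda; diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("estimates approach the truth at large n with small penalties", {
  set.seed(23)
  Lambda <- matrix(c(1.5, -0.5, 0, -0.5, 1.5, -0.4, 0, -0.4, 1.2), 3, 3)
  Theta <- matrix(0, 2, 3); Theta[1, 1] <- 0.8; Theta[2, 3] <- -0.7
  truth <- scggm_truth(Lambda, Theta)
  X <- sim_genotypes(2000, 2, seed = 5)
  Xs <- standardize_genotypes(X)
  Y <- sim_expressions(truth, Xs, seed = 6)
  fit <- scggm(X, Y, 1e-3, 1e-3,
               control = scggm_control(tol = 1e-8, max_iter = 10000))
  expect_lt(max(abs(fit$Lambda - Lambda)), 0.1)
  expect_lt(max(abs(fit$Theta - Theta)), 0.1)
})

test_that("solutions are equivariant under gene permutation", {
  set.seed(37)
  d <- sim_eqtl_dataset(n = 100, p = 5, q = 6, seed = 41)
  ctl <- scggm_control(tol = 1e-10, max_iter = 20000)
  fit <- scggm(d$X, d$Y, 0.05, 0.08, control = ctl)
  perm <- c(3, 1, 5, 2, 4)
  fitp <- scggm(d$X, d$Y[, perm], 0.05, 0.08, control = ctl)
  expect_lt(max(abs(fitp$Lambda - fit$Lambda[perm, perm])), 1e-6)
  expect_lt(max(abs(fitp$Theta - fit$Theta[, perm])), 1e-6)
})

test_that("warm-started paths reproduce cold-start solutions", {
  set.seed(43)
  d <- sim_eqtl_dataset(n = 100, p = 6, q = 8, seed = 47)
  ctl <- scggm_control(tol = 1e-11, max_iter = 50000)
  grid <- data.frame(lambda_net = c(0.2, 0.05, 0.05),
                     lambda_perturb = c(0.2, 0.05, 0.05))
  path <- scggm_path(d$X, d$Y, grid, control = ctl)
  # duplicated grid point: identical solutions
  expect_lt(max(abs(path[[2]]$Lambda - path[[3]]$Lambda)), 1e-5)
  # warm start agrees with cold start
  cold <- scggm(d$X, d$Y, 0.05, 0.05, control = ctl)
  expect_lt(abs(path[[2]]$fit_info$objective -
                  cold$fit_info$objective), 1e-6)
  # single-point grid equals a direct fit
  single <- scggm_path(d$X, d$Y, grid[1, ], control = ctl)
  expect_equal(single[[1]]$Lambda, path[[1]]$Lambda, tolerance = 1e-8)
})

test_that("cross-validation selects by held-out error with sparse tie-break", {
  set.seed(53)
  d <- sim_eqtl_dataset(n = 60, p = 5, q = 6, seed = 59)
  ctl <- scggm_control(tol = 1e-10, max_iter = 20000)

  # single-point grid: that point wins
  g1 <- data.frame(lambda_net = 0.1, lambda_perturb = 0.1)
  cv1 <- scggm_cv(d$X, d$Y, grid = g1, k = 3, control = ctl, seed = 1,
                  refit = FALSE)
  expect_equal(cv1$best$lambda_net, 0.1)

  # duplicated point: equal errors, deterministic selection
  g2 <- rbind(g1, g1)
  cv2 <- scggm_cv(d$X, d$Y, grid = g2, k = 3, control = ctl, seed = 1,
                  refit = FALSE)
  expect_equal(cv2$table$mean_error[1], cv2$table$mean_error[2],
               tolerance = 1e-4)

  # brute-force oracle: independent fold loop over a 3-point grid
  g3 <- data.frame(lambda_net = c(0.5, 0.1, 0.02),
                   lambda_perturb = c(0.5, 0.1, 0.02))
  cv3 <- scggm_cv(d$X, d$Y, grid = g3, k = 3, control = ctl, seed = 7,
                  refit = FALSE)
  n <- nrow(d$Y)
  perm <- withr::with_seed(7L, sample.int(n))
  sizes <- diff(floor(seq(0, n, length.out = 4)))
  fold_of <- integer(n); fold_of[perm] <- rep(1:3, times = sizes)
  manual <- matrix(NA_real_, 3, 3)
  for (f in 1:3) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    Xtr <- standardize_genotypes(d$X[tr, ])
    Ytr <- center_expressions(d$Y[tr, ])
    Xte <- standardize_genotypes(d$X[te, ], center = attr(Xtr, "center"),
                                 scale = attr(Xtr, "scale"))
    Yte <- sweep(d$Y[te, ], 2, attr(Ytr, "center"), "-")
    for (i in 1:3) {
      f2 <- scggm(Xtr, Ytr, g3$lambda_net[i], g3$lambda_perturb[i],
                  control = ctl, standardize = FALSE, center = FALSE)
      manual[i, f] <- prediction_error(f2, Xte, Yte)
    }
  }
  expect_equal(cv3$table$mean_error, rowMeans(manual), tolerance = 1e-4)
  best_manual <- which.min(rowMeans(manual))
  expect_equal(cv3$best$lambda_net, g3$lambda_net[best_manual])

  expect_error(scggm_cv(d$X, d$Y, grid = g1, k = 100), "folds")
})
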