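#' Optimizer settings for sparse CGGM estimation
#'
#' @param max_iter maximum accepted iterations.
#' @param tol relative objective-change stopping threshold; the fit
#'   stops once the change stays below `tol` for 3 consecutive
#'   accepted iterations.
#' @param backtracking_factor step shrink factor in (0, 1).
#' @param initial_step initial proximal-gradient step size.
#' @param verbose print the objective every 50 iterations.
#' @return List of class `scggm_control`.
#' @export
scggm_control <- function(max_iter = 2000L, tol = 1e-6,
                          backtracking_factor = 0.5, initial_step = 1,
                          verbose = FALSE) {
  stopifnot(max_iter >= 1, tol >= 0,
            backtracking_factor > 0, backtracking_factor < 1,
            initial_step > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 backtracking_factor = backtracking_factor,
                 initial_step = initial_step, verbose = isTRUE(verbose)),
            class = "scggm_control")
}

#' Elementwise soft-thresholding
#'
#' The proximal operator of the L1 penalty:
#' sign(m) * max(|m| - threshold, 0).  With `skip_diagonal` the
#' diagonal is returned unchanged, matching the convention that
#' diagonal precision entries are not penalized.
#'
#' @param M numeric matrix.
#' @param threshold nonnegative scalar.
#' @param skip_diagonal leave diagonal entries untouched.
#' @return Thresholded matrix.
#' @export
prox_l1 <- function(M, threshold, skip_diagonal = FALSE) {
  if (threshold < 0) stop("threshold must be nonnegative")
  out <- sign(M) * pmax(abs(M) - threshold, 0)
  if (skip_diagonal) diag(out) <- diag(M)
  out
}

#' Penalized objective of the sparse CGGM program
#'
#' Negative log-likelihood plus `lambda_net` times the L1 norm of the
#' off-diagonal of Lambda (diagonal unpenalized) plus `lambda_perturb`
#' times the L1 norm of Theta.
#'
#' @param model `scggm` object.
#' @param stats `scggm_stats`.
#' @param lambda_net,lambda_perturb nonnegative penalties.
#' @return Scalar objective value.
#' @export
scggm_objective <- function(model, stats, lambda_net, lambda_perturb) {
  if (lambda_net < 0 || lambda_perturb < 0)
    stop("penalties must be nonnegative")
  neg_log_likelihood(model, stats) +
    .penalty(model$Lambda, model$Theta, lambda_net, lambda_perturb)
}

.penalty <- function(Lambda, Theta, lambda_net, lambda_perturb) {
  off <- abs(Lambda); diag(off) <- 0
  lambda_net * sum(off) + lambda_perturb * sum(abs(Theta))
}

# Smooth part of the objective and its gradient, on raw (Lambda, Theta)
# matrices; returns NULL if Lambda fails Cholesky (objective +Inf there).
.smooth_value <- function(Lambda, Theta, stats) {
  R <- tryCatch(chol(Lambda), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  p <- nrow(Lambda)
  LiTt <- backsolve(R, backsolve(R, t(Theta), transpose = TRUE))
  val <- 0.5 * sum(Lambda * stats$Syy) + sum(Theta * stats$Sxy) +
    0.5 * sum((Theta %*% LiTt) * stats$Sxx) -
    sum(log(diag(R))) + 0.5 * p * log(2 * pi)
  list(value = val, R = R, LiTt = LiTt)
}

.smooth_grad <- function(Lambda, Theta, stats, cache) {
  Li <- chol2inv(cache$R)
  TLi <- t(cache$LiTt)
  SxxTLi <- stats$Sxx %*% TLi
  gL <- 0.5 * (stats$Syy - Li - crossprod(TLi, SxxTLi))
  list(Lambda = (gL + t(gL)) / 2, Theta = stats$Sxy + SxxTLi)
}

#' Fit a sparse CGGM
#'
#' Estimates the gene-network precision matrix Lambda and the direct
#' SNP-perturbation matrix Theta jointly by minimizing the penalized
#' negative log-likelihood
#' \deqn{\ell(\Lambda, \Theta) + \lambda_{net}\|\Lambda\|_{1,off}
#'   + \lambda_{perturb}\|\Theta\|_1,}
#' a convex program solved by an accelerated proximal-gradient method
#' (two-sequence Nesterov updates with backtracking line search on the
#' composite quadratic upper bound, and a monotone restart whenever an
#' extrapolated step would increase the objective).  Positive
#' definiteness of Lambda is maintained by rejecting trial updates that
#' fail a Cholesky factorization — the log-determinant barrier makes
#' the objective infinite there — rather than by projection.
#'
#' @param X genotype matrix, samples x SNPs (allele counts or dosages).
#' @param Y expression matrix, samples x genes.
#' @param lambda_net nonnegative penalty on off-diagonal Lambda.
#' @param lambda_perturb nonnegative penalty on Theta.
#' @param control optimizer settings, see [scggm_control()].
#' @param standardize standardize genotype columns (recommended; the
#'   default penalty scales assume it).
#' @param center mean-center expression columns.
#' @param init optional `scggm` object used as a warm start.
#' @param stats optional precomputed `scggm_stats`; when given, `X` and
#'   `Y` may be NULL and no preprocessing is applied.
#' @return Fitted `scggm` object; `fit_info` records iterations, final
#'   objective, the accepted-objective trace, and a convergence flag.
#' @export
scggm <- function(X, Y, lambda_net, lambda_perturb,
                  control = scggm_control(), standardize = TRUE,
                  center = TRUE, init = NULL, stats = NULL) {
  if (lambda_net < 0 || lambda_perturb < 0)
    stop("penalties must be nonnegative")
  if (is.null(stats)) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
      stop("NA or non-finite values in input data")
    if (standardize) X <- standardize_genotypes(X)
    if (center) Y <- center_expressions(Y)
    stats <- sufficient_stats(X, Y)
  }
  p <- nrow(stats$Syy); q <- nrow(stats$Sxx)

  if (is.null(init)) {
    Lambda <- diag(p); Theta <- matrix(0, q, p)
  } else {
    Lambda <- init$Lambda; Theta <- init$Theta
  }

  bt <- control$backtracking_factor
  step <- control$initial_step
  sm <- .smooth_value(Lambda, Theta, stats)
  if (is.null(sm)) stop("initial Lambda is not positive definite")
  obj <- sm$value + .penalty(Lambda, Theta, lambda_net, lambda_perturb)
  trace <- obj

  zL <- Lambda; zT <- Theta        # extrapolated sequence
  smz <- sm
  tk <- 1
  converged <- FALSE
  iter <- 0L
  small_steps <- 0L   # consecutive sub-tolerance objective changes
  just_restarted <- FALSE
  rel <- Inf

  while (iter < control$max_iter) {
    if (is.null(smz)) {            # extrapolation left the PD cone
      zL <- Lambda; zT <- Theta; tk <- 1
      smz <- .smooth_value(zL, zT, stats)
    }
    grad <- .smooth_grad(zL, zT, stats, smz)
    gz <- smz$value

    step <- min(step / bt, control$initial_step)  # let the step recover
    repeat {
      newL <- prox_l1(zL - step * grad$Lambda, step * lambda_net,
                      skip_diagonal = TRUE)
      newL <- (newL + t(newL)) / 2
      newT <- prox_l1(zT - step * grad$Theta, step * lambda_perturb)
      smn <- .smooth_value(newL, newT, stats)
      if (!is.null(smn)) {
        dL <- newL - zL; dT <- newT - zT
        quad <- gz + sum(grad$Lambda * dL) + sum(grad$Theta * dT) +
          (sum(dL^2) + sum(dT^2)) / (2 * step)
        if (smn$value <= quad + 1e-12) break
      }
      step <- step * bt
      if (step < 1e-14) stop("line search failed: step size underflow")
    }

    newobj <- smn$value + .penalty(newL, newT, lambda_net, lambda_perturb)

    if (newobj > obj + 1e-12 && !just_restarted) {
      # monotone restart: drop momentum and redo from current iterate
      # (a plain proximal step from the current iterate cannot increase
      # the objective, so one restart always suffices)
      zL <- Lambda; zT <- Theta; tk <- 1
      smz <- .smooth_value(zL, zT, stats)
      just_restarted <- TRUE
      next
    }
    just_restarted <- FALSE

    iter <- iter + 1L
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    w <- (tk - 1) / tnew
    zL <- newL + w * (newL - Lambda)
    zT <- newT + w * (newT - Theta)
    zL <- (zL + t(zL)) / 2
    Lambda <- newL; Theta <- newT
    tk <- tnew
    smz <- .smooth_value(zL, zT, stats)

    trace <- c(trace, newobj)
    rel <- abs(obj - newobj) / max(1, abs(obj))
    obj <- newobj
    if (control$verbose && iter %% 50L == 0L)
      message("iter ", iter, " objective ", format(obj, digits = 10))
    # momentum ramp-up can stall the objective briefly before further
    # progress, so demand the tolerance hold on consecutive iterations
    small_steps <- if (rel < control$tol) small_steps + 1L else 0L
    if (small_steps >= 3L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("sparse CGGM fit did not converge in ", control$max_iter,
            " iterations (relative change ", format(rel), ")")

  dimnames(Lambda) <- list(stats$gene_ids, stats$gene_ids)
  dimnames(Theta) <- list(stats$snp_ids, stats$gene_ids)
  scggm_model(Lambda, Theta, lambda_net, lambda_perturb,
              fit_info = list(iterations = iter, objective = obj,
                              objective_trace = trace,
                              converged = converged))
}

#' Subgradient optimality residual
#'
#' Maximum violation of the Karush-Kuhn-Tucker condition of the
#' penalized program at the fitted point: for penalized coordinates at
#' zero, max(|grad| - lambda, 0); for nonzero coordinates,
#' |grad + lambda * sign|; for unpenalized coordinates (the Lambda
#' diagonal), |grad|.  Zero at an exact optimum.
#'
#' @param model fitted `scggm` object.
#' @param stats `scggm_stats` used in fitting.
#' @param zero_tol entries with absolute value below this count as zero.
#' @return Scalar maximum KKT violation.
#' @export
scggm_kkt_residual <- function(model, stats, zero_tol = 1e-10) {
  g <- nll_gradient(model, stats)
  viol_block <- function(M, G, lam, skip_diag = FALSE) {
    nz <- abs(M) > zero_tol
    v <- ifelse(nz, abs(G + lam * sign(M)), pmax(abs(G) - lam, 0))
    if (skip_diag) diag(v) <- abs(diag(G))
    max(v)
  }
  max(viol_block(model$Lambda, g$Lambda, model$lambda_net, skip_diag = TRUE),
      viol_block(model$Theta, g$Theta, model$lambda_perturb))
}

#' Fit a warm-started path of sparse CGGMs
#'
#' Fits one model per penalty pair, warm-starting each fit from the
#' previous solution.  Convexity makes solutions independent of the
#' starting point (up to the stopping tolerance), so warm starts only
#' save iterations.
#'
#' @param X,Y data matrices as in [scggm()].
#' @param grid data frame (or matrix) with columns `lambda_net` and
#'   `lambda_perturb`, one row per penalty pair.
#' @param control optimizer settings.
#' @param stats optional precomputed `scggm_stats`.
#' @return List of `scggm` objects, one per grid row; entries that
#'   failed carry the condition object instead, with a warning.
#' @export
scggm_path <- function(X, Y, grid, control = scggm_control(),
                       stats = NULL) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty penalty grid")
  if (!all(c("lambda_net", "lambda_perturb") %in% names(grid)))
    stop("grid needs columns lambda_net and lambda_perturb")
  if (is.null(stats)) {
    stats <- sufficient_stats(standardize_genotypes(as.matrix(X)),
                              center_expressions(as.matrix(Y)))
  }
  out <- vector("list", nrow(grid))
  prev <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      scggm(NULL, NULL, grid$lambda_net[i], grid$lambda_perturb[i],
            control = control, init = prev, stats = stats),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("grid point ", i, " failed: ", conditionMessage(fit))
    } else {
      prev <- fit
    }
    out[[i]] <- fit
  }
  out
}

#' Default log-spaced penalty grid
#'
#' @param n_net,n_perturb grid sizes per penalty.
#' @param from,to range of each penalty (log-spaced), appropriate for
#'   standardized inputs.
#' @return Data frame with all penalty combinations, ordered from
#'   strongest to weakest so warm starts move from sparse to dense.
#' @export
scggm_grid <- function(n_net = 5, n_perturb = 5, from = 1e-3, to = 1) {
  ln <- sort(exp(seq(log(from), log(to), length.out = n_net)),
             decreasing = TRUE)
  lp <- sort(exp(seq(log(from), log(to), length.out = n_perturb)),
             decreasing = TRUE)
  expand.grid(lambda_perturb = lp, lambda_net = ln,
              KEEP.OUT.ATTRS = FALSE)[, c("lambda_net", "lambda_perturb")]
}

#' Cross-validated penalty selection
#'
#' k-fold cross-validation over a penalty grid.  Folds are contiguous
#' blocks of a seeded random permutation of samples.  Within each fold
#' the training block is centered/standardized and the held-out block
#' is transformed with the training statistics.  The CV error is the
#' mean squared error of the conditional-mean prediction E[y|x] = B'x
#' on held-out samples (per sample and per gene); ties are broken
#' toward the larger penalty sum, i.e. the sparser model.
#'
#' @param X,Y raw data matrices, samples x SNPs / samples x genes.
#' @param grid penalty grid as in [scggm_path()]; default [scggm_grid()].
#' @param k number of folds (>= 2, <= n).
#' @param control optimizer settings.
#' @param seed integer seed for the fold permutation.
#' @param metric `"mse"` for squared prediction error or `"loglik"` for
#'   held-out negative predictive log-likelihood.
#' @param refit refit on the full data at the selected penalties.
#' @return Object of class `scggm_cv`: `table` (tibble of grid points
#'   with mean/sd CV error), `best` (selected pair), `k`, and `fit`
#'   (full-data model at `best`, when `refit = TRUE`).
#' @export
scggm_cv <- function(X, Y, grid = scggm_grid(3, 3), k = 5,
                     control = scggm_control(), seed = NULL,
                     metric = c("mse", "loglik"), refit = TRUE) {
  metric <- match.arg(metric)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(Y)
  if (k < 2) stop("need at least 2 folds")
  if (k > n) stop("more folds than samples")
  grid <- as.data.frame(grid)

  perm <- if (is.null(seed)) sample.int(n) else
    withr::with_seed(as.integer(seed), sample.int(n))
  # contiguous blocks of the permutation: samples perm[1..n/k] are fold 1, etc.
  fold_of <- integer(n)
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_of[perm] <- rep(seq_len(k), times = sizes)

  errs <- matrix(NA_real_, nrow(grid), k)
  for (fold in seq_len(k)) {
    test_idx <- which(fold_of == fold)
    train_idx <- setdiff(seq_len(n), test_idx)
    Xtr <- standardize_genotypes(X[train_idx, , drop = FALSE])
    Ytr <- center_expressions(Y[train_idx, , drop = FALSE])
    Xte <- standardize_genotypes(X[test_idx, , drop = FALSE],
                                 center = attr(Xtr, "center"),
                                 scale = attr(Xtr, "scale"))
    Yte <- sweep(Y[test_idx, , drop = FALSE], 2L, attr(Ytr, "center"), "-")
    st <- sufficient_stats(Xtr, Ytr)
    fits <- scggm_path(NULL, NULL, grid, control = control, stats = st)
    for (i in seq_along(fits)) {
      if (inherits(fits[[i]], "error")) next
      if (metric == "mse") {
        errs[i, fold] <- prediction_error(fits[[i]], Xte, Yte)
      } else {
        st_te <- sufficient_stats(Xte, Yte)
        errs[i, fold] <- neg_log_likelihood(fits[[i]], st_te)
      }
    }
  }

  mean_err <- rowMeans(errs)
  sd_err <- apply(errs, 1L, stats::sd)
  ord <- order(mean_err, -(grid$lambda_net + grid$lambda_perturb))
  best_i <- ord[1L]
  tab <- tibble::tibble(lambda_net = grid$lambda_net,
                        lambda_perturb = grid$lambda_perturb,
                        mean_error = mean_err, sd_error = sd_err)
  res <- structure(list(
    table = tab,
    best = list(lambda_net = grid$lambda_net[best_i],
                lambda_perturb = grid$lambda_perturb[best_i]),
    k = k, metric = metric, seed = seed, fit = NULL
  ), class = "scggm_cv")
  if (refit) {
    res$fit <- scggm(X, Y, res$best$lambda_net, res$best$lambda_perturb,
                     control = control)
  }
  res
}

#' @export
print.scggm_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation over ", nrow(x$table),
      " penalty pairs (", x$metric, ")\n", sep = "")
  cat("selected: lambda_net =", format(x$best$lambda_net),
      ", lambda_perturb =", format(x$best$lambda_perturb), "\n")
  invisible(x)
}
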