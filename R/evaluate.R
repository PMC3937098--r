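#' Precision-recall curve for support recovery
#'
#' Ranks all candidate entries of an estimated parameter matrix in
#' descending order of absolute value and sweeps the ranked list
#' against the true support, recording precision and recall at each
#' distinct absolute value (tied entries enter together, so the curve
#' is deterministic).  For symmetric network matrices only the strict
#' upper triangle is ranked: self-edges are not network claims.
#'
#' @param estimate numeric matrix of estimated parameters.
#' @param truth_support logical (or numeric, nonzero = TRUE) matrix of
#'   the same shape marking true nonzeros.
#' @param symmetric rank only the strict upper triangle.
#' @return Object of class `scggm_pr`: tibble `points` with columns
#'   `threshold`, `tp`, `fp`, `precision`, `recall`; scalar `auprc`
#'   (trapezoid over recall); `n_true`; `n_candidates`; `prevalence`.
#' @export
precision_recall <- function(estimate, truth_support, symmetric = FALSE) {
  estimate <- as.matrix(estimate)
  truth <- as.matrix(truth_support) != 0
  if (!all(dim(estimate) == dim(truth)))
    stop("estimate and truth must have the same shape")
  if (symmetric) {
    keep <- upper.tri(estimate)
    scores <- abs(estimate[keep])
    labels <- truth[keep] | t(truth)[keep]
  } else {
    scores <- abs(as.vector(estimate))
    labels <- as.vector(truth)
  }
  n_true <- sum(labels)
  if (n_true == 0L) stop("truth support is empty")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  # group ties: last index of each distinct score
  last <- which(c(scores[-1L] != scores[-length(scores)], TRUE))
  tp <- cumsum(labels)[last]
  pos <- last
  precision <- tp / pos
  recall <- tp / n_true
  auprc <- .trapezoid_auprc(recall, precision)
  structure(list(
    points = tibble::tibble(threshold = scores[last], tp = tp,
                            fp = pos - tp, precision = precision,
                            recall = recall),
    auprc = auprc, n_true = n_true, n_candidates = length(scores),
    prevalence = n_true / length(scores)
  ), class = "scggm_pr")
}

# trapezoid over recall, with a flat extension from recall 0 to the
# first curve point
.trapezoid_auprc <- function(recall, precision) {
  r <- c(0, recall); pr <- c(precision[1L], precision)
  sum(diff(r) * (utils::head(pr, -1L) + utils::tail(pr, -1L)) / 2)
}

#' @export
print.scggm_pr <- function(x, ...) {
  cat("Precision-recall: AUPRC =", format(x$auprc, digits = 4),
      "( prevalence", format(x$prevalence, digits = 4), ",",
      x$n_true, "true /", x$n_candidates, "candidates )\n")
  invisible(x)
}

#' Test-set prediction error
#'
#' Mean squared error of the conditional-mean prediction E[y|x] = B'x
#' over held-out samples, averaged over samples and genes.  Accepts a
#' fitted model (B is obtained by inference) or a q x p coefficient
#' matrix directly.
#'
#' @param object `scggm` model or q x p matrix B.
#' @param Xtest held-out genotype matrix, standardized with the
#'   training center/scale.
#' @param Ytest held-out expression matrix, centered with the training
#'   means.
#' @return Nonnegative scalar.
#' @export
prediction_error <- function(object, Xtest, Ytest) {
  B <- if (inherits(object, "scggm")) conditional_moments(object)$B
       else as.matrix(object)
  Xtest <- as.matrix(Xtest); Ytest <- as.matrix(Ytest)
  if (nrow(Xtest) == 0L) stop("empty test set")
  if (nrow(Xtest) != nrow(Ytest))
    stop("test genotype and expression sample counts differ")
  if (nrow(B) != ncol(Xtest) || ncol(B) != ncol(Ytest))
    stop("coefficient matrix shape does not match test data")
  mean((Ytest - Xtest %*% B)^2)
}

#' Two-stage baseline: network then regression, separately
#'
#' The decoupled alternative to the joint fit, realized through the
#' special-case limits of the same program: a network-only stage with
#' the perturbation penalty large enough to force Theta to zero
#' (graphical-lasso-style estimation of Lambda from Syy alone), and a
#' per-gene regression stage with the network penalty large enough to
#' force Lambda diagonal (lasso-style estimation of the SNP effects).
#' The returned model combines the stage-1 network with the stage-2
#' perturbations.
#'
#' @param X,Y data matrices as in [scggm()].
#' @param lambda_net network penalty for stage 1.
#' @param lambda_perturb perturbation penalty for stage 2.
#' @param control optimizer settings.
#' @param big penalty value used to switch the other block off.
#' @param stats optional precomputed `scggm_stats`.
#' @return List of class `scggm_two_stage`: `network` (stage-1 model),
#'   `regression` (stage-2 model), `Lambda`, `Theta`, and `B` (total
#'   effects of the stage-2 model, whose support is the lasso support).
#' @export
fit_two_stage <- function(X, Y, lambda_net, lambda_perturb,
                          control = scggm_control(), big = 1e6,
                          stats = NULL) {
  if (is.null(stats)) {
    stats <- sufficient_stats(standardize_genotypes(as.matrix(X)),
                              center_expressions(as.matrix(Y)))
  }
  net <- scggm(NULL, NULL, lambda_net, big, control = control,
               stats = stats)
  reg <- scggm(NULL, NULL, big, lambda_perturb, control = control,
               stats = stats)
  structure(list(network = net, regression = reg,
                 Lambda = net$Lambda, Theta = reg$Theta,
                 B = conditional_moments(reg)$B),
            class = "scggm_two_stage")
}

#' Compare joint and two-stage estimation on one dataset
#'
#' Fits the joint sparse CGGM and the two-stage baseline (and
#' optionally a null model predicting zero), then scores network-
#' support recovery, eQTL-support recovery, and test-set prediction
#' error against a known truth.  Penalties for each method are selected
#' by cross-validation on the training data over the supplied grid.
#'
#' @param X,Y training data (raw genotypes, expressions).
#' @param truth `scggm_truth` object.
#' @param Xtest,Ytest optional held-out data for prediction error.
#' @param methods subset of `c("scggm", "two_stage")`.
#' @param grid penalty grid for cross-validation.
#' @param k CV folds.
#' @param control optimizer settings.
#' @param seed integer seed for fold assignment.
#' @return Object of class `scggm_comparison`: tibble `summary` with
#'   one row per method (`lambda_auprc`, `theta_auprc`,
#'   `prediction_error`) plus the `null` prediction error, and list
#'   `curves` of per-method PR curves; failed methods carry NA rows.
#' @export
compare_methods <- function(X, Y, truth, Xtest = NULL, Ytest = NULL,
                            methods = c("scggm", "two_stage"),
                            grid = scggm_grid(3, 3), k = 5,
                            control = scggm_control(), seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xtr <- standardize_genotypes(X)
  Ytr <- center_expressions(Y)
  have_test <- !is.null(Xtest) && !is.null(Ytest)
  if (have_test) {
    Xte <- standardize_genotypes(as.matrix(Xtest),
                                 center = attr(Xtr, "center"),
                                 scale = attr(Xtr, "scale"))
    Yte <- sweep(as.matrix(Ytest), 2L, attr(Ytr, "center"), "-")
  }
  lam_truth <- abs(truth$Lambda) > 1e-8; diag(lam_truth) <- FALSE
  theta_truth <- abs(truth$Theta) > 1e-8

  rows <- list(); curves <- list()
  for (m in methods) {
    res <- tryCatch({
      if (m == "scggm") {
        cv <- scggm_cv(X, Y, grid = grid, k = k, control = control,
                       seed = seed)
        fit <- cv$fit
        Lam <- fit$Lambda; The <- fit$Theta
        pe <- if (have_test) prediction_error(fit, Xte, Yte) else NA_real_
      } else {
        cv_net <- scggm_cv(X, Y, k = k, control = control, seed = seed,
          grid = data.frame(lambda_net = unique(grid$lambda_net),
                            lambda_perturb = 1e6))
        cv_reg <- scggm_cv(X, Y, k = k, control = control, seed = seed,
          grid = data.frame(lambda_net = 1e6,
                            lambda_perturb = unique(grid$lambda_perturb)))
        ts <- fit_two_stage(X, Y, cv_net$best$lambda_net,
                            cv_reg$best$lambda_perturb,
                            control = control)
        Lam <- ts$Lambda; The <- ts$Theta
        pe <- if (have_test) prediction_error(ts$B, Xte, Yte) else NA_real_
      }
      pr_l <- precision_recall(Lam, lam_truth, symmetric = TRUE)
      pr_t <- precision_recall(The, theta_truth)
      curves[[m]] <- list(lambda = pr_l, theta = pr_t)
      tibble::tibble(method = m, lambda_auprc = pr_l$auprc,
                     theta_auprc = pr_t$auprc, prediction_error = pe)
    }, error = function(e) {
      warning("method ", m, " failed: ", conditionMessage(e))
      tibble::tibble(method = m, lambda_auprc = NA_real_,
                     theta_auprc = NA_real_,
                     prediction_error = NA_real_)
    })
    rows[[m]] <- res
  }
  null_pe <- if (have_test) mean(Yte^2) else NA_real_
  structure(list(summary = do.call(rbind, rows), curves = curves,
                 null_prediction_error = null_pe),
            class = "scggm_comparison")
}

#' @export
print.scggm_comparison <- function(x, ...) {
  cat("Method comparison (higher AUPRC, lower error = better):\n")
  print(x$summary)
  if (is.finite(x$null_prediction_error))
    cat("null (B = 0) prediction error:",
        format(x$null_prediction_error, digits = 4), "\n")
  invisible(x)
}
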