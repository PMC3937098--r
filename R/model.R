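#' Construct a sparse CGGM
#'
#' A conditional Gaussian graphical model for expression traits y given
#' genotypes x,
#' \deqn{p(y | x) \propto \exp(-\tfrac12 y' \Lambda y - x' \Theta y),}
#' where `Lambda` (p x p, positive definite) is the gene-network
#' precision matrix — nonzero off-diagonals are conditional-dependence
#' edges — and `Theta` (q x p) holds direct SNP-perturbation weights —
#' a nonzero entry (i, j) makes SNP i a direct eQTL of gene j.
#'
#' @param Lambda p x p symmetric positive-definite matrix.
#' @param Theta q x p matrix of direct perturbation weights.
#' @param lambda_net,lambda_perturb nonnegative penalties the model was
#'   fitted with (NA for hand-built models).
#' @param fit_info optional list of optimizer diagnostics.
#' @return Object of class `scggm`.
#' @export
scggm_model <- function(Lambda, Theta, lambda_net = NA_real_,
                        lambda_perturb = NA_real_, fit_info = NULL) {
  Lambda <- as.matrix(Lambda)
  Theta <- as.matrix(Theta)
  p <- nrow(Lambda)
  if (ncol(Lambda) != p) stop("Lambda must be square")
  if (ncol(Theta) != p)
    stop("Theta must have one column per gene (", p, ")")
  if (max(abs(Lambda - t(Lambda))) > 1e-12 * max(1, max(abs(Lambda))))
    stop("Lambda must be symmetric")
  Lambda <- (Lambda + t(Lambda)) / 2
  model <- structure(list(
    Lambda = Lambda, Theta = Theta,
    lambda_net = lambda_net, lambda_perturb = lambda_perturb,
    fit_info = fit_info
  ), class = "scggm")
  .chol_lambda(model)  # errors if not PD
  model
}

# Cholesky factor of Lambda; the single gatekeeper for positive
# definiteness used by every likelihood/inference routine.
.chol_lambda <- function(model) {
  R <- tryCatch(chol(model$Lambda), error = function(e) NULL)
  if (is.null(R))
    stop("invalid model: Lambda is not positive definite")
  R
}

#' Log partition function of the conditional density
#'
#' The normalizer of the unnormalized density
#' exp(-y'Λy/2 - x'Θy) is the Gaussian integral
#' \deqn{\log Z(x) = \tfrac12 x' \Theta \Lambda^{-1} \Theta' x
#'   + \tfrac{p}{2} \log(2\pi) - \tfrac12 \log\det\Lambda.}
#'
#' @param model `scggm` object.
#' @param x numeric vector of length q (one sample's genotypes).
#' @return Scalar log normalizer.
#' @export
log_partition <- function(model, x) {
  R <- .chol_lambda(model)
  p <- nrow(model$Lambda)
  x <- as.numeric(x)
  if (length(x) != nrow(model$Theta))
    stop("x must have one entry per SNP")
  tx <- crossprod(model$Theta, x)          # Theta' x, length p
  v <- backsolve(R, backsolve(R, tx, transpose = TRUE))  # Lambda^{-1} Theta' x
  0.5 * sum(tx * v) + 0.5 * p * log(2 * pi) - sum(log(diag(R)))
}

#' Conditional moments implied by a sparse CGGM
#'
#' Inference on the graphical model: the conditional distribution of y
#' given x is Gaussian with mean B'x and covariance Sigma, where
#' B = -Theta Lambda^{-1} collects the total (direct plus
#' network-propagated) SNP effects and Sigma = Lambda^{-1}.
#'
#' @param model `scggm` object.
#' @return List with `B` (q x p) and `Sigma` (p x p).
#' @export
conditional_moments <- function(model) {
  R <- .chol_lambda(model)
  Sigma <- chol2inv(R)
  B <- -model$Theta %*% Sigma
  dimnames(B) <- dimnames(model$Theta)
  dimnames(Sigma) <- list(colnames(model$Theta), colnames(model$Theta))
  list(B = B, Sigma = (Sigma + t(Sigma)) / 2)
}

#' Average negative log-likelihood of a sparse CGGM
#'
#' Per-sample negative log-likelihood expressed through the sufficient
#' statistics:
#' \deqn{\ell = \tfrac12 tr(\Lambda S_{yy}) + tr(\Theta' S_{xy}')
#'   + \tfrac12 tr(\Theta \Lambda^{-1} \Theta' S_{xx})
#'   - \tfrac12 \log\det\Lambda + \tfrac{p}{2}\log 2\pi}
#' (the cross term is the average of x'Θy over samples).  The
#' \eqn{-\log\det\Lambda} term diverges at the positive-definite
#' boundary and acts as a log-barrier, so no explicit PD constraint is
#' needed during optimization.
#'
#' @param model `scggm` object.
#' @param stats `scggm_stats` from [sufficient_stats()].
#' @return Scalar; the mean of -log p(y_i | x_i).
#' @export
neg_log_likelihood <- function(model, stats) {
  .check_shapes(model, stats)
  R <- .chol_lambda(model)
  p <- nrow(model$Lambda)
  # Lambda^{-1} Theta' computed by triangular solves
  LiTt <- backsolve(R, backsolve(R, t(model$Theta), transpose = TRUE))
  0.5 * sum(model$Lambda * stats$Syy) +
    sum(model$Theta * stats$Sxy) +
    0.5 * sum((model$Theta %*% LiTt) * stats$Sxx) -
    sum(log(diag(R))) +
    0.5 * p * log(2 * pi)
}

#' Analytic gradient of the negative log-likelihood
#'
#' @param model `scggm` object.
#' @param stats `scggm_stats`.
#' @return List with `Lambda` (p x p, symmetric) and `Theta` (q x p)
#'   gradient blocks:
#'   dLambda = (Syy - Lambda^{-1} - Lambda^{-1}Theta'Sxx Theta Lambda^{-1})/2,
#'   dTheta = Sxy + Sxx Theta Lambda^{-1}.
#' @export
nll_gradient <- function(model, stats) {
  .check_shapes(model, stats)
  R <- .chol_lambda(model)
  Li <- chol2inv(R)                                # Lambda^{-1}
  TLi <- model$Theta %*% Li                        # q x p
  SxxTLi <- stats$Sxx %*% TLi                      # q x p
  gLambda <- 0.5 * (stats$Syy - Li - crossprod(TLi, SxxTLi))
  gLambda <- (gLambda + t(gLambda)) / 2
  gTheta <- stats$Sxy + SxxTLi
  list(Lambda = gLambda, Theta = gTheta)
}

.check_shapes <- function(model, stats) {
  p <- nrow(model$Lambda); q <- nrow(model$Theta)
  if (nrow(stats$Syy) != p || nrow(stats$Sxx) != q ||
      nrow(stats$Sxy) != q || ncol(stats$Sxy) != p)
    stop("model and sufficient statistics have inconsistent shapes")
  invisible(TRUE)
}

#' @export
print.scggm <- function(x, ...) {
  p <- nrow(x$Lambda); q <- nrow(x$Theta)
  edges <- sum(abs(x$Lambda[upper.tri(x$Lambda)]) > 1e-8)
  eqtls <- sum(abs(x$Theta) > 1e-8)
  cat("Sparse CGGM:", p, "genes,", q, "SNPs\n")
  cat("  network edges:", edges, "| direct eQTL effects:", eqtls, "\n")
  cat("  penalties: lambda_net =", format(x$lambda_net),
      ", lambda_perturb =", format(x$lambda_perturb), "\n")
  if (!is.null(x$fit_info))
    cat("  fit:", x$fit_info$iterations, "iterations, objective",
        format(x$fit_info$objective),
        if (isTRUE(x$fit_info$converged)) "(converged)" else
          "(NOT converged)", "\n")
  invisible(x)
}
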