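#' Mean-center expression traits
#'
#' Subtracts the column mean from each gene so every trait has zero mean,
#' the preprocessing the conditional Gaussian model assumes.
#'
#' @param Y numeric matrix, samples x genes.
#' @return Matrix of the same shape with zero column means and attributes
#'   `center` (the subtracted means) and `centered = TRUE`.
#' @export
center_expressions <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("expression matrix must be numeric")
  if (anyNA(Y)) stop("expression matrix contains missing values")
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu, "-")
  attr(Yc, "center") <- mu
  attr(Yc, "centered") <- TRUE
  Yc
}

#' Standardize genotype columns
#'
#' Scales each SNP column to mean 0 and unit variance.  Constant columns
#' are an error: a SNP with no variation carries no perturbation signal
#' and silently dropping it would desynchronize SNP identifiers.
#'
#' @param X numeric matrix, samples x SNPs; raw allele counts in
#'   \{0, 1, 2\} or already-numeric dosages.
#' @param center,scale optional numeric vectors (length q) of column
#'   centers/scales from a training set, to standardize held-out data
#'   with training statistics.
#' @return Standardized matrix with attributes `center`, `scale` and
#'   `standardized = TRUE`.
#' @export
standardize_genotypes <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("genotype matrix must be numeric")
  if (anyNA(X)) stop("genotype matrix contains missing values")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
  }
  if (any(scale < 1e-12)) {
    bad <- colnames(X)[scale < 1e-12]
    if (is.null(bad)) bad <- which(scale < 1e-12)
    stop("constant genotype column(s): ", paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  attr(Xs, "standardized") <- TRUE
  Xs
}

#' Align genotype and expression samples by shared identifiers
#'
#' Restricts both matrices to the intersection of their row (sample)
#' names, in the order of the expression matrix.  Samples present in
#' only one input are dropped with a message.
#'
#' @param X genotype matrix with sample row names.
#' @param Y expression matrix with sample row names.
#' @return List with elements `X` and `Y`, row-aligned.
#' @export
align_samples <- function(X, Y) {
  if (is.null(rownames(X)) || is.null(rownames(Y)))
    stop("both matrices need sample identifiers as row names")
  keep <- intersect(rownames(Y), rownames(X))
  if (length(keep) == 0L) stop("no shared sample identifiers")
  dropped <- setdiff(union(rownames(X), rownames(Y)), keep)
  if (length(dropped) > 0L)
    message("dropping ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  list(X = X[keep, , drop = FALSE], Y = Y[keep, , drop = FALSE])
}

#' Sufficient statistics for sparse CGGM estimation
#'
#' The penalized likelihood depends on the data only through the
#' sample (cross-)covariance blocks Sxx = X'X/n, Syy = Y'Y/n and
#' Sxy = X'Y/n of centered/standardized data, plus the sample count.
#'
#' @param X standardized genotype matrix (n x q).
#' @param Y centered expression matrix (n x p).
#' @return Object of class `scggm_stats`: list with `Sxx`, `Syy`,
#'   `Sxy`, `n`, `snp_ids`, `gene_ids`.
#' @export
sufficient_stats <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(X) != n) stop("X and Y must have the same number of samples")
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(X) || anyNA(Y)) stop("missing values in input data")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite values in input data")
  structure(list(
    Sxx = crossprod(X) / n,
    Syy = crossprod(Y) / n,
    Sxy = crossprod(X, Y) / n,
    n = n,
    snp_ids = colnames(X),
    gene_ids = colnames(Y)
  ), class = "scggm_stats")
}

#' @export
print.scggm_stats <- function(x, ...) {
  cat("Sufficient statistics: n =", x$n,
      "| q =", nrow(x$Sxx), "SNPs | p =", nrow(x$Syy), "genes\n")
  invisible(x)
}
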