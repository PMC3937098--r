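#' Total (direct plus propagated) SNP perturbation effects
#'
#' Solves B Lambda = -Theta for the indirect-effect matrix
#' B = -Theta Lambda^{-1}: entry (i, j) is the total effect of SNP i on
#' gene j after the direct perturbations have propagated through the
#' gene network.  A SNP reaches a gene only through the connected
#' component of the network containing a directly perturbed gene, so
#' with a block-diagonal Lambda, effects never cross blocks; with a
#' diagonal Lambda, the support of B equals that of Theta.
#'
#' @param model fitted `scggm` object.
#' @return Object of class `scggm_inference`: list with `B` (q x p) and
#'   `Sigma` (p x p conditional covariance Lambda^{-1}).
#' @export
indirect_effects <- function(model) {
  cm <- conditional_moments(model)
  structure(list(B = cm$B, Sigma = cm$Sigma), class = "scggm_inference")
}

#' @export
print.scggm_inference <- function(x, ...) {
  cat("CGGM inference: B is", nrow(x$B), "x", ncol(x$B),
      "(", sum(abs(x$B) > 1e-8), "nonzero effects )\n")
  invisible(x)
}

#' Decompose SNP effects over directly perturbed genes
#'
#' Splits the total-effect matrix B into one component per directly
#' perturbed gene k:
#' \deqn{B_k = -\Theta_{\cdot k}\, (\Lambda^{-1})_{k \cdot},}
#' the outer product of the k-th column of Theta with the k-th row of
#' Lambda^{-1}.  B_k records the share of every SNP effect that entered
#' the network through gene k, and the components over all perturbed
#' genes sum to B.  Genes with an all-zero Theta column contribute a
#' zero component and are omitted.
#'
#' @param model fitted `scggm` object.
#' @param zero_tol Theta entries with absolute value at or below this
#'   count as zero when selecting perturbed genes.
#' @return Object of class `scggm_decomposition`: `components`, a named
#'   list of q x p matrices, and `gene_indices`, the perturbed-gene
#'   indices they correspond to.
#' @export
decompose_effects <- function(model, zero_tol = 1e-8) {
  R <- .chol_lambda(model)
  Sigma <- chol2inv(R)
  perturbed <- which(apply(abs(model$Theta) > zero_tol, 2L, any))
  components <- lapply(perturbed, function(k) {
    Bk <- -outer(model$Theta[, k], Sigma[k, ])
    dimnames(Bk) <- dimnames(model$Theta)
    Bk
  })
  gene_ids <- colnames(model$Theta)
  names(components) <- if (is.null(gene_ids)) as.character(perturbed) else
    gene_ids[perturbed]
  structure(list(components = components,
                 gene_indices = as.integer(perturbed)),
            class = "scggm_decomposition")
}

#' @export
print.scggm_decomposition <- function(x, ...) {
  cat("Perturbation-effect decomposition over",
      length(x$components), "directly perturbed gene(s)\n")
  invisible(x)
}

#' Decompose expression covariance into network and SNP parts
#'
#' At the unpenalized maximum-likelihood solution the optimality
#' (moment-matching) condition of the model gives
#' \deqn{S_{yy} = \Lambda^{-1} + B' S_{xx} B,}
#' splitting observed expression covariance into the part generated by
#' the gene network (the conditional covariance Lambda^{-1}) and the
#' part induced by SNP perturbations propagating through it
#' (B'Sxx B).  Under an L1 penalty the identity holds only
#' approximately; the residual Syy minus both parts, and its Frobenius
#' norm relative to \\|Syy\\|, quantify that sparsity bias.
#'
#' @param model fitted `scggm` object.
#' @param stats `scggm_stats` from the same (standardized) data used to
#'   fit the model.
#' @return Object of class `scggm_cov_decomposition`: `network_part`,
#'   `snp_part`, `residual`, and `relative_residual_norm`.
#' @export
decompose_covariance <- function(model, stats) {
  .check_shapes(model, stats)
  cm <- conditional_moments(model)
  snp_part <- crossprod(cm$B, stats$Sxx %*% cm$B)
  snp_part <- (snp_part + t(snp_part)) / 2
  residual <- stats$Syy - cm$Sigma - snp_part
  structure(list(
    network_part = cm$Sigma,
    snp_part = snp_part,
    residual = residual,
    relative_residual_norm =
      norm(residual, "F") / norm(stats$Syy, "F")
  ), class = "scggm_cov_decomposition")
}

#' @export
print.scggm_cov_decomposition <- function(x, ...) {
  cat("Covariance decomposition: Syy ~ network + SNP parts\n")
  cat("  relative residual (Frobenius):",
      format(x$relative_residual_norm), "\n")
  invisible(x)
}

#' Label SNP-gene effects as direct or indirect
#'
#' Compares the supports of the direct-perturbation matrix Theta and
#' the total-effect matrix B: a pair with a nonzero B entry is
#' `"direct"` when its Theta entry is also nonzero (a direct
#' perturbation plus its propagation) and `"indirect"` when the SNP
#' only reaches the gene through the network.
#'
#' @param model fitted `scggm` object.
#' @param zero_tol support threshold on absolute values.
#' @return Tibble with columns `snp`, `gene`, `theta`, `b`, `type`.
#' @export
effect_types <- function(model, zero_tol = 1e-8) {
  B <- indirect_effects(model)$B
  nz <- which(abs(B) > zero_tol, arr.ind = TRUE)
  snp_ids <- rownames(model$Theta) %||% as.character(seq_len(nrow(model$Theta)))
  gene_ids <- colnames(model$Theta) %||% as.character(seq_len(ncol(model$Theta)))
  direct <- abs(model$Theta[nz]) > zero_tol
  tibble::tibble(
    snp = snp_ids[nz[, 1L]],
    gene = gene_ids[nz[, 2L]],
    theta = model$Theta[nz],
    b = B[nz],
    type = ifelse(direct, "direct", "indirect")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
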