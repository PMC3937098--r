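#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted sparse CGGM
#'
#' One row per nonzero parameter: network edges (strict upper
#' triangle of Lambda) and direct SNP perturbations (entries of
#' Theta).
#'
#' @param x fitted `scggm` object.
#' @param zero_tol support threshold on absolute values.
#' @param ... unused.
#' @return Tibble with columns `term_type` (`"edge"`/`"perturbation"`),
#'   `from`, `to`, `weight`.
#' @method tidy scggm
#' @export
tidy.scggm <- function(x, zero_tol = 1e-8, ...) {
  gene_ids <- colnames(x$Theta) %||% as.character(seq_len(ncol(x$Theta)))
  snp_ids <- rownames(x$Theta) %||% as.character(seq_len(nrow(x$Theta)))
  ut <- upper.tri(x$Lambda)
  enz <- which(ut & abs(x$Lambda) > zero_tol, arr.ind = TRUE)
  tnz <- which(abs(x$Theta) > zero_tol, arr.ind = TRUE)
  rbind(
    tibble::tibble(term_type = "edge",
                   from = gene_ids[enz[, 1L]], to = gene_ids[enz[, 2L]],
                   weight = x$Lambda[enz]),
    tibble::tibble(term_type = "perturbation",
                   from = snp_ids[tnz[, 1L]], to = gene_ids[tnz[, 2L]],
                   weight = x$Theta[tnz])
  )
}

#' One-row summary of a fitted sparse CGGM
#'
#' @param x fitted `scggm` object.
#' @param zero_tol support threshold.
#' @param ... unused.
#' @return Tibble with gene/SNP counts, penalties, nonzero counts, and
#'   optimizer diagnostics.
#' @method glance scggm
#' @export
glance.scggm <- function(x, zero_tol = 1e-8, ...) {
  tibble::tibble(
    p = ncol(x$Theta), q = nrow(x$Theta),
    lambda_net = x$lambda_net, lambda_perturb = x$lambda_perturb,
    n_edges = sum(abs(x$Lambda[upper.tri(x$Lambda)]) > zero_tol),
    n_perturbations = sum(abs(x$Theta) > zero_tol),
    objective = x$fit_info$objective %||% NA_real_,
    iterations = x$fit_info$iterations %||% NA_integer_,
    converged = x$fit_info$converged %||% NA
  )
}

#' @describeIn scggm_cv tidy method: the cross-validation error table.
#' @param x `scggm_cv` object.
#' @param ... unused.
#' @method tidy scggm_cv
#' @export
tidy.scggm_cv <- function(x, ...) x$table

#' @describeIn scggm_cv glance method: selected penalties and their error.
#' @method glance scggm_cv
#' @export
glance.scggm_cv <- function(x, ...) {
  i <- which(x$table$lambda_net == x$best$lambda_net &
               x$table$lambda_perturb == x$best$lambda_perturb)[1L]
  tibble::tibble(lambda_net = x$best$lambda_net,
                 lambda_perturb = x$best$lambda_perturb,
                 mean_error = x$table$mean_error[i],
                 sd_error = x$table$sd_error[i], folds = x$k)
}

#' @describeIn precision_recall tidy method: the PR points.
#' @param x `scggm_pr` object.
#' @param ... unused.
#' @method tidy scggm_pr
#' @export
tidy.scggm_pr <- function(x, ...) x$points

#' @describeIn precision_recall glance method: AUPRC and baseline.
#' @method glance scggm_pr
#' @export
glance.scggm_pr <- function(x, ...) {
  tibble::tibble(auprc = x$auprc, prevalence = x$prevalence,
                 n_true = x$n_true, n_candidates = x$n_candidates)
}
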