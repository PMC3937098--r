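# Synthetic eQTL data with the generative structure the model assumes:
# gene networks built as graph Laplacians (module-structured or
# scale-free), sparse direct-perturbation matrices, LD-structured
# genotypes, and conditional Gaussian expression sampling.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Laplacian of a weighted undirected graph plus diagonal jitter:
# off-diagonals are negated edge weights, the diagonal is the incident
# weight sum plus diag_jitter, which is also the smallest eigenvalue
# direction (Laplacian row sums are zero), guaranteeing PD.
.laplacian_precision <- function(W, diag_jitter) {
  L <- -W
  diag(L) <- rowSums(W)
  diag(L) <- diag(L) + diag_jitter
  (L + t(L)) / 2
}

#' Module-structured gene-network precision matrix
#'
#' Partitions `p` genes into `n_modules` modules of near-equal size,
#' connects within-module pairs with probability `p_within` and
#' between-module pairs with probability `p_between`, draws edge
#' weights uniformly from `weight_range`, and returns the graph
#' Laplacian of the weight matrix with `diag_jitter` added to the
#' diagonal, which makes it positive definite.
#'
#' @param p number of genes.
#' @param n_modules number of modules.
#' @param p_within,p_between edge probabilities within/between modules.
#' @param weight_range length-2 numeric, uniform edge-weight range.
#' @param diag_jitter positive value added to the Laplacian diagonal.
#' @param seed optional integer seed (generators are pure functions of
#'   their arguments plus the seed).
#' @return p x p positive-definite matrix with attribute `modules`, the
#'   module assignment of each gene.
#' @export
sim_module_network <- function(p, n_modules = 3, p_within = 0.2,
                               p_between = 0.01,
                               weight_range = c(0.4, 0.8),
                               diag_jitter = 0.1, seed = NULL) {
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_between > p_within)
    stop("p_between must not exceed p_within")
  if (diag_jitter <= 0) stop("diag_jitter must be positive")
  if (weight_range[1] >= weight_range[2])
    stop("weight_range must be an increasing pair")
  .with_seed(seed, {
    modules <- sort(rep_len(seq_len(n_modules), p))
    modules <- modules[sample.int(p)]
    W <- matrix(0, p, p)
    idx <- which(upper.tri(W), arr.ind = TRUE)
    same <- modules[idx[, 1L]] == modules[idx[, 2L]]
    prob <- ifelse(same, p_within, p_between)
    on <- stats::runif(nrow(idx)) < prob
    w <- stats::runif(sum(on), weight_range[1], weight_range[2])
    W[idx[on, , drop = FALSE]] <- w
    W <- W + t(W)
    out <- .laplacian_precision(W, diag_jitter)
    attr(out, "modules") <- modules
    out
  })
}

#' Scale-free gene-network precision matrix
#'
#' Draws a node-degree sequence from a discrete power law
#' P(k) proportional to k^(-degree_exponent), repairs it to the nearest
#' graphical sequence (decrementing the largest degrees until the
#' Erdős–Gallai condition holds, checked with igraph), realizes a
#' simple graph with that degree sequence, assigns uniform edge
#' weights, and returns the jittered graph Laplacian as in
#' [sim_module_network()].
#'
#' @param p number of genes.
#' @param degree_exponent power-law exponent (> 1).
#' @param max_degree largest degree allowed in the draw (default p - 1).
#' @param weight_range,diag_jitter,seed as in [sim_module_network()].
#' @return p x p positive-definite matrix with attribute `degrees`, the
#'   realized degree sequence.
#' @export
sim_scalefree_network <- function(p, degree_exponent = 2.5,
                                  max_degree = NULL,
                                  weight_range = c(0.4, 0.8),
                                  diag_jitter = 0.1, seed = NULL) {
  if (degree_exponent <= 1) stop("degree_exponent must exceed 1")
  if (is.null(max_degree)) max_degree <- p - 1L
  .with_seed(seed, {
    ks <- seq_len(max_degree)
    pk <- ks^(-degree_exponent); pk <- pk / sum(pk)
    deg <- sample(ks, p, replace = TRUE, prob = pk)
    # parity fix, then decrement largest degrees until graphical
    if (sum(deg) %% 2L == 1L) {
      i <- which.max(deg); deg[i] <- deg[i] - 1L
    }
    guard <- 0L
    while (!igraph::is_graphical(deg)) {
      i <- which.max(deg)
      deg[i] <- deg[i] - 2L
      if (deg[i] < 0L) deg[i] <- 0L
      guard <- guard + 1L
      if (guard > 10L * p) stop("could not repair degree sequence")
    }
    # Havel-Hakimi realization (simple graph, exact degrees), then
    # degree-preserving rewiring to randomize the topology
    g <- igraph::realize_degseq(deg)
    if (igraph::ecount(g) > 1L)
      g <- igraph::rewire(g, igraph::keeping_degseq(
        niter = 10L * igraph::ecount(g)))
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    m <- sum(A[upper.tri(A)])
    W <- matrix(0, p, p)
    W[upper.tri(W)][A[upper.tri(A)] > 0] <-
      stats::runif(m, weight_range[1], weight_range[2])
    W <- W + t(W)
    out <- .laplacian_precision(W, diag_jitter)
    attr(out, "degrees") <- rowSums(A > 0)
    out
  })
}

#' Sparse direct-perturbation matrix
#'
#' Generates the q x p matrix of direct SNP-to-gene effects under one
#' of three sparsity designs:
#' \describe{
#'   \item{per_module_single_gene}{one randomly chosen gene per module
#'     receives perturbations; each SNP hits it with probability
#'     `perturb_prob` (requires `modules`).}
#'   \item{uniform}{every SNP-gene pair is a direct effect with
#'     probability `perturb_prob`.}
#'   \item{hub_extra}{the uniform design plus one extra randomly chosen
#'     eQTL SNP for every hub gene with more than `hub_threshold`
#'     network neighbors (requires `degrees`).}
#' }
#' Nonzero effect sizes are drawn uniformly from `effect_range` with
#' random signs.
#'
#' @param p,q gene and SNP counts.
#' @param pattern sparsity design, see Details.
#' @param perturb_prob per-entry (or per-SNP) perturbation probability.
#' @param effect_range length-2 positive range of absolute effects.
#' @param modules integer module assignment (per_module_single_gene).
#' @param degrees integer network degrees per gene (hub_extra).
#' @param hub_threshold neighbor count above which a gene is a hub.
#' @param seed optional integer seed.
#' @return q x p matrix.
#' @export
sim_direct_perturbations <- function(p, q,
    pattern = c("per_module_single_gene", "uniform", "hub_extra"),
    perturb_prob = 0.05, effect_range = c(0.6, 1.0), modules = NULL,
    degrees = NULL, hub_threshold = 20, seed = NULL) {
  pattern <- match.arg(pattern)
  if (perturb_prob < 0 || perturb_prob > 1)
    stop("perturb_prob must lie in [0, 1]")
  if (pattern == "per_module_single_gene" && is.null(modules))
    stop("per_module_single_gene pattern needs a module partition")
  if (pattern == "hub_extra" && is.null(degrees))
    stop("hub_extra pattern needs network degrees")
  .with_seed(seed, {
    Theta <- matrix(0, q, p)
    draw <- function(k) {
      stats::runif(k, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), k, replace = TRUE)
    }
    if (pattern == "per_module_single_gene") {
      for (m in unique(modules)) {
        gene <- resample(which(modules == m), 1L)
        hit <- stats::runif(q) < perturb_prob
        Theta[hit, gene] <- draw(sum(hit))
      }
    } else {
      hit <- matrix(stats::runif(q * p) < perturb_prob, q, p)
      Theta[hit] <- draw(sum(hit))
      if (pattern == "hub_extra") {
        for (gene in which(degrees > hub_threshold)) {
          snp <- sample.int(q, 1L)
          Theta[snp, gene] <- draw(1L)
        }
      }
    }
    Theta
  })
}

resample <- function(x, k) x[sample.int(length(x), k)]

#' Simulate LD-structured genotypes
#'
#' Draws two haplotypes per sample from a first-order Markov chain
#' along the SNPs — each allele copies its left neighbor with
#' probability `ld_decay`, otherwise it is a fresh Bernoulli draw at
#' the site's allele frequency — and sums them to allele counts in
#' \{0, 1, 2\}.  Per-site allele frequencies are uniform in
#' `[maf_lo, maf_hi]`.  Columns that come out constant are resampled.
#' A stand-in for real reference-panel genotypes: it emulates minor
#' allele frequency filtering and local LD, nothing more.
#'
#' @param n,q sample and SNP counts.
#' @param maf_lo,maf_hi allele-frequency range, 0 < maf_lo <= maf_hi <= 0.5.
#' @param ld_decay neighbor-copy probability in [0, 1).
#' @param seed optional integer seed.
#' @return n x q integer-valued matrix with sample/SNP dimnames.
#' @export
sim_genotypes <- function(n, q, maf_lo = 0.1, maf_hi = 0.5,
                          ld_decay = 0.5, seed = NULL) {
  if (maf_lo <= 0 || maf_lo > maf_hi || maf_hi > 0.5)
    stop("need 0 < maf_lo <= maf_hi <= 0.5")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  .with_seed(seed, {
    f <- stats::runif(q, maf_lo, maf_hi)
    hap <- function() {
      H <- matrix(0L, n, q)
      H[, 1L] <- as.integer(stats::runif(n) < f[1L])
      for (j in seq_len(q)[-1L]) {
        copy <- stats::runif(n) < ld_decay
        fresh <- as.integer(stats::runif(n) < f[j])
        H[, j] <- ifelse(copy, H[, j - 1L], fresh)
      }
      H
    }
    X <- hap() + hap()
    storage.mode(X) <- "double"
    # resample any constant column at its own frequency
    for (j in which(apply(X, 2L, function(v) length(unique(v)) == 1L))) {
      repeat {
        v <- as.integer(stats::runif(n) < f[j]) +
          as.integer(stats::runif(n) < f[j])
        if (length(unique(v)) > 1L) break
      }
      X[, j] <- v
    }
    dimnames(X) <- list(sprintf("sample%03d", seq_len(n)),
                        sprintf("snp%04d", seq_len(q)))
    X
  })
}

#' Bundle true simulation parameters
#'
#' @param Lambda true precision matrix (positive definite).
#' @param Theta true direct-perturbation matrix.
#' @param modules optional module assignment.
#' @param params list of generator parameters (including seeds).
#' @return Object of class `scggm_truth` with `Lambda`, `Theta`,
#'   `B` (= -Theta Lambda^{-1}), `modules`, `params`.
#' @export
scggm_truth <- function(Lambda, Theta, modules = NULL, params = list()) {
  model <- scggm_model(Lambda, Theta)
  structure(list(Lambda = model$Lambda, Theta = model$Theta,
                 B = conditional_moments(model)$B,
                 modules = modules, params = params),
            class = "scggm_truth")
}

#' Sample expression traits from a CGGM
#'
#' Each sample's expression vector is drawn from the conditional
#' Gaussian N(B' x_i, Lambda^{-1}) implied by the true model, using the
#' Cholesky factor of Lambda.
#'
#' @param truth `scggm_truth` object.
#' @param X standardized genotype matrix (n x q).
#' @param seed optional integer seed.
#' @return n x p expression matrix with gene dimnames.
#' @export
sim_expressions <- function(truth, X, seed = NULL) {
  X <- as.matrix(X)
  p <- nrow(truth$Lambda)
  n <- nrow(X)
  R <- chol(truth$Lambda)
  .with_seed(seed, {
    mean_part <- X %*% truth$B
    Z <- matrix(stats::rnorm(n * p), n, p)
    # rows of Z %*% t(R^-1) have covariance (R'R)^-1 = Lambda^-1
    noise <- t(backsolve(R, t(Z)))
    Y <- mean_part + noise
    dimnames(Y) <- list(rownames(X), sprintf("gene%03d", seq_len(p)))
    Y
  })
}

#' Simulate a complete eQTL dataset
#'
#' End-to-end generator: network (module or scale-free), direct
#' perturbations, LD-structured genotypes, and expressions sampled
#' either from the conditional graphical model (`design = "cggm"`) or
#' from the pleiotropic linear-regression design
#' (`design = "regression"`, see [sim_regression_design()]).
#'
#' @param n,p,q sample, gene and SNP counts.
#' @param design generative model for expressions.
#' @param topology network topology.
#' @param n_modules,p_within,p_between,weight_range,diag_jitter network
#'   parameters, see [sim_module_network()].
#' @param degree_exponent scale-free exponent.
#' @param perturb_prob,effect_range perturbation parameters, see
#'   [sim_direct_perturbations()].
#' @param hub_threshold extra-eQTL hub cutoff (scale-free topology).
#' @param maf_range,ld_decay genotype parameters.
#' @param seed integer seed; all stages derive their randomness from it.
#' @return List with `X` (raw genotypes), `Y` (expressions), and
#'   `truth` (`scggm_truth`).
#' @export
sim_eqtl_dataset <- function(n = 300, p = 30, q = 60,
                             design = c("cggm", "regression"),
                             topology = c("module", "scalefree"),
                             n_modules = 3, p_within = 0.2,
                             p_between = 0.01,
                             weight_range = c(0.4, 0.8),
                             diag_jitter = 0.1, degree_exponent = 2.5,
                             perturb_prob = 0.05,
                             effect_range = c(0.6, 1.0),
                             hub_threshold = 20,
                             maf_range = c(0.1, 0.5), ld_decay = 0.5,
                             seed = NULL) {
  design <- match.arg(design)
  topology <- match.arg(topology)
  .with_seed(seed, {
    if (topology == "module") {
      Lambda <- sim_module_network(p, n_modules, p_within, p_between,
                                   weight_range, diag_jitter)
      modules <- attr(Lambda, "modules")
      degrees <- NULL
    } else {
      Lambda <- sim_scalefree_network(p, degree_exponent,
                                      weight_range = weight_range,
                                      diag_jitter = diag_jitter)
      modules <- NULL
      degrees <- attr(Lambda, "degrees")
    }
    X <- sim_genotypes(n, q, maf_range[1], maf_range[2], ld_decay)
    Xs <- standardize_genotypes(X)
    params <- list(n = n, p = p, q = q, design = design,
                   topology = topology, n_modules = n_modules,
                   p_within = p_within, p_between = p_between,
                   weight_range = weight_range,
                   diag_jitter = diag_jitter,
                   degree_exponent = degree_exponent,
                   perturb_prob = perturb_prob,
                   effect_range = effect_range,
                   hub_threshold = hub_threshold,
                   maf_range = maf_range, ld_decay = ld_decay,
                   seed = seed)
    if (design == "cggm") {
      pattern <- if (topology == "module") "per_module_single_gene"
        else "hub_extra"
      Theta <- sim_direct_perturbations(
        p, q, pattern = pattern, perturb_prob = perturb_prob,
        effect_range = effect_range, modules = modules,
        degrees = degrees, hub_threshold = hub_threshold)
      truth <- scggm_truth(Lambda, Theta, modules = modules,
                           params = params)
      Y <- sim_expressions(truth, Xs)
    } else {
      reg <- sim_regression_design(Lambda, q = q, modules = modules,
                                   eqtl_prob = perturb_prob,
                                   effect_range = effect_range,
                                   X = Xs, params = params)
      truth <- reg$truth
      Y <- reg$Y
    }
    rownames(Y) <- rownames(X)
    list(X = X, Y = Y, truth = truth)
  })
}

#' Pleiotropic linear-regression simulation design
#'
#' Expressions follow the standard multivariate regression model
#' Y = X B* + E with noise rows E_i ~ N(0, Lambda^{-1}), where the
#' regression coefficients B* have pleiotropic structure: for each gene
#' module, each SNP is an eQTL of all genes in the module with
#' probability `eqtl_prob`, with uniformly drawn association strengths
#' of random sign.
#'
#' @param Lambda true noise precision matrix (with `modules` attribute
#'   or supplied via `modules`).
#' @param q SNP count.
#' @param modules integer module assignment per gene.
#' @param eqtl_prob per-(SNP, module) eQTL probability.
#' @param effect_range absolute association-strength range.
#' @param X standardized genotype matrix (n x q); if NULL, only the
#'   truth is returned.
#' @param params parameter record stored in the truth object.
#' @param seed optional integer seed.
#' @return List with `truth` (`scggm_truth` whose `B` is the regression
#'   coefficient matrix B*) and `Y` (n x p, when `X` is given).  The
#'   truth's `Theta` is the implied graphical-model parameterization
#'   -B* Lambda.
#' @export
sim_regression_design <- function(Lambda, q, modules = NULL,
                                  eqtl_prob = 0.05,
                                  effect_range = c(0.6, 1.0), X = NULL,
                                  params = list(), seed = NULL) {
  if (is.null(modules)) modules <- attr(Lambda, "modules")
  if (is.null(modules)) stop("pleiotropic design needs a module partition")
  p <- nrow(Lambda)
  .with_seed(seed, {
    Bstar <- matrix(0, q, p)
    for (m in unique(modules)) {
      genes <- which(modules == m)
      snps <- which(stats::runif(q) < eqtl_prob)
      for (s in snps) {
        k <- length(genes)
        Bstar[s, genes] <- stats::runif(k, effect_range[1],
                                        effect_range[2]) *
          sample(c(-1, 1), k, replace = TRUE)
      }
    }
    # equivalent graphical-model parameterization: B = -Theta Lambda^-1
    Theta <- -Bstar %*% Lambda
    truth <- scggm_truth(Lambda, Theta, modules = modules,
                         params = params)
    Y <- NULL
    if (!is.null(X)) {
      n <- nrow(X)
      R <- chol(Lambda)
      Z <- matrix(stats::rnorm(n * p), n, p)
      Y <- X %*% Bstar + t(backsolve(R, t(Z)))
      colnames(Y) <- sprintf("gene%03d", seq_len(p))
    }
    list(truth = truth, Y = Y)
  })
}
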