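# Plain-text exchange formats: TSV matrices with sample-ID first
# column, JSON model archives with sparse triplets, edge lists.

#' Read a genotype or expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds column (SNP or
#' gene) identifiers and whose first column holds sample identifiers.
#' Genotype values are validated to lie in \{0, 1, 2\}; duplicate row
#' or column identifiers and non-numeric cells are errors.
#'
#' @param path file path.
#' @param kind `"genotype"` or `"expression"`.
#' @return Numeric matrix with sample row names and ID column names.
#' @export
read_matrix_tsv <- function(path, kind = c("genotype", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected sample-ID column plus data columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", path)
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate column IDs in ", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at data row ", bad[1L], ", column ",
         names(df)[-1L][bad[2L]], " in ", path)
  }
  if (kind == "genotype" && !all(num %in% c(0, 1, 2))) {
    bad <- which(!(num %in% c(0, 1, 2)), arr.ind = FALSE)[1L]
    rc <- arrayInd(bad, dim(num))
    stop("genotype value not in {0,1,2} at data row ", rc[1L],
         ", column ", names(df)[-1L][rc[2L]], " in ", path)
  }
  dimnames(num) <- list(ids, names(df)[-1L])
  num
}

#' Write a matrix as TSV with full decimal precision
#'
#' @param M numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  M <- as.matrix(M)
  if (is.null(rownames(M)))
    rownames(M) <- sprintf("row%03d", seq_len(nrow(M)))
  if (is.null(colnames(M)))
    colnames(M) <- sprintf("col%03d", seq_len(ncol(M)))
  chars <- matrix(sprintf("%.17g", M), nrow(M), ncol(M),
                  dimnames = dimnames(M))
  df <- data.frame(id = rownames(M), chars, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.sparse_triplets <- function(M, zero_tol = 0) {
  nz <- which(abs(M) > zero_tol, arr.ind = TRUE)
  list(i = as.integer(nz[, 1L]), j = as.integer(nz[, 2L]),
       x = sprintf("%.17g", M[nz]))
}

.from_triplets <- function(tr, nrow, ncol) {
  M <- matrix(0, nrow, ncol)
  if (length(tr$i) > 0L)
    M[cbind(tr$i, tr$j)] <- as.numeric(tr$x)
  M
}

#' Save a fitted model as a JSON archive
#'
#' Stores Lambda and Theta as full-precision sparse triplets together
#' with identifiers, penalties, fit diagnostics, and a format version.
#' Loading reproduces every matrix entry exactly.
#'
#' @param model `scggm` object.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "scggm"))
  p <- nrow(model$Lambda); q <- nrow(model$Theta)
  obj <- list(
    format = "scggm-model", version = 1L,
    p = p, q = q,
    gene_ids = colnames(model$Theta) %||% sprintf("gene%03d", seq_len(p)),
    snp_ids = rownames(model$Theta) %||% sprintf("snp%04d", seq_len(q)),
    lambda_net = model$lambda_net,
    lambda_perturb = model$lambda_perturb,
    # numeric payloads as %.17g strings: exact double round trip
    Lambda = .sparse_triplets(model$Lambda),
    Theta = .sparse_triplets(model$Theta),
    fit_info = model$fit_info[c("iterations", "objective", "converged")]
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a model archive written by [write_model()]
#'
#' @param path archive path.
#' @return `scggm` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "scggm-model"))
    stop("not a model archive: ", path)
  if (obj$version > 1L) stop("unsupported archive version ", obj$version)
  Lambda <- .from_triplets(obj$Lambda, obj$p, obj$p)
  Theta <- .from_triplets(obj$Theta, obj$q, obj$p)
  dimnames(Lambda) <- list(obj$gene_ids, obj$gene_ids)
  dimnames(Theta) <- list(obj$snp_ids, obj$gene_ids)
  scggm_model(Lambda, Theta, obj$lambda_net, obj$lambda_perturb,
              fit_info = obj$fit_info)
}

#' Write the gene network as an edge list
#'
#' One line per strict-upper-triangle nonzero of Lambda, ordered by
#' gene index pair: `gene_i<TAB>gene_j<TAB>weight` (tsv) or
#' `gene_i<TAB>pp<TAB>gene_j` (sif, for network viewers).
#'
#' @param Lambda symmetric precision matrix with gene dimnames.
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @param zero_tol support threshold.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(Lambda, path,
                                   format = c("tsv", "sif"),
                                   zero_tol = 1e-8) {
  format <- match.arg(format)
  Lambda <- as.matrix(Lambda)
  if (max(abs(Lambda - t(Lambda))) > 1e-8)
    stop("Lambda must be symmetric")
  ids <- rownames(Lambda) %||% as.character(seq_len(nrow(Lambda)))
  ut <- upper.tri(Lambda)
  nz <- which(ut & abs(Lambda) > zero_tol, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  lines <- if (nrow(nz) == 0L) character(0) else if (format == "tsv") {
    paste(ids[nz[, 1L]], ids[nz[, 2L]],
          format(Lambda[nz], digits = 17, trim = TRUE), sep = "\t")
  } else {
    paste(ids[nz[, 1L]], "pp", ids[nz[, 2L]], sep = "\t")
  }
  header <- if (format == "tsv") "gene_i\tgene_j\tweight" else NULL
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run a full simulate-fit-infer-analyze pipeline
#'
#' Orchestrates one reproducible run: simulate (or load) data, select
#' penalties by cross-validation, fit, run inference, write all
#' artifacts, and record a JSON report.  Identical configuration and
#' seed yield byte-identical model archives.
#'
#' @param config list (or path to a JSON file) with elements:
#'   `out_dir` (required); `seed` (integer, default 1); `simulate`
#'   (list of [sim_eqtl_dataset()] arguments) or `genotype_file` +
#'   `expression_file`; `grid` (data frame or list, default a 3x3
#'   log-spaced grid); `folds` (default 5); `control` (list of
#'   [scggm_control()] arguments); `top_k_hotspots` (default 20);
#'   `min_hub_neighbors` (default 10).
#' @return Run report (list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (is.null(config$out_dir)) stop("config needs out_dir")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, stages = list(),
                 config_hash = .config_hash(config))
  out <- function(...) file.path(config$out_dir, ...)

  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) e)
    ok <- !inherits(res, "error")
    report$stages[[name]] <<- list(
      ok = ok, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      error = if (ok) NULL else conditionMessage(res))
    if (!ok) stop("stage '", name, "' failed: ", conditionMessage(res))
    res
  }

  data <- stage("data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- seed
      d <- do.call(sim_eqtl_dataset, args)
      write_matrix_tsv(d$X, out("genotypes.tsv"))
      write_matrix_tsv(d$Y, out("expressions.tsv"))
      write_model(scggm_model(d$truth$Lambda, d$truth$Theta),
                  out("truth.json"))
      d
    } else {
      if (is.null(config$genotype_file) || is.null(config$expression_file))
        stop("config needs either simulate or genotype_file + expression_file")
      if (!file.exists(config$genotype_file))
        stop("missing file: ", config$genotype_file)
      if (!file.exists(config$expression_file))
        stop("missing file: ", config$expression_file)
      X <- read_matrix_tsv(config$genotype_file, "genotype")
      Y <- read_matrix_tsv(config$expression_file, "expression")
      al <- align_samples(X, Y)
      list(X = al$X, Y = al$Y, truth = NULL)
    }
  })

  control <- do.call(scggm_control, as.list(config$control %||% list()))
  grid <- if (is.null(config$grid)) scggm_grid(3, 3) else
    as.data.frame(config$grid)

  cv <- stage("cv", scggm_cv(data$X, data$Y, grid = grid,
                             k = config$folds %||% 5, control = control,
                             seed = seed))
  fit <- cv$fit
  report$selected <- cv$best
  report$fit <- fit$fit_info[c("iterations", "objective", "converged")]

  stage("model", {
    write_model(fit, out("model.json"))
    write_network_edgelist(fit$Lambda, out("network.tsv"))
  })

  stage("inference", {
    inf <- indirect_effects(fit)
    write_matrix_tsv(inf$B, out("indirect_effects.tsv"))
    write_matrix_tsv(inf$Sigma, out("conditional_covariance.tsv"))
  })

  stage("analysis", {
    hubs <- hub_modules(fit$Lambda, config$min_hub_neighbors %||% 10)
    hot <- eqtl_hotspots(fit$Theta, config$top_k_hotspots %||% 20)
    utils::write.table(
      data.frame(hub = hubs$hub, n_neighbors = hubs$n_neighbors,
                 neighbors = vapply(hubs$neighbors, paste,
                                    character(1), collapse = ",")),
      out("hubs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(snp = hot$snp, n_genes = hot$n_genes,
                 genes = vapply(hot$genes, paste, character(1),
                                collapse = ",")),
      out("hotspots.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(data$truth)) {
    stage("evaluate", {
      lam_truth <- abs(data$truth$Lambda) > 1e-8
      diag(lam_truth) <- FALSE
      ev <- list(lambda_auprc = NA_real_, theta_auprc = NA_real_)
      if (any(lam_truth)) {
        pr_l <- precision_recall(fit$Lambda, lam_truth, symmetric = TRUE)
        ev$lambda_auprc <- pr_l$auprc
        utils::write.table(pr_l$points, out("pr_lambda.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      if (any(abs(data$truth$Theta) > 1e-8)) {
        pr_t <- precision_recall(fit$Theta, abs(data$truth$Theta) > 1e-8)
        ev$theta_auprc <- pr_t$auprc
        utils::write.table(pr_t$points, out("pr_theta.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      report$evaluation <- ev
    })
  }

  writeLines(jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE,
                              null = "null", pretty = TRUE),
             out("report.json"))
  invisible(report)
}

# order-independent hash of the configuration (timestamps excluded by
# construction: only config content enters)
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], digits = NA,
                        auto_unbox = TRUE, null = "null")
  # small stable polynomial hash over the serialized config
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 1e9
  sprintf("%09.0f", h)
}
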