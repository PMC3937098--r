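# Downstream analyses of a fitted gene network: degree structure,
# hubs, eQTL hotspots, cis/trans labeling, gene-set enrichment.

#' Weighted node degrees of the gene network
#'
#' Sum of absolute off-diagonal precision entries incident to each
#' gene; zero for isolated genes.
#'
#' @param Lambda symmetric precision matrix.
#' @return Named numeric vector of length p.
#' @export
weighted_degree <- function(Lambda) {
  Lambda <- as.matrix(Lambda)
  if (max(abs(Lambda - t(Lambda))) > 1e-8)
    stop("Lambda must be symmetric")
  A <- abs(Lambda); diag(A) <- 0
  rowSums(A)
}

#' Hub genes and their neighborhoods
#'
#' A hub is a gene with more than `min_neighbors` network neighbors
#' (genes with an off-diagonal precision entry above `zero_tol` in
#' absolute value); each hub with its immediate neighbors forms a
#' hub-gene module.
#'
#' @param Lambda symmetric precision matrix with gene dimnames.
#' @param min_neighbors minimum neighbor count to qualify as a hub.
#' @param zero_tol support threshold on absolute entries.
#' @return Tibble with columns `hub`, `n_neighbors`, `neighbors`
#'   (list-column of gene IDs), sorted by neighbor count descending,
#'   ties by gene ID.
#' @export
hub_modules <- function(Lambda, min_neighbors = 10, zero_tol = 1e-8) {
  if (min_neighbors < 1) stop("min_neighbors must be at least 1")
  Lambda <- as.matrix(Lambda)
  ids <- rownames(Lambda) %||% as.character(seq_len(nrow(Lambda)))
  A <- abs(Lambda) > zero_tol; diag(A) <- FALSE
  counts <- rowSums(A)
  hubs <- which(counts >= min_neighbors)
  hubs <- hubs[order(-counts[hubs], ids[hubs])]
  tibble::tibble(
    hub = ids[hubs],
    n_neighbors = as.integer(counts[hubs]),
    neighbors = lapply(hubs, function(i) ids[which(A[i, ])])
  )
}

#' eQTL hotspots: SNPs that directly perturb many genes
#'
#' Ranks SNPs by the number of genes they directly perturb (nonzero
#' entries of their Theta row) and returns the top `top_k` with their
#' regulated-gene modules.  SNPs perturbing no gene are excluded; ties
#' break by SNP ID.
#'
#' @param Theta q x p direct-perturbation matrix with SNP row names.
#' @param top_k number of hotspots to return.
#' @param zero_tol support threshold.
#' @return Tibble with columns `snp`, `n_genes`, `genes` (list-column).
#' @export
eqtl_hotspots <- function(Theta, top_k = 20, zero_tol = 1e-8) {
  if (top_k < 1) stop("top_k must be at least 1")
  Theta <- as.matrix(Theta)
  snp_ids <- rownames(Theta) %||% as.character(seq_len(nrow(Theta)))
  gene_ids <- colnames(Theta) %||% as.character(seq_len(ncol(Theta)))
  A <- abs(Theta) > zero_tol
  counts <- rowSums(A)
  keep <- which(counts > 0L)
  keep <- keep[order(-counts[keep], snp_ids[keep])]
  keep <- utils::head(keep, top_k)
  tibble::tibble(
    snp = snp_ids[keep],
    n_genes = as.integer(counts[keep]),
    genes = lapply(keep, function(i) gene_ids[which(A[i, ])])
  )
}

#' Power-law fit of the cumulative degree distribution
#'
#' Ordinary least squares of log10(fraction of nodes with degree >= d)
#' on log10(d), evaluated at the observed distinct positive degrees.
#' A scale-free network gives an approximately linear relation with
#' negative slope.
#'
#' @param degrees nonnegative numeric degrees (weighted or binary).
#' @return List with `slope`, `intercept`, `r_squared`, and the fitted
#'   points as tibble `points` (`degree`, `cumulative_fraction`).
#' @export
powerlaw_fit <- function(degrees) {
  d <- degrees[degrees > 0]
  if (length(d) == 0L) stop("all degrees are zero")
  xs <- sort(unique(d))
  if (length(xs) < 3L)
    stop("need at least 3 distinct positive degrees for a power-law fit")
  frac <- vapply(xs, function(v) mean(d >= v), numeric(1))
  fit <- stats::lm(log10(frac) ~ log10(xs))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       points = tibble::tibble(degree = xs, cumulative_fraction = frac))
}

#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis when the gene's interval overlaps the SNP's linkage
#' window `[start - window_bp, end + window_bp]` on the same
#' chromosome (1-based inclusive coordinates, touching counts as
#' overlap); otherwise trans.  Pairs whose SNP or gene has no
#' coordinates are labeled `unknown` with a message.
#'
#' @param pairs data frame with columns `snp` and `gene` (IDs).
#' @param snp_intervals,gene_intervals data frames with columns
#'   `chrom`, `start`, `end`, `id`.
#' @param window_bp half-width added to each SNP interval.
#' @return Input tibble with an added `type` column
#'   (`"cis"`/`"trans"`/`"unknown"`).
#' @export
cis_trans_classify <- function(pairs, snp_intervals, gene_intervals,
                               window_bp = 20000) {
  if (window_bp < 0) stop("window_bp must be nonnegative")
  pairs <- tibble::as_tibble(pairs)
  .check_intervals(snp_intervals); .check_intervals(gene_intervals)
  snp_gr <- .as_granges(snp_intervals, flank = window_bp)
  gene_gr <- .as_granges(gene_intervals)
  si <- match(pairs$snp, snp_intervals$id)
  gi <- match(pairs$gene, gene_intervals$id)
  known <- !is.na(si) & !is.na(gi)
  if (any(!known))
    message(sum(!known), " pair(s) lack coordinates; labeled unknown")
  type <- rep("unknown", nrow(pairs))
  if (any(known)) {
    same_chr <- as.character(GenomicRanges::seqnames(snp_gr))[si[known]] ==
      as.character(GenomicRanges::seqnames(gene_gr))[gi[known]]
    ov <- IRanges::poverlaps(IRanges::ranges(snp_gr)[si[known]],
                             IRanges::ranges(gene_gr)[gi[known]])
    type[known] <- ifelse(same_chr & as.logical(ov), "cis", "trans")
  }
  pairs$type <- type
  pairs
}

.check_intervals <- function(df) {
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(df)))
    stop("interval table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("interval with start > end")
  invisible(TRUE)
}

.as_granges <- function(df, flank = 0) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, df$start - flank),
                              end = df$end + flank))
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided over-representation p-value for the overlap between a
#' gene module and an annotation category within a stated universe:
#' the upper hypergeometric tail
#' \deqn{p = \sum_{k \ge o} C(K, k)\, C(N-K, n-k) / C(N, n)} with
#' N = |universe|, K = |category|, n = |module|, o = observed overlap
#' (equivalently a one-sided Fisher's exact test), computed in log
#' space.  The universe must be supplied explicitly: it materially
#' changes the p-value and no default is defensible.
#'
#' @param module_genes,category_genes character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all analyzed genes.
#' @return Object of class `scggm_enrichment`: list with
#'   `module_size`, `category_size`, `overlap`, `universe_size`,
#'   `p_value`.
#' @export
enrichment_test <- function(module_genes, category_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  module_genes <- unique(module_genes)
  category_genes <- unique(category_genes)
  if (!all(module_genes %in% universe))
    stop("module genes outside the universe")
  if (!all(category_genes %in% universe))
    stop("category genes outside the universe")
  N <- length(universe); K <- length(category_genes)
  n <- length(module_genes)
  o <- length(intersect(module_genes, category_genes))
  # upper tail P(X >= o) for X ~ Hypergeometric(N, K, n)
  p <- if (o == 0L) 1 else
    stats::phyper(o - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(module_size = n, category_size = K, overlap = o,
                 universe_size = N, p_value = p),
            class = "scggm_enrichment")
}

#' @export
print.scggm_enrichment <- function(x, ...) {
  cat("Over-representation: overlap", x$overlap, "of module",
      x$module_size, "vs category", x$category_size, "in universe",
      x$universe_size, "\n  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Enrichment of several modules against several categories
#'
#' @param modules named list of gene-ID vectors.
#' @param categories named list of gene-ID vectors.
#' @param universe character vector of all analyzed genes.
#' @return Tibble with one row per module x category pair.
#' @export
enrichment_table <- function(modules, categories, universe) {
  rows <- list()
  for (m in names(modules)) for (g in names(categories)) {
    e <- enrichment_test(modules[[m]], categories[[g]], universe)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      module = m, category = g, module_size = e$module_size,
      category_size = e$category_size, overlap = e$overlap,
      p_value = e$p_value)
  }
  do.call(rbind, rows)
}
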