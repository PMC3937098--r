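test_that("weighted degrees sum absolute off-diagonal entries", {
  expect_equal(weighted_degree(diag(c(1, 2, 3))), rep(0, 3),
               ignore_attr = TRUE)

  L2 <- matrix(c(1, -0.7, -0.7, 1), 2, 2)
  expect_equal(weighted_degree(L2), c(0.7, 0.7), ignore_attr = TRUE)

  set.seed(3)
  L <- random_pd_matrix(6)
  d <- weighted_degree(L)
  manual <- numeric(6)
  for (i in 1:6) for (j in 1:6) if (i != j)
    manual[i] <- manual[i] + abs(L[i, j])
  expect_equal(d, manual, ignore_attr = TRUE)

  expect_error(weighted_degree(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("hub modules collect immediate neighbors above a cutoff", {
  # star graph: center with 5 leaves
  p <- 6
  L <- diag(p)
  for (j in 2:6) { L[1, j] <- L[j, 1] <- -0.2 }
  diag(L) <- c(1.5, rep(1, 5))
  rownames(L) <- colnames(L) <- paste0("g", 1:6)
  hubs <- hub_modules(L, min_neighbors = 3)
  expect_equal(nrow(hubs), 1L)
  expect_equal(hubs$hub, "g1")
  expect_equal(hubs$n_neighbors, 5L)
  expect_setequal(hubs$neighbors[[1]], paste0("g", 2:6))

  # empty network
  expect_equal(nrow(hub_modules(diag(4), 1)), 0L)

  # recount oracle on a random sparse network
  set.seed(7)
  A <- matrix(stats::rnorm(100) * (stats::runif(100) < 0.2), 10, 10)
  A <- (A + t(A)) / 2; diag(A) <- 0
  L <- -A; diag(L) <- rowSums(abs(A)) + 0.5
  rownames(L) <- colnames(L) <- sprintf("g%02d", 1:10)
  hubs <- hub_modules(L, min_neighbors = 1)
  for (r in seq_len(nrow(hubs))) {
    i <- match(hubs$hub[r], rownames(L))
    nb <- which(abs(L[i, ]) > 1e-8 & seq_len(10) != i)
    expect_setequal(hubs$neighbors[[r]], rownames(L)[nb])
  }
  expect_true(all(diff(hubs$n_neighbors) <= 0))
})

test_that("eQTL hotspots rank SNPs by direct target counts", {
  expect_equal(nrow(eqtl_hotspots(matrix(0, 5, 4))), 0L)

  Th <- matrix(0, 5, 6)
  Th[2, c(1, 3, 5)] <- c(0.5, -0.2, 0.9)
  rownames(Th) <- paste0("s", 1:5); colnames(Th) <- paste0("g", 1:6)
  hot <- eqtl_hotspots(Th, top_k = 20)
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$snp, "s2")
  expect_equal(hot$n_genes, 3L)
  expect_setequal(hot$genes[[1]], c("g1", "g3", "g5"))

  # counting oracle on a random sparse matrix
  set.seed(11)
  Th2 <- matrix(stats::rnorm(200) * (stats::runif(200) < 0.15), 20, 10)
  rownames(Th2) <- sprintf("s%02d", 1:20)
  colnames(Th2) <- sprintf("g%02d", 1:10)
  hot2 <- eqtl_hotspots(Th2, top_k = 5)
  counts <- rowSums(Th2 != 0)
  counts <- counts[counts > 0]
  counts <- counts[order(-counts, names(counts))]
  expect_equal(hot2$snp, names(counts)[seq_len(nrow(hot2))])
  expect_equal(hot2$n_genes, as.integer(counts[seq_len(nrow(hot2))]),
               ignore_attr = TRUE)
})

test_that("power-law fit recovers a constructed exponent exactly", {
  # degrees whose cumulative distribution is exactly c * d^-2:
  # P(D >= d) proportional to d^-2 at degrees 1, 2, 4, 8, 16
  ds <- c(1, 2, 4, 8, 16)
  # construct by tail differences so that the empirical tail is d^-2
  tail_target <- 1024 / ds^2
  n_at <- c(tail_target[-length(ds)] - tail_target[-1], tail_target[5])
  degs <- rep(ds, times = n_at)
  fit <- powerlaw_fit(degs)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # doubling degrees changes intercept only
  fit2 <- powerlaw_fit(2 * degs)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fit2$intercept, fit$intercept)))

  expect_error(powerlaw_fit(rep(0, 5)), "zero")
  expect_error(powerlaw_fit(rep(3, 10)), "distinct")
})

test_that("cis/trans labels follow windowed interval overlap", {
  snps <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(1000, 50000, 1000),
                     end = c(1000, 50000, 1000),
                     id = c("s1", "s2", "s3"))
  genes <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                      start = c(1500, 100000, 21000),
                      end = c(2000, 101000, 22000),
                      id = c("g1", "g2", "g3"))
  pairs <- data.frame(snp = c("s1", "s1", "s3", "s1", "s1"),
                      gene = c("g1", "g2", "g1", "g3", "gX"))
  suppressMessages(
    lab <- cis_trans_classify(pairs, snps, genes, window_bp = 20000))
  expect_equal(lab$type[1], "cis")     # gene inside the window
  expect_equal(lab$type[2], "trans")   # same chrom, beyond window
  expect_equal(lab$type[3], "trans")   # different chromosome
  expect_equal(lab$type[4], "cis")     # touching boundary counts
  expect_equal(lab$type[5], "unknown") # missing coordinates
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  # enumeration oracle over all C(N, n) module draws
  enum_p <- function(N, K, n, o) {
    draws <- utils::combn(N, n)
    cat_set <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% cat_set) >= o)
    mean(hits)
  }
  universe <- letters[1:10]
  e <- enrichment_test(letters[c(1, 2, 3, 5, 7)], letters[1:4],
                       universe)
  expect_equal(e$overlap, 3L)
  expect_equal(e$p_value, enum_p(10, 4, 5, 3), tolerance = 1e-12)

  # exhaustive sweep over all instances with N <= 12 (spot N values)
  for (N in c(5, 8, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in 1:N) for (n in 1:N) {
      for (o in 0:min(K, n)) {
        mod <- c(uni[seq_len(o)],
                 uni[setdiff(seq_len(N), seq_len(K))][seq_len(n - o)])
        if (length(mod) != n || anyNA(mod)) next
        e <- enrichment_test(mod, uni[seq_len(K)], uni)
        expect_equal(e$p_value, enum_p(N, K, n, e$overlap),
                     tolerance = 1e-10)
      }
    }
  }

  # zero overlap: p = 1
  e0 <- enrichment_test(letters[5:7], letters[1:3], letters[1:10])
  expect_equal(e0$p_value, 1)

  expect_error(enrichment_test(c("zz"), letters[1:3], letters[1:10]),
               "universe")
})

test_that("enrichment p-value is monotone decreasing in overlap", {
  N <- 40; K <- 12; n <- 10
  uni <- paste0("g", seq_len(N))
  ps <- vapply(0:min(K, n), function(o) {
    mod <- c(uni[seq_len(o)],
             uni[(K + 1):N][seq_len(n - o)])
    enrichment_test(mod, uni[seq_len(K)], uni)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("analyses are invariant to relabeling permutations", {
  set.seed(13)
  L <- sim_module_network(12, 2, p_within = 0.6, seed = 17)
  rownames(L) <- colnames(L) <- sprintf("g%02d", 1:12)
  perm <- sample(12)
  Lp <- L[perm, perm]
  h1 <- hub_modules(L, 1); h2 <- hub_modules(Lp, 1)
  expect_equal(h1$hub, h2$hub)
  expect_equal(lapply(h1$neighbors, sort), lapply(h2$neighbors, sort))
  expect_equal(sort(weighted_degree(L)), sort(weighted_degree(Lp)),
               ignore_attr = TRUE)
})
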