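mk_expr <- function(counts, lib = NULL, len = NULL, stages = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(n))
  lib <- lib %||% setNames(pmax(colSums(counts), 1) * 2, colnames(counts))
  len <- len %||% setNames(rep(1000, n), rownames(counts))
  stages <- stages %||% rep("A", ncol(counts))
  design <- tibble::tibble(sample = colnames(counts), stage = stages,
                           replicate = stats::ave(seq_along(stages), stages,
                                                  FUN = seq_along))
  expression_matrix(counts, lib, len, design)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("FPKM follows the unit formula exactly", {
  m <- mk_expr(matrix(c(10L, 0L), 2, 1), lib = c(s1 = 1e6),
               len = c(f1 = 1000, f2 = 800))
  fk <- fpkm(m)
  expect_equal(fk["f1", "s1"], 10)
  expect_equal(fk["f2", "s1"], 0)

  set.seed(2)
  counts <- matrix(rpois(50, 40), 10, 5)
  m2 <- mk_expr(counts)
  fk2 <- fpkm(m2)
  for (i in 1:10) for (j in 1:5) {
    expect_equal(fk2[i, j],
                 unname(counts[i, j] / (m2$lengths[i] / 1e3) /
                          (m2$lib_sizes[j] / 1e6)))
  }
})

test_that("size factors reproduce the geometric-mean analytic case", {
  c1 <- c(10L, 20L, 40L, 80L)
  m <- mk_expr(cbind(s1 = c1, s2 = 2L * c1))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  m2 <- mk_expr(cbind(s1 = c1, s2 = c1, s3 = c1))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))

  set.seed(8)
  counts <- matrix(rnbinom(600, mu = 50, size = 5) + 1L, 100, 6)
  m3 <- mk_expr(counts)
  sf3 <- size_factors(m3)
  ref <- exp(rowMeans(log(counts)))
  for (j in 1:6) expect_equal(unname(sf3[j]), median(counts[, j] / ref))

  zeros <- matrix(0L, 3, 2)
  zeros[1, 1] <- 5L
  expect_error(size_factors(mk_expr(zeros)), "all-positive")
})

test_that("the NB Wald test honors its conventions and null limit", {
  set.seed(10)
  counts <- matrix(rnbinom(100 * 6, mu = 100, size = 1e6), 100, 6)
  counts[1, ] <- 0L  # all-zero feature
  m <- mk_expr(counts, stages = rep(c("A", "B"), each = 3))
  res <- nb_wald_test(m, "A", "B")
  expect_equal(res$p[1], 1)
  expect_equal(res$log2fc[1], 0)
  # near-zero dispersion, equal means: statistics concentrate near zero
  expect_lt(median(abs(res$stat[-1])), 2)
  expect_true(all(res$p >= 0 & res$p <= 1))

  expect_error(nb_wald_test(mk_expr(matrix(0L, 2, 6),
                                    stages = rep(c("A", "B"), each = 3)),
                            "A", "B"), "all-zero")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (rep in 1:1000) {
    p <- runif(sample(1:20, 1L))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  p_sorted <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p_sorted)) >= 0))
})

test_that("DEL calls require both thresholds and union by feature", {
  res <- tibble::tibble(
    feature = c("a", "b", "c"),
    mean_a = 1, mean_b = 1,
    log2fc = c(1.1, 0.9, -1.5),
    se = 0.1, stat = 0,
    p = c(1e-4, 1e-4, 1e-4)
  )
  class(res) <- c("lnc_diffexp", class(res))
  d <- call_dels(list(ct = res))
  tab <- d$per_contrast
  expect_true(tab$is_del[tab$feature == "a"])   # padj < .05, |l2fc| > 1
  expect_false(tab$is_del[tab$feature == "b"])  # fold change 1.87 < 2
  expect_true(tab$is_del[tab$feature == "c"])

  r2 <- res; r2$feature <- c("b", "c", "d")
  d2 <- call_dels(list(c1 = res, c2 = r2))
  expect_setequal(d2$union, c("a", "c", "b", "d"))
})

test_that("planted archetypes are recovered as pure clusters", {
  set.seed(19)
  arch <- list(c(1, 1, 6), c(1, 3, 9), c(1, 1, 1),
               c(9, 3, 1), c(6, 1, 1), c(1, 6, 1))
  rows <- list(); truth <- integer()
  for (a in seq_along(arch)) {
    for (k in 1:10) {
      prof <- rep(arch[[a]], each = 3) * 100
      # flat profiles stay exactly constant: once z-scored, any noise on a
      # flat feature IS its structure, so only the sd-floor zero profile
      # makes the flat archetype a coherent cluster
      noise <- if (a == 3L) 0 else rnorm(9, sd = 0.5)
      rows[[length(rows) + 1L]] <- prof + noise
      truth <- c(truth, a)
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- sprintf("f%02d", seq_len(nrow(mat)))
  design <- tibble::tibble(sample = paste0("s", 1:9),
                           stage = rep(c("S1", "S2", "S3"), each = 3),
                           replicate = rep(1:3, 3))
  colnames(mat) <- design$sample
  cl <- cluster_profiles(mat, design, 6L)
  ari <- adjusted_rand_index(cl$assignments$cluster[match(rownames(mat),
                                                          cl$assignments$feature)],
                             truth)
  expect_equal(ari, 1)

  # order invariance
  perm <- sample(nrow(mat))
  cl2 <- cluster_profiles(mat[perm, ], design, 6L)
  j <- dplyr::inner_join(cl$assignments, cl2$assignments, by = "feature")
  expect_equal(adjusted_rand_index(j$cluster.x, j$cluster.y), 1)

  # constant feature degenerates to the all-zero profile
  mat2 <- rbind(mat, flat = rep(5, 9))
  cl3 <- cluster_profiles(mat2, design, 6L)
  expect_true(all(cl3$z["flat", ] == 0))

  expect_error(cluster_profiles(mat[1:3, ], design, 6L), "fewer features")
})

test_that("PCA scores separate stages, center, and respect duplicates", {
  set.seed(21)
  base <- matrix(rnorm(50 * 9, mean = 8), 50, 9)
  base[1:25, 1:3] <- base[1:25, 1:3] + 6  # strong stage-1 signature
  base[26:50, 7:9] <- base[26:50, 7:9] + 6
  fk <- 2^base
  rownames(fk) <- paste0("f", 1:50)
  design <- tibble::tibble(sample = paste0("s", 1:9),
                           stage = rep(c("S1", "S2", "S3"), each = 3),
                           replicate = rep(1:3, 3))
  colnames(fk) <- design$sample
  sc <- pca_scores(fk, design)
  expect_equal(mean(sc$PC1), 0, tolerance = 1e-8)
  expect_equal(mean(sc$PC2), 0, tolerance = 1e-8)
  # silhouette of stage labels on the 2 components
  xy <- as.matrix(sc[, c("PC1", "PC2")])
  d <- as.matrix(dist(xy))
  sil <- vapply(1:9, function(i) {
    own <- design$stage == design$stage[i]
    a <- mean(d[i, own & seq_len(9) != i])
    b <- min(vapply(setdiff(unique(design$stage), design$stage[i]),
                    function(s) mean(d[i, design$stage == s]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  fk2 <- cbind(fk, s10 = fk[, "s1"])
  sc2 <- pca_scores(fk2)
  expect_equal(sc2$PC1[sc2$sample == "s10"], sc2$PC1[sc2$sample == "s1"])
  expect_equal(sc2$PC2[sc2$sample == "s10"], sc2$PC2[sc2$sample == "s1"])
})

test_that("lncRNAs sit below mRNAs in FPKM on the synthetic study", {
  sim <- fx_sim()
  fk <- fx_fpkm()
  arche <- sim$archetypes
  lnc <- arche$feature[arche$group == "lnc"]
  mrna <- arche$feature[arche$group == "mRNA"]
  expect_lt(median(fk[lnc, ]), median(fk[mrna, ]))
})
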