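# Count normalization, moment-based negative-binomial Wald testing,
# differential-lncRNA calls, profile clustering and PCA.

#' Expression matrix container
#'
#' Bundles a feature x library fragment-count matrix with library sizes,
#' spliced feature lengths and the stage/replicate design.
#'
#' @param counts Integer matrix, features in rows, libraries in columns
#'   (both dimnames required).
#' @param lib_sizes Named numeric vector of total mapped fragments per
#'   library; must be >= the column sums of `counts`.
#' @param lengths Named numeric vector of spliced lengths (nt) per feature.
#' @param design Tibble with columns `sample`, `stage`, `replicate` matching
#'   the columns of `counts`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, lib_sizes, lengths, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have feature rownames and library colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  lib_sizes <- lib_sizes[colnames(counts)]
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lib_sizes)) || any(is.na(lengths))) {
    abort("lib_sizes/lengths must cover all libraries/features")
  }
  if (any(lib_sizes < colSums(counts))) {
    abort("lib_sizes must be at least the column sums of counts")
  }
  if (any(lengths <= 0)) abort("feature lengths must be positive")
  design <- as_tibble(design)
  if (!identical(sort(design$sample), sort(colnames(counts)))) {
    abort("design$sample must match count columns")
  }
  design <- design[match(colnames(counts), design$sample), ]
  structure(list(counts = counts, lib_sizes = lib_sizes, lengths = lengths,
                 design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d libraries (%d stage(s))\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$stage))))
  invisible(x)
}

#' Read counts + design from TSV
#'
#' The counts TSV has a `feature` column, a `length` column and one column
#' per library; the design TSV has `sample`, `stage`, `replicate`,
#' `lib_size`.
#'
#' @param counts_path,design_path File paths.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(counts_path, design_path) {
  ct <- read.delim(counts_path, check.names = FALSE)
  ds <- as_tibble(read.delim(design_path))
  m <- as.matrix(ct[, ds$sample, drop = FALSE])
  rownames(m) <- ct$feature
  expression_matrix(m, setNames(ds$lib_size, ds$sample),
                    setNames(ct$length, ct$feature),
                    ds[c("sample", "stage", "replicate")])
}

#' Write an expression matrix to TSV
#'
#' @param m An `expression_matrix`.
#' @param counts_path,design_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_expression_tsv <- function(m, counts_path, design_path) {
  ct <- data.frame(feature = rownames(m$counts),
                   length = m$lengths[rownames(m$counts)],
                   m$counts, check.names = FALSE)
  write.table(ct, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- m$design
  ds$lib_size <- m$lib_sizes[ds$sample]
  write.table(ds, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `counts / (length/1e3) / (lib_size/1e6)`.
#'
#' @param m An `expression_matrix`.
#' @return Numeric matrix of FPKM values, same shape as the counts.
#' @export
fpkm <- function(m) {
  if (any(m$lib_sizes == 0)) abort("fpkm: zero library size")
  sweep(m$counts / (m$lengths / 1e3), 2L, m$lib_sizes / 1e6, `/`)
}

#' Median-of-ratios size factors
#'
#' The normalization of count-based differential expression: the reference
#' is the per-feature geometric mean over libraries (features with any zero
#' excluded); each library's factor is the median of its ratios to the
#' reference.
#'
#' @param m An `expression_matrix` or a bare counts matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "expression_matrix")) m$counts else as.matrix(m)
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos)) {
    abort(paste0("size_factors: no feature has all-positive counts; ",
                 "supply a pseudo-reference or filter libraries"))
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- exp(rowMeans(logc))
  apply(counts[pos, , drop = FALSE], 2L, function(col) median(col / ref))
}

#' Moment-based negative-binomial Wald test
#'
#' A transparent stand-in for the usual count-model differential test:
#' counts are normalized by [size_factors()], a per-feature dispersion is
#' estimated by the method of moments on the normalized counts pooled across
#' the two groups (floored at 1e-8) and shrunk 50/50 toward a mean-dispersion
#' trend fitted by regressing the per-feature estimates on `1/mean`, the
#' log2 fold change uses pseudocount-0.5 group means, and its standard error
#' comes from the delta method under the NB variance `mu + alpha*mu^2`.
#' The Wald statistic is referred to the standard normal, two-sided.
#'
#' @param m An `expression_matrix`.
#' @param stage_a,stage_b Stage labels in `m$design$stage`; the fold change
#'   is `stage_b` over `stage_a`.
#' @param sf Optional precomputed size factors.
#' @return A `lnc_diffexp` tibble: `feature`, `mean_a`, `mean_b`, `log2fc`,
#'   `se`, `stat`, `p`, plus attributes recording the contrast.
#' @export
nb_wald_test <- function(m, stage_a, stage_b, sf = NULL) {
  st <- m$design$stage
  ia <- which(st == stage_a)
  ib <- which(st == stage_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    abort("nb_wald_test: each stage needs >= 2 replicates")
  }
  sub <- m$counts[, c(ia, ib), drop = FALSE]
  if (all(sub[, seq_along(ia)] == 0) || all(sub[, -seq_along(ia)] == 0)) {
    abort("nb_wald_test: a stage has all-zero counts for every feature")
  }
  sf <- sf %||% size_factors(m)
  norm <- sweep(m$counts, 2L, sf, `/`)
  na <- norm[, ia, drop = FALSE]
  nb <- norm[, ib, drop = FALSE]
  mu_a <- rowMeans(na)
  mu_b <- rowMeans(nb)
  # moment dispersion pooled across both groups: the average of the
  # within-group pooled variance (unbiased but noisy at few replicates,
  # which alone makes the Wald test liberal) and the grand-centered total
  # variance (which absorbs part of the tested effect and alone is
  # conservative); their mean is near-nominally calibrated at 3 vs 3
  va <- apply(na, 1L, stats::var)
  vb <- apply(nb, 1L, stats::var)
  df_a <- length(ia) - 1L
  df_b <- length(ib) - 1L
  within_var <- (va * df_a + vb * df_b) / (df_a + df_b)
  total_var <- apply(cbind(na, nb), 1L, stats::var)
  pooled_var <- (within_var + total_var) / 2
  pooled_mu <- (mu_a * length(ia) + mu_b * length(ib)) / (length(ia) + length(ib))
  alpha_hat <- pmax((pooled_var - pooled_mu) / pooled_mu^2, 1e-8)
  ok <- pooled_mu > 0
  alpha_trend <- fit_dispersion_trend(alpha_hat[ok], pooled_mu[ok])
  alpha <- alpha_hat
  alpha[ok] <- 0.5 * alpha_hat[ok] + 0.5 * alpha_trend(pooled_mu[ok])
  alpha <- pmax(alpha, 1e-8)

  l2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  var_log2 <- function(mu, n, a) {
    v <- (mu + a * mu^2) / n            # var of the group mean
    v / ((mu + 0.5)^2 * log(2)^2)       # delta method on log2(mean + 0.5)
  }
  se <- sqrt(var_log2(mu_a, length(ia), alpha) +
               var_log2(mu_b, length(ib), alpha))
  both_zero <- mu_a == 0 & mu_b == 0
  stat <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  p[both_zero] <- 1
  l2fc[both_zero] <- 0
  out <- tibble(
    feature = rownames(m$counts),
    mean_a = unname(mu_a), mean_b = unname(mu_b),
    log2fc = unname(l2fc), se = unname(se), stat = unname(stat),
    p = unname(p)
  )
  attr(out, "contrast") <- c(stage_a, stage_b)
  class(out) <- c("lnc_diffexp", class(out))
  out
}

# dispersion trend alpha(mu) = a0 + a1/mu, least squares; the flat-trend
# fallback uses the mean (what the regression would return), not the median,
# whose downward bias on the skewed moment estimates makes the test liberal
fit_dispersion_trend <- function(alpha_hat, mu) {
  if (length(mu) < 3L || stats::var(1 / mu) == 0) {
    a <- c(mean(alpha_hat), 0)
  } else {
    fit <- lm(alpha_hat ~ I(1 / mu))
    a <- coef(fit)
    if (!all(is.finite(a))) a <- c(mean(alpha_hat), 0)
  }
  function(x) pmax(a[1L] + a[2L] / x, 1e-8)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; delegates to `stats::p.adjust(method = "BH")` after
#' validating the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differential lncRNAs
#'
#' Applies the joint rule — BH-adjusted p below `del_alpha` and absolute
#' fold change above `del_min_fc` — to one or more contrasts and returns the
#' per-contrast calls plus their de-duplicated union.
#'
#' @param results Named list of [nb_wald_test()] tibbles (one per contrast).
#' @param cfg A [pipeline_config()].
#' @return List: `per_contrast` (tibble with `contrast`, `feature`,
#'   `log2fc`, `p`, `padj`, `is_del`) and `union` (character vector of DEL
#'   feature ids).
#' @export
call_dels <- function(results, cfg = pipeline_config()) {
  per <- purrr::imap(results, function(res, nm) {
    res %>%
      mutate(padj = bh_adjust(.data$p),
             is_del = .data$padj < cfg$del_alpha &
               abs(.data$log2fc) > log2(cfg$del_min_fc),
             contrast = nm) %>%
      select("contrast", "feature", "log2fc", "se", "p", "padj", "is_del")
  }) %>% bind_rows()
  list(
    per_contrast = per,
    union = unique(per$feature[per$is_del])
  )
}

#' Cluster differential expression profiles
#'
#' Features are z-scored across the libraries (constant features map to an
#' all-zero profile via an sd floor), clustered hierarchically (Euclidean
#' distance, complete linkage) and cut to `n_clusters`; each cluster's mean
#' stage profile — its "fitting curve" — is reported.
#'
#' @param fpkm_mat FPKM (or any expression) matrix restricted to the
#'   features to cluster, libraries in columns.
#' @param design Tibble `sample`, `stage`, `replicate` for the columns.
#' @param n_clusters Number of clusters.
#' @return A `lnc_clusters` object: list with `assignments` (tibble
#'   `feature`, `cluster`), `profiles` (tibble `cluster`, `stage`,
#'   `mean_z`), and the z-score matrix.
#' @export
cluster_profiles <- function(fpkm_mat, design, n_clusters = 6L) {
  fpkm_mat <- as.matrix(fpkm_mat)
  if (nrow(fpkm_mat) < n_clusters) {
    abort("cluster_profiles: fewer features than clusters")
  }
  fpkm_mat <- fpkm_mat[order(rownames(fpkm_mat)), , drop = FALSE]
  z <- t(apply(fpkm_mat, 1L, function(x) {
    s <- max(sd(x), 1e-9)
    (x - mean(x)) / s
  }))
  hc <- hclust(dist(z, method = "euclidean"), method = "complete")
  cl <- cutree(hc, k = n_clusters)
  assignments <- tibble(feature = rownames(z), cluster = unname(cl))
  profiles <- as_tibble(z, rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "zscore") %>%
    left_join(design, by = "sample") %>%
    left_join(assignments, by = "feature") %>%
    group_by(.data$cluster, .data$stage) %>%
    summarise(mean_z = mean(.data$zscore), .groups = "drop")
  structure(list(assignments = assignments, profiles = profiles, z = z),
            class = "lnc_clusters")
}

#' @export
print.lnc_clusters <- function(x, ...) {
  cat(sprintf("<lnc_clusters> %d features in %d clusters\n",
              nrow(x$assignments), length(unique(x$assignments$cluster))))
  invisible(x)
}

#' PCA sample scores
#'
#' Centers `log2(FPKM + 1)` per feature and returns the sample scores on the
#' first two principal components (SVD). Component signs are fixed by making
#' each component's largest-magnitude loading positive, so scores are
#' reproducible across platforms.
#'
#' @param fpkm_mat FPKM matrix, features x libraries (>= 3 libraries).
#' @param design Optional design tibble joined onto the scores.
#' @return Tibble: `sample`, `PC1`, `PC2` (+ design columns), with variance
#'   fractions in attribute `var_explained`.
#' @export
pca_scores <- function(fpkm_mat, design = NULL) {
  fpkm_mat <- as.matrix(fpkm_mat)
  if (ncol(fpkm_mat) < 3L) abort("pca_scores: need >= 3 samples")
  lg <- log2(fpkm_mat + 1)
  lg <- lg - rowMeans(lg)
  if (all(abs(lg) < 1e-12)) {
    out <- tibble(sample = colnames(fpkm_mat), PC1 = 0, PC2 = 0)
    attr(out, "var_explained") <- c(0, 0)
    return(out)
  }
  sv <- svd(t(lg))  # samples x features
  k <- min(2L, ncol(sv$u))
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  if (k < 2L) scores <- cbind(scores, 0)
  out <- tibble(sample = colnames(fpkm_mat),
                PC1 = scores[, 1L], PC2 = scores[, 2L])
  if (!is.null(design)) out <- left_join(out, as_tibble(design), by = "sample")
  attr(out, "var_explained") <- (sv$d^2 / sum(sv$d^2))[1:2]
  out
}
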