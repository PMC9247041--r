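# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `lnc_diffexp` from [nb_wald_test()].
#' @param ... Unused.
#' @return The underlying tibble with BH-adjusted p-values added.
#' @method tidy lnc_diffexp
#' @export
tidy.lnc_diffexp <- function(x, ...) {
  out <- as_tibble(x)
  out$padj <- bh_adjust(out$p)
  out
}

#' @rdname tidy.lnc_diffexp
#' @method glance lnc_diffexp
#' @export
glance.lnc_diffexp <- function(x, ...) {
  padj <- bh_adjust(x$p)
  tibble(
    n_features = nrow(x),
    contrast = paste(attr(x, "contrast"), collapse = " vs "),
    n_sig_padj05 = sum(padj < 0.05),
    median_se = median(x$se)
  )
}

#' Tidy cluster assignments
#'
#' @param x A `lnc_clusters` from [cluster_profiles()].
#' @param ... Unused.
#' @return Tibble `feature`, `cluster`.
#' @method tidy lnc_clusters
#' @export
tidy.lnc_clusters <- function(x, ...) as_tibble(x$assignments)

#' @rdname tidy.lnc_clusters
#' @method glance lnc_clusters
#' @export
glance.lnc_clusters <- function(x, ...) {
  tibble(n_features = nrow(x$assignments),
         n_clusters = length(unique(x$assignments$cluster)))
}

#' Tidy an enrichment result
#'
#' @param x A `lnc_enrichment` from [ora()].
#' @param ... Unused.
#' @return The enrichment tibble.
#' @method tidy lnc_enrichment
#' @export
tidy.lnc_enrichment <- function(x, ...) {
  class(x) <- setdiff(class(x), "lnc_enrichment")
  as_tibble(x)
}

#' Cluster "fitting curve" plot
#'
#' Mean z-scored expression per cluster across the developmental stages.
#'
#' @param object A `lnc_clusters`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnc_clusters
#' @export
autoplot.lnc_clusters <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$stage, y = .data$mean_z,
                               group = factor(.data$cluster),
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "stage", y = "mean z-score", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Cascade funnel plot
#'
#' @param object A `lnc_cascade`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnc_cascade
#' @export
autoplot.lnc_cascade <- function(object, ...) {
  d <- object$counts %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "first failing rule", y = "transcripts") +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param scores Output of [pca_scores()] (with a design joined in).
#' @return A ggplot object.
#' @export
plot_pca <- function(scores) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("stage" %in% names(scores)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::theme_minimal()
}
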