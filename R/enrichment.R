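# Hypergeometric over-representation analysis of target gene sets against
# supplied term maps (GO/KEGG-style), BH-corrected.

#' Over-representation analysis
#'
#' For each term, tests whether the study set contains more term genes than
#' expected under sampling without replacement from the population:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' population size, `K` the population genes carrying the term, `n` the
#' study size and `k` the study genes carrying it. Term gene sets are
#' intersected with the population first; terms with `K = 0` are skipped.
#' BH adjustment is applied across the tested terms.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param term_map Tibble with columns `term`, `gene` (optionally `label`).
#' @return A `lnc_enrichment` tibble: `term`, `label`, `k`, `n`, `K`, `N`,
#'   `p`, `padj`, sorted by `padj` then `p`.
#' @export
#' @examples
#' tm <- tibble::tibble(term = "T1", gene = paste0("g", 1:5))
#' ora(paste0("g", 1:5), paste0("g", 1:20), tm)
ora <- function(study, population, term_map) {
  study <- unique(study)
  population <- unique(population)
  stray <- setdiff(study, population)
  if (length(stray)) {
    abort(paste0("study genes absent from population: ",
                 paste(head(stray, 5L), collapse = ", ")))
  }
  term_map <- as_tibble(term_map) %>%
    filter(.data$gene %in% population) %>%
    distinct(.data$term, .data$gene,
             .keep_all = TRUE)
  if (!"label" %in% names(term_map)) term_map$label <- term_map$term
  N <- length(population)
  n <- length(study)
  res <- term_map %>%
    group_by(.data$term) %>%
    summarise(
      label = first(.data$label),
      K = n(),
      k = sum(.data$gene %in% study),
      .groups = "drop"
    ) %>%
    filter(.data$K > 0L) %>%
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) %>%
    mutate(padj = bh_adjust(.data$p)) %>%
    select("term", "label", "k", "n", "K", "N", "p", "padj") %>%
    arrange(.data$padj, .data$p)
  class(res) <- c("lnc_enrichment", class(res))
  res
}

#' Read a term map TSV
#'
#' @param path TSV with columns `term`, `gene` and optionally `label`.
#' @return Tibble.
#' @export
read_term_map <- function(path) {
  as_tibble(read.delim(path, colClasses = "character"))
}
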