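# End-to-end orchestration: the lncRNA filter cascade and the full run.

#' lncRNA filter cascade
#'
#' Applies the five retention rules in a fixed order — class code in
#' {u, i, o, x}, spliced length >= `min_length`, exon count >= `min_exons`,
#' maximum FPKM across libraries >= `min_fpkm`, consensus noncoding — and
#' attributes each rejected transcript to its first failing stage, so the
#' per-stage counts are well defined and sum to the input size.
#'
#' @param classified Output of [classify_transcripts()].
#' @param verdicts Output of [coding_verdicts()].
#' @param fpkm_mat FPKM matrix covering the candidates (rownames are
#'   transcript ids).
#' @param cfg A [pipeline_config()].
#' @return A `lnc_cascade` list: `table` (per-transcript tibble with
#'   `stage` = `retained` or the first failing rule) and `counts` (tibble
#'   `stage`, `n` in cascade order).
#' @export
filter_cascade <- function(classified, verdicts, fpkm_mat,
                           cfg = pipeline_config()) {
  tbl <- classified %>%
    left_join(verdicts, by = "transcript_id")
  missing_v <- tbl$transcript_id[is.na(tbl$noncoding)]
  if (length(missing_v)) {
    abort(paste0("filter_cascade: no coding verdict for: ",
                 paste(head(missing_v, 5L), collapse = ", ")))
  }
  missing_f <- setdiff(tbl$transcript_id, rownames(fpkm_mat))
  if (length(missing_f)) {
    abort(paste0("filter_cascade: no FPKM for: ",
                 paste(head(missing_f, 5L), collapse = ", ")))
  }
  max_fpkm <- apply(fpkm_mat[tbl$transcript_id, , drop = FALSE], 1L, max)
  tbl <- tbl %>%
    mutate(
      max_fpkm = unname(max_fpkm),
      stage = dplyr::case_when(
        !.data$class_code %in% c("u", "i", "o", "x") ~ "class",
        .data$length < cfg$min_length ~ "length",
        .data$n_exons < cfg$min_exons ~ "exons",
        .data$max_fpkm < cfg$min_fpkm ~ "fpkm",
        !.data$noncoding ~ "coding",
        TRUE ~ "retained"
      )
    )
  stages <- c("class", "length", "exons", "fpkm", "coding", "retained")
  counts <- tibble(stage = stages,
                   n = unname(vapply(stages, function(s) sum(tbl$stage == s),
                                     integer(1L))))
  structure(list(table = tbl, counts = counts), class = "lnc_cascade")
}

#' @export
print.lnc_cascade <- function(x, ...) {
  cat("<lnc_cascade>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-9s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  invisible(x)
}

#' Run the full pipeline on a simulated (or assembled) study
#'
#' Executes classification, coding-potential scoring, the filter cascade,
#' expression analysis (FPKM, the three pairwise stage contrasts,
#' differential lncRNA calls, profile clustering, PCA), cis/trans target
#' prediction, ceRNA network assembly, synteny-based positional
#' conservation, and over-representation of cis targets, and returns all
#' stage outputs plus a reproducible run manifest.
#'
#' Trans-target prediction is restricted to `max_trans_lnc` differential
#' lncRNAs against `max_trans_mrna` mRNAs to keep the duplex search at desk
#' scale; both caps are parameters.
#'
#' @param sim A [simulate_study()] result.
#' @param cfg A [pipeline_config()].
#' @param term_map Optional term map for enrichment; if `NULL` a synthetic
#'   map over annotated genes is built from the gene ranks.
#' @param max_trans_lnc,max_trans_mrna Pair caps for the duplex search.
#' @return A `lnc_run` list with stage outputs and `manifest`.
#' @export
run_all <- function(sim, cfg = pipeline_config(), term_map = NULL,
                    max_trans_lnc = 10L, max_trans_mrna = 20L) {
  t0 <- Sys.time()
  classified <- classify_transcripts(sim$candidates, sim$ann)
  verdicts <- coding_verdicts(sim$cand_seqs, cfg)
  fk <- fpkm(sim$expr)
  cascade <- filter_cascade(classified, verdicts, fk, cfg)
  retained <- cascade$table %>% filter(.data$stage == "retained")

  contrasts <- list(S1_S2 = c("S1", "S2"), S1_S3 = c("S1", "S3"),
                    S2_S3 = c("S2", "S3"))
  sf <- size_factors(sim$expr)
  tests <- purrr::map(contrasts, function(ct) {
    res <- nb_wald_test(sim$expr, ct[1L], ct[2L], sf = sf)
    res[res$feature %in% retained$transcript_id, ]
  })
  dels <- call_dels(tests, cfg)
  clusters <- if (length(dels$union) >= cfg$n_clusters) {
    cluster_profiles(fk[dels$union, , drop = FALSE], sim$expr$design,
                     cfg$n_clusters)
  } else NULL
  pca <- pca_scores(fk[retained$transcript_id, , drop = FALSE],
                    sim$expr$design)

  lnc_spans <- transcript_spans(sim$candidates) %>%
    filter(.data$transcript_id %in% dels$union)
  cis <- cis_targets(lnc_spans, sim$ann, cfg$cis_window)

  trans_lncs <- head(intersect(dels$union, names(sim$cand_seqs)), max_trans_lnc)
  mrna_ids <- sim$ann$transcripts %>%
    left_join(sim$ann$genes %>% select("gene_id", "biotype"), by = "gene_id") %>%
    filter(.data$biotype == "coding") %>%
    pull("transcript_id")
  trans <- trans_targets(sim$cand_seqs[trans_lncs],
                         sim$ref_seqs[head(mrna_ids, max_trans_mrna)], cfg)

  lnc_sites <- scan_sites(sim$mirnas, sim$cand_seqs[retained$transcript_id],
                          cfg$mirna_max_score)
  mrna_sites <- scan_sites(sim$mirnas, sim$ref_seqs[mrna_ids],
                           cfg$mirna_max_score)
  network <- build_network(lnc_sites, mrna_sites)

  blocks <- find_synteny_blocks(sim$ortho$orthologs, sim$ann, sim$ortho$ann_b,
                                cfg$min_anchors, cfg$max_gap)
  lincs <- retained %>%
    filter(.data$category == "lincRNA") %>%
    left_join(transcript_spans(sim$candidates), by = "transcript_id") %>%
    transmute(id = .data$transcript_id, chrom = .data$chrom.x,
              start = .data$start, end = .data$end)
  positional <- positional_conservation(lincs, sim$ortho$lncs_b, sim$ann,
                                        sim$ortho$ann_b, blocks,
                                        sim$ortho$orthologs, cfg)

  if (is.null(term_map)) term_map <- synthetic_term_map(sim$ann)
  population <- unique(term_map$gene)
  study <- intersect(unique(cis$gene_id), population)
  enrich <- if (length(study)) ora(study, population, term_map) else NULL

  manifest <- list(
    config = unclass(cfg),
    seed = sim$params$rng_seed,
    n_candidates = length(unique(sim$candidates$transcript_id)),
    cascade_counts = cascade$counts,
    n_retained = nrow(retained),
    n_dels = length(dels$union),
    dels_per_contrast = dels$per_contrast %>%
      group_by(.data$contrast) %>% summarise(n = sum(.data$is_del)),
    n_cis = nrow(cis), n_trans = nrow(trans),
    n_triples = nrow(network$triples),
    n_blocks = nrow(blocks$blocks),
    n_positional_pairs = nrow(positional),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(
    classified = classified, verdicts = verdicts, cascade = cascade,
    retained = retained, tests = tests, dels = dels, clusters = clusters,
    pca = pca, cis = cis, trans = trans, sites = list(lnc = lnc_sites,
                                                      mrna = mrna_sites),
    network = network, blocks = blocks, positional = positional,
    enrichment = enrich, manifest = manifest
  ), class = "lnc_run")
}

#' @export
print.lnc_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<lnc_run> %d candidates -> %d lncRNAs; %d DELs; ",
                     "%d cis / %d trans targets; %d ceRNA triples; ",
                     "%d synteny blocks; %d positional pairs\n"),
              m$n_candidates, m$n_retained, m$n_dels, m$n_cis, m$n_trans,
              m$n_triples, m$n_blocks, m$n_positional_pairs))
  invisible(x)
}

# a deterministic toy term map: genes binned by rank into pseudo-terms
synthetic_term_map <- function(ann, genes_per_term = 15L) {
  g <- ann$genes %>% filter(.data$biotype == "coding") %>%
    arrange(.data$chrom, .data$rank)
  tibble(term = sprintf("TERM%03d", (seq_len(nrow(g)) - 1L) %/% genes_per_term + 1L),
         gene = g$gene_id)
}

#' Study summary ratios
#'
#' Recomputes headline ratios of a lncRNA survey from its printed counts:
#' the percentage of lncRNAs with cross-species sequence homologs, the
#' average number of cis targets per differential lncRNA, and per-species
#' homology percentages.
#'
#' @param counts A named list or one-row data frame with
#'   `n_lncRNAs`, `n_homologous`, `n_cis_targets`, `n_dels`,
#'   `n_arabidopsis_homologs`.
#' @return Tibble with `seq_homology_pct`, `cis_targets_per_del`,
#'   `arabidopsis_homology_pct`.
#' @export
survey_ratios <- function(counts) {
  tibble(
    seq_homology_pct = 100 * counts$n_homologous / counts$n_lncRNAs,
    cis_targets_per_del = counts$n_cis_targets / counts$n_dels,
    arabidopsis_homology_pct =
      100 * counts$n_arabidopsis_homologs / counts$n_lncRNAs
  )
}
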