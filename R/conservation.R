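# Sequence-level homology between lncRNA sets (seeded ungapped extension with
# Karlin-Altschul E-values) and synteny-based positional conservation.

#' Seeded ungapped homology search
#'
#' A nucleotide search in the classic seed-and-extend style: exact seeds of
#' length `word` on both strands are extended ungapped in both directions
#' with +1/match, -2/mismatch and an X-drop of 20; the best-scoring hit per
#' (query, subject) pair is kept. E-values follow Karlin-Altschul statistics
#' `E = K m n exp(-lambda S)` with lambda solved numerically for the +1/-2
#' scheme at the subject-set base composition and the published K for that
#' scheme; `n` is the total subject-set length. Hits must satisfy
#' `evalue < homology_evalue` (strict) and
#' `query_coverage >= homology_min_coverage` (inclusive).
#'
#' @param queries,subjects Named character vectors of sequences.
#' @param cfg A [pipeline_config()].
#' @param word Seed length (default 11).
#' @param xdrop X-drop termination threshold (default 20).
#' @return Tibble: `query_id`, `subject_id`, `strand`, `score`, `align_len`,
#'   `identities`, `bitscore`, `evalue`, `query_coverage`.
#' @export
homology_search <- function(queries, subjects, cfg = pipeline_config(),
                            word = 11L, xdrop = 20) {
  if (!length(queries) || any(!nzchar(queries))) {
    abort("homology_search: empty query")
  }
  subjects_up <- toupper(subjects)
  comp <- base_composition(subjects_up)
  lambda <- karlin_lambda(comp)
  K <- 0.621  # published ungapped K for the +1/-2 nucleotide scheme
  n_db <- sum(nchar(subjects_up))
  rows <- list()
  for (q in names(queries)) {
    qseq <- toupper(queries[[q]])
    m <- nchar(qseq)
    for (s in names(subjects_up)) {
      best <- NULL
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") qseq else revcomp(qseq)
        h <- best_ungapped_hit(qs, subjects_up[[s]], word, xdrop)
        if (!is.null(h) && (is.null(best) || h$score > best$score)) {
          h$strand <- strand
          best <- h
        }
      }
      if (is.null(best)) next
      evalue <- K * m * n_db * exp(-lambda * best$score)
      cov <- best$align_len / m
      if (evalue < cfg$homology_evalue && cov >= cfg$homology_min_coverage) {
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q, subject_id = s, strand = best$strand,
          score = unname(best$score), align_len = unname(best$align_len),
          identities = unname(best$identities),
          bitscore = unname((lambda * best$score - log(K)) / log(2)),
          evalue = unname(evalue), query_coverage = unname(cov)
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble(query_id = character(), subject_id = character(),
                  strand = character(), score = numeric(),
                  align_len = integer(), identities = integer(),
                  bitscore = numeric(), evalue = numeric(),
                  query_coverage = numeric()))
  }
  bind_rows(rows)
}

base_composition <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
  p <- as.numeric(tb)
  if (sum(p) == 0) p <- rep(1, 4)
  p <- pmax(p / sum(p), 1e-6)
  setNames(p / sum(p), c("A", "C", "G", "T"))
}

# lambda solving sum_ij p_i p_j exp(lambda * s_ij) = 1 for s = +1/-2
karlin_lambda <- function(p, match = 1, mismatch = -2) {
  f <- function(l) {
    sum(outer(p, p) * exp(l * ifelse(diag(4) == 1, match, mismatch))) - 1
  }
  uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

# best ungapped seed-and-extend hit of query vs one subject
best_ungapped_hit <- function(q, s, word, xdrop) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < word || ns < word) return(NULL)
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  skmers <- substring(s, seq_len(ns - word + 1L), word:ns)
  pos_by_kmer <- split(seq_len(ns - word + 1L), skmers)
  qkmers <- substring(q, seq_len(nq - word + 1L), word:nq)
  seeds <- list()
  for (i in seq_along(qkmers)) {
    js <- pos_by_kmer[[qkmers[i]]]
    if (!is.null(js)) seeds[[length(seeds) + 1L]] <- cbind(i, js)
  }
  if (!length(seeds)) return(NULL)
  seeds <- do.call(rbind, seeds)
  # seeds contiguous on a diagonal yield the identical extension; keep run starts
  d <- seeds[, 1L] - seeds[, 2L]
  key <- paste(d, seeds[, 1L])
  prev <- paste(d, seeds[, 1L] - 1L)
  seeds <- seeds[!prev %in% key, , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(seeds))) {
    h <- extend_ungapped(qc, sc, seeds[k, 1L], seeds[k, 2L], word, xdrop)
    if (is.null(best) || h$score > best$score) best <- h
  }
  best
}

extend_ungapped <- function(qc, sc, qi, sj, word, xdrop) {
  sc_match <- 1; sc_mis <- -2
  score <- word * sc_match
  # right extension
  score_r <- 0; best_r <- 0; len_r <- 0L
  i <- qi + word; j <- sj + word
  while (i <= length(qc) && j <= length(sc)) {
    score_r <- score_r + if (qc[i] == sc[j]) sc_match else sc_mis
    if (score_r > best_r) { best_r <- score_r; len_r <- i - (qi + word) + 1L }
    if (best_r - score_r >= xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  # left extension
  score_l <- 0; best_l <- 0; len_l <- 0L
  i <- qi - 1L; j <- sj - 1L
  while (i >= 1L && j >= 1L) {
    score_l <- score_l + if (qc[i] == sc[j]) sc_match else sc_mis
    if (score_l > best_l) { best_l <- score_l; len_l <- qi - i }
    if (best_l - score_l >= xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  q_start <- qi - len_l; q_end <- qi + word - 1L + len_r
  s_start <- sj - len_l
  idx <- seq_len(q_end - q_start + 1L)
  ident <- sum(qc[q_start + idx - 1L] == sc[s_start + idx - 1L])
  list(score = score + best_r + best_l,
       align_len = q_end - q_start + 1L,
       identities = ident,
       q_start = q_start, q_end = q_end)
}

#' Syntenic block detection
#'
#' Chains collinear ortholog anchors in the style of collinearity tools:
#' anchors are grouped by chromosome pair, and the longest strictly monotone
#' (same orientation) or anti-monotone (inverted) gene-rank chains with
#' per-step rank gaps at most `max_gap` on both genomes are extracted
#' greedily, longest first; chains shorter than `min_anchors` are dropped
#' and each anchor belongs to at most one block.
#'
#' @param orthologs Tibble `gene_a`, `gene_b` of one-to-one ortholog pairs.
#' @param ann_a,ann_b `genome_annotation` objects for the two genomes.
#' @param min_anchors Minimum chain length (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @return A `synteny` object: list with `blocks` (tibble `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation`, `n_anchors`) and `anchors` (tibble
#'   `block_id`, `gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
find_synteny_blocks <- function(orthologs, ann_a, ann_b,
                                min_anchors = 5L, max_gap = 25L) {
  orthologs <- as_tibble(orthologs)
  if (anyDuplicated(orthologs[c("gene_a", "gene_b")])) {
    warn("duplicated ortholog pair(s) removed")
    orthologs <- distinct(orthologs, .data$gene_a, .data$gene_b)
  }
  anchors <- orthologs %>%
    inner_join(ann_a$genes %>%
                 select(gene_a = "gene_id", chrom_a = "chrom", rank_a = "rank"),
               by = "gene_a") %>%
    inner_join(ann_b$genes %>%
                 select(gene_b = "gene_id", chrom_b = "chrom", rank_b = "rank"),
               by = "gene_b")
  blocks <- list(); assigned <- list(); bid <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- anchors %>%
      filter(.data$chrom_a == parts[1L], .data$chrom_b == parts[2L]) %>%
      arrange(.data$rank_a, .data$rank_b)
    avail <- rep(TRUE, nrow(sub))
    repeat {
      ch <- longest_chain(sub[avail, ], max_gap)
      if (is.null(ch) || nrow(ch$anchors) < min_anchors) break
      bid <- bid + 1L
      blocks[[bid]] <- tibble(block_id = bid, chrom_a = parts[1L],
                              chrom_b = parts[2L],
                              orientation = ch$orientation,
                              n_anchors = nrow(ch$anchors))
      assigned[[bid]] <- ch$anchors %>% mutate(block_id = bid)
      used <- paste(ch$anchors$gene_a, ch$anchors$gene_b)
      avail[paste(sub$gene_a, sub$gene_b) %in% used] <- FALSE
    }
  }
  if (!bid) {
    return(structure(list(
      blocks = tibble(block_id = integer(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      n_anchors = integer()),
      anchors = tibble(block_id = integer(), gene_a = character(),
                       gene_b = character(), rank_a = integer(),
                       rank_b = integer())
    ), class = "synteny"))
  }
  structure(list(
    blocks = bind_rows(blocks),
    anchors = bind_rows(assigned) %>%
      select("block_id", "gene_a", "gene_b", "rank_a", "rank_b")
  ), class = "synteny")
}

#' @export
print.synteny <- function(x, ...) {
  cat(sprintf("<synteny> %d block(s), %d anchors\n",
              nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

# longest strictly monotone / anti-monotone chain with bounded rank gaps,
# O(n^2) dynamic program per direction
longest_chain <- function(sub, max_gap) {
  n <- nrow(sub)
  if (!n) return(NULL)
  best <- NULL
  for (dir in c(1L, -1L)) {
    len <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ga <- sub$rank_a[i] - sub$rank_a[j]
        gb <- dir * (sub$rank_b[i] - sub$rank_b[j])
        if (ga > 0L && ga <= max_gap && gb > 0L && gb <= max_gap &&
            len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    k <- which.max(len)
    if (is.null(best) || len[k] > nrow(best$anchors)) {
      idx <- integer()
      while (!is.na(k)) { idx <- c(k, idx); k <- prev[k] }
      best <- list(anchors = sub[idx, ],
                   orientation = if (dir == 1L) "same" else "inverted")
    }
  }
  best
}

#' Positional conservation of lncRNAs across two genomes
#'
#' For each genome-A lncRNA, the `neighbor_k` nearest protein-coding genes
#' upstream and downstream (by gene rank, fewer at chromosome ends) are
#' mapped through the ortholog table; if at least `min_conserved_neighbors`
#' of them are anchors of a single syntenic block, the lncRNA is paired with
#' every genome-B lncRNA whose span lies inside the genome-B interval
#' spanned by that block's matched anchors.
#'
#' @param lncs_a Tibble `id`, `chrom`, `start`, `end` of genome-A lncRNAs.
#' @param lncs_b Same for genome B.
#' @param ann_a,ann_b `genome_annotation` objects.
#' @param synteny A `synteny` object from [find_synteny_blocks()].
#' @param orthologs Tibble `gene_a`, `gene_b`.
#' @param cfg A [pipeline_config()].
#' @return Tibble: `lnc_a`, `lnc_b`, `block_id`, `n_conserved_neighbors`.
#' @export
positional_conservation <- function(lncs_a, lncs_b, ann_a, ann_b, synteny,
                                    orthologs, cfg = pipeline_config()) {
  out <- list()
  coding_a <- ann_a$genes %>% filter(.data$biotype == "coding")
  genes_b <- ann_b$genes
  for (r in seq_len(nrow(lncs_a))) {
    lnc <- lncs_a[r, ]
    cg <- coding_a %>% filter(.data$chrom == lnc$chrom) %>% arrange(.data$rank)
    if (!nrow(cg)) {
      warn(sprintf("lncRNA %s: no coding genes on its chromosome, skipped",
                   lnc$id))
      next
    }
    up <- cg %>% filter(.data$end <= lnc$start) %>% tail(cfg$neighbor_k)
    down <- cg %>% filter(.data$start >= lnc$end) %>% head(cfg$neighbor_k)
    neigh <- c(up$gene_id, down$gene_id)
    if (!length(neigh)) next
    in_block <- synteny$anchors %>% filter(.data$gene_a %in% neigh)
    if (!nrow(in_block)) next
    tally <- in_block %>% count(.data$block_id, sort = TRUE)
    if (tally$n[1L] < cfg$min_conserved_neighbors) next
    b <- tally$block_id[1L]
    banch <- synteny$anchors %>% filter(.data$block_id == b)
    bg <- genes_b %>% filter(.data$gene_id %in% banch$gene_b)
    lo <- min(bg$start); hi <- max(bg$end)
    chrom_b <- bg$chrom[1L]
    mates <- lncs_b %>%
      filter(.data$chrom == chrom_b, .data$start >= lo, .data$end <= hi)
    if (!nrow(mates)) next
    out[[length(out) + 1L]] <- tibble(
      lnc_a = lnc$id, lnc_b = mates$id, block_id = b,
      n_conserved_neighbors = tally$n[1L]
    )
  }
  if (!length(out)) {
    return(tibble(lnc_a = character(), lnc_b = character(),
                  block_id = integer(), n_conserved_neighbors = integer()))
  }
  bind_rows(out)
}
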