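# Plant-rule miRNA target sites on lncRNAs and mRNAs, and ceRNA
# (lncRNA - miRNA - mRNA) network assembly.

#' Plant-rule miRNA site penalty
#'
#' Scores the antiparallel, ungapped pairing of a miRNA (5'->3') against a
#' transcript window of equal length. Per aligned position: Watson-Crick
#' pair 0, G:U wobble 0.5, mismatch 1; penalties at miRNA positions 2-13
#' (from its 5' end) are doubled, reflecting the functional core of plant
#' complementarity rules. Lower is better; 0 is perfect complementarity.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param window Transcript subsequence of the same length (read 5'->3').
#' @return List: `score` and `alignment`, a string over
#'   `|` (Watson-Crick), `o` (G:U), `.` (mismatch), one symbol per miRNA
#'   position (5'->3').
#' @export
score_site <- function(mirna, window) {
  mirna <- to_rna(mirna)
  window <- to_rna(window)
  n <- nchar(mirna)
  if (nchar(window) != n) abort("score_site: window length must equal miRNA length")
  mi <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  # antiparallel: miRNA position k pairs window position n - k + 1
  wi <- rev(strsplit(window, "", fixed = TRUE)[[1L]])
  pr <- pairable(mi, wi)
  pen <- ifelse(pr$wc, 0, ifelse(pr$ok, 0.5, 1))
  core <- seq_len(n) >= 2L & seq_len(n) <= 13L
  pen[core] <- pen[core] * 2
  list(score = sum(pen),
       alignment = paste0(ifelse(pr$wc, "|", ifelse(pr$ok, "o", ".")),
                          collapse = ""))
}

#' Find miRNA sites on a transcript
#'
#' Exhaustive scan of every window of miRNA length; all sites with penalty
#' at or below `max_score` are reported (overlaps allowed) and the best one
#' is flagged. The scan is vectorized over window offsets.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence, 5'->3'.
#' @param mirna_id,transcript_id Identifiers copied into the output.
#' @param max_score Penalty cutoff, inclusive (default 4).
#' @return Tibble: `mirna_id`, `transcript_id`, `offset` (0-based window
#'   start), `score`, `alignment`, `best`.
#' @export
find_sites <- function(mirna, transcript, mirna_id = "mirna",
                       transcript_id = "tx", max_score = 4) {
  empty <- tibble(mirna_id = character(), transcript_id = character(),
                  offset = integer(), score = numeric(),
                  alignment = character(), best = logical())
  mirna <- to_rna(mirna)
  transcript <- to_rna(transcript)
  k <- nchar(mirna)
  n <- nchar(transcript)
  if (n < k) return(empty)
  mi <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  tx <- strsplit(transcript, "", fixed = TRUE)[[1L]]
  n_win <- n - k + 1L
  total <- numeric(n_win)
  weights <- ifelse(seq_len(k) >= 2L & seq_len(k) <= 13L, 2, 1)
  # miRNA position p pairs transcript position offset + (k - p) (0-based offset)
  for (p in seq_len(k)) {
    txb <- tx[(k - p + 1L):(k - p + n_win)]
    wc <- !is.na(WC_PARTNER[mi[p]]) & txb == WC_PARTNER[[mi[p]]]
    gu <- (mi[p] == "G" & txb == "U") | (mi[p] == "U" & txb == "G")
    total <- total + weights[p] * ifelse(wc, 0, ifelse(gu, 0.5, 1))
  }
  keep <- which(total <= max_score)
  if (!length(keep)) return(empty)
  rows <- purrr::map(keep, function(off) {
    al <- score_site(mirna, substr(transcript, off, off + k - 1L))
    tibble(mirna_id = mirna_id, transcript_id = transcript_id,
           offset = off - 1L, score = al$score, alignment = al$alignment)
  }) %>% bind_rows()
  rows$best <- seq_len(nrow(rows)) == which.min(rows$score)
  rows
}

#' Scan miRNA sets against transcript sets
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param max_score Penalty cutoff, inclusive.
#' @return Site tibble as in [find_sites()], one row per reported site.
#' @export
scan_sites <- function(mirnas, transcripts, max_score = 4) {
  out <- list()
  for (m in names(mirnas)) {
    for (tx in names(transcripts)) {
      s <- find_sites(mirnas[[m]], transcripts[[tx]], m, tx, max_score)
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  }
  if (!length(out)) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  offset = integer(), score = numeric(),
                  alignment = character(), best = logical()))
  }
  bind_rows(out)
}

#' Assemble a ceRNA network
#'
#' One lncRNA - miRNA - mRNA triple is emitted for every miRNA with at least
#' one site on the lncRNA and one on the mRNA (cross product over its
#' partners). miRNA-lncRNA and miRNA-mRNA edges are also reported
#' separately, so miRNAs with partners on only one side still appear in the
#' edge tables.
#'
#' @param lnc_sites Site tibble for miRNAs vs lncRNAs.
#' @param mrna_sites Site tibble for miRNAs vs mRNAs.
#' @return A `cerna_network`: list with `triples`, `edges`, `nodes` tibbles.
#' @export
build_network <- function(lnc_sites, mrna_sites) {
  lnc_pairs <- distinct(lnc_sites, .data$mirna_id, lnc_id = .data$transcript_id)
  mrna_pairs <- distinct(mrna_sites, .data$mirna_id, mrna_id = .data$transcript_id)
  triples <- inner_join(lnc_pairs, mrna_pairs, by = "mirna_id",
                        relationship = "many-to-many") %>%
    select("lnc_id", "mirna_id", "mrna_id")
  edges <- bind_rows(
    lnc_pairs %>% transmute(from = .data$mirna_id, to = .data$lnc_id,
                            type = "miRNA-lncRNA"),
    mrna_pairs %>% transmute(from = .data$mirna_id, to = .data$mrna_id,
                             type = "miRNA-mRNA")
  )
  nodes <- bind_rows(
    tibble(id = unique(c(lnc_pairs$mirna_id, mrna_pairs$mirna_id)),
           type = "miRNA"),
    tibble(id = unique(lnc_pairs$lnc_id), type = "lncRNA"),
    tibble(id = unique(mrna_pairs$mrna_id), type = "mRNA")
  )
  structure(list(triples = triples, edges = edges, nodes = nodes),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d triples, %d edges, %d nodes\n",
              nrow(x$triples), nrow(x$edges), nrow(x$nodes)))
  invisible(x)
}

#' Export a ceRNA network to GraphML
#'
#' @param net A `cerna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
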