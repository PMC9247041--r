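# Coding-potential scoring: longest ORF, Fickett TESTCODE, in-frame hexamer
# log-likelihood ratio, and a PWM protein-motif scan, combined by intersection
# into a consensus noncoding verdict.

#' Longest open reading frame
#'
#' Scans the three forward frames (transcripts come from strand-specific
#' assembly, so the antisense frames belong to a different transcript) for
#' ATG-initiated reading frames. The ORF extends to the first in-frame stop
#' codon (included in the length) or, if none occurs, to the last complete
#' codon (`has_stop = FALSE`). Ties are broken by smaller start offset. If no
#' ATG exists in any frame, the longest stop-free codon stretch is returned
#' with `has_start = FALSE`.
#'
#' @param seq A nucleotide string over A/C/G/T/N.
#' @return A one-row tibble: `start`, `end` (0-based offsets in the
#'   transcript), `frame` (0-2), `length_nt`, `has_start`, `has_stop`.
#' @export
find_longest_orf <- function(seq) {
  if (!nzchar(seq)) abort("find_longest_orf: empty sequence")
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  consider <- function(start, end, frame, has_start, has_stop) {
    len <- end - start
    if (is.null(best) || len > best$length_nt ||
        (len == best$length_nt && start < best$start)) {
      best <<- tibble(start = start, end = end, frame = frame,
                      length_nt = len, has_start = has_start,
                      has_stop = has_stop)
    }
  }
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    codons <- substring(seq, f + 1L + 3L * (seq_len(ncod) - 1L),
                        f + 3L * seq_len(ncod))
    orf_start <- NA_integer_  # codon index of current ATG
    for (k in seq_len(ncod)) {
      if (codons[k] %in% stops) {
        if (!is.na(orf_start)) {
          consider(f + 3L * (orf_start - 1L), f + 3L * k, f, TRUE, TRUE)
          orf_start <- NA_integer_
        }
      } else if (is.na(orf_start) && codons[k] == "ATG") {
        orf_start <- k
      }
    }
    if (!is.na(orf_start)) {
      consider(f + 3L * (orf_start - 1L), f + 3L * ncod, f, TRUE, FALSE)
    }
  }
  if (!is.null(best)) return(best)
  # no ATG anywhere: longest stop-free codon stretch
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    codons <- substring(seq, f + 1L + 3L * (seq_len(ncod) - 1L),
                        f + 3L * seq_len(ncod))
    run_start <- 1L
    for (k in seq_len(ncod + 1L)) {
      if (k > ncod || codons[k] %in% stops) {
        if (k > run_start) {
          consider(f + 3L * (run_start - 1L), f + 3L * (k - 1L), f, FALSE, FALSE)
        }
        run_start <- k + 1L
      }
    }
  }
  if (is.null(best)) {
    best <- tibble(start = 0L, end = 0L, frame = 0L, length_nt = 0L,
                   has_start = FALSE, has_stop = FALSE)
  }
  best
}

# Fickett (1982) TESTCODE lookup tables: probability-of-coding values for
# binned position-asymmetry and composition parameters, with the published
# per-base weights.
fickett_tables <- function() {
  list(
    position_prob = list(
      A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
      C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
      G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
      T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
    ),
    position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    position_edges = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
    content_prob = list(
      A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
      C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
      G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
      T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
    ),
    content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
    content_edges = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  )
}

#' Fickett TESTCODE score
#'
#' The classic coding-potential statistic from period-3 positional base
#' asymmetry and base composition: for each base, the counts in the three
#' codon positions give a position parameter `max/(min+1)` and the overall
#' fraction gives a content parameter; both are mapped through the published
#' lookup tables and combined with the published weights. Higher scores
#' indicate coding; 0.74 is the conventional "likely coding" boundary.
#'
#' @param seq Nucleotide string, length >= 200 nt (shorter transcripts never
#'   reach this stage of the filter cascade).
#' @return A single numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 200L) abort("fickett_score: sequence shorter than 200 nt")
  tabs <- fickett_tables()
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(pos[chars == b] + 1L, nbins = 3L)
    ppar <- max(cnt) / (min(cnt) + 1)
    pbin <- which(ppar >= tabs$position_edges)[1L]
    cpar <- sum(cnt) / n
    cbin <- which(cpar >= tabs$content_edges)[1L]
    score <- score +
      tabs$position_prob[[b]][pbin] * tabs$position_weight[[b]] +
      tabs$content_prob[[b]][cbin] * tabs$content_weight[[b]]
  }
  score
}

#' In-frame hexamer log-likelihood ratio
#'
#' Mean over the in-frame (codon-step) hexamers of
#' `log2(coding_freq / noncoding_freq)`, in bits. The frame is that of the
#' transcript's longest ORF (frame 0 if the sequence has none). Positive
#' values indicate coding-like hexamer usage.
#'
#' @param seq Nucleotide string.
#' @param coding_freq,noncoding_freq Named numeric vectors over all 4096
#'   hexamers (probabilities including pseudocounts, see [hexamer_table()]).
#' @return A single numeric LLR in bits (0 if the sequence has no complete
#'   in-frame hexamer).
#' @export
hexamer_llr <- function(seq, coding_freq, noncoding_freq) {
  seq <- toupper(seq)
  if (length(coding_freq) != 4096L || length(noncoding_freq) != 4096L ||
      any(coding_freq <= 0) || any(noncoding_freq <= 0)) {
    abort("hexamer tables must cover all 4096 hexamers with positive frequencies")
  }
  orf <- find_longest_orf(seq)
  frame <- if (orf$has_start) orf$frame else 0L
  n <- nchar(seq)
  starts <- seq.int(frame + 1L, by = 3L, length.out = max(0L, (n - frame - 5L) %/% 3L + 1L))
  starts <- starts[starts + 5L <= n]
  if (!length(starts)) return(0)
  hex <- substring(seq, starts, starts + 5L)
  hex <- hex[!grepl("[^ACGT]", hex)]
  if (!length(hex)) return(0)
  mean(log2(coding_freq[hex] / noncoding_freq[hex]))
}

#' Hexamer frequency table from training sequences
#'
#' Counts frame-0 codon-step hexamers over the training set and converts to
#' probabilities with a pseudocount on all 4096 hexamers.
#'
#' @param seqs Character vector of training sequences.
#' @param pseudocount Added to every hexamer count (default 1).
#' @return Named numeric vector of 4096 probabilities.
#' @export
hexamer_table <- function(seqs, pseudocount = 1) {
  all_hex <- all_hexamers()
  counts <- setNames(numeric(4096L), all_hex)
  for (s in toupper(seqs)) {
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, by = 3L, length.out = (n - 5L) %/% 3L + 1L)
    hex <- substring(s, starts, starts + 5L)
    hex <- hex[!grepl("[^ACGT]", hex)]
    tb <- table(hex)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

#' Default hexamer models
#'
#' Analytic tables matching the synthetic-data generator's emission models:
#' the coding table is the product of the generator's codon-usage
#' probabilities over two in-frame codons; the noncoding table is the product
#' of its noncoding base-composition probabilities. Real analyses should
#' train [hexamer_table()] on organism-specific CDS/noncoding sets instead.
#'
#' @return List with elements `coding` and `noncoding`, each a named numeric
#'   vector of 4096 probabilities.
#' @export
default_hexamer_tables <- function() {
  hex <- all_hexamers()
  cu <- sim_codon_usage()
  codon1 <- substr(hex, 1L, 3L)
  codon2 <- substr(hex, 4L, 6L)
  coding <- unname(cu[codon1] * cu[codon2])
  coding[is.na(coding)] <- 0
  coding <- coding + 1e-6
  coding <- coding / sum(coding)
  bp <- sim_noncoding_base_probs()
  mat <- matrix(unlist(strsplit(hex, "")), ncol = 6L, byrow = TRUE)
  noncoding <- apply(mat, 1L, function(r) prod(bp[r]))
  noncoding <- noncoding / sum(noncoding)
  list(coding = setNames(coding, hex), noncoding = setNames(noncoding, hex))
}

# ---- protein motif scan ----------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_frames <- function(seq) {
  seq <- toupper(seq)
  tab <- codon_table()
  lapply(0:2, function(f) {
    n <- nchar(seq)
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) return("")
    codons <- substring(seq, f + 1L + 3L * (seq_len(ncod) - 1L),
                        f + 3L * seq_len(ncod))
    aa <- tab[codons]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  })
}

#' Scan translated frames against a protein motif database
#'
#' Translates the three forward frames and slides each motif's position
#' weight matrix (log-odds over the 20 amino acids) along them; any window
#' scoring at or above the motif's threshold is a hit. Windows containing a
#' stop or ambiguous residue are skipped.
#'
#' @param seq Nucleotide string.
#' @param motif_db A list of motifs, each `list(name, pwm, threshold)` with
#'   `pwm` a 20-row (amino-acid named) numeric matrix.
#' @return List: `hit` (logical) and `hits`, a tibble of
#'   `motif`, `frame`, `offset_aa`, `score`.
#' @export
domain_scan <- function(seq, motif_db = synthetic_motif_db()) {
  if (!length(motif_db)) abort("domain_scan: empty motif database")
  for (m in motif_db) {
    if (!all(is.finite(m$pwm))) {
      abort(sprintf("motif '%s' has non-finite PWM entries", m$name))
    }
  }
  frames <- translate_frames(seq)
  hits <- list()
  for (f in 0:2) {
    aa <- strsplit(frames[[f + 1L]], "", fixed = TRUE)[[1L]]
    for (m in motif_db) {
      w <- ncol(m$pwm)
      if (length(aa) < w) next
      for (off in seq_len(length(aa) - w + 1L)) {
        win <- match(aa[off:(off + w - 1L)], rownames(m$pwm))
        if (anyNA(win)) next
        s <- sum(m$pwm[cbind(win, seq_len(w))])
        if (s >= m$threshold) {
          hits[[length(hits) + 1L]] <-
            tibble(motif = m$name, frame = f, offset_aa = off - 1L, score = s)
        }
      }
    }
  }
  hits <- if (length(hits)) bind_rows(hits) else
    tibble(motif = character(), frame = integer(), offset_aa = integer(),
           score = numeric())
  list(hit = nrow(hits) > 0L, hits = hits)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic protein-motif database
#'
#' A small database of consensus-peptide PWMs standing in for a curated
#' domain library (which is external data outside this package's scope).
#' Each motif scores +2 for its consensus residue and -1 otherwise; the
#' threshold requires near-consensus windows, so random peptides essentially
#' never hit. The synthetic-data generator plants these consensus peptides
#' into its domain-bearing decoy transcripts.
#'
#' @return A motif list usable by [domain_scan()].
#' @export
synthetic_motif_db <- function() {
  consensi <- c(
    domA = "WHDEKRCWQYML",
    domB = "FYWHPKDERNCQ",
    domC = "MKWCHRYDEQFP"
  )
  lapply(names(consensi), function(nm) {
    aa <- strsplit(consensi[[nm]], "", fixed = TRUE)[[1L]]
    pwm <- matrix(-1, nrow = 20L, ncol = length(aa),
                  dimnames = list(AA20, NULL))
    pwm[cbind(match(aa, AA20), seq_along(aa))] <- 2
    # consensus scores 24; >= 18 means at most two non-consensus residues
    list(name = nm, pwm = pwm, threshold = 18)
  })
}

#' Consensus coding-potential verdict
#'
#' A transcript is called noncoding only if all three predictors agree
#' (longest ORF below `orf_cutoff`, Fickett score below `fickett_cutoff`,
#' hexamer LLR below 0 bits) and the motif scan finds no conserved domain —
#' the intersection rule under which the confident set is smaller than any
#' single predictor's.
#'
#' @param seqs Named character vector of transcript sequences.
#' @param cfg A [pipeline_config()].
#' @param tables Hexamer tables (list with `coding`, `noncoding`); default
#'   [default_hexamer_tables()].
#' @param motif_db Motif database; default [synthetic_motif_db()].
#' @return Tibble: `transcript_id`, `orf_score` (nt), `fickett`, `hexamer`
#'   (bits), `domain_hit`, `noncoding`.
#' @export
coding_verdicts <- function(seqs, cfg = pipeline_config(),
                            tables = default_hexamer_tables(),
                            motif_db = synthetic_motif_db()) {
  stopifnot(!is.null(names(seqs)))
  rows <- purrr::map(names(seqs), function(id) {
    s <- seqs[[id]]
    orf <- find_longest_orf(s)
    fick <- if (nchar(s) >= 200L) fickett_score(s) else 0
    hex <- hexamer_llr(s, tables$coding, tables$noncoding)
    dom <- domain_scan(s, motif_db)$hit
    tibble(
      transcript_id = id,
      orf_score = orf$length_nt,
      fickett = fick,
      hexamer = hex,
      domain_hit = dom,
      noncoding = orf$length_nt < cfg$orf_cutoff &
        fick < cfg$fickett_cutoff & hex < 0 & !dom
    )
  })
  bind_rows(rows)
}
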