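# Synthetic-data generator: builds a genome, annotation, truth-labeled
# candidate transcripts, negative-binomial counts, miRNAs with planted sites
# and a rearranged ortholog genome, so every pipeline stage can be tested
# against known ground truth without any external download.

#' Simulation parameters
#'
#' Defaults define the study conditions the generator emulates: a 3-stage x
#' 3-replicate strand-specific design, candidate transcripts of every
#' positional class plus structured decoys, negative-binomial counts with
#' `variance = mu + dispersion * mu^2`, systematically lower lncRNA than
#' mRNA expression, six stage-profile archetypes, planted miRNA
#' complementarity, and a rearranged second genome with planted positionally
#' conserved and non-conserved lncRNAs.
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param genes_per_chrom Reference genes per chromosome (default 70).
#' @param noncoding_gene_frac Fraction of reference genes that are noncoding
#'   (default 0.1).
#' @param n_u,n_i,n_o,n_x,n_eq Candidates per intended class code.
#' @param n_short,n_mono,n_lowexpr,n_codinglike,n_domain Decoy candidates:
#'   shorter than 200 nt, single-exon, never-expressed, ORF-bearing
#'   coding-like, and domain-motif-bearing.
#' @param nb_dispersion NB dispersion alpha (default 0.1).
#' @param lnc_mu,mrna_mu Log-normal location of base means; the ~20-fold gap
#'   mirrors the systematically lower expression of lncRNAs.
#' @param de_frac Fraction of lncRNA candidates assigned a non-flat stage
#'   archetype (default 0.5).
#' @param mrna_de_frac Same for mRNAs (default 0.2).
#' @param n_mirna_planted,n_mirna_decoy Planted and decoy miRNAs.
#' @param n_pos_conserved,n_pos_nonconserved Planted positionally conserved
#'   and non-conserved lncRNAs.
#' @param n_inversions,n_translocations,n_random_deletions Rearrangement
#'   operations applied to the ortholog genome.
#' @param rearrange_window Genes per inversion/translocation segment; kept
#'   larger than twice the synteny `max_gap` so that a collinear chain can
#'   neither step across a rearranged segment nor tunnel through it on a
#'   single interior anchor, making blocks coincide with the constructed
#'   segments (default 52).
#' @param rng_seed Master seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_chroms = 2L,
                              genes_per_chrom = 160L,
                              noncoding_gene_frac = 0.1,
                              n_u = 180L, n_i = 60L, n_o = 70L, n_x = 70L,
                              n_eq = 40L,
                              n_short = 40L, n_mono = 40L, n_lowexpr = 40L,
                              n_codinglike = 40L, n_domain = 20L,
                              nb_dispersion = 0.1,
                              lnc_mu = 100, mrna_mu = 2000,
                              de_frac = 0.5, mrna_de_frac = 0.2,
                              n_mirna_planted = 8L, n_mirna_decoy = 5L,
                              n_pos_conserved = 6L, n_pos_nonconserved = 3L,
                              n_inversions = 2L, n_translocations = 1L,
                              n_random_deletions = 4L,
                              rearrange_window = 52L,
                              rng_seed = 20260101L) {
  p <- as.list(environment())
  stopifnot(p$nb_dispersion > 0, p$genes_per_chrom >= 10L)
  class(p) <- "simulation_params"
  p
}

# base emission models ------------------------------------------------------

sim_noncoding_base_probs <- function() {
  c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
}

# codon usage with strong positional bias (GC-leaning 1st/3rd positions),
# stop codons excluded; makes coding sequences separable by period-3
# statistics and hexamer usage by construction
sim_codon_usage <- function() {
  p1 <- c(A = 0.15, C = 0.25, G = 0.40, T = 0.20)
  p2 <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  p3 <- c(A = 0.10, C = 0.40, G = 0.40, T = 0.10)
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  w <- as.vector(outer(outer(p1, p2), p3))
  names(w) <- codons
  w <- w[!names(w) %in% c("TAA", "TAG", "TGA")]
  w / sum(w)
}

rand_seq <- function(n, probs = sim_noncoding_base_probs()) {
  if (n <= 0L) return("")
  paste0(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

rand_codons <- function(n) {
  cu <- sim_codon_usage()
  paste0(sample(names(cu), n, replace = TRUE, prob = cu), collapse = "")
}

# cap ATG-initiated stop-free stretches below `cap` nt by inserting stops
disrupt_orfs <- function(seq, cap = 240L) {
  for (iter in 1:40) {
    orf <- find_longest_orf(seq)
    if (!orf$has_start || orf$length_nt < cap) return(seq)
    at <- orf$start + 3L * min(25L, (orf$length_nt %/% 3L) %/% 2L)
    substr(seq, at + 1L, at + 3L) <- "TAA"
  }
  seq
}

# noncoding sequence with verified noncoding-side margins on all predictors
designed_noncoding <- function(n, tables) {
  for (try in 1:30) {
    s <- disrupt_orfs(rand_seq(n))
    if (find_longest_orf(s)$length_nt >= 270L) next
    if (n >= 200L && fickett_score(s) >= 0.70) next
    if (hexamer_llr(s, tables$coding, tables$noncoding) >= -0.02) next
    return(s)
  }
  abort("designed_noncoding: could not satisfy constraints")
}

# coding sequence: short UTRs flanking a clean ORF of >= 100 codons
designed_coding <- function(total_len, tables) {
  stopifnot(total_len >= 380L)
  utr5 <- 30L
  ncod <- max(100L, (total_len - utr5 - 30L - 6L) %/% 3L)
  utr3 <- total_len - utr5 - 6L - 3L * ncod
  paste0(designed_noncoding(utr5, tables), "ATG", rand_codons(ncod), "TAA",
         if (utr3 > 0L) designed_noncoding(utr3, tables) else "")
}

aa_to_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  vapply(strsplit(aa, "", fixed = TRUE)[[1L]],
         function(a) names(gc)[gc == a][1L], character(1L))
}

# ---- world construction ----------------------------------------------------

new_world <- function() {
  list(pieces = list(), genes = list(), free = list(), introns1 = list())
}

#' Simulate a complete study
#'
#' Runs every generator in a fixed order under the master seed and returns
#' the genome, reference annotation, truth-labeled candidate transcripts
#' with spliced sequences, the count matrix and design, miRNAs, the
#' rearranged ortholog genome, and the full truth bundle.
#'
#' @param params A [simulation_params()].
#' @return A `lnc_simulation` list; see the package vignette for the
#'   component-by-component description.
#' @export
simulate_study <- function(params = simulation_params()) {
  set.seed(params$rng_seed)
  tables <- default_hexamer_tables()

  w <- build_genes(params, tables)
  w <- place_candidates(w, params, tables)
  genome <- assemble_genome(w)
  ann <- annotation(w$ref_exons, biotypes = w$biotypes)
  genome <- verify_candidates(w, genome, params, tables)

  cand_seqs <- spliced_sequences(w$cand_exons, genome)
  mir <- plant_mirnas(w, genome, cand_seqs, params, tables)
  genome <- mir$genome
  cand_seqs <- spliced_sequences(w$cand_exons, genome)
  ref_seqs <- spliced_sequences(w$ref_exons, genome)

  cnt <- generate_counts(
    count_features(w, ann), params
  )
  # enforce the planted expression regimes against the realized FPKM
  cnt <- enforce_fpkm_regimes(cnt, w, params)

  ortho <- generate_ortholog_genome(ann, lincRNA_loci(w), params)

  truth <- list(
    classes = w$truth_classes,
    coding = w$truth_coding,
    cascade = cascade_truth(w),
    de = cnt$de_truth,
    clusters = cnt$cluster_truth,
    cerna = mir$cerna_truth,
    mirna_decoys = mir$decoy_ids,
    positional = ortho$positional_truth
  )
  structure(list(
    params = params,
    genome = genome,
    ann = ann,
    candidates = w$cand_exons,
    cand_seqs = cand_seqs,
    ref_seqs = ref_seqs,
    expr = cnt$expr,
    archetypes = cnt$archetypes,
    mirnas = mir$mirnas,
    ortho = ortho,
    truth = truth
  ), class = "lnc_simulation")
}

#' @export
print.lnc_simulation <- function(x, ...) {
  cat(sprintf(
    "<lnc_simulation> %d candidates, %d reference genes, %d miRNAs, %d counted features\n",
    length(unique(x$candidates$transcript_id)), nrow(x$ann$genes),
    length(x$mirnas), nrow(x$expr$counts)))
  invisible(x)
}

build_genes <- function(params, tables) {
  pieces <- list(); genes <- list(); free <- list(); introns1 <- list()
  ref_exons <- list(); biotypes <- list()
  gid <- 0L
  for (ci in seq_len(params$n_chroms)) {
    chrom <- paste0("chr", ci)
    cursor <- 15000L
    for (g in seq_len(params$genes_per_chrom)) {
      gid <- gid + 1L
      id <- sprintf("G%04d", gid)
      biotype <- if (runif(1) < params$noncoding_gene_frac) "noncoding" else "coding"
      n_ex <- sample(2:4, 1L)
      ex_lens <- sample(150:400, n_ex, replace = TRUE)
      while (sum(ex_lens) < 420L) ex_lens[n_ex] <- ex_lens[n_ex] + 100L
      in_lens <- c(sample(1600:2600, 1L),
                   if (n_ex > 2L) sample(300:900, n_ex - 2L) else integer())
      starts <- cursor + c(0L, cumsum(ex_lens[-n_ex] + in_lens))
      ends <- starts + ex_lens
      strand <- sample(c("+", "-"), 1L)
      spliced_len <- sum(ex_lens)
      spliced <- if (biotype == "coding") {
        designed_coding(spliced_len, tables)
      } else {
        designed_noncoding(spliced_len, tables)
      }
      genomic <- if (strand == "+") spliced else revcomp(spliced)
      cum <- c(0L, cumsum(ex_lens))
      for (e in seq_len(n_ex)) {
        pieces[[length(pieces) + 1L]] <- list(
          chrom = chrom, start = starts[e], end = ends[e],
          seq = substr(genomic, cum[e] + 1L, cum[e + 1L])
        )
      }
      tx_id <- paste0(id, ".1")
      ref_exons[[gid]] <- tibble(chrom = chrom, start = starts, end = ends,
                                 strand = strand, transcript_id = tx_id,
                                 gene_id = id)
      biotypes[[gid]] <- tibble(gene_id = id, biotype = biotype)
      introns1[[gid]] <- list(chrom = chrom, start = ends[1L],
                              end = starts[2L], gene = id, used = FALSE)
      gene_start <- starts[1L]; gene_end <- ends[n_ex]
      genes[[gid]] <- list(id = id, chrom = chrom, start = gene_start,
                           end = gene_end, strand = strand,
                           biotype = biotype, spliced = spliced,
                           first_exon = c(starts[1L], ends[1L]),
                           last_exon = c(starts[n_ex], ends[n_ex]),
                           exons = ref_exons[[gid]])
      gap <- sample(12000:24000, 1L)
      # first/last 3 kb of each gap are reserved for overlap candidates
      free[[length(free) + 1L]] <- list(chrom = chrom,
                                        start = gene_end + 3000L,
                                        end = gene_end + gap - 3000L)
      cursor <- gene_end + gap
    }
  }
  list(pieces = pieces, genes = genes, free = free, introns1 = introns1,
       ref_exons = bind_rows(ref_exons), biotypes = bind_rows(biotypes))
}

alloc_space <- function(w, chrom, len) {
  fits <- which(vapply(w$free, function(f) {
    (is.null(chrom) || f$chrom == chrom) && f$end - f$start >= len + 600L
  }, logical(1L)))
  if (!length(fits)) {
    abort("simulate_study: ran out of intergenic space; increase gap sizes")
  }
  k <- if (length(fits) == 1L) fits else sample(fits, 1L)
  f <- w$free[[k]]
  s <- f$start + 300L
  w$free[[k]]$start <- s + len + 300L
  list(w = w, chrom = f$chrom, start = s)
}

# build a multi-exon candidate wholly inside free space, writing designed
# sequence pieces for every exon
make_free_candidate <- function(w, id, ex_lens, in_lens, tables,
                                content = "noncoding") {
  span <- sum(ex_lens) + sum(in_lens)
  a <- alloc_space(w, NULL, span)
  w <- a$w
  starts <- a$start + c(0L, cumsum(ex_lens[-length(ex_lens)] + in_lens))
  ends <- starts + ex_lens
  strand <- sample(c("+", "-"), 1L)
  spliced <- switch(content,
    noncoding = designed_noncoding(sum(ex_lens), tables),
    coding = designed_coding(sum(ex_lens), tables),
    domain = designed_domain(sum(ex_lens), tables)
  )
  genomic <- if (strand == "+") spliced else revcomp(spliced)
  cum <- c(0L, cumsum(ex_lens))
  for (e in seq_along(ex_lens)) {
    w$pieces[[length(w$pieces) + 1L]] <- list(
      chrom = a$chrom, start = starts[e], end = ends[e],
      seq = substr(genomic, cum[e] + 1L, cum[e + 1L])
    )
  }
  exons <- tibble(chrom = a$chrom, start = starts, end = ends,
                  strand = strand, transcript_id = id, gene_id = id)
  list(w = w, exons = exons)
}

# noncoding-background sequence carrying a short ORF (< 100 codons) whose
# peptide contains a motif-database consensus
designed_domain <- function(total_len, tables) {
  db <- synthetic_motif_db()
  m <- db[[sample(length(db), 1L)]]
  cons <- paste0(rownames(m$pwm)[apply(m$pwm, 2L, which.max)], collapse = "")
  cod <- aa_to_codons(cons)
  n_pad <- 55L  # flanking codons; ORF total 55+12+1+1 codons < 100
  neutral <- function(k) {
    cu <- sim_codon_usage()
    flat <- rep(1 / length(cu), length(cu))
    paste0(sample(names(cu), k, replace = TRUE, prob = flat), collapse = "")
  }
  orf <- paste0("ATG", neutral(20L), paste0(cod, collapse = ""),
                neutral(n_pad - 20L), "TAA")
  rest <- total_len - nchar(orf)
  stopifnot(rest >= 60L)
  n5 <- rest %/% 2L
  paste0(designed_noncoding(n5, tables), orf,
         designed_noncoding(rest - n5, tables))
}

place_candidates <- function(w, params, tables) {
  cand <- list(); classes <- list(); coding <- list()
  add <- function(exons, role, class, coding_label) {
    cand[[length(cand) + 1L]] <<- exons
    classes[[length(classes) + 1L]] <<-
      tibble(transcript_id = exons$transcript_id[1L], role = role,
             class = class)
    coding[[length(coding) + 1L]] <<-
      tibble(transcript_id = exons$transcript_id[1L], label = coding_label)
  }
  two_exons <- function(total) {
    e1 <- sample(150:max(151L, total - 200L), 1L)
    c(e1, total - e1)
  }

  # intergenic candidates and decoys
  mk_free <- function(n, prefix, role, content, len_range, n_ex_fun) {
    for (k in seq_len(n)) {
      id <- sprintf("%s%04d", prefix, k)
      total <- sample(len_range[1L]:len_range[2L], 1L)
      ex_lens <- n_ex_fun(total)
      in_lens <- if (length(ex_lens) > 1L) {
        sample(150:400, length(ex_lens) - 1L, replace = TRUE)
      } else integer()
      res <- make_free_candidate(w, id, ex_lens, in_lens, tables, content)
      w <<- res$w
      # every free-space candidate is intergenic, hence class 'u'
      add(res$exons, role, "u",
          if (content %in% c("coding", "domain")) "coding" else "noncoding")
    }
  }
  mk_free(params$n_u, "LNCU", "u", "noncoding", c(400L, 1200L),
          function(tot) {
            if (tot >= 800L && runif(1) < 0.5) {
              e <- sample(150:240, 2L, replace = TRUE)
              c(e, tot - sum(e))
            } else {
              two_exons(tot)
            }
          })
  mk_free(params$n_short, "DSHT", "short", "noncoding", c(120L, 180L),
          function(tot) c(60L, tot - 60L))
  mk_free(params$n_mono, "DMON", "mono", "noncoding", c(400L, 800L),
          function(tot) tot)
  mk_free(params$n_lowexpr, "DLOW", "lowexpr", "noncoding", c(400L, 1000L),
          two_exons)
  mk_free(params$n_codinglike, "DCOD", "codinglike", "coding", c(500L, 900L),
          two_exons)
  mk_free(params$n_domain, "DDOM", "domain", "domain", c(520L, 900L),
          two_exons)

  # intronic candidates: inside the first (long) intron of a gene
  intron_ids <- sample(seq_along(w$introns1))
  placed_i <- 0L
  for (k in intron_ids) {
    if (placed_i >= params$n_i) break
    it <- w$introns1[[k]]
    if (it$end - it$start < 1500L) next
    placed_i <- placed_i + 1L
    id <- sprintf("LNCI%04d", placed_i)
    ex_lens <- c(sample(250:350, 1L), sample(200:300, 1L))
    in_len <- sample(180:280, 1L)
    s <- it$start + 120L
    starts <- s + c(0L, ex_lens[1L] + in_len)
    ends <- starts + ex_lens
    stopifnot(ends[2L] <= it$end - 120L)
    strand <- sample(c("+", "-"), 1L)
    spliced <- designed_noncoding(sum(ex_lens), tables)
    genomic <- if (strand == "+") spliced else revcomp(spliced)
    cum <- c(0L, cumsum(ex_lens))
    for (e in 1:2) {
      w$pieces[[length(w$pieces) + 1L]] <- list(
        chrom = it$chrom, start = starts[e], end = ends[e],
        seq = substr(genomic, cum[e] + 1L, cum[e + 1L])
      )
    }
    add(tibble(chrom = it$chrom, start = starts, end = ends, strand = strand,
               transcript_id = id, gene_id = id),
        "i", "i", "noncoding")
  }
  if (placed_i < params$n_i) abort("could not place all intronic candidates")

  # sense ('o') and antisense ('x') overlap candidates
  stopifnot(params$n_o <= length(w$genes), params$n_x <= length(w$genes))
  o_genes <- sample(seq_along(w$genes), params$n_o)
  x_genes <- sample(seq_along(w$genes), params$n_x)
  for (k in seq_len(params$n_o)) {
    g <- w$genes[[o_genes[k]]]
    id <- sprintf("LNCO%04d", k)
    ov <- sample(60:140, 1L)
    ext1 <- sample(150:300, 1L)
    e1s <- g$last_exon[2L] - ov
    e1e <- g$last_exon[2L] + ext1
    in_len <- sample(200:350, 1L)
    e2len <- sample(200:350, 1L)
    e2s <- e1e + in_len
    e2e <- e2s + e2len
    stopifnot(e2e <= g$end + 2900L)
    w$pieces[[length(w$pieces) + 1L]] <- list(
      chrom = g$chrom, start = g$end, end = e1e,
      seq = private_overlap_seq(g, ext1, tables, where = "after")
    )
    w$pieces[[length(w$pieces) + 1L]] <- list(
      chrom = g$chrom, start = e2s, end = e2e,
      seq = designed_noncoding(e2len, tables)
    )
    add(tibble(chrom = g$chrom, start = c(e1s, e2s), end = c(e1e, e2e),
               strand = g$strand, transcript_id = id, gene_id = id),
        "o", "o", "noncoding")
  }
  for (k in seq_len(params$n_x)) {
    g <- w$genes[[x_genes[k]]]
    id <- sprintf("LNCX%04d", k)
    ov <- sample(60:140, 1L)
    ext1 <- sample(150:300, 1L)
    e1s <- g$start - ext1
    e1e <- g$start + ov
    in_len <- sample(200:350, 1L)
    e2len <- sample(200:350, 1L)
    e2e <- e1s - in_len
    e2s <- e2e - e2len
    stopifnot(e2s >= g$start - 2900L)
    w$pieces[[length(w$pieces) + 1L]] <- list(
      chrom = g$chrom, start = e1s, end = g$start,
      seq = private_overlap_seq(g, ext1, tables, where = "before")
    )
    w$pieces[[length(w$pieces) + 1L]] <- list(
      chrom = g$chrom, start = e2s, end = e2e,
      seq = designed_noncoding(e2len, tables)
    )
    strand <- if (g$strand == "+") "-" else "+"
    add(tibble(chrom = g$chrom, start = c(e2s, e1s), end = c(e2e, e1e),
               strand = strand, transcript_id = id, gene_id = id),
        "x", "x", "noncoding")
  }

  # '=' candidates: exact copies of coding reference transcripts
  coding_genes <- which(vapply(w$genes, function(g) g$biotype == "coding",
                               logical(1L)))
  eq_src <- sample(coding_genes, params$n_eq)
  for (k in seq_len(params$n_eq)) {
    g <- w$genes[[eq_src[k]]]
    id <- sprintf("EQTX%04d", k)
    ex <- g$exons %>% mutate(transcript_id = id, gene_id = id)
    add(ex, "eq", "=", "coding")
  }

  w$cand_exons <- bind_rows(cand)
  w$truth_classes <- bind_rows(classes)
  w$truth_coding <- bind_rows(coding)
  w
}

# designed sequence for the private extension of an overlap candidate;
# plain noncoding content, placed as genomic strand content
private_overlap_seq <- function(g, len, tables, where) {
  designed_noncoding(len, tables)
}

assemble_genome <- function(w) {
  piece_tbl <- bind_rows(lapply(w$pieces, function(p) {
    tibble(chrom = p$chrom, start = p$start, end = p$end, seq = p$seq)
  }))
  chroms <- sort(unique(c(piece_tbl$chrom, w$ref_exons$chrom)))
  out <- setNames(character(length(chroms)), chroms)
  for (ch in chroms) {
    pt <- piece_tbl %>% filter(.data$chrom == ch) %>% arrange(.data$start)
    stopifnot(all(pt$start[-1L] >= pt$end[-nrow(pt)]))
    chunks <- character(2L * nrow(pt) + 1L)
    cursor <- 0L
    for (i in seq_len(nrow(pt))) {
      chunks[2L * i - 1L] <- rand_seq(pt$start[i] - cursor)
      chunks[2L * i] <- pt$seq[i]
      cursor <- pt$end[i]
    }
    chunks[2L * nrow(pt) + 1L] <- rand_seq(15000L)
    out[ch] <- paste0(chunks, collapse = "")
  }
  out
}

# post-assembly check that every candidate's full spliced sequence meets its
# intended coding-potential profile; overlap candidates inherit reference
# sequence, so failures are patched by regenerating private pieces
verify_candidates <- function(w, genome, params, tables) {
  seqs <- spliced_sequences(w$cand_exons, genome)
  roles <- w$truth_classes
  for (r in seq_len(nrow(roles))) {
    id <- roles$transcript_id[r]
    role <- roles$role[r]
    if (role %in% c("eq", "short", "mono")) next
    s <- seqs[[id]]
    ok <- function(s) {
      orf_ok <- find_longest_orf(s)$length_nt < 300L
      fick_ok <- nchar(s) < 200L || fickett_score(s) < pipeline_config()$fickett_cutoff
      hex_ok <- hexamer_llr(s, tables$coding, tables$noncoding) < 0
      if (role == "codinglike") {
        find_longest_orf(s)$length_nt >= 300L
      } else if (role == "domain") {
        orf_ok && fick_ok && hex_ok && domain_scan(s)$hit
      } else {
        orf_ok && fick_ok && hex_ok && !domain_scan(s)$hit
      }
    }
    if (ok(s)) next
    # patch: regenerate the candidate's own (non-reference) sequence content
    ex <- w$cand_exons %>% filter(.data$transcript_id == id) %>%
      arrange(.data$start)
    fixed <- FALSE
    for (try in 1:25) {
      if (role %in% c("o", "x")) {
        # regenerate only the private (non-overlapping) region
        priv <- private_region(ex, w)
        repl <- designed_noncoding(priv$end - priv$start, tables)
        gseq <- if (ex$strand[1L] == "+") repl else revcomp(repl)
        substr(genome[[priv$chrom]], priv$start + 1L, priv$end) <- gseq
      } else {
        total <- sum(ex$end - ex$start)
        spliced <- switch(role,
          codinglike = designed_coding(total, tables),
          domain = designed_domain(total, tables),
          designed_noncoding(total, tables)
        )
        genomic <- if (ex$strand[1L] == "+") spliced else revcomp(spliced)
        cum <- c(0L, cumsum(ex$end - ex$start))
        for (e in seq_len(nrow(ex))) {
          substr(genome[[ex$chrom[e]]], ex$start[e] + 1L, ex$end[e]) <-
            substr(genomic, cum[e] + 1L, cum[e + 1L])
        }
      }
      s2 <- spliced_sequences(ex, genome)[[id]]
      if (ok(s2)) { fixed <- TRUE; break }
    }
    if (!fixed) abort(sprintf("could not stabilize candidate %s (%s)", id, role))
  }
  genome
}

# the portion of an overlap candidate outside every reference exon
private_region <- function(ex, w) {
  chrom <- ex$chrom[1L]
  span <- c(min(ex$start), max(ex$end))
  ref <- w$ref_exons %>% filter(.data$chrom == chrom)
  lo <- span[1L]; hi <- span[2L]
  for (i in seq_len(nrow(ref))) {
    if (ref$start[i] < hi && ref$end[i] > lo) {
      if (ref$end[i] >= lo && ref$start[i] <= lo) lo <- ref$end[i]
      if (ref$start[i] <= hi && ref$end[i] >= hi) hi <- ref$start[i]
    }
  }
  list(chrom = chrom, start = lo, end = hi)
}

cascade_truth <- function(w) {
  spans <- transcript_spans(w$cand_exons)
  w$truth_classes %>%
    left_join(spans, by = "transcript_id") %>%
    mutate(expected_stage = dplyr::case_when(
      !.data$class %in% c("u", "i", "o", "x") ~ "class",
      .data$length < 200L ~ "length",
      .data$n_exons < 2L ~ "exons",
      .data$role == "lowexpr" ~ "fpkm",
      .data$role %in% c("codinglike", "domain") ~ "coding",
      TRUE ~ "retained"
    )) %>%
    select("transcript_id", "role", "class", "expected_stage")
}

# ---- counts ---------------------------------------------------------------

sim_archetypes <- function() {
  list(`1` = c(1, 1, 6), `2` = c(1, 3, 9), `3` = c(1, 1, 1),
       `4` = c(9, 3, 1), `5` = c(6, 1, 1), `6` = c(1, 6, 1))
}

count_features <- function(w, ann) {
  spans <- transcript_spans(w$cand_exons)
  cand <- w$truth_classes %>%
    left_join(spans %>% select("transcript_id", "length"), by = "transcript_id") %>%
    mutate(group = dplyr::case_when(
      .data$role == "lowexpr" ~ "lowexpr",
      .data$role %in% c("eq", "codinglike") ~ "mRNA_like",
      TRUE ~ "lnc"
    )) %>%
    select(feature = "transcript_id", "length", "group")
  refs <- ann$transcripts %>%
    left_join(ann$genes %>% select("gene_id", "biotype"), by = "gene_id") %>%
    mutate(group = ifelse(.data$biotype == "coding", "mRNA", "lnc")) %>%
    select(feature = "transcript_id", "length", "group")
  bind_rows(cand, refs)
}

#' Generate negative-binomial counts for a 3-stage design
#'
#' Each feature gets a base mean (log-normal, with lncRNA-labeled features
#' systematically ~20-fold below mRNA-labeled ones) and one of six stage
#' archetypes (three stage-peaked profiles, monotone up, monotone down,
#' flat); counts for 3 stages x 3 replicates are drawn from
#' `NB(mu = base * archetype[stage] * depth_j, var = mu + alpha mu^2)`.
#' Differential-expression truth per pairwise contrast follows from the
#' archetype ratios.
#'
#' @param features Tibble `feature`, `length`, `group` with group one of
#'   `mRNA`, `mRNA_like`, `lnc`, `lowexpr`.
#' @param params A [simulation_params()].
#' @return List: `expr` (an [expression_matrix()]), `archetypes`,
#'   `de_truth` (`feature`, `contrast`, `direction`), `cluster_truth`.
#' @export
generate_counts <- function(features, params = simulation_params()) {
  stages <- c("S1", "S2", "S3")
  design <- tibble(
    sample = paste0(rep(stages, each = 3L), "_r", rep(1:3, 3L)),
    stage = rep(stages, each = 3L),
    replicate = rep(1:3, 3L)
  )
  arch <- sim_archetypes()
  n <- nrow(features)
  base_mu <- numeric(n)
  for (g in unique(features$group)) {
    idx <- which(features$group == g)
    base_mu[idx] <- switch(g,
      mRNA = , mRNA_like = exp(rnorm(length(idx), log(params$mrna_mu), 0.5)),
      lnc = exp(rnorm(length(idx), log(params$lnc_mu), 0.5)),
      lowexpr = 0.03
    )
  }
  de_ok <- features$group %in% c("lnc", "mRNA", "mRNA_like")
  de_frac <- ifelse(features$group == "lnc", params$de_frac, params$mrna_de_frac)
  is_de <- de_ok & runif(n) < de_frac
  archetype <- ifelse(is_de, sample(c(1L, 2L, 4L, 5L, 6L), n, replace = TRUE), 3L)
  depth <- runif(9L, 0.85, 1.2)
  mult <- do.call(rbind, arch[as.character(archetype)])
  counts <- matrix(0L, n, 9L, dimnames = list(features$feature, design$sample))
  for (j in seq_len(9L)) {
    stage_idx <- match(design$stage[j], stages)
    mu <- base_mu * mult[, stage_idx] * depth[j]
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / params$nb_dispersion)
  }
  lib_sizes <- setNames(round(2e7 * depth), design$sample)
  lib_sizes <- pmax(lib_sizes, colSums(counts))
  expr <- expression_matrix(counts, lib_sizes,
                            setNames(features$length, features$feature), design)
  contrasts <- list(S1_S2 = c(1L, 2L), S1_S3 = c(1L, 3L), S2_S3 = c(2L, 3L))
  de_truth <- purrr::imap(contrasts, function(cidx, nm) {
    lr <- log2(mult[, cidx[2L]] / mult[, cidx[1L]])
    tibble(feature = features$feature,
           contrast = nm,
           direction = ifelse(abs(lr) < 1, "null",
                              ifelse(lr > 0, "up", "down")),
           log2fc_true = lr)
  }) %>% bind_rows()
  de_truth$direction[features$group[match(de_truth$feature, features$feature)] ==
                       "lowexpr"] <- "null"
  list(
    expr = expr,
    archetypes = tibble(feature = features$feature, group = features$group,
                        archetype = archetype, base_mu = base_mu),
    de_truth = de_truth,
    cluster_truth = tibble(feature = features$feature,
                           archetype = archetype)[is_de, ]
  )
}

# redraw count rows whose realized FPKM contradicts the planted regime
enforce_fpkm_regimes <- function(cnt, w, params) {
  expr <- cnt$expr
  fk <- fpkm(expr)
  arch <- sim_archetypes()
  roles <- setNames(w$truth_classes$role, w$truth_classes$transcript_id)
  for (f in rownames(expr$counts)) {
    role <- roles[f]
    if (is.na(role)) next
    target_low <- role == "lowexpr"
    bad <- if (target_low) max(fk[f, ]) >= 0.1 else max(fk[f, ]) < 0.1
    tries <- 0L
    while (bad && tries < 50L) {
      tries <- tries + 1L
      a <- cnt$archetypes[cnt$archetypes$feature == f, ]
      mult <- arch[[as.character(a$archetype)]]
      stage_idx <- match(expr$design$stage, c("S1", "S2", "S3"))
      mu <- a$base_mu * mult[stage_idx]
      expr$counts[f, ] <- rnbinom(9L, mu = mu, size = 1 / params$nb_dispersion)
      fk[f, ] <- expr$counts[f, ] / (expr$lengths[f] / 1e3) /
        (expr$lib_sizes / 1e6)
      bad <- if (target_low) max(fk[f, ]) >= 0.1 else max(fk[f, ]) < 0.1
    }
    if (bad && target_low) {
      expr$counts[f, ] <- 0L
      bad <- FALSE
    }
    if (bad) abort(sprintf("cannot realize expression regime for %s", f))
  }
  cnt$expr <- expr
  cnt
}

# ---- miRNAs ---------------------------------------------------------------

plant_mirnas <- function(w, genome, cand_seqs, params, tables) {
  u_plus <- w$truth_classes %>%
    filter(.data$role == "u") %>%
    inner_join(transcript_spans(w$cand_exons), by = "transcript_id") %>%
    filter(.data$strand == "+", .data$length >= 450L)
  stopifnot(nrow(u_plus) >= params$n_mirna_planted)
  lnc_ids <- sample(u_plus$transcript_id, params$n_mirna_planted)
  coding_tx <- w$ref_exons %>%
    semi_join(w$biotypes %>% filter(.data$biotype == "coding"), by = "gene_id") %>%
    distinct(.data$transcript_id)
  mrna_ids <- sample(coding_tx$transcript_id, params$n_mirna_planted)
  mirnas <- character(0L)
  cerna <- list()
  for (k in seq_len(params$n_mirna_planted)) {
    mrna_seq <- spliced_sequences(
      w$ref_exons %>% filter(.data$transcript_id == mrna_ids[k]), genome
    )[[1L]]
    off <- sample(100:(nchar(mrna_seq) - 140L), 1L)
    window <- substr(mrna_seq, off, off + 20L)
    mir <- revcomp(window)  # perfect antiparallel complement, score 0
    mir_id <- sprintf("miR%03d", k)
    mirnas[mir_id] <- mir

    # plant a near-perfect site into the lncRNA: one mismatch at miRNA
    # position 16 (outside the doubled 2-13 core), site within one exon
    lnc_ex <- w$cand_exons %>% filter(.data$transcript_id == lnc_ids[k]) %>%
      arrange(.data$start)
    site <- mismatch_site(mir, mir_pos = 16L)
    done <- FALSE
    for (try in 1:10) {
      ex_row <- lnc_ex[nrow(lnc_ex), ]
      if (ex_row$end - ex_row$start < 80L) ex_row <- lnc_ex[1L, ]
      gpos <- ex_row$start + 20L + 25L * (try - 1L)
      if (gpos + 21L > ex_row$end - 10L) break
      old <- genome[[ex_row$chrom]]
      substr(genome[[ex_row$chrom]], gpos + 1L, gpos + 21L) <- site
      s2 <- spliced_sequences(lnc_ex, genome)[[1L]]
      if (find_longest_orf(s2)$length_nt < 300L &&
          hexamer_llr(s2, tables$coding, tables$noncoding) < 0 &&
          fickett_score(s2) < pipeline_config()$fickett_cutoff) {
        done <- TRUE
        break
      }
      genome[[ex_row$chrom]] <- old
    }
    if (!done) abort(sprintf("could not plant miRNA site in %s", lnc_ids[k]))
    cerna[[k]] <- tibble(lnc_id = lnc_ids[k], mirna_id = mir_id,
                         mrna_id = mrna_ids[k])
  }
  # decoys: random 21-mers verified to have no qualifying site anywhere
  all_seq_exons <- bind_rows(w$cand_exons, w$ref_exons)
  all_seqs <- spliced_sequences(all_seq_exons, genome)
  decoys <- character(0L)
  while (length(decoys) < params$n_mirna_decoy) {
    cand_mir <- rand_seq(21L, c(A = .25, C = .25, G = .25, T = .25))
    hits <- scan_sites(setNames(cand_mir, "tmp"), all_seqs,
                       max_score = pipeline_config()$mirna_max_score)
    if (!nrow(hits)) {
      id <- sprintf("decoy%02d", length(decoys) + 1L)
      decoys[id] <- cand_mir
    }
  }
  list(genome = genome,
       mirnas = c(mirnas, decoys),
       cerna_truth = bind_rows(cerna),
       decoy_ids = names(decoys))
}

# transcript-strand site for a miRNA: reverse complement with a designed
# clean mismatch (neither Watson-Crick nor wobble) at the given miRNA position
mismatch_site <- function(mir, mir_pos) {
  site <- revcomp(chartr("U", "T", mir))
  sp <- nchar(mir) - mir_pos + 1L
  mb <- substr(chartr("T", "U", mir), mir_pos, mir_pos)
  partner <- WC_PARTNER[[mb]]
  forbidden <- c(partner, if (mb == "G") "U", if (mb == "U") "G")
  forbidden <- chartr("U", "T", forbidden)
  repl <- setdiff(c("A", "C", "G", "T"), c(forbidden, substr(site, sp, sp)))[1L]
  substr(site, sp, sp) <- repl
  site
}

# ---- ortholog genome ------------------------------------------------------

lincRNA_loci <- function(w) {
  w$truth_classes %>%
    filter(.data$role == "u") %>%
    inner_join(transcript_spans(w$cand_exons), by = "transcript_id") %>%
    transmute(id = .data$transcript_id, chrom = .data$chrom,
              start = .data$start, end = .data$end)
}

#' Generate a rearranged ortholog genome
#'
#' Copies the reference gene order, applies inversions, one translocation
#' and gene deletions, lays the surviving genes out on synthetic coordinates
#' and emits a one-to-one ortholog table for surviving protein-coding genes.
#' Chosen lncRNAs are planted as positionally conserved (their 5+5 coding
#' neighbors stay inside one intact segment, and a genome-B lncRNA is placed
#' between the orthologs of their immediate flanks) or as non-conserved
#' (enough flanking genes are deleted that at most 3 neighbors remain
#' mappable). Rearranged segments are at least `rearrange_window` genes long
#' so that, with the default synteny gap limit, each segment chains into its
#' own block and the expected pair set can be derived from the segment
#' structure alone.
#'
#' @param ann Reference `genome_annotation`.
#' @param lncs Tibble `id`, `chrom`, `start`, `end` of candidate intergenic
#'   lncRNAs eligible for planting.
#' @param params A [simulation_params()].
#' @return List: `ann_b`, `orthologs`, `lncs_b`, `positional_truth` (list
#'   with `pairs`, `conserved`, `nonconserved`), `segments`.
#' @export
generate_ortholog_genome <- function(ann, lncs, params = simulation_params()) {
  genes <- ann$genes %>% arrange(.data$chrom, .data$rank)
  k <- pipeline_config()$neighbor_k
  # neighbors by rank among coding genes
  coding_by_chrom <- split(
    genes %>% filter(.data$biotype == "coding"),
    genes$chrom[genes$biotype == "coding"]
  )
  neighbor_sets <- lapply(seq_len(nrow(lncs)), function(i) {
    lnc <- lncs[i, ]
    cg <- coding_by_chrom[[lnc$chrom]]
    if (is.null(cg)) return(NULL)
    up <- cg %>% filter(.data$end <= lnc$start) %>% tail(k)
    down <- cg %>% filter(.data$start >= lnc$end) %>% head(k)
    list(up = up$gene_id, down = down$gene_id)
  })
  names(neighbor_sets) <- lncs$id

  # plan rearrangement windows first, so planting never starves them of space
  chroms <- unique(genes$chrom)
  win <- params$rearrange_window
  op_windows <- list()
  translocated_plan <- NULL
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ids <- genes$gene_id[genes$chrom == ch]
    ops <- list()
    if (params$n_inversions >= ci) {
      s <- pick_window(length(ids), win, integer(), integer())
      if (!is.na(s)) ops$inv <- s:(s + win - 1L)
    }
    if (params$n_translocations >= 1L && ci == 1L && length(chroms) > 1L) {
      s <- pick_window(length(ids), win, integer(),
                       avoid = if (!is.null(ops$inv)) ops$inv else integer())
      if (!is.na(s)) ops$trans <- s:(s + win - 1L)
    }
    op_windows[[ch]] <- ops
  }
  op_genes <- unlist(lapply(chroms, function(ch) {
    ids <- genes$gene_id[genes$chrom == ch]
    ids[unlist(op_windows[[ch]])]
  }))

  full <- vapply(names(neighbor_sets), function(id) {
    ns <- neighbor_sets[[id]]
    !is.null(ns) && length(ns$up) == k && length(ns$down) == k &&
      !length(intersect(unlist(ns), op_genes))
  }, logical(1L))
  eligible <- lncs$id[full]
  # spread choices over chromosomes deterministically
  n_cons <- min(params$n_pos_conserved, length(eligible))
  conserved <- character(0L); used_genes <- character(0L)
  noncons <- character(0L)
  for (id in sample(eligible)) {
    ns <- unlist(neighbor_sets[[id]])
    if (length(intersect(ns, used_genes))) next
    if (length(conserved) < n_cons) {
      conserved <- c(conserved, id)
      used_genes <- c(used_genes, ns)
    } else if (length(noncons) < params$n_pos_nonconserved) {
      noncons <- c(noncons, id)
      used_genes <- c(used_genes, ns)
    }
    if (length(conserved) == n_cons &&
        length(noncons) == params$n_pos_nonconserved) break
  }
  protected <- unique(unlist(lapply(conserved, function(id)
    unlist(neighbor_sets[[id]]))))

  deleted <- character(0L)
  for (id in noncons) {
    ns <- neighbor_sets[[id]]
    keep <- c(utils::head(ns$up, 2L), utils::head(ns$down, 1L))
    deleted <- c(deleted, setdiff(unlist(ns), keep))
  }
  # random scattered deletions among unprotected coding genes
  pool <- genes %>%
    filter(.data$biotype == "coding",
           !.data$gene_id %in% c(protected, deleted, unlist(neighbor_sets[noncons])))
  if (params$n_random_deletions > 0L && nrow(pool)) {
    deleted <- c(deleted,
                 sample(pool$gene_id, min(params$n_random_deletions, nrow(pool))))
  }

  # segment structure per chromosome: list of (gene ids in B order, segment id)
  seg_tbl <- list()
  b_orders <- list()
  seg_id <- 0L
  translocated <- NULL
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ids <- genes$gene_id[genes$chrom == ch]
    ops <- op_windows[[ch]]
    if (!is.null(ops$trans)) translocated <- ids[ops$trans]
    # build B order of this chromosome as segments
    idx <- seq_along(ids)
    breaks <- sort(unique(c(0L,
                            if (!is.null(ops$inv)) c(min(ops$inv) - 1L, max(ops$inv)),
                            if (!is.null(ops$trans)) c(min(ops$trans) - 1L, max(ops$trans)),
                            length(ids))))
    order_b <- character(0L)
    segs <- list()
    for (s in seq_len(length(breaks) - 1L)) {
      seg_idx <- (breaks[s] + 1L):breaks[s + 1L]
      if (!length(seg_idx) || breaks[s] >= breaks[s + 1L]) next
      if (!is.null(ops$trans) && all(seg_idx %in% ops$trans)) next  # moved away
      seg_id <- seg_id + 1L
      seg_ids <- ids[seg_idx]
      if (!is.null(ops$inv) && all(seg_idx %in% ops$inv)) seg_ids <- rev(seg_ids)
      order_b <- c(order_b, seg_ids)
      segs[[length(segs) + 1L]] <- tibble(gene_a = seg_ids, segment = seg_id)
    }
    b_orders[[ch]] <- order_b
    seg_tbl[[ch]] <- bind_rows(segs)
  }
  if (!is.null(translocated)) {
    seg_id <- seg_id + 1L
    ch2 <- chroms[length(chroms)]
    b_orders[[ch2]] <- c(b_orders[[ch2]], translocated)
    seg_tbl[[ch2]] <- bind_rows(seg_tbl[[ch2]],
                                tibble(gene_a = translocated, segment = seg_id))
  }
  segments <- bind_rows(seg_tbl, .id = "chrom_b")

  # lay out genome B
  b_exons <- list(); b_bio <- list(); b_pos <- list()
  for (ch in names(b_orders)) {
    ids <- setdiff(b_orders[[ch]], deleted)
    if (!length(ids)) next
    starts <- 5000L + (seq_along(ids) - 1L) * 8000L
    src <- genes[match(ids, genes$gene_id), ]
    bid <- paste0("B_", ids)
    btx <- paste0(bid, ".1")
    b_exons[[ch]] <- tibble(chrom = paste0("B", ch), start = starts,
                            end = starts + 2000L, strand = src$strand,
                            transcript_id = btx, gene_id = bid)
    b_bio[[ch]] <- tibble(gene_id = bid, biotype = src$biotype)
    b_pos[[ch]] <- tibble(gene_a = ids, gene_b = bid,
                          chrom_b = paste0("B", ch),
                          b_start = starts, b_end = starts + 2000L)
  }
  b_pos <- bind_rows(b_pos)
  ann_b <- annotation(bind_rows(b_exons), biotypes = bind_rows(b_bio))
  orthologs <- genes %>%
    filter(.data$biotype == "coding", !.data$gene_id %in% deleted) %>%
    inner_join(b_pos, by = c(gene_id = "gene_a")) %>%
    select(gene_a = "gene_id", "gene_b")

  # planted genome-B lncRNAs between the B orthologs of each conserved
  # lncRNA's immediate flanking genes
  lncs_b <- list()
  for (i in seq_along(conserved)) {
    id <- conserved[i]
    ns <- neighbor_sets[[id]]
    flank <- c(tail(ns$up, 1L), utils::head(ns$down, 1L))
    fb <- b_pos[match(flank, b_pos$gene_a), ]
    lo <- min(fb$b_start, fb$b_end); hi <- max(fb$b_start, fb$b_end)
    mid <- (lo + hi) %/% 2L
    lncs_b[[i]] <- tibble(id = sprintf("lncB%03d", i), chrom = fb$chrom_b[1L],
                          start = mid - 300L, end = mid + 300L)
  }
  lncs_b <- if (length(lncs_b)) bind_rows(lncs_b) else
    tibble(id = character(), chrom = character(),
           start = integer(), end = integer())

  # expected pair set from the segment structure alone (independent of the
  # synteny module): a lncRNA pairs with every planted B lncRNA inside the
  # B-coordinate range of its best segment
  seg_of_gene <- setNames(segments$segment, segments$gene_a)
  pairs <- list()
  for (id in c(conserved, noncons)) {
    ns <- unlist(neighbor_sets[[id]])
    mappable <- setdiff(ns, deleted)
    if (!length(mappable)) next
    segs <- table(seg_of_gene[mappable])
    best <- names(segs)[which.max(segs)]
    if (max(segs) < pipeline_config()$min_conserved_neighbors) next
    seg_genes <- setdiff(segments$gene_a[segments$segment == as.integer(best)],
                         deleted)
    sb <- b_pos[b_pos$gene_a %in% seg_genes, ]
    lo <- min(sb$b_start); hi <- max(sb$b_end)
    mates <- lncs_b %>%
      filter(.data$chrom == sb$chrom_b[1L],
             .data$start >= lo, .data$end <= hi)
    if (nrow(mates)) {
      pairs[[length(pairs) + 1L]] <- tibble(lnc_a = id, lnc_b = mates$id)
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(lnc_a = character(), lnc_b = character())

  list(ann_b = ann_b, orthologs = orthologs, lncs_b = lncs_b,
       positional_truth = list(pairs = pairs, conserved = conserved,
                               nonconserved = noncons),
       segments = segments, deleted = deleted)
}

pick_window <- function(n, win, protected_idx, avoid) {
  if (n < win + 10L) return(NA_integer_)
  starts <- sample(5:(n - win - 5L))
  for (s in starts) {
    idx <- s:(s + win - 1L)
    if (!length(intersect(idx, protected_idx)) && !length(intersect(idx, avoid))) {
      return(s)
    }
  }
  NA_integer_
}

# ---- file output ----------------------------------------------------------

#' Write every simulated input to disk
#'
#' Emits genome FASTA, reference GFF3, candidate GTF + transcript FASTA,
#' counts and design TSV, miRNA FASTA, ortholog TSV, genome-B GFF3, and the
#' truth bundle as JSON. Outputs are byte-identical for a fixed seed.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$ann, file.path(dir, "annotation.gff3"))
  write_transcripts_gtf(sim$candidates, file.path(dir, "candidates.gtf"))
  write_fasta(sim$cand_seqs, file.path(dir, "candidates.fa"))
  write_expression_tsv(sim$expr, file.path(dir, "counts.tsv"),
                       file.path(dir, "design.tsv"))
  write_fasta(sim$mirnas, file.path(dir, "mirnas.fa"))
  write.table(sim$ortho$orthologs, file.path(dir, "orthologs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation(sim$ortho$ann_b, file.path(dir, "annotation_b.gff3"))
  truth <- sim$truth
  truth$positional$pairs <- as.data.frame(truth$positional$pairs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
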