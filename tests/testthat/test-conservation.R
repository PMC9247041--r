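rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

test_that("homology search finds self-matches and honors both thresholds", {
  set.seed(3)
  q <- rand_dna(300)
  subj <- c(hit = q, other = rand_dna(300))
  h <- homology_search(c(q1 = q), subj)
  expect_true("hit" %in% h$subject_id)
  self <- h[h$subject_id == "hit", ]
  expect_lt(self$evalue, 1e-10)
  expect_equal(self$query_coverage, 1.0)

  # 25-nt exact block in a 125-nt query: coverage exactly 0.20 is retained
  core <- rand_dna(25)
  q2 <- paste0(strrep("A", 50), core, strrep("A", 50))
  s2 <- paste0(rand_dna(100), core, rand_dna(100))
  # flanking A-runs would extend the alignment; cap them with mismatch-rich
  # context by using GC flanks on the subject
  s2 <- paste0(strrep("G", 100), core, strrep("C", 100))
  h2 <- homology_search(c(q2 = q2), c(s2 = s2),
                        pipeline_config(homology_evalue = 1))
  row <- h2[h2$subject_id == "s2", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$align_len, 25L)
  expect_equal(row$query_coverage, 0.20)

  # the same hit fails a stricter inclusive coverage bound
  h3 <- homology_search(c(q2 = q2), c(s2 = s2),
                        pipeline_config(homology_evalue = 1,
                                        homology_min_coverage = 0.201))
  expect_equal(nrow(h3), 0L)

  expect_error(homology_search(c(q = ""), subj), "empty")
})

test_that("hit scores match an independent seed-and-extend oracle", {
  set.seed(11)
  oracle_best_score <- function(q, s, word = 11L, xdrop = 20) {
    qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
    best <- -Inf
    for (i in seq_len(length(qc) - word + 1L)) {
      for (j in seq_len(length(sc) - word + 1L)) {
        if (!all(qc[i:(i + word - 1L)] == sc[j:(j + word - 1L)])) next
        scr <- word
        run <- 0; bst <- 0
        ii <- i + word; jj <- j + word
        while (ii <= length(qc) && jj <= length(sc)) {
          run <- run + if (qc[ii] == sc[jj]) 1 else -2
          bst <- max(bst, run)
          if (bst - run >= xdrop) break
          ii <- ii + 1L; jj <- jj + 1L
        }
        scr <- scr + bst
        run <- 0; bst <- 0
        ii <- i - 1L; jj <- j - 1L
        while (ii >= 1L && jj >= 1L) {
          run <- run + if (qc[ii] == sc[jj]) 1 else -2
          bst <- max(bst, run)
          if (bst - run >= xdrop) break
          ii <- ii - 1L; jj <- jj - 1L
        }
        best <- max(best, scr + bst)
      }
    }
    best
  }
  n_hits <- 0L
  for (rep in 1:60) {
    q <- rand_dna(80)
    s <- rand_dna(120)
    if (rep %% 2 == 0) {
      k <- sample(12:30, 1L)
      pos_q <- sample(1:(80 - k + 1L), 1L)
      pos_s <- sample(1:(120 - k + 1L), 1L)
      substr(s, pos_s, pos_s + k - 1L) <- substr(q, pos_q, pos_q + k - 1L)
    }
    got <- homology_search(c(q = q), c(s = s),
                           pipeline_config(homology_evalue = 1e9,
                                           homology_min_coverage = 1e-9))
    fwd <- oracle_best_score(q, s)
    rc <- chartr("ACGT", "TGCA",
                 paste0(rev(strsplit(q, "")[[1]]), collapse = ""))
    rev_ <- oracle_best_score(rc, s)
    want <- max(fwd, rev_)
    if (is.infinite(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$score, want)
      n_hits <- n_hits + 1L
    }
  }
  expect_gt(n_hits, 20L)
})

test_that("E-values decrease monotonically in score", {
  set.seed(13)
  subj <- c(s = rand_dna(2000))
  comp <- peachlnc:::base_composition(toupper(subj))
  lambda <- peachlnc:::karlin_lambda(comp)
  scores <- c(20, 40, 60, 80)
  ev <- 0.621 * 500 * 2000 * exp(-lambda * scores)
  expect_true(all(diff(ev) < 0))
})

mk_two_genomes <- function(rank_b_order, n = 10L) {
  ids_a <- sprintf("a%02d", 1:n)
  exons_a <- tibble::tibble(
    chrom = "c1", start = (1:n) * 10000L, end = (1:n) * 10000L + 2000L,
    strand = "+", transcript_id = paste0(ids_a, ".1"), gene_id = ids_a
  )
  ids_b <- sprintf("b%02d", 1:n)
  starts_b <- order(rank_b_order) # position of each gene in B
  exons_b <- tibble::tibble(
    chrom = "cB", start = rank_b_order * 10000L,
    end = rank_b_order * 10000L + 2000L,
    strand = "+", transcript_id = paste0(ids_b, ".1"), gene_id = ids_b
  )
  list(
    ann_a = annotation(exons_a),
    ann_b = annotation(exons_b),
    orthologs = tibble::tibble(gene_a = ids_a, gene_b = ids_b)
  )
}

test_that("collinear, inverted and shuffled anchor sets chain as expected", {
  g <- mk_two_genomes(1:10)
  syn <- find_synteny_blocks(g$orthologs, g$ann_a, g$ann_b, 5L, 25L)
  expect_equal(nrow(syn$blocks), 1L)
  expect_equal(syn$blocks$n_anchors, 10L)
  expect_equal(syn$blocks$orientation, "same")

  gi <- mk_two_genomes(10:1)
  syn_i <- find_synteny_blocks(gi$orthologs, gi$ann_a, gi$ann_b, 5L, 25L)
  expect_equal(nrow(syn_i$blocks), 1L)
  expect_equal(syn_i$blocks$orientation, "inverted")

  # a shuffle with no chain >= 5 (verified by exhaustive enumeration)
  set.seed(19)
  repeat {
    perm <- sample(10)
    if (oracle_longest_chain_len(1:10, perm, max_gap = 2L) < 5L) break
  }
  gs <- mk_two_genomes(perm)
  syn_s <- find_synteny_blocks(gs$orthologs, gs$ann_a, gs$ann_b, 5L, 2L)
  expect_equal(nrow(syn_s$blocks), 0L)

  # duplicated ortholog pairs are deduplicated with a warning
  dup <- dplyr::bind_rows(g$orthologs, g$orthologs[1, ])
  expect_warning(find_synteny_blocks(dup, g$ann_a, g$ann_b, 5L, 25L),
                 "duplicated")
})

test_that("block anchors satisfy their monotonicity invariant", {
  sim <- fx_sim()
  syn <- find_synteny_blocks(sim$ortho$orthologs, sim$ann, sim$ortho$ann_b)
  for (b in syn$blocks$block_id) {
    a <- syn$anchors[syn$anchors$block_id == b, ]
    a <- a[order(a$rank_a), ]
    expect_true(all(diff(a$rank_a) > 0))
    dr <- diff(a$rank_b)
    orient <- syn$blocks$orientation[syn$blocks$block_id == b]
    if (orient == "same") expect_true(all(dr > 0)) else expect_true(all(dr < 0))
    expect_true(all(abs(diff(a$rank_a)) <= 25))
    expect_true(all(abs(dr) <= 25))
  }
})

test_that("positional conservation applies the >= 4 neighbor vote", {
  g <- mk_two_genomes(1:10)
  syn <- find_synteny_blocks(g$orthologs, g$ann_a, g$ann_b, 5L, 25L)
  # lncRNA between genes 5 and 6 with a genome-B lncRNA in the block
  lnc_a <- tibble::tibble(id = "LA", chrom = "c1",
                          start = 52500L, end = 53000L)
  lnc_b <- tibble::tibble(id = "LB", chrom = "cB",
                          start = 52500L, end = 53000L)
  pos <- positional_conservation(lnc_a, lnc_b, g$ann_a, g$ann_b, syn,
                                 g$orthologs)
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$lnc_b, "LB")
  expect_equal(pos$n_conserved_neighbors, 10L)

  # with only 3 mappable neighbors the vote fails
  few <- g$orthologs[c(4, 5, 6), ]
  syn_few <- find_synteny_blocks(few, g$ann_a, g$ann_b, 3L, 25L)
  pos_few <- positional_conservation(lnc_a, lnc_b, g$ann_a, g$ann_b,
                                     syn_few, few)
  expect_equal(nrow(pos_few), 0L)

  # chromosome without coding genes is skipped with a warning
  lnc_alien <- tibble::tibble(id = "LX", chrom = "c9", start = 1L, end = 10L)
  expect_warning(
    out <- positional_conservation(lnc_alien, lnc_b, g$ann_a, g$ann_b, syn,
                                   g$orthologs),
    "no coding genes")
  expect_equal(nrow(out), 0L)
})
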