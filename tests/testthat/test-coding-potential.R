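test_that("constructed ORFs are found with the expected span", {
  set.seed(3)
  cu <- peachlnc:::sim_codon_usage()
  body <- paste0(sample(names(cu), 100, replace = TRUE, prob = cu),
                 collapse = "")
  orf_seq <- paste0("ATG", body, "TAA")
  # embed in a stop-rich context so no longer frame exists
  ctx <- paste0(strrep("TAA", 15), orf_seq, strrep("TGA", 15))
  orf <- find_longest_orf(ctx)
  expect_equal(orf$length_nt, 306L)
  expect_true(orf$has_start && orf$has_stop)
  expect_equal(substr(ctx, orf$start + 1L, orf$start + 3L), "ATG")

  none <- find_longest_orf("TTTTTTTTTTTT")
  expect_false(none$has_start)
  expect_equal(none$length_nt, 12L)  # longest stop-free codon stretch

  expect_error(find_longest_orf(""), "empty")
})

test_that("longest ORF matches brute-force enumeration on random sequences", {
  set.seed(17)
  for (rep in 1:500) {
    n <- sample(30:150, 1L)
    s <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    expect_equal(got$length_nt, want$length_nt, info = s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
  }
})

test_that("Fickett score hits minimal position bins on a period-4 repeat", {
  s <- strrep("ACGT", 100)
  tabs <- peachlnc:::fickett_tables()
  # every base equally frequent in the three frame positions -> last bin
  expect_lt(fickett_score(s), 0.74)
  min_pos <- sum(vapply(c("A", "C", "G", "T"), function(b)
    tabs$position_prob[[b]][10] * tabs$position_weight[[b]], numeric(1)))
  contrib <- fickett_score(s) -
    sum(vapply(c("A", "C", "G", "T"), function(b) {
      cbin <- which(0.25 >= tabs$content_edges)[1L]
      tabs$content_prob[[b]][cbin] * tabs$content_weight[[b]]
    }, numeric(1)))
  expect_equal(contrib, min_pos, tolerance = 1e-12)
})

test_that("Fickett score is stable under period-preserving duplication", {
  set.seed(23)
  for (rep in 1:5) {
    s <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    expect_equal(fickett_score(paste0(s, s)), fickett_score(s),
                 tolerance = 0.06)
  }
  expect_error(fickett_score("ACGT"), "200")
})

test_that("Fickett score agrees with an independent reimplementation", {
  set.seed(29)
  for (rep in 1:100) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(200:600, 1L),
                       replace = TRUE, prob = runif(4, 0.5, 1.5)),
                collapse = "")
    expect_equal(fickett_score(s), oracle_fickett(s), tolerance = 1e-12)
  }
})

test_that("hexamer LLR identities hold", {
  tabs <- default_hexamer_tables()
  set.seed(41)
  s <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  expect_equal(hexamer_llr(s, tabs$coding, tabs$coding), 0)

  # single hexamer with 2:1 frequency ratio -> exactly one bit
  co <- setNames(rep(1 / 4096, 4096L), names(tabs$coding))
  nc <- co
  co["AAAAAA"] <- 2 * nc[["AAAAAA"]]
  expect_equal(hexamer_llr("AAAAAA", co, nc), 1.0)

  expect_error(hexamer_llr(s, tabs$coding[-1], tabs$noncoding), "4096")
})

test_that("coding-model draws score positive in expectation", {
  set.seed(53)
  tabs <- default_hexamer_tables()
  cu <- peachlnc:::sim_codon_usage()
  llrs <- replicate(300, {
    s <- paste0(sample(names(cu), 80, replace = TRUE, prob = cu),
                collapse = "")
    hexamer_llr(s, tabs$coding, tabs$noncoding)
  })
  # mean > 0 at high confidence
  expect_gt(mean(llrs) / (sd(llrs) / sqrt(length(llrs))), 2.6)
})

test_that("domain scan finds planted consensus motifs and nothing in stop runs", {
  db <- synthetic_motif_db()
  m <- db[[1L]]
  cons <- paste0(rownames(m$pwm)[apply(m$pwm, 2L, which.max)], collapse = "")
  cod <- peachlnc:::aa_to_codons(cons)
  planted <- paste0("ATGGCA", paste0(cod, collapse = ""), "GCATAA")
  expect_true(domain_scan(planted, db)$hit)
  expect_false(domain_scan(strrep("TAA", 30), db)$hit)
  bad <- db
  bad[[1L]]$pwm[1L, 1L] <- Inf
  expect_error(domain_scan(planted, bad), "non-finite")
})

test_that("domain scan equals exhaustive window scoring on random input", {
  set.seed(61)
  for (rep in 1:20) {
    pwm <- matrix(rnorm(20 * 6), nrow = 20,
                  dimnames = list(peachlnc:::AA20, NULL))
    db <- list(list(name = "r", pwm = pwm, threshold = 4))
    s <- paste0(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
    got <- domain_scan(s, db)$hits
    # oracle: translate frames by hand and score every window
    want <- 0L
    gc <- Biostrings::GENETIC_CODE
    for (f in 0:2) {
      ncod <- (nchar(s) - f) %/% 3L
      aa <- unname(gc[substring(s, f + 1L + 3L * (0:(ncod - 1L)),
                                f + 3L * (1:ncod))])
      for (off in seq_len(max(0L, ncod - 6L + 1L))) {
        win <- aa[off:(off + 5L)]
        if (any(is.na(win)) || any(!win %in% rownames(pwm))) next
        if (sum(pwm[cbind(match(win, rownames(pwm)), 1:6)]) >= 4) {
          want <- want + 1L
        }
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("the consensus verdict is the intersection of all four evidences", {
  cfg <- pipeline_config()
  tabs <- default_hexamer_tables()
  sim <- fx_small_sim()
  v <- coding_verdicts(sim$cand_seqs[1:10], cfg, tabs)
  manual <- v$orf_score < cfg$orf_cutoff & v$fickett < cfg$fickett_cutoff &
    v$hexamer < 0 & !v$domain_hit
  expect_equal(v$noncoding, manual)

  # 2-of-3 noncoding with a long ORF is still coding
  set.seed(71)
  cu <- peachlnc:::sim_codon_usage()
  coding_seq <- paste0("ATG", paste0(sample(names(cu), 150, replace = TRUE,
                                            prob = cu), collapse = ""), "TAA")
  vc <- coding_verdicts(c(tx = coding_seq), cfg, tabs)
  expect_gte(vc$orf_score, cfg$orf_cutoff)
  expect_false(vc$noncoding)

  # all predictors noncoding but a domain hit -> rejected
  db <- synthetic_motif_db()
  m <- db[[2L]]
  cons <- paste0(rownames(m$pwm)[apply(m$pwm, 2L, which.max)], collapse = "")
  dom_seq <- peachlnc:::designed_domain(600L, tabs)
  vd <- coding_verdicts(c(tx = dom_seq), cfg, tabs)
  expect_true(vd$domain_hit)
  expect_false(vd$noncoding)
  expect_lt(vd$orf_score, cfg$orf_cutoff)
})

test_that("stricter cutoffs never enlarge the retained set", {
  sim <- fx_small_sim()
  seqs <- sim$cand_seqs[1:30]
  v1 <- coding_verdicts(seqs, pipeline_config())
  v2 <- coding_verdicts(seqs, pipeline_config(orf_cutoff = 200L,
                                              fickett_cutoff = 0.5))
  expect_true(all(v2$noncoding <= v1$noncoding))
})
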