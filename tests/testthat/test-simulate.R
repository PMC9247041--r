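test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_study(small_params(seed = 77L))
  s2 <- simulate_study(small_params(seed = 77L))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$candidates, s2$candidates)
  expect_identical(s1$expr$counts, s2$expr$counts)
  expect_identical(s1$mirnas, s2$mirnas)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("constructive guarantees hold on the generated world", {
  sim <- fx_small_sim()
  # every coding gene's transcript carries an ORF of >= 300 nt
  coding_tx <- sim$ann$transcripts$transcript_id[
    sim$ann$genes$biotype[match(sim$ann$transcripts$gene_id,
                                sim$ann$genes$gene_id)] == "coding"]
  for (id in coding_tx[1:10]) {
    expect_gte(find_longest_orf(sim$ref_seqs[[id]])$length_nt, 300L)
  }
  # gene ranks strictly increase with coordinates on each chromosome
  for (ch in unique(sim$ann$genes$chrom)) {
    g <- sim$ann$genes[sim$ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_equal(g$rank, seq_len(nrow(g)) - 1L)
  }
  # 'u' candidates overlap no gene span
  u_ids <- sim$truth$classes$transcript_id[sim$truth$classes$class == "u"]
  spans <- transcript_spans(sim$candidates)
  for (id in u_ids[1:10]) {
    sp <- spans[spans$transcript_id == id, ]
    expect_equal(nrow(genes_overlapping(sim$ann, sp$chrom, sp$start, sp$end)),
                 0L)
  }
  # 'x' candidates overlap a reference exon on the opposite strand
  x_ids <- sim$truth$classes$transcript_id[sim$truth$classes$class == "x"]
  for (id in x_ids) {
    ex <- sim$candidates[sim$candidates$transcript_id == id, ]
    ref_ex <- sim$ann$exons[sim$ann$exons$chrom == ex$chrom[1L] &
                              sim$ann$exons$strand != ex$strand[1L], ]
    ovl <- any(vapply(seq_len(nrow(ex)), function(i)
      any(ref_ex$start < ex$end[i] & ref_ex$end > ex$start[i]), logical(1L)))
    expect_true(ovl, info = id)
  }
  # spliced sequence length equals the exon-length sum for every candidate
  expect_identical(unname(nchar(sim$cand_seqs[spans$transcript_id])),
                   spans$length)
})

test_that("the full candidate set classifies back to its intended classes", {
  sim <- fx_small_sim()
  cl <- classify_transcripts(sim$candidates, sim$ann)
  truth <- sim$truth$classes
  j <- dplyr::inner_join(cl, truth, by = "transcript_id")
  expect_equal(nrow(j), nrow(truth))
  expect_identical(j$class_code, j$class)
})

test_that("NB counts hit their planted means and dispersion limits", {
  set.seed(101)
  # planted fold change: stage-3 mean / stage-1 mean over many draws
  mu <- 100; fc <- 4; alpha <- 0.1
  draws1 <- rnbinom(10000, mu = mu, size = 1 / alpha)
  draws3 <- rnbinom(10000, mu = mu * fc, size = 1 / alpha)
  expect_equal(mean(draws3) / mean(draws1), fc, tolerance = 0.02 * fc)
  # dispersion -> 0: variance/mean -> 1 (Poisson limit)
  tiny <- rnbinom(20000, mu = 50, size = 1 / 1e-6)
  expect_equal(var(tiny) / mean(tiny), 1, tolerance = 0.05)
  # fixed seed reproducibility of a feature row
  set.seed(11); a <- rnbinom(9, mu = 100, size = 10)
  set.seed(11); b <- rnbinom(9, mu = 100, size = 10)
  expect_identical(a, b)
})

test_that("count generation encodes archetypes, groups, and library sizes", {
  sim <- fx_small_sim()
  expr <- sim$expr
  expect_true(all(expr$counts >= 0))
  expect_true(all(expr$lib_sizes >= colSums(expr$counts)))
  arch <- sim$archetypes
  # lncRNA base means sit well below mRNA base means
  expect_lt(median(arch$base_mu[arch$group == "lnc"]),
            median(arch$base_mu[arch$group == "mRNA"]) / 5)
  # lowexpr decoys never reach 0.1 FPKM; other candidates always do
  fk <- fpkm(expr)
  roles <- sim$truth$classes
  low <- roles$transcript_id[roles$role == "lowexpr"]
  rest <- roles$transcript_id[!roles$role %in% "lowexpr"]
  expect_true(all(apply(fk[low, , drop = FALSE], 1, max) < 0.1))
  expect_true(all(apply(fk[rest, , drop = FALSE], 1, max) >= 0.1))
})

test_that("planted miRNAs carry their designed sites; decoys carry none", {
  sim <- fx_small_sim()
  cfg <- pipeline_config()
  for (r in seq_len(nrow(sim$truth$cerna))) {
    tr <- sim$truth$cerna[r, ]
    lnc_hits <- find_sites(sim$mirnas[[tr$mirna_id]],
                           sim$cand_seqs[[tr$lnc_id]],
                           max_score = cfg$mirna_max_score)
    mrna_hits <- find_sites(sim$mirnas[[tr$mirna_id]],
                            sim$ref_seqs[[tr$mrna_id]],
                            max_score = cfg$mirna_max_score)
    expect_gte(nrow(lnc_hits), 1L)
    expect_gte(nrow(mrna_hits), 1L)
    expect_equal(min(mrna_hits$score), 0)   # perfect complement
    expect_lte(min(lnc_hits$score), 1)      # one designed mismatch
  }
  for (d in sim$truth$mirna_decoys) {
    hits <- scan_sites(sim$mirnas[d],
                       c(sim$cand_seqs, sim$ref_seqs),
                       max_score = cfg$mirna_max_score)
    expect_equal(nrow(hits), 0L)
  }
})

test_that("a zero-rearrangement ortholog genome is one block per chromosome", {
  sim <- fx_small_sim()  # built with zero inversions/translocations
  syn <- find_synteny_blocks(sim$ortho$orthologs, sim$ann, sim$ortho$ann_b)
  expect_equal(nrow(syn$blocks), length(unique(sim$ann$genes$chrom)))
  expect_true(all(syn$blocks$orientation == "same"))
  # ortholog table is one-to-one
  expect_false(anyDuplicated(sim$ortho$orthologs$gene_a) > 0)
  expect_false(anyDuplicated(sim$ortho$orthologs$gene_b) > 0)
})
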