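test_that("cis targets respect the inclusive window and side labels", {
  ref <- annotation(tibble::tibble(
    chrom = "c1",
    start = c(10000L, 300000L, 460000L),
    end = c(12000L, 302000L, 462000L),
    strand = "+",
    transcript_id = c("gA.1", "gB.1", "gC.1"),
    gene_id = c("gA", "gB", "gC")
  ))
  lnc <- tibble::tibble(transcript_id = "L", chrom = "c1",
                        start = 62000L, end = 64000L)
  hits <- cis_targets(lnc, ref, window = 100000L)
  expect_equal(hits$gene_id, "gA")  # 50 kb upstream
  expect_equal(hits$side, "upstream")
  expect_equal(hits$distance, 50000L)
  # gB is 236 kb away -> excluded; boundary exactly at window is kept
  lnc2 <- tibble::tibble(transcript_id = "L2", chrom = "c1",
                         start = 200000L, end = 200100L)
  h2 <- cis_targets(lnc2, ref, window = 100000L)
  expect_setequal(h2$gene_id, c("gB"))
  expect_equal(h2$distance, 99900L)
})

test_that("cis targets equal a brute-force distance scan and grow with window", {
  set.seed(37)
  starts <- sort(sample(seq(1000L, 2000000L, by = 1000L), 120L))
  ref <- annotation(tibble::tibble(
    chrom = "c1", start = starts, end = starts + sample(500:3000, 120L, TRUE),
    strand = sample(c("+", "-"), 120L, TRUE),
    transcript_id = sprintf("g%d.1", 1:120), gene_id = sprintf("g%d", 1:120)
  ))
  for (rep in 1:500) {
    s <- sample(1:2000000, 1L); e <- s + sample(100:5000, 1L)
    win <- sample(c(10000L, 50000L, 100000L), 1L)
    lnc <- tibble::tibble(transcript_id = "L", chrom = "c1", start = s, end = e)
    got <- sort(cis_targets(lnc, ref, win)$gene_id)
    g <- ref$genes
    d <- ifelse(g$end <= s, s - g$end, ifelse(g$start >= e, g$start - e, 0L))
    expect_identical(got, sort(g$gene_id[d <= win]))
  }
  lnc <- tibble::tibble(transcript_id = "L", chrom = "c1",
                        start = 1000000L, end = 1000100L)
  n_small <- nrow(cis_targets(lnc, ref, 20000L))
  n_big <- nrow(cis_targets(lnc, ref, 150000L))
  expect_lte(n_small, n_big)
})

test_that("duplex energy of a GC helix equals the hand-summed stack total", {
  a <- "GGGGGCCCCC"
  b <- a  # its own reverse complement
  h <- duplex_energy(a, b, seed_len = 6L)
  # 10 pairs: 4 GG/CC stacks, 1 GC/GC stack, 4 CC/GG stacks + initiation
  hand <- 4.09 + 4 * oracle_stack("G", "G", "C", "C") +
    oracle_stack("G", "C", "C", "G") + 4 * oracle_stack("C", "C", "G", "G")
  expect_equal(h$energy, hand)
  expect_equal(h$a_start, 0L); expect_equal(h$a_end, 10L)
  expect_equal(h$b_start, 0L); expect_equal(h$b_end, 10L)
})

test_that("duplex search is symmetric and returns nothing without a seed", {
  # poly-A vs poly-C share no complementary run at all
  expect_equal(nrow(duplex_energy(strrep("A", 12), strrep("C", 12), 6L)), 0L)
  set.seed(43)
  for (rep in 1:20) {
    a <- paste0(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    ha <- duplex_energy(a, b, 5L)
    hb <- duplex_energy(b, a, 5L)
    expect_equal(nrow(ha), nrow(hb))
    if (nrow(ha)) expect_equal(ha$energy, hb$energy)
  }
  expect_error(duplex_energy("", "ACGT"), "empty")
})

test_that("duplex energies equal exhaustive enumeration on random pairs", {
  set.seed(47)
  n_checked <- 0L
  for (rep in 1:200) {
    na <- sample(15:40, 1L); nb <- sample(15:40, 1L)
    a <- paste0(sample(c("A", "C", "G", "T"), na, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), nb, TRUE), collapse = "")
    if (rep %% 3 == 0) {
      # plant a complementary block so hits are frequent
      k <- sample(6:12, 1L)
      frag <- substr(a, 1, k)
      rc <- chartr("ACGT", "TGCA", paste0(rev(strsplit(frag, "")[[1]]),
                                          collapse = ""))
      pos <- sample(1:(nb - k + 1L), 1L)
      substr(b, pos, pos + k - 1L) <- rc
    }
    got <- duplex_energy(a, b, 6L)
    want <- oracle_duplex(a, b, 6L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, info = paste(a, b))
    } else {
      expect_equal(got$energy, want, info = paste(a, b))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 30L)
})

test_that("the trans cutoff is strict", {
  set.seed(51)
  lnc <- paste0(strrep("A", 30), "GGGGGGCCCCCC", strrep("A", 30))
  mrna <- paste0(strrep("T", 25), "GGGGGGCCCCCC", strrep("T", 25))
  e <- duplex_energy(lnc, mrna, 6L)$energy
  at <- pipeline_config(trans_energy_cutoff = e)
  below <- pipeline_config(trans_energy_cutoff = e + 1e-9)
  expect_equal(nrow(trans_targets(c(L = lnc), c(M = mrna), at)), 0L)
  expect_equal(nrow(trans_targets(c(L = lnc), c(M = mrna), below)), 1L)
})

test_that("a planted GC-rich 25-mer complement scores far below -20", {
  set.seed(57)
  core <- paste0(sample(c("G", "C"), 25, TRUE), collapse = "")
  lnc <- paste0(strrep("A", 40), core, strrep("A", 40))
  rc <- chartr("ACGT", "TGCA",
               paste0(rev(strsplit(core, "")[[1]]), collapse = ""))
  mrna <- paste0(strrep("T", 40), rc, strrep("T", 40))
  hits <- trans_targets(c(L = lnc), c(M = mrna), pipeline_config())
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$energy, -40)

  # unrelated random 500-nt transcripts (study background composition,
  # A/T 0.3, C/G 0.2) rarely cross -20
  fp <- 0L
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (rep in 1:100) {
    x <- paste0(sample(names(bg), 500, TRUE, prob = bg), collapse = "")
    y <- paste0(sample(names(bg), 500, TRUE, prob = bg), collapse = "")
    h <- duplex_energy(x, y, 6L)
    if (nrow(h) && h$energy < -20) fp <- fp + 1L
  }
  expect_lt(fp / 100, 0.05)
})
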