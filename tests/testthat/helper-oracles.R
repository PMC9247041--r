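# Independent brute-force oracles. Each re-derives the expected result from
# first principles with plain loops, sharing no code path with the package
# implementation it checks.

# ---- classification oracle -------------------------------------------------

# ref: a genome_annotation; tx: exon data frame of one transcript
oracle_class_code <- function(tx, ref) {
  tx <- tx[order(tx$start), ]
  chrom <- tx$chrom[1L]; strand <- tx$strand[1L]
  span <- c(min(tx$start), max(tx$end))
  genes <- ref$genes[ref$genes$chrom == chrom, ]
  span_hit <- FALSE
  for (g in seq_len(nrow(genes))) {
    if (genes$start[g] < span[2L] && genes$end[g] > span[1L]) span_hit <- TRUE
  }
  if (!span_hit) return("u")
  exonic_same <- FALSE; exonic_anti <- FALSE
  ref_ex <- ref$exons[ref$exons$chrom == chrom, ]
  for (i in seq_len(nrow(tx))) {
    for (j in seq_len(nrow(ref_ex))) {
      if (ref_ex$start[j] < tx$end[i] && ref_ex$end[j] > tx$start[i]) {
        if (ref_ex$strand[j] == strand) exonic_same <- TRUE else exonic_anti <- TRUE
      }
    }
  }
  # '=': identical intron chain with a same-strand reference transcript
  eq <- FALSE
  ref_tx_ids <- unique(ref$transcripts$transcript_id[
    ref$transcripts$chrom == chrom & ref$transcripts$strand == strand])
  for (tid in ref_tx_ids) {
    rex <- ref_ex[ref_ex$transcript_id == tid, ]
    rex <- rex[order(rex$start), ]
    if (nrow(tx) == 1L) {
      if (nrow(rex) == 1L && tx$start >= rex$start && tx$end <= rex$end) eq <- TRUE
    } else if (nrow(rex) == nrow(tx) && nrow(tx) > 1L) {
      ic_tx <- cbind(tx$end[-nrow(tx)], tx$start[-1L])
      ic_rx <- cbind(rex$end[-nrow(rex)], rex$start[-1L])
      if (all(ic_tx == ic_rx)) eq <- TRUE
    }
  }
  if (eq && exonic_same) return("=")
  if (exonic_anti) return("x")
  if (exonic_same) return("o")
  # 'i': wholly inside one intron of some overlapping reference transcript
  for (tid in unique(ref_ex$transcript_id)) {
    rex <- ref_ex[ref_ex$transcript_id == tid, ]
    rex <- rex[order(rex$start), ]
    if (nrow(rex) < 2L) next
    for (k in seq_len(nrow(rex) - 1L)) {
      if (span[1L] >= rex$end[k] && span[2L] <= rex$start[k + 1L]) return("i")
    }
  }
  "other"
}

# random (transcript, annotation) instance for classifier stress tests
random_classify_instance <- function() {
  n_genes <- sample(2:4, 1L)
  ref_exons <- list()
  cursor <- sample(500:2000, 1L)
  for (g in seq_len(n_genes)) {
    n_tx <- sample(1:2, 1L)
    g_strand <- sample(c("+", "-"), 1L)
    gstart <- cursor
    for (t in seq_len(n_tx)) {
      n_ex <- sample(1:3, 1L)
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(100:600, n_ex - 1L, replace = TRUE) else integer()
      starts <- gstart + sample(0:200, 1L) + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ref_exons[[length(ref_exons) + 1L]] <- tibble::tibble(
        chrom = "c1", start = starts, end = starts + ex_len, strand = g_strand,
        transcript_id = sprintf("rg%d.%d", g, t), gene_id = sprintf("rg%d", g)
      )
    }
    cursor <- cursor + sample(1500:4000, 1L)
  }
  ref <- annotation(dplyr::bind_rows(ref_exons))
  # candidate: random interval near or inside the gene landscape
  n_ex <- sample(1:3, 1L)
  ex_len <- sample(60:250, n_ex, replace = TRUE)
  in_len <- if (n_ex > 1L) sample(50:400, n_ex - 1L, replace = TRUE) else integer()
  anchor <- sample(200:(cursor + 1000L), 1L)
  starts <- anchor + c(0L, cumsum(ex_len[-n_ex] + in_len))
  tx <- tibble::tibble(chrom = "c1", start = starts, end = starts + ex_len,
                       strand = sample(c("+", "-"), 1L),
                       transcript_id = "cand", gene_id = "cand")
  list(tx = tx, ref = ref)
}

# ---- ORF oracle ------------------------------------------------------------

oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  cands <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    cods <- substring(seq, f + 1L + 3L * (0:(ncod - 1L)), f + 3L * (1:ncod))
    for (a in seq_len(ncod)) {
      if (cods[a] != "ATG") next
      # skip ATGs preceded (since last stop) by an earlier ATG in frame
      blocked <- FALSE
      b <- a - 1L
      while (b >= 1L && !(cods[b] %in% stops)) {
        if (cods[b] == "ATG") blocked <- TRUE
        b <- b - 1L
      }
      if (blocked) next
      e <- a
      while (e <= ncod && !(cods[e] %in% stops)) e <- e + 1L
      has_stop <- e <= ncod
      end_cod <- if (has_stop) e else ncod
      cands[[length(cands) + 1L]] <- list(
        start = f + 3L * (a - 1L), end = f + 3L * end_cod, frame = f,
        has_start = TRUE, has_stop = has_stop
      )
    }
  }
  if (!length(cands)) {
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 1L) next
      cods <- substring(seq, f + 1L + 3L * (0:(ncod - 1L)), f + 3L * (1:ncod))
      a <- 1L
      for (e in 1:(ncod + 1L)) {
        if (e > ncod || cods[e] %in% stops) {
          if (e > a) {
            cands[[length(cands) + 1L]] <- list(
              start = f + 3L * (a - 1L), end = f + 3L * (e - 1L), frame = f,
              has_start = FALSE, has_stop = FALSE)
          }
          a <- e + 1L
        }
      }
    }
  }
  if (!length(cands)) {
    return(list(start = 0L, end = 0L, length_nt = 0L))
  }
  lens <- vapply(cands, function(x) x$end - x$start, numeric(1L))
  starts <- vapply(cands, function(x) x$start, numeric(1L))
  best <- order(-lens, starts)[1L]
  out <- cands[[best]]
  out$length_nt <- out$end - out$start
  out
}

# ---- Fickett second implementation ----------------------------------------

oracle_fickett <- function(seq) {
  tabs <- peachlnc:::fickett_tables()
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1L]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0L, 0L, 0L)
    for (i in seq_along(ch)) {
      if (ch[i] == b) cnt[(i - 1L) %% 3L + 1L] <- cnt[(i - 1L) %% 3L + 1L] + 1L
    }
    ppar <- max(cnt) / (min(cnt) + 1)
    pbin <- 10L
    for (k in 1:10) if (ppar >= tabs$position_edges[k]) { pbin <- k; break }
    cpar <- sum(cnt) / length(ch)
    cbin <- 10L
    for (k in 1:10) if (cpar >= tabs$content_edges[k]) { cbin <- k; break }
    total <- total + tabs$position_prob[[b]][pbin] * tabs$position_weight[[b]] +
      tabs$content_prob[[b]][cbin] * tabs$content_weight[[b]]
  }
  total
}

# ---- BH oracle -------------------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# ---- duplex oracle ---------------------------------------------------------

# independently transcribed Turner 2004 stack matrix (dG37, kcal/mol);
# rows: first pair x1:y1, cols written (y2,x2) in the source convention
oracle_stack_matrix <- local({
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  matrix(c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
  ), nrow = 6L, byrow = TRUE, dimnames = list(pairs, pairs))
})

oracle_stack <- function(x1, x2, y1, y2) {
  row <- paste0(x1, y1); col <- paste0(y2, x2)
  if (!row %in% rownames(oracle_stack_matrix) ||
      !col %in% colnames(oracle_stack_matrix)) return(NA_real_)
  oracle_stack_matrix[row, col]
}

oracle_pair <- function(x, y) {
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  list(ok = (!is.na(wc[x]) && wc[[x]] == y) ||
         (x == "G" && y == "U") || (x == "U" && y == "G"),
       wc = !is.na(wc[x]) && wc[[x]] == y)
}

# exhaustive enumeration over every ungapped antiparallel offset and every
# contiguous paired sub-run containing a Watson-Crick seed of >= seed_len
oracle_duplex <- function(a, b, seed_len = 6L, init = 4.09) {
  a <- chartr("Tt", "Uu", toupper(a)); b <- chartr("Tt", "Uu", toupper(b))
  ac <- strsplit(a, "")[[1L]]
  rb <- rev(strsplit(b, "")[[1L]])
  na <- length(ac); nb <- length(rb)
  best <- Inf
  for (d in (1L - nb):(na - 1L)) {
    i_lo <- max(1L, 1L + d); i_hi <- min(na, nb + d)
    if (i_hi - i_lo + 1L < seed_len) next
    idx <- i_lo:i_hi
    ok <- logical(length(idx)); wc <- logical(length(idx))
    for (t in seq_along(idx)) {
      pr <- oracle_pair(ac[idx[t]], rb[idx[t] - d])
      ok[t] <- pr$ok; wc[t] <- pr$wc
    }
    for (u in seq_along(idx)) {
      if (!ok[u]) next
      for (v in u:length(idx)) {
        if (!all(ok[u:v])) break
        if (v - u + 1L < seed_len) next
        # WC seed of >= seed_len within [u, v]?
        run <- 0L; has_seed <- FALSE
        for (t in u:v) {
          run <- if (wc[t]) run + 1L else 0L
          if (run >= seed_len) has_seed <- TRUE
        }
        if (!has_seed) next
        e <- init
        for (t in u:(v - 1L)) {
          e <- e + oracle_stack(ac[idx[t]], ac[idx[t + 1L]],
                                rb[idx[t] - d], rb[idx[t + 1L] - d])
        }
        if (e < best) best <- e
      }
    }
  }
  if (is.infinite(best)) NULL else best
}

# ---- miRNA site oracle -----------------------------------------------------

oracle_site_score <- function(mirna, window) {
  mirna <- chartr("Tt", "Uu", toupper(mirna))
  window <- chartr("Tt", "Uu", toupper(window))
  mi <- strsplit(mirna, "")[[1L]]
  wi <- strsplit(window, "")[[1L]]
  n <- length(mi)
  s <- 0
  for (p in seq_len(n)) {
    pr <- oracle_pair(mi[p], wi[n - p + 1L])
    pen <- if (pr$wc) 0 else if (pr$ok) 0.5 else 1
    if (p >= 2L && p <= 13L) pen <- pen * 2
    s <- s + pen
  }
  s
}

oracle_sites <- function(mirna, transcript, max_score) {
  k <- nchar(mirna); n <- nchar(transcript)
  hits <- list()
  for (off in seq_len(n - k + 1L)) {
    sc <- oracle_site_score(mirna, substr(transcript, off, off + k - 1L))
    if (sc <= max_score) {
      hits[[length(hits) + 1L]] <- c(offset = off - 1L, score = sc)
    }
  }
  if (!length(hits)) return(data.frame(offset = integer(), score = numeric()))
  as.data.frame(do.call(rbind, hits))
}

# ---- hypergeometric enumeration -------------------------------------------

oracle_hyper_upper <- function(N, K, n, k) {
  tot <- 0
  for (j in k:min(n, K)) {
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  }
  tot / choose(N, n)
}

# ---- chain enumeration (synteny) ------------------------------------------

# exhaustive longest chain over <= ~15 anchors: all subsequences via DFS
oracle_longest_chain_len <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  ord <- order(rank_a, rank_b)
  ra <- rank_a[ord]; rb <- rank_b[ord]
  best <- 0L
  for (dir in c(1L, -1L)) {
    ext <- function(last, len) {
      best <<- max(best, len)
      for (j in seq_len(n)) {
        ga <- ra[j] - ra[last]
        gb <- dir * (rb[j] - rb[last])
        if (ga > 0L && ga <= max_gap && gb > 0L && gb <= max_gap) ext(j, len + 1L)
      }
    }
    for (s in seq_len(n)) ext(s, 1L)
  }
  best
}

# ---- adjusted Rand index ---------------------------------------------------

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
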