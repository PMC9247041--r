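# Cis-target prediction by genomic proximity and trans-target prediction by
# ungapped nearest-neighbor RNA-RNA duplex energy.

# RNA nearest-neighbor helix stack free energies, dG37 in kcal/mol,
# Turner 2004 parameter set (Mathews et al. 2004; as distributed with the
# ViennaRNA rna_turner2004.par tables). Watson-Crick and G:U wobble stacks.
# Key convention: a stack of consecutive pairs x1:y1, x2:y2 along the top
# strand (5'->3'; bottom strand antiparallel) is looked up as
# "x1 x2 / y1 y2" flattened to the string x1x2y1y2 over the RNA alphabet.
rna_stack_table <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  m <- matrix(c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
  ), nrow = 6L, byrow = TRUE, dimnames = list(pairs, pairs))
  # matrix rows are the pair (x1,y1); columns index the inner pair written
  # (y2,x2) in the source convention -- flatten to x1x2y1y2 keys
  out <- new.env(parent = emptyenv())
  for (p1 in pairs) {
    for (col in pairs) {
      x1 <- substr(p1, 1L, 1L); y1 <- substr(p1, 2L, 2L)
      y2 <- substr(col, 1L, 1L); x2 <- substr(col, 2L, 2L)
      assign(paste0(x1, x2, y1, y2), m[p1, col], envir = out)
    }
  }
  out
}

.pkg_cache <- new.env(parent = emptyenv())

stack_energy <- function(x1, x2, y1, y2) {
  if (is.null(.pkg_cache$stacks)) .pkg_cache$stacks <- rna_stack_table()
  key <- paste0(x1, x2, y1, y2)
  if (!exists(key, envir = .pkg_cache$stacks, inherits = FALSE)) {
    return(NA_real_)
  }
  get(key, envir = .pkg_cache$stacks, inherits = FALSE)
}

DUPLEX_INIT <- 4.09  # helix initiation penalty, kcal/mol (Xia et al. 1998)

to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

pairable <- function(x, y) {
  wc <- !is.na(WC_PARTNER[x]) & WC_PARTNER[x] == y
  gu <- (x == "G" & y == "U") | (x == "U" & y == "G")
  list(ok = wc | gu, wc = wc)
}

#' Minimum ungapped RNA-RNA duplex energy
#'
#' Considers every ungapped antiparallel pairing of the two sequences.
#' Within each maximal contiguous run of pairable positions (Watson-Crick or
#' G:U), the contiguous sub-run that minimizes the summed nearest-neighbor
#' stack energies is found exactly, subject to containing an exact
#' Watson-Crick seed of at least `seed_len` pairs; the reported energy is
#' the helix initiation penalty plus that stack sum. Bulges and internal
#' loops are out of scope, which keeps an exhaustive enumeration oracle
#' exact.
#'
#' @param a,b Nucleotide strings (T and U are equivalent).
#' @param seed_len Minimum exact-complement seed length (default 6).
#' @return A one-row tibble `energy`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open spans of the paired region in each input), or a
#'   zero-row tibble if no seed exists.
#' @export
duplex_energy <- function(a, b, seed_len = 6L) {
  if (!nzchar(a) || !nzchar(b)) abort("duplex_energy: empty sequence")
  a <- to_rna(a); b <- to_rna(b)
  na <- nchar(a); nb <- nchar(b)
  empty <- tibble(energy = numeric(), a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer())
  if (na < seed_len || nb < seed_len) return(empty)
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  rbv <- rev(strsplit(b, "", fixed = TRUE)[[1L]])  # b reversed: antiparallel
  # seeds: common seed_len-mers of a and revcomp(b)
  rc <- unname(WC_PARTNER[rbv])
  rc[is.na(rc)] <- "N"
  kmer <- function(ch, k) {
    n <- length(ch)
    if (n < k) return(character())
    s <- vapply(seq_len(n - k + 1L),
                function(i) paste0(ch[i:(i + k - 1L)], collapse = ""),
                character(1L))
    s
  }
  ka <- kmer(ac, seed_len)
  kb <- kmer(rc, seed_len)
  hits_b <- split(seq_along(kb), kb)
  diags <- integer()
  for (i in seq_along(ka)) {
    js <- hits_b[[ka[i]]]
    if (!is.null(js)) diags <- c(diags, i - js)
  }
  diags <- unique(diags)
  if (!length(diags)) return(empty)
  best <- NULL
  for (d in diags) {
    # a index i pairs rb index i - d
    i_lo <- max(1L, 1L + d)
    i_hi <- min(na, nb + d)
    idx_a <- i_lo:i_hi
    idx_rb <- idx_a - d
    pr <- pairable(ac[idx_a], rbv[idx_rb])
    res <- best_subrun(pr$ok, pr$wc, ac[idx_a], rbv[idx_rb], seed_len)
    if (!is.null(res)) {
      res$a_start <- idx_a[res$u] - 1L
      res$a_end <- idx_a[res$v]
      # rb index r corresponds to b position nb - r + 1 (1-based)
      res$b_start <- nb - idx_rb[res$v]
      res$b_end <- nb - idx_rb[res$u] + 1L
      if (is.null(best) || res$energy < best$energy) best <- res
    }
  }
  if (is.null(best)) return(empty)
  tibble(energy = best$energy, a_start = best$a_start, a_end = best$a_end,
         b_start = best$b_start, b_end = best$b_end)
}

# exact minimum-energy contiguous pair sub-run containing a WC seed run
best_subrun <- function(ok, wc, xa, xb, seed_len) {
  n <- length(ok)
  runs <- rle_runs(ok)
  best <- NULL
  for (r in seq_len(nrow(runs))) {
    if (!runs$value[r] || runs$len[r] < seed_len) next
    lo <- runs$from[r]; hi <- runs$to[r]
    span <- lo:hi
    wcr <- rle_runs(wc[span])
    wcr <- wcr[wcr$value & wcr$len >= seed_len, , drop = FALSE]
    if (!nrow(wcr)) next
    L <- length(span)
    stacks <- vapply(seq_len(L - 1L), function(t) {
      stack_energy(xa[span[t]], xa[span[t + 1L]], xb[span[t]], xb[span[t + 1L]])
    }, numeric(1L))
    cs <- c(0, cumsum(stacks))
    for (u in seq_len(L)) {
      for (v in u:L) {
        if (v - u + 1L < seed_len) next
        has_seed <- any(pmin(wcr$to, v) - pmax(wcr$from, u) + 1L >= seed_len)
        if (!has_seed) next
        e <- DUPLEX_INIT + (cs[v] - cs[u])
        if (is.null(best) || e < best$energy) {
          best <- list(energy = e, u = span[u], v = span[v])
        }
      }
    }
  }
  best
}

rle_runs <- function(x) {
  r <- rle(x)
  to <- cumsum(r$lengths)
  tibble(value = r$values, len = r$lengths,
         from = to - r$lengths + 1L, to = to)
}

#' Cis targets of lncRNAs
#'
#' All annotated genes whose span lies within `window` nt of a lncRNA span
#' (boundary-to-boundary distance, inclusive; overlap counts as distance 0),
#' on either strand.
#'
#' @param lnc_spans Tibble with `transcript_id`, `chrom`, `start`, `end`
#'   (e.g. from [transcript_spans()]).
#' @param ref A `genome_annotation`.
#' @param window Window size in nt (default from [pipeline_config()]).
#' @return Tibble: `transcript_id`, `gene_id`, `distance` (nt, 0 if
#'   overlapping), `side` (`upstream`/`downstream`/`overlapping`).
#' @export
cis_targets <- function(lnc_spans, ref, window = pipeline_config()$cis_window) {
  out <- purrr::pmap(
    list(lnc_spans$transcript_id, lnc_spans$chrom,
         lnc_spans$start, lnc_spans$end),
    function(id, chrom, s, e) {
      g <- ref$genes[ref$genes$chrom == chrom, ]
      if (!nrow(g)) return(NULL)
      dist <- ifelse(g$end <= s, s - g$end,
                     ifelse(g$start >= e, g$start - e, 0L))
      side <- ifelse(g$end <= s, "upstream",
                     ifelse(g$start >= e, "downstream", "overlapping"))
      keep <- dist <= window
      if (!any(keep)) return(NULL)
      tibble(transcript_id = id, gene_id = g$gene_id[keep],
             distance = as.integer(dist[keep]), side = side[keep])
    })
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(transcript_id = character(), gene_id = character(),
                  distance = integer(), side = character())
  }
  out
}

#' Trans targets of lncRNAs
#'
#' Scores every (lncRNA, mRNA) pair with [duplex_energy()] and keeps pairs
#' whose minimum energy is strictly below the cutoff (one best duplex per
#' pair).
#'
#' @param lnc_seqs,mrna_seqs Named character vectors of spliced sequences.
#' @param cfg A [pipeline_config()]; uses `trans_energy_cutoff` and
#'   `duplex_seed_len`.
#' @return Tibble: `lnc_id`, `mrna_id`, `energy`, `lnc_start`, `lnc_end`,
#'   `mrna_start`, `mrna_end`.
#' @export
trans_targets <- function(lnc_seqs, mrna_seqs, cfg = pipeline_config()) {
  rows <- list()
  for (ln in names(lnc_seqs)) {
    for (mr in names(mrna_seqs)) {
      h <- duplex_energy(lnc_seqs[[ln]], mrna_seqs[[mr]],
                         seed_len = cfg$duplex_seed_len)
      if (nrow(h) && h$energy < cfg$trans_energy_cutoff) {
        rows[[length(rows) + 1L]] <- tibble(
          lnc_id = ln, mrna_id = mr, energy = h$energy,
          lnc_start = h$a_start, lnc_end = h$a_end,
          mrna_start = h$b_start, mrna_end = h$b_end
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble(lnc_id = character(), mrna_id = character(),
                  energy = numeric(), lnc_start = integer(),
                  lnc_end = integer(), mrna_start = integer(),
                  mrna_end = integer()))
  }
  bind_rows(rows)
}
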