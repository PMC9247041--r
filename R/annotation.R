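#' @section Coordinate convention:
#' All coordinates inside the package are 0-based half-open `[start, end)`;
#' GFF3/GTF files (1-based inclusive) are converted at the I/O boundary.
#' @name peachlnc-coordinates
#' @keywords internal
NULL

# ---- exon tables -----------------------------------------------------------

#' Validate an exon table
#'
#' An exon table is the package's transcript representation: one row per exon
#' with columns `chrom`, `start`, `end`, `strand`, `transcript_id`, `gene_id`,
#' coordinates 0-based half-open. Exons of a transcript must be
#' non-overlapping, on one chromosome and strand.
#'
#' @param exons A data frame of exons.
#' @return The validated exon table, sorted by transcript and start,
#'   invisibly usable in a pipe.
#' @export
validate_exons <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  miss <- setdiff(need, names(exons))
  if (length(miss)) {
    abort(paste0("exon table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  exons <- as_tibble(exons)
  if (any(exons$start < 0) || any(exons$end <= exons$start)) {
    abort("exon coordinates must satisfy 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("exon strand must be '+' or '-' (unstranded transcripts are rejected)")
  }
  exons <- arrange(exons, .data$transcript_id, .data$start)
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      one_chrom = length(unique(.data$chrom)) == 1L,
      one_strand = length(unique(.data$strand)) == 1L,
      disjoint = all(.data$start[-1L] >= .data$end[-length(.data$end)]) ||
        n() == 1L,
      .groups = "drop"
    ) %>%
    filter(!.data$one_chrom | !.data$one_strand | !.data$disjoint)
  if (nrow(bad)) {
    abort(paste0("invalid transcript(s): ",
                 paste(utils::head(bad$transcript_id, 5L), collapse = ", ")))
  }
  exons
}

#' Summarise an exon table at transcript level
#'
#' @param exons A validated exon table.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (span), `n_exons`, `length` (spliced nt).
#' @export
transcript_spans <- function(exons) {
  validate_exons(exons) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      length = sum(.data$end - .data$start),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "n_exons", "length")
}

# ---- genome annotation -----------------------------------------------------

#' Build a genome annotation from an exon table
#'
#' Groups transcripts under genes, computes gene spans (min start to max end
#' over all transcripts of the locus), assigns per-chromosome gene ranks
#' (0-based, consecutive in coordinate order), and builds a `GRanges` interval
#' index for overlap queries.
#'
#' @param exons Exon table (see [validate_exons()]).
#' @param biotypes Optional tibble `gene_id`, `biotype` with biotype one of
#'   `"coding"`, `"noncoding"`; genes absent from it default to `"coding"`.
#' @return A `genome_annotation` object: list with tibbles `exons`,
#'   `transcripts`, `genes` and `GRanges` indexes.
#' @export
annotation <- function(exons, biotypes = NULL) {
  exons <- validate_exons(exons)
  txs <- transcript_spans(exons)
  genes <- txs %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = n(),
      .groups = "drop"
    )
  if (!is.null(biotypes)) {
    genes <- left_join(genes, as_tibble(biotypes)[c("gene_id", "biotype")],
                       by = "gene_id")
    genes$biotype[is.na(genes$biotype)] <- "coding"
  } else {
    genes$biotype <- "coding"
  }
  genes <- genes %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .data$end, .data$gene_id, .by_group = TRUE) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$rank)
  ann <- list(
    exons = exons,
    transcripts = txs,
    genes = genes,
    gr_genes = granges_from(genes, genes$gene_id),
    gr_exons = granges_from(exons, exons$transcript_id)
  )
  class(ann) <- "genome_annotation"
  ann
}

granges_from <- function(tbl, names) {
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = tbl$strand
  )
  names(gr) <- names
  gr
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Genes overlapping an interval
#'
#' Returns the genes whose span intersects the query (>= 1 shared base),
#' using the annotation's interval index; strand is ignored unless given.
#'
#' @param ann A `genome_annotation`.
#' @param chrom,start,end Query interval, 0-based half-open.
#' @param strand Optional strand filter (`"+"` or `"-"`).
#' @return Tibble of matching gene rows.
#' @export
genes_overlapping <- function(ann, chrom, start, end, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, ann$gr_genes, ignore.strand = TRUE)
  out <- ann$genes[S4Vectors::subjectHits(hits), ]
  if (!is.null(strand)) out <- filter(out, .data$strand == .env$strand)
  out
}

# ---- file I/O --------------------------------------------------------------

#' Read a genome annotation from GFF3 or GTF
#'
#' Coordinates are converted from the file's 1-based inclusive convention to
#' the internal 0-based half-open one. Gene biotype is taken from a
#' `gene_biotype`/`biotype` attribute when present (values containing
#' "noncoding"/"lncRNA"/"lnc_RNA" map to `"noncoding"`), else `"coding"`.
#'
#' @param path File path.
#' @param dialect `"gff3"` or `"gtf"`; default guessed from the extension.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dialect <- dialect %||% guess_dialect(path)
  check_gff_lines(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  if (dialect == "gtf") {
    ex <- df[df$type == "exon", ]
    exons <- tibble(
      chrom = as.character(ex$seqnames),
      start = ex$start - 1L,
      end = ex$end,
      strand = as.character(ex$strand),
      transcript_id = ex$transcript_id,
      gene_id = ex$gene_id
    )
    bios <- gtf_biotypes(df)
  } else {
    tx_types <- c("mRNA", "transcript", "lnc_RNA", "lincRNA", "ncRNA")
    txf <- df[df$type %in% tx_types, ]
    parent_chr <- function(p) vapply(p, function(x) as.character(x)[1L], character(1L))
    tx2gene <- setNames(parent_chr(txf$Parent), txf$ID)
    ex <- df[df$type == "exon", ]
    tx_of_exon <- parent_chr(ex$Parent)
    exons <- tibble(
      chrom = as.character(ex$seqnames),
      start = ex$start - 1L,
      end = ex$end,
      strand = as.character(ex$strand),
      transcript_id = tx_of_exon,
      gene_id = unname(tx2gene[tx_of_exon])
    )
    # exon must lie inside its transcript's declared bounds
    txb <- tibble(transcript_id = txf$ID, tstart = txf$start - 1L, tend = txf$end)
    chk <- inner_join(exons, txb, by = "transcript_id")
    off <- chk$start < chk$tstart | chk$end > chk$tend
    if (any(off)) {
      abort(paste0("exon outside declared transcript bounds for: ",
                   paste(unique(chk$transcript_id[off])[1:min(3, sum(off))],
                         collapse = ", ")))
    }
    bios <- gff3_biotypes(df)
  }
  annotation(exons, biotypes = bios)
}

guess_dialect <- function(path) {
  if (grepl("\\.(gtf)$", path, ignore.case = TRUE)) "gtf" else "gff3"
}

check_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1L))
  bad <- body[nf < 8L]
  if (length(bad)) {
    abort(sprintf("malformed annotation line %d in %s (%d field(s), expected 9)",
                  bad[1L], path, nf[which(body == bad[1L])]))
  }
  invisible(TRUE)
}

biotype_of <- function(x) {
  ifelse(grepl("noncoding|lnc", x, ignore.case = TRUE), "noncoding", "coding")
}

gtf_biotypes <- function(df) {
  col <- intersect(c("gene_biotype", "biotype"), names(df))
  if (!length(col)) return(NULL)
  b <- df[!is.na(df[[col[1L]]]), c("gene_id", col[1L])]
  if (!nrow(b)) return(NULL)
  tibble(gene_id = b$gene_id, biotype = biotype_of(b[[col[1L]]])) %>% distinct()
}

gff3_biotypes <- function(df) {
  col <- intersect(c("gene_biotype", "biotype"), names(df))
  if (!length(col)) return(NULL)
  g <- df[df$type == "gene" & !is.na(df[[col[1L]]]), c("ID", col[1L])]
  if (!nrow(g)) return(NULL)
  tibble(gene_id = g$ID, biotype = biotype_of(g[[col[1L]]])) %>% distinct()
}

#' Write a genome annotation to GFF3 or GTF
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive. GFF3 output uses gene/mRNA/exon rows
#' linked by ID/Parent; GTF output uses transcript/exon rows with
#' `gene_id`/`transcript_id` attributes.
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @param dialect `"gff3"` or `"gtf"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  ex <- ann$exons
  tx <- ann$transcripts
  gn <- ann$genes
  if (dialect == "gtf") {
    feats <- bind_rows(
      tx %>% mutate(type = "transcript"),
      ex %>% left_join(select(tx, "transcript_id"), by = "transcript_id") %>%
        mutate(type = "exon")
    )
    gr <- GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end), feats$strand,
      type = feats$type, gene_id = feats$gene_id,
      transcript_id = feats$transcript_id,
      gene_biotype = gn$biotype[match(feats$gene_id, gn$gene_id)]
    )
    rtracklayer::export(gr, path, format = "gtf")
  } else {
    gfeat <- gn %>% mutate(type = "gene", ID = .data$gene_id, Parent = NA_character_)
    tfeat <- tx %>% mutate(type = "mRNA", ID = .data$transcript_id, Parent = .data$gene_id)
    efeat <- ex %>%
      group_by(.data$transcript_id) %>%
      mutate(ID = paste0(.data$transcript_id, ".exon", row_number())) %>%
      ungroup() %>%
      mutate(type = "exon", Parent = .data$transcript_id)
    feats <- bind_rows(
      select(gfeat, "chrom", "start", "end", "strand", "type", "ID", "Parent"),
      select(tfeat, "chrom", "start", "end", "strand", "type", "ID", "Parent"),
      select(efeat, "chrom", "start", "end", "strand", "type", "ID", "Parent")
    )
    gr <- GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end), feats$strand,
      type = feats$type, ID = feats$ID,
      Parent = ifelse(is.na(feats$Parent), "", feats$Parent),
      gene_biotype = gn$biotype[match(feats$ID, gn$gene_id)]
    )
    gr$Parent[gr$Parent == ""] <- NA_character_
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Write candidate transcripts as GTF
#'
#' @param exons Exon table of the candidates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(exons, path) {
  exons <- validate_exons(exons)
  gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end), exons$strand,
    type = "exon", gene_id = exons$gene_id, transcript_id = exons$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# ---- sequences -------------------------------------------------------------

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings that return plain named character vectors,
#' the sequence currency of this package.
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Spliced transcript sequences
#'
#' Concatenates exon substrings of the chromosome sequence in coordinate
#' order and reverse-complements minus-strand transcripts, yielding each
#' transcript's 5'->3' spliced sequence.
#'
#' @param exons Exon table.
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector, one sequence per transcript.
#' @export
spliced_sequences <- function(exons, genome) {
  exons <- validate_exons(exons)
  miss <- setdiff(unique(exons$chrom), names(genome))
  if (length(miss)) abort(paste0("chromosome(s) absent from genome: ",
                                 paste(miss, collapse = ", ")))
  too_far <- exons$end > nchar(genome)[match(exons$chrom, names(genome))]
  if (any(too_far)) {
    abort(paste0("exon beyond chromosome end in transcript(s): ",
                 paste(unique(exons$transcript_id[too_far]), collapse = ", ")))
  }
  pieces <- substring(genome[exons$chrom], exons$start + 1L, exons$end)
  out <- vapply(split(pieces, exons$transcript_id)[unique(exons$transcript_id)],
                paste0, character(1L), collapse = "")
  minus <- transcript_spans(exons) %>% filter(.data$strand == "-")
  if (nrow(minus)) out[minus$transcript_id] <- revcomp(out[minus$transcript_id])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
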