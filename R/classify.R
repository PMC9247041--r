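#' Class codes for assembled transcripts
#'
#' Each candidate transcript is compared with the reference annotation and
#' given a one-symbol class code describing its positional relationship, in
#' the style of transcript-comparison tools:
#'
#' * `=` — intron chain identical to a reference transcript (single-exon
#'   candidates match a single-exon reference contained within its exon
#'   boundaries);
#' * `x` — exonic overlap with a reference exon on the opposite strand
#'   (antisense);
#' * `o` — exonic overlap with a reference exon on the same strand (sense);
#' * `i` — fully contained in a single intron of a reference transcript on
#'   either strand, with no exonic overlap anywhere;
#' * `u` — no overlap with any reference gene span (intergenic);
#' * `other` — remaining configurations (e.g. spanning an intron/exon
#'   boundary without touching an exon of that gene).
#'
#' When several conditions hold the code is resolved by the fixed priority
#' `=` > `x` > `o` > `i` > `u`: exonic evidence outranks intronic
#' containment, and antisense overlap is the most specific novel signal.
#' Overlap means at least one shared base. A candidate on a chromosome
#' absent from the reference is classed `u` with a warning.
#'
#' @param candidates Exon table of candidate transcripts.
#' @param ref A `genome_annotation`.
#' @return Tibble: `transcript_id`, `gene_id`, `class_code`, `category`
#'   (lincRNA/intronic/sense/antisense, `NA` for `=`/`other`), `chrom`,
#'   `strand`, `n_exons`, `length`.
#' @export
#' @examples
#' ref <- annotation(tibble::tibble(
#'   chrom = "chr1", start = c(1000L, 2000L), end = c(1500L, 2500L),
#'   strand = "+", transcript_id = "t1", gene_id = "g1"
#' ))
#' cand <- tibble::tibble(
#'   chrom = "chr1", start = c(5000L, 6000L), end = c(5300L, 6200L),
#'   strand = "+", transcript_id = "c1", gene_id = "c1"
#' )
#' classify_transcripts(cand, ref)
classify_transcripts <- function(candidates, ref) {
  candidates <- validate_exons(candidates)
  spans <- transcript_spans(candidates)
  known <- unique(ref$genes$chrom)
  off_chrom <- setdiff(unique(spans$chrom), known)
  if (length(off_chrom)) {
    warn(paste0("candidate chromosome(s) absent from reference, classed 'u': ",
                paste(off_chrom, collapse = ", ")))
  }
  ex_by_tx <- split(candidates, candidates$transcript_id)
  codes <- vapply(spans$transcript_id, function(id) {
    assign_class_code(ex_by_tx[[id]], ref)
  }, character(1L))
  spans %>%
    mutate(class_code = unname(codes),
           category = class_to_category(.data$class_code)) %>%
    select("transcript_id", "gene_id", "class_code", "category",
           "chrom", "strand", "n_exons", "length")
}

#' Class code of a single transcript
#'
#' @param tx_exons Exon table of one transcript (rows sorted internally).
#' @param ref A `genome_annotation`.
#' @return A single class code string.
#' @export
assign_class_code <- function(tx_exons, ref) {
  tx_exons <- arrange(tx_exons, .data$start)
  chrom <- tx_exons$chrom[1L]
  strand <- tx_exons$strand[1L]
  span <- c(min(tx_exons$start), max(tx_exons$end))

  if (!chrom %in% unique(ref$genes$chrom)) return("u")

  ovl_genes <- genes_overlapping(ref, chrom, span[1L], span[2L])
  if (!nrow(ovl_genes)) return("u")

  # reference transcripts on this chromosome whose span intersects ours
  ref_tx <- ref$transcripts %>%
    filter(.data$chrom == .env$chrom,
           .data$start < span[2L], .data$end > span[1L])
  ref_ex <- ref$exons %>% semi_join(ref_tx, by = "transcript_id")

  exonic_same <- exon_overlap_any(tx_exons, filter(ref_ex, .data$strand == .env$strand))
  exonic_anti <- exon_overlap_any(tx_exons, filter(ref_ex, .data$strand != .env$strand))

  if (exonic_same && intron_chain_match(tx_exons, ref_tx, ref$exons)) return("=")
  if (exonic_anti) return("x")
  if (exonic_same) return("o")
  if (within_single_intron(tx_exons, ref_tx, ref$exons)) return("i")
  "other"
}

exon_overlap_any <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  for (i in seq_len(nrow(a))) {
    if (any(b$start < a$end[i] & b$end > a$start[i])) return(TRUE)
  }
  FALSE
}

# intron chain identity against any same-strand reference transcript;
# single-exon candidates: containment within a single-exon reference exon
intron_chain_match <- function(tx_exons, ref_tx, ref_exons) {
  strand <- tx_exons$strand[1L]
  cand_introns <- intron_chain(tx_exons)
  for (tid in ref_tx$transcript_id[ref_tx$strand == strand]) {
    rex <- ref_exons[ref_exons$transcript_id == tid, ]
    rex <- arrange(rex, .data$start)
    if (nrow(tx_exons) == 1L) {
      if (nrow(rex) == 1L &&
          tx_exons$start >= rex$start && tx_exons$end <= rex$end) {
        return(TRUE)
      }
    } else if (nrow(rex) > 1L) {
      if (identical(cand_introns, intron_chain(rex))) return(TRUE)
    }
  }
  FALSE
}

intron_chain <- function(exons) {
  exons <- arrange(exons, .data$start)
  if (nrow(exons) < 2L) return(NULL)
  cbind(exons$end[-nrow(exons)], exons$start[-1L])
}

# transcript entirely inside one intron of some reference transcript
within_single_intron <- function(tx_exons, ref_tx, ref_exons) {
  span <- c(min(tx_exons$start), max(tx_exons$end))
  for (tid in ref_tx$transcript_id) {
    introns <- intron_chain(arrange(
      ref_exons[ref_exons$transcript_id == tid, ], .data$start))
    if (is.null(introns)) next
    if (any(span[1L] >= introns[, 1L] & span[2L] <= introns[, 2L])) return(TRUE)
  }
  FALSE
}

#' Map retained class codes to lncRNA categories
#'
#' `u` -> lincRNA, `i` -> intronic, `o` -> sense, `x` -> antisense. Codes
#' `=` and `other` are not novel lncRNA candidates and are rejected.
#'
#' @param code Character vector of class codes.
#' @return Character vector of categories (`NA` for rejected codes).
#' @export
class_to_category <- function(code) {
  map <- c(u = "lincRNA", i = "intronic", o = "sense", x = "antisense")
  unname(map[code])
}

#' @rdname class_to_category
#' @details `categorize()` is the strict single-code form: it errors on a
#'   code outside `u`/`i`/`o`/`x`.
#' @export
categorize <- function(code) {
  if (length(code) != 1L || !code %in% c("u", "i", "o", "x")) {
    abort(sprintf("class code '%s' is not a novel lncRNA candidate", code))
  }
  class_to_category(code)
}

#' Per-chromosome lncRNA counts
#'
#' Counts categorized lncRNAs by chromosome and category, at transcript and
#' at locus level (loci = distinct `gene_id` groups).
#'
#' @param classified Output of [classify_transcripts()] restricted to
#'   retained transcripts (non-`NA` category).
#' @return Tibble: `chrom`, `category`, `n_transcripts`, `n_loci`.
#' @export
summarize_by_chromosome <- function(classified) {
  if (!nrow(classified)) {
    return(tibble(chrom = character(), category = character(),
                  n_transcripts = integer(), n_loci = integer()))
  }
  classified %>%
    filter(!is.na(.data$category)) %>%
    group_by(.data$chrom, .data$category) %>%
    summarise(n_transcripts = n(),
              n_loci = length(unique(.data$gene_id)),
              .groups = "drop")
}
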