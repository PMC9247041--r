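#' Pipeline configuration
#'
#' Collects every tunable threshold of the lncRNA discovery pipeline in one
#' validated object. Defaults follow the study design the pipeline models:
#' transcripts shorter than 200 nt, with a single exon, or never expressed
#' above 0.1 FPKM are not considered lncRNA candidates; cis targets are genes
#' within 100 kb; trans targets require a duplex energy below -20 kcal/mol;
#' differential lncRNAs need BH-adjusted p < 0.05 and fold change > 2;
#' sequence homology requires E < 0.001 at >= 20% query coverage; positional
#' conservation requires >= 4 of the 5+5 flanking coding genes to land in one
#' syntenic block.
#'
#' @param min_length Minimum spliced transcript length in nt (default 200).
#' @param min_exons Minimum exon count (default 2).
#' @param min_fpkm Minimum of the per-library maximum FPKM (default 0.1).
#' @param cis_window Genomic window for cis-target search in nt (default 1e5).
#' @param trans_energy_cutoff Duplex-energy cutoff in kcal/mol, strict
#'   (default -20).
#' @param del_alpha BH-adjusted p-value cutoff for differential calls
#'   (default 0.05).
#' @param del_min_fc Minimum fold change for differential calls (default 2).
#' @param n_clusters Number of expression-profile clusters (default 6).
#' @param homology_evalue E-value cutoff for sequence homology, strict
#'   (default 0.001).
#' @param homology_min_coverage Minimum query coverage fraction, inclusive
#'   (default 0.20).
#' @param neighbor_k Coding neighbors taken on each side of a lncRNA for the
#'   positional-conservation vote (default 5).
#' @param min_conserved_neighbors Neighbors that must map into a single
#'   syntenic block (default 4).
#' @param orf_cutoff Longest-ORF length (nt) above which a transcript is
#'   called coding (default 300, i.e. 100 codons).
#' @param fickett_cutoff Fickett TESTCODE score above which a transcript is
#'   called coding (default 0.74, the classic "likely coding" boundary).
#' @param mirna_max_score Maximum plant-rule penalty for a reported miRNA
#'   site (default 4).
#' @param duplex_seed_len Minimum exact-complement seed for duplex search
#'   (default 6).
#' @param min_anchors Minimum ortholog anchors per syntenic block (default 5).
#' @param max_gap Maximum gene-rank gap between consecutive anchors
#'   (default 25).
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return A named list with class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$cis_window
pipeline_config <- function(min_length = 200L,
                            min_exons = 2L,
                            min_fpkm = 0.1,
                            cis_window = 100000L,
                            trans_energy_cutoff = -20,
                            del_alpha = 0.05,
                            del_min_fc = 2,
                            n_clusters = 6L,
                            homology_evalue = 0.001,
                            homology_min_coverage = 0.20,
                            neighbor_k = 5L,
                            min_conserved_neighbors = 4L,
                            orf_cutoff = 300L,
                            fickett_cutoff = 0.74,
                            mirna_max_score = 4,
                            duplex_seed_len = 6L,
                            min_anchors = 5L,
                            max_gap = 25L,
                            rng_seed = 1L) {
  cfg <- list(
    min_length = as.integer(min_length),
    min_exons = as.integer(min_exons),
    min_fpkm = min_fpkm,
    cis_window = as.integer(cis_window),
    trans_energy_cutoff = trans_energy_cutoff,
    del_alpha = del_alpha,
    del_min_fc = del_min_fc,
    n_clusters = as.integer(n_clusters),
    homology_evalue = homology_evalue,
    homology_min_coverage = homology_min_coverage,
    neighbor_k = as.integer(neighbor_k),
    min_conserved_neighbors = as.integer(min_conserved_neighbors),
    orf_cutoff = as.integer(orf_cutoff),
    fickett_cutoff = fickett_cutoff,
    mirna_max_score = mirna_max_score,
    duplex_seed_len = as.integer(duplex_seed_len),
    min_anchors = as.integer(min_anchors),
    max_gap = as.integer(max_gap),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("min_length", "min_exons", "min_fpkm", "cis_window", "del_alpha",
           "n_clusters", "homology_evalue", "homology_min_coverage",
           "neighbor_k", "min_conserved_neighbors", "orf_cutoff",
           "fickett_cutoff", "mirna_max_score", "duplex_seed_len",
           "min_anchors", "max_gap")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) ||
        cfg[[nm]] <= 0) {
      abort(sprintf("pipeline_config: `%s` must be a single positive number", nm))
    }
  }
  if (cfg$trans_energy_cutoff >= 0) {
    abort("pipeline_config: `trans_energy_cutoff` must be negative (kcal/mol)")
  }
  if (cfg$del_min_fc <= 1) {
    abort("pipeline_config: `del_min_fc` must exceed 1")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
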