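---
title: "Methods: lncRNA discovery, expression, targets and conservation in peachlnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, expression, targets and conservation in peachlnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peachlnc)
```

peachlnc re-implements, as a tested R package, the transcript-level analysis
used in genome-wide surveys of long noncoding RNAs (lncRNAs) in fruit
transcriptomes: classification of assembled transcripts against a reference
annotation, a coding-potential consensus filter, negative-binomial
differential expression across developmental stages, cis/trans target
prediction, ceRNA network assembly, and sequence plus positional
conservation against a second genome. This vignette explains the models,
the tunable parameters and the deliberate numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Coordinates and containers

All internal coordinates are 0-based half-open; GFF3/GTF input and output
(1-based inclusive) convert at the I/O boundary, which removes off-by-one
ambiguity from every overlap and distance rule. Transcripts are plain exon
tables (tibbles), annotations are `genome_annotation` objects backed by a
`GRanges` interval index, and counts live in an `expression_matrix` with
library sizes, feature lengths and the stage/replicate design. Unstranded
transcripts are rejected at validation: the data the pipeline models are
strand-specific, and every positional rule below depends on strand.

## Transcript classification

Each candidate receives one class code relative to the reference:
`=` (intron chain identical to a reference transcript; single-exon
candidates must be contained within a single-exon reference's exon), `x`
(exonic overlap, opposite strand), `o` (exonic overlap, same strand), `i`
(contained in a single intron of a reference transcript on either strand,
with no exonic overlap anywhere), `u` (no overlap with any gene span), and
`other` for residual geometries. Overlap means at least one shared base.
When several conditions hold, the fixed priority `=` > `x` > `o` > `i` >
`u` applies: exonic evidence is stronger than intronic containment, and
antisense overlap is the most specific novel signal. Codes `u`, `i`, `o`,
`x` map to the lincRNA, intronic, sense and antisense lncRNA categories;
`=` and `other` are not novel lncRNA candidates. The classifier is verified
against an exhaustive pairwise exon-overlap oracle on 1,000 random
instances.

## Coding-potential consensus

Four independent evidences are combined by intersection — a transcript is
noncoding only if all of them agree:

* **Longest ORF** below 300 nt (100 codons). ORFs are ATG-initiated, run to
  the first in-frame stop (included in the length), and only the three
  forward frames are scanned because the assembly is strand-specific.
* **Fickett TESTCODE** below 0.74, the statistic's classic "likely coding"
  boundary, computed from the published position-asymmetry and composition
  lookup tables embedded in the package.
* **Hexamer log-likelihood ratio** below 0 bits: the mean over in-frame
  hexamers of `log2(coding/noncoding)` frequency. The default tables are
  derived analytically from the synthetic generator's own emission models;
  for real data, organism-specific tables should be trained with
  `hexamer_table()`.
* **No protein-motif hit**: the three forward translations are scanned
  against a PWM motif database. The packaged database is synthetic (built
  from fixed consensus peptides) and stands in for a curated domain
  library, which is external data outside the package's scope.

The intersection rule makes the confident set smaller than any single
predictor's, and rejections are monotone: stricter cutoffs never enlarge
the retained set.

## The filter cascade

Candidates are retained when class code is in {u, i, o, x}, spliced length
is at least 200 nt, the transcript has at least 2 exons, the maximum FPKM
across libraries is at least 0.1, and the coding consensus is noncoding.
Each rejected transcript is attributed to its *first* failing rule in that
fixed order, so per-stage counts are well defined and sum to the input
size. The FPKM rule reads "maximum over libraries" — the most permissive
reading consistent with an expression floor; at desk-scale library sizes
this mostly removes never-observed transcripts, which is what the planted
`lowexpr` decoys emulate.

## Differential expression

Counts are normalized with median-of-ratios size factors (geometric-mean
reference over all-positive features). The test is a deliberately
transparent moment-based negative-binomial Wald test, not a GLM: the
per-feature dispersion is a method-of-moments estimate pooled across both
groups (`(s^2 - mu)/mu^2`, floored at 1e-8) whose variance term averages
the within-group pooled variance with the grand-centered total variance —
at 3 replicates the within-group view alone is liberal (plug-in dispersion
noise inflates the Wald tails) and the total-variance view alone is
conservative (it absorbs part of the tested effect); their average is
near-nominally calibrated. The estimate is then shrunk 50/50 toward a trend
fitted by regressing the estimates on `1/mu` across features; the log2
fold change uses pseudocount-0.5 normalized means; its standard error
comes from the delta method under `var = mu + alpha mu^2`; and the Wald
statistic is referred to the standard normal. There is no outlier
replacement, no independent filtering, and no LFC shrinkage — the contract
is "negative binomial + BH + thresholds", kept simple enough to calibrate:
on 2,000 simulated null features (mu = 100, dispersion 0.1, 3 vs 3) the
type-I fraction at p < 0.05 falls within [0.03, 0.07], and planted 4-fold
changes are detected with power at least 0.8 under the full differential
rule (BH-adjusted p < 0.05 and fold change > 2, both required). Features
with all-zero counts in both groups report log2FC 0 and p = 1 by
convention.

Differential lncRNAs (DELs) are called per pairwise stage contrast and
united by feature id. DEL profiles are z-scored per feature (sd floor
1e-9, so constant features map to the zero profile), clustered
hierarchically with Euclidean distance and complete linkage — stated
explicitly because heatmap tooling defaults vary — and cut to 6 clusters,
whose mean stage profiles are the "fitting curves". PCA uses centered
`log2(FPKM+1)` with SVD; component signs are fixed by making the
largest-magnitude loading positive so scores reproduce across platforms.

## Targets

**Cis**: all genes whose span lies within 100 kb of the lncRNA span,
boundary-to-boundary, inclusive; overlap counts as distance 0. Span
distance (not TSS distance) is the least ambiguous reading of a "within
100 kb" rule and is tested against a brute-force scan.

**Trans**: the minimum ungapped antiparallel duplex energy between lncRNA
and mRNA, seeded at exact Watson-Crick runs of at least 6 pairs. Energies
are the helix initiation penalty (4.09 kcal/mol) plus nearest-neighbor
stack terms from the embedded Turner 2004 table (Watson-Crick and G:U
stacks, as distributed with ViennaRNA's parameter files). Within a
contiguous pairable run the energy-minimal sub-run containing a seed is
found exactly, which also guarantees the "minimum over extensions"
property; a greedy stop-at-first-worsening extension would not. Bulges,
internal loops and accessibility terms are out of scope — a documented
divergence from full interaction-prediction tools that keeps an exhaustive
enumeration oracle exact. Pairs qualify strictly below -20 kcal/mol.

## ceRNA networks

miRNA sites are scored with a plant-style complementarity penalty:
Watson-Crick 0, G:U wobble 0.5, mismatch 1, doubled at miRNA positions
2-13; sites with penalty at most 4 (the conventional plant cutoff) are
reported from an exhaustive ungapped window scan. A lncRNA-miRNA-mRNA
triple exists for every miRNA with at least one site on each side; edges
are emitted separately so miRNAs with partners on only one side still
appear. Target-mimicry bulge detection is not modelled.

## Conservation

**Sequence**: a seeded (11-mer), ungapped, X-drop-20 extension search with
+1/-2 scoring on both strands. E-values follow Karlin-Altschul statistics;
lambda is solved numerically for the +1/-2 scheme at the subject
composition, while K uses the published value for that scheme (0.621) —
solving the full renewal series buys nothing here because the only use of
E is a 1e-3 threshold, decades away from both self-matches and random
hits. Hits need E < 0.001 (strict) and query coverage >= 20% (inclusive);
coverage is measured on the query because the biological question is "how
much of this lncRNA is conserved".

**Positional**: ortholog anchors are chained per chromosome pair into the
longest strictly monotone (or anti-monotone, for inversions) gene-rank
chains with per-step gaps of at most 25 on both genomes, greedily longest
first, keeping chains of at least 5 anchors — the published defaults of
the standard collinearity tool. For each lncRNA, the 5 nearest
protein-coding genes on each side (by rank; noncoding loci are skipped)
are mapped through the ortholog table; if at least 4 land in a single
block, the lncRNA is paired with every genome-B lncRNA inside the B
interval spanned by that block's anchors. The ">= 4 in the same block"
reading, query-side coverage, and the "any lncRNA inside the matched
interval" counterpart rule are the broadest defensible readings of the
underlying procedure and are recorded here as design choices.

## Enrichment

Over-representation uses the hypergeometric upper tail on term maps
supplied as plain TSV inputs, BH-corrected across terms. No ontology-graph
propagation is performed: term content is external data. The default
background is the set of annotated genes carrying at least one term.

## The synthetic study

`simulate_study()` generates, under one master seed, everything the
pipeline consumes, with exported truth labels: a two-chromosome genome
(160 genes per chromosome) whose coding genes carry clean >= 100-codon
ORFs emitted from a positionally biased codon model, while noncoding
sequence comes from a different base composition with any ATG-initiated
stretch capped below 100 codons — this construction makes the three
coding-potential scores separable by design, and the generator verifies
every candidate's verdict at build time. Candidates of every class are
placed constructively (intergenic, intronic, exon-overlapping on each
strand, exact reference copies) plus decoys for each cascade rule: < 200
nt, single-exon, never-expressed, ORF-bearing coding-like, and short-ORF
transcripts carrying a planted protein motif.

Counts follow `NB(mu, var = mu + 0.1 mu^2)` for 3 stages x 3 replicates
with per-library depth factors; lncRNA base means sit ~20-fold below mRNA
means, mirroring the systematically lower expression of lncRNAs. Six
stage archetypes (peaks at each stage, monotone up, monotone down, flat)
define both the differential truth and the cluster truth; planted
contrasts use 3-to-9-fold ratios so that truth labels are comfortably
inside the detection region rather than on the fold-change boundary.

miRNAs are planted as exact reverse complements of mRNA windows, with a
single designed mismatch (outside the doubled core) at their lncRNA site;
decoy miRNAs are verified at generation to have no qualifying site
anywhere. The ortholog genome applies inversions, a translocation and
gene deletions to the gene order; rearranged segments span 52 genes —
more than twice the chaining gap limit — so a collinear chain can neither
step across a rearranged segment nor tunnel through it on a single
interior anchor, and the expected positional pairs can be derived from
the constructed segment structure without running the synteny module.
Non-conserved lncRNAs are planted by deleting flanking genes until at
most 3 neighbors remain mappable, exercising the >= 4 vote's negative
side.

What passing these tests shows: the implementation applies its stated
rules exactly and recovers truth that is separable by construction. What
it does not show: performance on real assemblies, where coding and
noncoding sequence composition overlap, dispersion varies per gene,
strand bleed-through and fragmented transcripts exist, and orthology is
noisy. The generator deliberately omits those complications
(no reads, no sequencing error, no rRNA contamination).

## Problem sizes and reproducibility

The packaged study uses 600 candidates over 320 reference genes, a scale
chosen so the full suite — simulation, every stage, and the brute-force
oracles — runs comfortably on a single CPU. Every generator draw flows
from one master seed; a fixed seed makes all outputs byte-identical,
which the test suite asserts on the written files. `scripts/acceptance.R`
re-runs the whole analysis from scratch for any seed and writes the
recovered quantities as JSON.

## Known limitations

* The NB Wald stand-in is calibrated for the simulated regime; real data
  with heavy-tailed dispersion would need the full GLM machinery it
  deliberately omits.
* Duplex prediction ignores bulges, loops and accessibility; absolute
  energies are comparable only within the ungapped model.
* The homology E-value uses a fixed published K; lambda alone adapts to
  composition.
* Loci are distinct `gene_id` groups after classification; no attempt is
  made to merge partially overlapping sense transcripts into reference
  genes.
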