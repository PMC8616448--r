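---
title: "GGAA-microsatellite enhancer analysis: models, parameters and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GGAA-microsatellite enhancer analysis: models, parameters and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggaareg)
```

# Setting

ETS fusion oncoproteins such as EWSR1-FLI1 bind multimerized GGAA motifs —
GGAA microsatellites — and turn them into de novo enhancers. The analyses
this package implements connect three layers of evidence: where such
microsatellites sit in the DNA, where the fusion protein binds (ChIP-seq
peaks), and which genes respond when the fusion protein or one of its
target transcription factors is knocked down. Each section below describes
one stage's model, its tunable parameters (with units and defaults), and
the numerical conventions it commits to.

# Coordinate conventions

Internally every interval is 0-based, half-open `[start, end)`. BED input is
native; 1-based inclusive sources (gene-model TSVs, GTF, printed browser
coordinates such as `chr7:121,943,497-121,943,663`) are converted once at the
reading boundary by `read_gene_models()` / `convert_printed_coords()` and
converted back only for display. One convention everywhere removes the
classic off-by-one drift between BED intersections and browser coordinates.

The transcription start site of a gene is its first transcribed base:
`start` for a plus-strand gene, `end - 1` for a minus-strand gene. Gene
models therefore must carry `+` or `-`; an undirected gene has no TSS and is
rejected.

# The microsatellite scanner

A **locus** is a maximal in-frame tiling of 4-mer blocks drawn from the
repeat unit (default `GGAA`) plus a set of allowed single-block
interruptions (default `GGAG`), trimmed so the first and last block are
perfect units. "In frame" means all blocks sit at offsets congruent to the
locus start modulo 4; "maximal" means no further in-frame block on either
side belongs to the set. Per locus the scanner reports the perfect-unit
count (`total_units`), the longest streak of consecutive perfect units
(`longest_run`) and the interruption count; the locus length is always
`4 * (total_units + interruption_count)`.

Parameters of `scan_config()`:

| parameter | default | meaning |
|---|---|---|
| `unit` | `GGAA` | the 4-bp repeat unit (the ETS core on the plus strand) |
| `allowed_interruptions` | `GGAG` | 4-mers that may interrupt the tract singly without breaking it |
| `min_seed_run` | 4 units | minimum contiguous perfect run to nucleate a reported locus |
| `min_total_units` | 8 units | minimum perfect units per reported locus |
| `scan_both_strands` | TRUE | also scan the reverse-complement unit (TTCC), reported as minus-strand loci in forward coordinates |

The repeat-calling rule itself is a design choice: published descriptions of
these tracts mention unit counts, contiguous runs, and GGAG units
intercalated among the GGAA units, but not a formal calling rule. The
maximal-tiling-with-trim definition is the simplest rule consistent with
that structure; only single-block interruptions are allowed because an
interruption run of two or more 4-mers is indistinguishable from the tract
simply ending. The thresholds (4-unit seed, 8 units total) suppress the
dense genome-wide background of short GGAA runs while retaining any tract
of the published scale (tens of units); both live in configuration and are
logged with every pipeline run, not hard-coded. `N` bases never match, so
unknown sequence terminates a locus rather than being claimed as repeat.
Opposite-strand loci may overlap and are both reported — GGAA is not its own
reverse complement, and strand identity matters for ETS binding —
deduplication is left to the caller.

# Peak and gene assignment

`annotate_peaks_with_msats()` flags a peak as microsatellite-coincident when
it overlaps at least `min_overlap_bp` (default 1) bases of any locus on
either strand.

`genes_with_internal_peaks()` treats "inside the gene" as the full genomic
span, introns included. The default rule is any-overlap (≥ 1 bp); the
stricter `fully-contained` and `midpoint-inside` rules are available because
the original in-house scripts this stage models never published their
containment rule. All three are tested against brute-force oracles.

`nearest_peaks_to_tss()` searches a window of `max_distance_bp` (default
10 000 bp, i.e. 10 kb on each side of the TSS) and reports the nearest peak
upstream and downstream **in the gene's strand frame**: for a minus-strand
gene, genomically rightward of the TSS is upstream. Distance is measured
from the nearer peak edge — peak summits are not uniformly available in
public deposits — as `TSS - end` for a genomically left peak and
`start - TSS` for a right peak, with a TSS-overlapping peak reported
downstream at distance 0. Note the small asymmetry this inherits from
half-open coordinates: the downstream gap counts the TSS base itself, so
reflecting all coordinates shifts left-measured gaps by +1 and
right-measured gaps by −1. The test suite asserts that exact ±1 invariant
rather than pretending reflection is distance-preserving. Equidistant peaks
on one side are broken deterministically (smaller start wins) and all ties
are listed in a secondary column.

# Regulation calls

`classify_regulation()` applies inclusive thresholds exactly as such results
are printed: *down* when `log2fc <= -lfc_threshold` **and**
`padj <= padj_threshold` (defaults 1 and 0.05), *up* symmetrically,
*unchanged* otherwise. A missing `padj` — the DESeq2 convention for genes
removed by independent filtering — is never significant. Directions are
stored relative to the knockdown contrast in the input table;
`relabel_to_fusion()` provides the inverted framing (down upon knockdown =
fusion-activated) because both framings circulate in this literature and
silently mixing them is the classic error.

Catalog matching (`select_catalog_subset()`) is by exact identifier; the
count of catalog members absent from the dataset is reported rather than
guessed around, since symbol-vs-Ensembl mismatches should be visible, not
papered over. `regulated_fraction()` rounds half away from zero (the
convention of printed percentages; base R's `round()` would round 12.5 to
12).

# Overlap, Fisher test and enrichment

`overlap_summary()` takes two call sets and a **stated universe** — the
sampling frame for the chance model. The universe is a required input
because published analyses rarely state theirs; the pipeline default is the
genes present in both DE tables. The query set (first argument, by
convention the smaller knockdown set) defines the percentage denominator.
Concordance is counted on the overlap by matching direction labels.

The chance model is the exact one-sided Fisher test: with margins fixed,
`P[X >= n_overlap]` under the hypergeometric distribution. The
implementation builds the probability terms by ratio recursion outward from
the distribution's mode — consecutive hypergeometric terms differ by an
exact small rational, so cumulative products keep full double precision —
and normalizes. This stays within 1e-12 relative error for margins up to
10⁴, verified against exhaustive enumeration on every table with total ≤ 60
and against `stats::phyper` at large margins. (A log-factorial/log-sum-exp
formulation was rejected: lgamma's absolute error lands in an exponent of
magnitude ~10⁵ and caps accuracy near 1e-11.) The test is one-sided
(enrichment) because the scientific claim it supports is directional.

`annotation_enrichment()` is the generic over-representation statistic: per
term, observed vs `|query| * |term ∩ universe| / |universe|`, fold
enrichment, one-sided Fisher p, and Benjamini–Hochberg FDR across terms
(via `stats::p.adjust`, cross-checked against a hand-computed step-up).
Reproducing any specific annotation database's term contents is out of
scope; the annotation map is caller-supplied.

# Allele lengths, expression, growth arithmetic

Fragment analysis reports amplicon sizes; `estimate_repeat_units()` inverts
`length = flank + 4 * units` with ties (x.5) rounded away from zero.
Heterozygous samples contribute the mean of their two allele lengths —
matching how mean allele length is plotted in this assay — and
`correlate_length_expression()` computes Pearson (default) or Spearman
correlation on ≥ 3 pairs, with zero-variance inputs rejected as undefined
rather than returned as NaN. Pearson on mean length is the default because
that is the quantity such figures plot; Spearman is offered because sample
sizes are small (a dozen cell lines) and no coefficient convention is
established. Exclusions (e.g. an outlier cell line) are explicit arguments
recorded in the result object — never silent row drops. Significance
testing of r is deliberately omitted at these sample sizes; the estimate is
descriptive.

`relative_expression()` is `2^−ΔCt` with ΔCt = Ct_gene − Ct_reference.
`population_doublings()` is `log2(final / initial)`: the conventional
growth formula. Some published write-ups print the inverted ratio
(initial/final), which yields negative doublings for a growing culture; the
package implements the convention that makes `doubling_time()` =
elapsed/doublings positive and meaningful, and documents the choice here.

# The synthetic world

`sim_config()` states one fixed world; its defaults are the conditions the
analyses above are meant to face, at desk scale:

* **Genome**: 4 chromosomes × 100 kb at GC 0.41 (human-like); 40 planted
  loci of 8–30 units, interruption probability 0.15 per junction, half on
  the minus strand. Background sequence is rejection-checked: if scanning
  the assembled genome does not reproduce the planted truth exactly (a
  chance background tract, or a planted locus extended by a chance in-frame
  flank), the genome is redrawn. Planted truth is therefore the *complete*
  truth, which is what makes exact-recovery tests meaningful.
* **Peaks**: exactly 60% of loci receive a fully covering peak of 200–800 bp;
  60 decoy peaks avoid all loci.
* **Genes**: 150 gene models of 2–15 kb, half minus-strand; exactly 12% are
  placed to contain one coincident peak entirely within the gene body (so
  every containment rule agrees), the rest avoid all coincident peaks.
* **DE tables**: 25 000 genes (annotated-transcriptome scale); marginals of
  1456 and 174 regulated genes with 67 shared, of which a fraction 39/67 is
  direction-concordant — the headline structure of the fusion-vs-target
  knockdown comparison this pipeline serves. Regulated genes draw
  |log2FC| in [1, 5] and padj in [0, 0.05]; unregulated genes stay below
  |log2FC| < 1, and 10% of them get NA padj (with arbitrary fold changes) to
  exercise the NA rule. padj values are *planted, not fitted*: DE model
  fitting is out of scope, so the tables are a structural stand-in for
  DESeq2 output, not a statistical emulation of count noise.
* **Alleles**: 12 samples, 80 bp flank, 10–30 repeat units, heterozygous
  with probability 0.5; expression is `r·z + sqrt(1−r²)·ε` on the
  standardized mean length (target r = 0.9), rescaled to positive relative
  units. The linear-Gaussian construction makes the population correlation
  exactly r and collapses to a deterministic line at |r| = 1.

Two sampling modes exist for the DE pair: exact planted counts (default; all
overlap/concordance recovery tests are exact) and independent
per-gene regulation (`de$independent = TRUE`), the null world used to check
that the Fisher p-value is calibrated. Exact counts would be wrong for
calibration — a deterministic overlap has no null distribution — hence the
two modes.

Determinism: the master seed fixes every output byte-for-byte. Each
component (genome, peaks, genes, DE, alleles) seeds its own stream at a
fixed offset from the master seed, so editing one configuration block never
perturbs the others' draws.

What the generator does **not** emulate — and hence what a green test does
not establish: read-level sequencing noise, realistic ChIP-seq signal
shapes and peak-calling artifacts, human genome repeat background (100 kb
random sequence has no Alu/LINE structure), correlated multiple-testing
structure in DE tables, or population genetics of allele lengths. Green
recovery tests establish that the *computations* are correct on inputs with
known truth, not that the biology of any particular dataset is reproduced.
Dataset-dependent published counts (how many genes a given knockdown
regulates, specific enrichment tables) depend on accession data and
annotation versions and are covered only by the procedure implementations
and the property suites.

# Numerical choices and degenerate inputs

* Percentages round half away from zero; overlap percentages to one
  decimal.
* `round((length − flank)/4)` ties round away from zero (28.5 → 29).
* Empty gene lists, empty universes, zero-variance vectors, non-positive
  cell counts, and genes without strand all raise immediate errors rather
  than propagating NaN.
* Sequences shorter than one unit scan to an empty result, not an error.
* Equidistant-peak ties and same-start locus conflicts resolve
  deterministically (smaller start, then longer interval).
* The scanner resolves overlapping candidate tilings from shifted frames
  (possible only for self-overlapping units, not GGAA) greedily by start
  position, documented for exotic unit choices.

# Known limitations

* The scanner's locus definition is one defensible formalization; counts
  for a specific genomic tract can differ by a unit or two under other
  conventions (e.g. counting GGAAG-type partial overlaps). Containment of a
  locus in a named gene feature (intron vs exon) is whatever the supplied
  gene model says; the package takes no position.
* Peak distances are edge-based; where summits are available a
  summit-based distance would be sharper.
* The Fisher test's universe choice dominates its p-value; the package
  requires the universe to be stated precisely because this choice is so
  often left implicit.
* No liftover, BAM/CRAM, bigWig or full GFF3 support; inputs are FASTA,
  BED, TSV/GTF-subset gene models and TSV tables.
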