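# ggaareg

Linking GGAA-microsatellite enhancers bound by an ETS fusion oncoprotein to
the genes it regulates.

In Ewing sarcoma, the chimeric transcription factor EWSR1-FLI1 binds tandem
arrays of the ETS core motif GGAA — GGAA microsatellites — and converts them
into de novo enhancers that drive its target genes. Studies of this mechanism
keep re-running the same computational chain: find the microsatellites in
DNA, intersect them with ChIP-seq binding peaks, relate the bound sites to
gene bodies and transcription start sites, classify genes as regulated from
knockdown differential-expression tables, and ask whether two regulated gene
sets overlap more than chance and in the same direction. `ggaareg` packages
that chain as tested, reusable functions for R users in regulatory genomics,
together with a synthetic-data generator so every stage can be validated
against known ground truth without any sequencing download.

## The core computations

* **Microsatellite scanner.** A locus is a maximal in-frame tiling of 4-mer
  blocks from {unit} ∪ {interruptions} (defaults GGAA and GGAG), trimmed so
  it begins and ends on a perfect unit, with ≥ 8 units total and a contiguous
  run of ≥ 4 (both configurable). Both strands are scanned (TTCC tracts are
  minus-strand loci). Per locus the scanner reports total units *n*, the
  longest contiguous run, and the interruption count — e.g. an interrupted
  tract with 28 units of which 16 contiguous.
* **Peak-to-gene assignment.** A peak is *inside* a gene when it overlaps the
  gene's genomic span (any-overlap by default; fully-contained and
  midpoint-inside rules available). Near-promoter assignment finds, per gene,
  the nearest peak on each side of the TSS within a window (default 10 kb),
  with upstream/downstream defined in the gene's strand frame and distance
  measured from the nearer peak edge to the TSS.
* **Regulation calls.** With DESeq2-style inputs, a gene is *down* when
  log₂FC ≤ −θ and p_adj ≤ α (defaults θ = 1, α = 0.05), *up* symmetrically;
  NA p_adj is never significant. Calls can be restricted to a
  transcription-factor catalog (e.g. a GO-term membership list).
* **Overlap statistics.** For regulated sets A (query) and B over a stated
  gene universe of size N, the package reports |A∩B|, the percentage of A
  shared, direction-concordant and discordant counts, and the exact
  one-sided Fisher p-value P[X ≥ |A∩B|] from the hypergeometric tail
  (computed by ratio recursion from the mode; accurate to > 12 significant
  digits for margins up to 10⁴). Annotation over-representation reports
  fold enrichment observed/expected with Benjamini–Hochberg FDR.
* **Allele length vs expression.** Fragment-analysis allele sizes convert to
  repeat units via round((length − flank)/4); mean allele length per sample
  is correlated (Pearson or Spearman) with relative expression (2^−ΔCt),
  with explicit, recorded sample exclusions.

All genomic coordinates are 0-based half-open internally; BED is native and
1-based formats (gene TSVs, GTF, printed browser coordinates) are converted
at the boundary.

## Worked example

The `analysis/` directory holds the pipeline as numbered driver scripts over
the package functions. Running them in order from the repository root
(`Rscript analysis/01_simulate.R` … `06_allele_correlation.R`) builds the
synthetic study world and analyses it, writing tables under `results/`.
Output from a complete run:

```
planted 40 microsatellite loci (8-29 units, 22 on the minus strand)
peaks: 84 total, 24 covering a locus, 60 decoys
genes: 150, of which 18 contain a coincident peak
DE truth: 1456 and 174 regulated, 67 shared, 39 concordant

recovered all 40 planted loci with exact boundaries and unit counts
reference-structure tract: 28 units, longest run 16, 2 interruptions

24 of 84 peaks are microsatellite-coincident
18 out of 150 genes (12%) contain a coincident peak inside the gene body
nearest-peak assignments within 10 kb of a TSS: 105 (71 upstream, 34 downstream)

catalog: 1635 members present in the dataset, 39 absent
94 down + 130 up = 224 regulated catalog members (14% of those present)

67 of 174 query genes also regulated in the second set (38.5%)
concordant: 25 up + 14 down = 39; discordant: 28
one-sided Fisher exact p = 1.475e-37 (universe 25000)

pearson correlation between mean allele length and expression: r = 0.898 (n = 12)
```

Reading the numbers: the scanner recovered every planted microsatellite
exactly; the planted 12% gene-containment fraction and the planted 67/174
overlap (38.5%, 39 concordant) come back unchanged through the full
pipeline, and the tiny Fisher p confirms the planted dependence between the
two regulated sets; the allele-length correlation estimate (r = 0.898, n =
12) sits next to its planted value of 0.9.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full synthetic-world analysis from scratch with the installed
package — simulation, scan, peak and gene assignment, DE classification,
overlap statistics and the allele-length correlation — logging the headline
counts, and writes the results JSON to `--out`. The seed controls every
random stream.

## Method details

See `vignettes/ggaa-microsatellite-pipeline.Rmd` for the model and
procedure descriptions, parameter meanings and defaults, what the synthetic
generator does and does not emulate, numerical conventions, and known
limitations.
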