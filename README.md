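# shortiso

Discovery and validation of 5'-truncated transcript isoforms driven by
internal alternative promoters.

## The problem

Genes sometimes express a shortened transcript that begins deep inside the
gene body: the 5' exons are transcriptionally silent while a terminal 3'
exon block is active, driven by an internal alternative promoter rather
than the canonical one. When that truncated transcript carries an ATG in
frame with the canonical stop codon, it encodes a C-terminal protein
fragment that can lack N-terminal domains (signal peptides, extracellular
regions, transmembrane segments) and acquire new biology. Detecting such
isoforms requires stitching together evidence across omics layers, and
`shortiso` implements that inference chain for computational biologists
working from standard file formats:

1. **Exon-level quantification** — per-exon read counting from BED
   (including split reads) and RPKM profiles:
   RPKM = c / ((L/10³)(N/10⁶)) for count *c*, exon length *L*, library
   size *N*.
2. **Breakpoint calling** — exhaustive two-block contrast on
   y = log2(RPKM+1): s(k) = mean(y[k..E]) − mean(y[1..k−1]), maximized
   over k with a boundary refinement at the log-midpoint threshold
   √(τ_on·τ_off); profiles are classified as `short_3prime`,
   `full_length`, `not_expressed` or `ambiguous`.
3. **Promoter evidence** — fold-enrichment scoring of H3K27ac, H3K4me3,
   RNA Pol II and H3K27me3 tracks around the breakpoint, the canonical
   TSS and the 5' gene body, yielding an `alternative_promoter` /
   `canonical_only` / `no_evidence` verdict.
4. **ORF scanning** — every ATG in frame with, and free of internal
   stops before, the canonical stop codon; translation, average-mass
   (kDa) estimation, and domain loss/retention/truncation assessment.
5. **Proteomic validation** — tryptic digestion, exact peptide mapping
   with sequence coverage, N-terminal-peptide logic for isoform support,
   and label-free quantification of isoform-unique peptides (summed
   fragment-ion XIC areas, Welch t-test on log2 sample means).
6. **Synthetic data** — negative-binomial count, ChIP-track and peptide
   simulators that plant the full ground-truth pattern, so every stage is
   testable end to end without downloads.

A DE-table utility (`rank_and_intersect`) intersects the top-N most
strongly upregulated genes across datasets.

## Worked example

The synthetic locus plants the target pattern: a 28-exon gene, silent over
exons 1–22 and expressed over 23–28 in treated samples, with an in-frame
ATG at exon 23 giving a ~28 kDa C-terminal protein whose transmembrane
domain is lost.

```r
library(shortiso)
cfg <- sim_config(seed = 1)
gm  <- simulate_gene_model(cfg)

sim <- simulate_counts(cfg, state = "short", n_samples = 3)
m   <- exon_expression_matrix(sim$counts, rep(cfg$exon_length, cfg$E),
                              sim$library_sizes)
call <- detect_breakpoint(exon_profile(m, "sample1"))
call
#> isoform_call: short_3prime at exon 23 (score 1.60; 5' 0.05, 3' 1.66 log2 units)

tracks <- simulate_chip_tracks(cfg, gm$transcript)
classify_alternative_promoter(tracks, gm$transcript, call$breakpoint_k)
#> promoter_evidence: alternative_promoter
#>   alt active 3.72x (canonical 0.74x); 5' body H3K27me3 5.04x

orf <- orf_candidates(gm$transcript, spliced_sequence(gm$transcript, gm$genome),
                      first_exon = call$breakpoint_k, domains = gm$domains)[[1]]
orf
#> orf_candidate: start nt 3301 (exon 23), 250 aa, 27.7 kDa, delta 1100
#>   domains lost: transmembrane | retained: cytoplasmic_tail | truncated:

pep <- simulate_peptides(cfg, gm)
map_peptides(pep$unique_peptides, gm$short_protein)
#> coverage_report: 37.6% of 250 aa covered by 6 peptide(s)
quantify_peptides(pep$observations, pep$unique_peptides)
#> quant_result: fold change 1.840 (control 1.05e+03 vs treated 1.93e+03); t = 14.1, p = 0.000162
```

Reading the output: the treated profile is called a 3'-restricted short
isoform breaking at exon 23; chromatin tracks show a ~3.7-fold active-mark
gain at that boundary with a silent canonical promoter and a ~5-fold
H3K27me3-repressed 5' body; the first stop-anchored ORF starts at exon 23
and encodes a 250-aa, 27.7 kDa fragment without the transmembrane domain;
six isoform-unique peptides cover 37.6% of that protein and are ~1.8-fold
induced in the treated condition (true simulated fold: 2).

`run_pipeline()` chains all stages from a single configuration (paths or
in-memory objects) and writes per-stage TSVs plus a provenance-stamped
JSON report; `write_synthetic_fixtures()` emits a complete plain-text
fixture directory (FASTA, GTF, BED, bedGraph, TSV).

## Scope

Differential-expression estimation, enrichment analysis, survival
analysis, raw mass-spectrometry spectrum processing and read alignment
are out of scope; the package consumes their standard outputs (DE tables,
peptide-area tables, BED/bedGraph). See the vignette
(`vignettes/truncated-isoform-inference.Rmd`) for the models, parameter
defaults and design rationale.
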