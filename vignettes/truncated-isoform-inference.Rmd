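---
title: "Inferring 5'-truncated isoforms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring 5'-truncated isoforms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortiso)
```

## The problem

Some genes express, besides their canonical full-length transcript, a
5'-truncated isoform driven by an internal alternative promoter. The
hallmark pattern in RNA-seq is a per-exon expression profile that is silent
over the 5' exons and active over a terminal 3' block — for example a
28-exon gene whose reads map only to exons 23–28 under a treatment
condition. When the truncated transcript contains an ATG in frame with the
canonical stop codon, it can encode a C-terminal protein fragment that
lacks N-terminal domains (such as a transmembrane segment), with its own
biology. `shortiso` packages the complete inference chain for this
phenomenon: exon-level quantification, truncation-breakpoint calling,
chromatin evidence for the internal promoter, stop-anchored ORF
prediction with domain-loss assessment, and peptide-level validation and
quantification.

## Exon-level quantification

Reads (BED 3/6, or BED 12 with split blocks) are counted per exon: a read
increments every exon it overlaps by at least `min_overlap` bp (default
1 bp), and is never fractionally assigned. This matches how a coverage
track is read by eye and keeps the statistic monotone in coverage. Counts
become RPKM,

$$\mathrm{RPKM} = \frac{c}{(L/10^3)\,(N/10^6)},$$

with $c$ the exon count, $L$ the exon length (bp) and $N$ the sample's
total mapped reads. The library size defaults to the total read count of
the sample's BED input; when quantifying a single locus against a
pre-computed library size, pass it explicitly. Whether only uniquely
mapped reads enter the BED input is an upstream decision the package
documents but does not police.

## Breakpoint calling

`detect_breakpoint()` transforms a per-exon RPKM profile to
$y_e = \log_2(\mathrm{RPKM}_e + 1)$ (the pseudocount keeps zeros finite;
log scale stabilizes multiplicative noise) and evaluates, for every
candidate breakpoint $k \in 2..E$, the two-block contrast

$$s(k) = \operatorname{mean}(y_{k..E}) - \operatorname{mean}(y_{1..k-1}).$$

The $k$ maximizing $s$ locates the step; ties take the smallest $k$,
i.e. the longest short transcript consistent with the data.

**Boundary refinement.** The block-mean contrast is exact at locating a
clean step but weakly informed about the boundary exon itself: dropping a
below-average expressed exon from the 3' block *raises* $s$ slightly
(by roughly $T/n_3^2$, with $T$ the 3' block total), so a raw argmax
systematically trims weak boundary exons under realistic count noise.
The called breakpoint is therefore refined locally: it walks left while
the neighbouring exon is expressed and right while the boundary exon is
silent, judged against the log-scale midpoint of the two class
thresholds, $\tau_{\mathrm{mid}} = \sqrt{\tau_{on}\tau_{off}}$. For
negative-binomial counts at the default simulation conditions
(means 100 vs 2), this midpoint (≈0.32 RPKM ≈ 14 reads) sits next to the
likelihood-ratio crossover between the on- and off-distributions
(~15 reads), so single-exon assignment is near-optimal. A useful side
effect: permuting values within the expressed block never moves the
refined breakpoint on step-dominated profiles, which holds exactly in the
package's property tests.

**Classification.** With defaults $\tau_{on} = 1$ RPKM,
$\tau_{off} = 0.1$ RPKM, $\delta = 1$ (log2 units), all configurable:

* `short_3prime` — $s(k^\*) \ge \delta$, mean 5'-block RPKM $\le
  \tau_{off}$, mean 3'-block RPKM $\ge \tau_{on}$;
* `full_length` — every exon $\ge \tau_{on}$;
* `not_expressed` — every exon $< \tau_{off}$;
* `ambiguous` — anything else.

No printed thresholds exist for this decision in the source material; the
defaults separate the reference fixture (zeros over exons 1–22, clear
expression over 23–28) unambiguously and are deliberately conservative:
a handful of stray reads on 5' exons at very deep sequencing pushes a
control sample to `ambiguous` rather than `not_expressed`, which we
consider the honest answer. Consensus across samples is by strict
majority (ties `ambiguous`); the consensus breakpoint is the median of
per-sample breakpoints among short calls, using the lower median so the
result stays an integer exon index.

The package reports a point estimate with thresholds, not a significance
statement; multi-breakpoint segmentation and junction-read assembly are
out of scope.

## Chromatin evidence for the internal promoter

The expected signature of an internal alternative promoter at breakpoint
$k$ is: no active-mark signal at the canonical promoter, Polycomb-type
repression (H3K27me3) over the 5' gene body, and strong H3K27ac/H3K4me3/
RNA Pol II occupancy just 5' of the expressed block.
`classify_alternative_promoter()` scores this from binned signal tracks
(bedGraph) with length-weighted window means, as fold enrichments rather
than peak calls — the evidence in the source data is track-level, and
ratios cancel library-size differences (scores are invariant to
rescaling any one track).

* Active score: candidate window = ±`window` bp (default 2000) around the
  5' genomic end of exon $k$, anchored there because the internal
  promoter sits immediately 5' of the expressed block; each available
  active mark contributes `window mean / locus-wide mean`, averaged.
  The alternative promoter is active when this score reaches `rho_act`
  (default 3) while the canonical-TSS window's analogous score stays
  below it.
* Repressive score: mean H3K27me3 over the genomic span of exons
  $1..k{-}1$ divided by its mean over the span of exons $k..E$. The
  locus-wide mean is *not* used as the reference here: the repressed body
  typically covers most of the locus, so a locus-wide background would be
  dominated by the very signal being tested and the ratio would saturate
  near 1 regardless of enrichment. The 5'-body-versus-3'-region contrast
  is the comparison the biology defines (repressed body, clean short-
  isoform region). The body counts as repressed at `rho_rep` (default 3);
  without an H3K27me3 track the condition is vacuously true and flagged.

Verdict: `alternative_promoter` iff both conditions hold;
`canonical_only` when only the canonical TSS is active; otherwise
`no_evidence`. The thresholds are conventions — no quantitative cutoffs
for "strong accumulation" exist in the source — chosen so a fivefold
peak over background separates cleanly from flat tracks at the simulated
noise level.

## Stop-anchored ORF prediction

`find_inframe_starts()` returns every ATG that is (i) inside the search
window (by default the expressed region from the breakpoint exon), (ii)
in frame with the canonical stop codon, and (iii) free of in-frame stop
codons before that stop. Every candidate protein is therefore a
C-terminal suffix of the canonical protein, which `assess_domains()`
verifies before classifying each annotated domain by the candidate's
N-terminal offset $\Delta$ (canonical length − candidate length):
*lost* if the domain ends at or before $\Delta$, *retained* if it starts
after $\Delta$, *truncated* otherwise — a partition, checked as such.

Start codons are restricted to ATG; near-cognate starts (CUG/GUG) would
inflate the candidate list without evidence to rank them. Protein masses
use average (not monoisotopic) residue masses because the comparison
target is a gel-band size; kDa values are reported to one decimal and
compared to gel estimates at integer resolution.

## Peptide-level validation and quantification

In-silico tryptic digestion cleaves after K/R except before P, with
configurable missed cleavages and a length filter (7–25 aa is used as the
detectable range). `map_peptides()` matches observed peptides exactly
(I/L equivalence is an explicit switch, off by default) at every
occurrence and reports covered residues and percent coverage.

Isoform support follows the N-terminal logic: a peptide mapping entirely
within, or straddling into, the first $\Delta$ residues of the canonical
protein requires full-length protein (`full_length_supported`); with no
such peptide and at least `m_min` (default 2) shared peptides the data
support the short isoform. Absence of N-terminal peptides is weaker
evidence than presence, hence the asymmetric rule.

Label-free quantification sums fragment-ion XIC areas per peptide and
sample, averages over the isoform-unique peptides per sample (missing
peptides are excluded from that sample's mean, with a warning), and
compares conditions by fold change plus a Welch unpaired two-sided t-test
on log2 sample averages — intensities are multiplicative, so the log
scale is the right home for the test. "Unique" peptides are supplied as a
set; the default operationalization takes tryptic peptides lying entirely
in the shared C-terminal region and absent from an optional background
proteome.

## The synthetic-data generators

The generators produce the study conditions as ground truth:

* **Gene model** — 28 exons × 150 bp, introns 2,000 bp, a canonical ORF
  opening at the transcript start with a planted in-frame ATG at the
  first nt of exon 23 and a shared stop in exon 28. The short ORF is
  250 aa: with the mean residue mass over the 61 sense codons
  (111.93 Da), that is the ORF length whose expected product mass is the
  28 kDa the short protein runs at — the generated locus is a synthetic
  stand-in for the real one, not its sequence. A transmembrane domain is
  placed entirely in the lost region, a C-terminal domain in the retained
  region.
* **Counts** — negative binomial (the overdispersed RNA-seq convention),
  mean 100 reads per expressed exon, on/off ratio 50 (silent-exon mean 2),
  dispersion 0.2, Poisson in the dispersion→0 limit. The per-sample
  library size is the locus total plus a background of $3\times10^8$
  reads. That default is fixed by arithmetic, not tuning: with the class
  thresholds above, the silent block clears $\tau_{off}$ only when
  $N \ge 1.33\times10^8$ (2 reads over 0.15 kb) and the expressed block
  clears $\tau_{on}$ only when $N \le 6.67\times10^8$ (100 reads over
  0.15 kb); $3\times10^8$ sits mid-window with margin on both sides,
  the deep-sequencing regime in which a truly silent 5' body is
  distinguishable from leakage.
* **ChIP tracks** — background 1.0 plus Gaussian noise (sd = 0.2 ×
  background, clamped at 0) in 100-bp bins; the alternative-promoter
  scenario adds a fivefold peak of 5,000 bp full width at the exon-k
  boundary on the active marks and a fivefold elevation of H3K27me3 over
  the 5' body. The peak width is set so the ±2,000 bp scoring window sits
  inside the enriched domain, the scale of an active-promoter H3K27ac
  domain.
* **Peptides** — tryptic peptides of the short protein; six unique
  peptides are selected whose combined span is the subset-sum closest to
  40% coverage (the reported coverage of the short protein); per-sample
  summed areas are `base × fold × lognormal(CV 20%)` split over three
  fragment ions, detected with probability 0.9; the true fold change is
  2.0 with n = 3 per condition. Because disjoint tryptic peptides cover
  in whole-peptide steps (7–25 aa ≈ 3–10% of a 250-aa protein), the
  closest achievable set can sit up to about half a peptide (~5 points)
  from the 40% target; tests allow exactly that granularity.

One global seed fans out to fixed per-generator substreams, so adding a
generator never perturbs the others; all outputs are byte-identical under
a fixed seed.

**What the simulations do not emulate:** mappability artifacts, GC and
positional coverage bias, spliced-read ambiguity at exon borders,
fragment-length effects, ChIP input correction, peptide ionization
differences, or any inter-gene context. Passing recovery tests therefore
demonstrates the inference is correct *under the stated noise families*,
not that real data meet those assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use 500 count simulations for
breakpoint recovery and specificity, 200 track simulations for the
promoter verdict, 200 peptide tables for fold-change recovery, and
1,000-case oracle-equivalence sweeps for the ORF and breakpoint searches
— sizes at which the binomial error on a 95% recovery rate is about one
percentage point, while a full run stays in the minutes range on one CPU.
Other numerical conventions: ties in the breakpoint score take the
smallest k; the consensus breakpoint uses the lower median; degenerate
quantification inputs (a group with fewer than two samples, non-positive
sample means) report the fold change and skip the test with a warning
rather than failing; a promoter scoring window narrower than the track
bin width warns explicitly.

## Known limitations

* The breakpoint caller assumes a single 5'-silent/3'-active step; genes
  with several alternative starts need a segmentation method.
* Promoter evidence is a fold-enrichment convention, not a calibrated
  peak caller, and has no replicate model.
* ORF enumeration is unguided by translation-initiation context; it
  reports all stop-anchored candidates and leaves ranking to protein
  evidence.
* Peptide matching is exact; modified or mutated peptides will not map.
* Exon numbering follows the annotation given to the package; when a gene
  has several reference transcripts the user must pin the transcript ID.
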