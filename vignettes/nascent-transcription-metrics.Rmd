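---
title: "Quantifying pausing, elongation and splicing from tag libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pausing, elongation and splicing from tag libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Inflammatory (TLR4-responsive) genes in macrophages fall into two kinetic
groups: immediate/early (I/E) genes, induced more than 3-fold within an
hour of stimulation, and late genes, essentially flat at 1 h (< 1.2-fold)
but strongly induced (> 4-fold) by 12 h. The two groups differ not in
whether they are "on" or "off" at baseline — both carry active-promoter
histone marks and measurable basal transcripts — but in *how* induction is
achieved: I/E promoters accumulate paused RNA polymerase II just downstream
of the TSS, positioned by TATA-box/TBP architecture, and stimulation
releases that polymerase into productive elongation. `nascentmetrics`
implements the quantitative machinery needed to characterize this picture
genome-wide, plus a synthetic-data generator that makes every estimator
testable by parameter recovery.

Every assay is reduced to a **tag library**: the multiset of 5'-end
positions of uniquely mapped reads, with strand and library metadata.
Three conventions govern everything downstream:

* **Depth normalization.** Each tag carries weight
  `1e7 / total_mapped`, so the weighted mass of any library is exactly
  10^7 tags and densities are comparable across libraries. Duplicate tags
  at one position are all retained and all weighted.
* **Half-fragment shifting.** ChIP tags are 5' ends of ~200-bp sonicated
  fragments; shifting plus-strand tags by `+floor(fragment/2)` and
  minus-strand tags by the negative of that centers each tag on its
  fragment. Nascent-transcription (GRO-Seq), RNA-Seq and CAGE tags are
  *not* shifted: their 5' (or 3') ends are themselves the signal.
* **Gene-oriented coordinates.** The TSS is position 0, downstream is
  positive along the gene strand, and minus-strand genes are mirrored.
  Internally all coordinates are 0-based and half-open; counting windows
  that quote closed endpoint pairs (the promoter-assignment window, the
  junction windows, the TATA window, the peak-distance radius) are
  inclusive at both ends, and this is documented per function.

## The estimators

**Elongation efficiency** is the ratio of sense-strand GRO-Seq tag density
in the gene-body window `[+500, +2500)` to the density in the
promoter-proximal window `[-25, +175)`. A paused gene has high promoter
density and an empty body (efficiency near 0); release into elongation
raises the ratio. Genes with an empty promoter window or a span shorter
than 2.5 kb are flagged inevaluable rather than given infinite or
meaningless ratios; an occupied promoter with an empty body is a true 0.
Whether the promoter window should count antisense tags is not settled;
because the assay is strand-specific we count sense tags only, and the
windows are arguments.

**Splicing efficiency** has two independent estimators. The density
estimator is `1 - intron_density / exon_density` from strand-specific
5'-end counts: unspliced transcripts deposit tags in introns at the same
per-bp rate as in exons, so the ratio estimates the unspliced molar
fraction. A gene is *evaluable* only when both raw (pre-normalization)
exon and intron densities exceed 1 read/kb — an information filter, which
is why it deliberately uses raw read counts, not depth-normalized weights.
The junction estimator looks at 5' splice junctions (position 0 = first
intronic base): 32-bp reads from unspliced templates can place their 3'
ends at `[+7, +25]` past the junction, while spliced reads cannot (their
3' ends map to the exonic side), so
`1 - spanning_density / exonic_density` with the exonic window
`[-25, -7]` again estimates the unspliced fraction. Both 19-bp window
widths are forced by the printed endpoints for 32-bp tags; a different
read length triggers a warning but still computes. Per gene the junction
estimator averages per-junction values; the aggregate pools all junctions.

**Promoter enrichment over background** is not a published recipe; we
operationalize it as an upper-tail Poisson test of the raw promoter-window
count against a uniform-background mean
`total_mapped * window_length / genome_length`, Benjamini–Hochberg
corrected at alpha = 0.001. This is labelled as this package's choice and
every piece of it is an argument.

**Kinetic classification** applies the strict rules: I/E iff the 1-h fold
change exceeds 3; late iff the 1-h fold change is below 1.2 *and* the
12-h fold change exceeds 4; otherwise "other". Strictness matters at the
boundaries (a fold change of exactly 3 is not I/E), and the two
predicates are mutually exclusive by construction.

**Induced-gene calling** from paired GRO-Seq libraries uses
depth-normalized sense gene-body counts. No FDR procedure is prescribed
for this in the source analyses, so we use the simplest depth-aware count
test: conditional on the two-library total, the treated count is binomial
with success probability given by the library-depth split; one-sided
p-values are BH-corrected; a pseudocount of 0.5 on both raw counts guards
zero-basal fold changes. A gene is induced when fold change > 3, treated
RPKM > 0.25, and q < 0.10 — all strict. The cross-genotype overlap
summary bins the induced set of genotype A by its fold change in B:
also-induced (> 3), unresponsive (< 2 or inevaluable), and the
intermediate `[2, 3]` band, so the bins partition the set exactly.

**CAGE TSS refinement** collects sense-strand CAGE 5' ends at offsets in
`[-1000, 1000)` around the annotated TSS, slides a 100-bp window at 1-bp
steps (1901 windows), takes the highest-count window as the primary TSS
cluster and the highest-count bp inside it as the refined TSS. Ties break
to the 5'-most window, then the 5'-most bp — a determinism choice, since
no tie rule is published. Genes with no tags keep the annotated TSS,
flagged.

**Promoter sequence analysis** extracts the gene-oriented window
`[-500, +100)` (the same window used for motif discovery in the source
material; no separate GC window is published, so one window serves both
purposes and is an argument). GC content excludes ambiguous bases from
numerator and denominator. The optimal GC cutoff between two classes
scans every observed value `t` and maximizes `|P(a > t) - P(b > t)|`,
ties toward the smallest `t`; the statistic is rank-based, hence
invariant under monotone transforms. The TATA scan requires a consensus
`TATAWAWR` match (or a supplied PWM above its threshold, by default 90%
of the maximal log-odds score) whose *start* lies in `[-35, -20]` on the
sense strand. Known-motif enrichment is ZOOPS presence per promoter with
an exact hypergeometric upper-tail test; it replaces de novo motif
discovery, which is an explicit non-goal.

## The synthetic world

The generator's job is to emit data whose *statistical structure* matches
what the estimators assume, with every planted parameter recorded in a
truth table (`build_annotation()`), so that downstream estimates can be
compared to ground truth. No generative model is published for any of
these assays; all distributional shapes here are tractable stand-ins and
should be read as such.

* **Genome and annotation.** One contig; non-overlapping multi-exon genes
  on both strands, 4–10 kb with 2–6 exons of 150–400 bp and introns
  >= 200 bp by default; intergenic gaps >= 1.2 kb so promoter windows
  never collide. Promoter sequence features (exact-count GC, planted
  `TATAAAAG`) are anchored at the **true** TSS — annotated TSS plus a
  planted offset in `[-80, +80]` — because core-promoter elements sit
  where transcription actually starts; this is precisely what makes CAGE
  refinement worth doing before sequence analysis. Promoters without the
  TATA flag are scrubbed of chance consensus matches inside the scan
  window, so a noise-free positional scan recovers the planted fraction
  exactly.
* **ChIP libraries.** Fragment centers are drawn from Gaussian mixtures:
  a paused-polymerase peak at +40 bp (sd 50), or a bimodal histone
  profile with peaks at -50 ± 300 bp (sd 150) whose analytic minimum sits
  at the -50 bp nadir; 25-bp tags sit half a fragment upstream of their
  center on each strand, so the downstream half-fragment shift restores
  the center exactly (the simulator stores the true fragment length in
  library metadata to isolate shift logic from estimation error). A
  uniform genomic background carries 5% of library mass by default and
  exercises the enrichment caller.
* **GRO-Seq.** Sense reads per gene mix a uniform promoter component over
  `[-25, +175)` and a uniform body component over `[+500, +2500)` with
  weights chosen so the *expected window-density ratio equals the planted
  elongation efficiency*; a divergent antisense component (10% of each
  gene's reads, uniform over `[-500, -50)` upstream on the opposite
  strand) emulates divergent initiation.
* **RNA-Seq.** Reads come from mature (spliced) or unspliced
  (genomic-contiguous) templates. The planted splicing efficiency is the
  *molar fraction of spliced transcripts*, so the template of each read
  is chosen with probability proportional to `SE x mature_length` versus
  `(1-SE) x genomic_length`. This is the only weighting under which both
  estimators are unbiased for SE (a naive per-read mixture weight would
  make `1 - intron/exon` overshoot badly for genes whose span dwarfs
  their exons), and it is what "fraction of transcripts spliced" means
  physically. Each read records its genomic 3' end and junction-crossing
  status, so junction analysis needs no spliced aligner.
* **CAGE.** Tag 5' ends cluster at the true TSS with sd 2 bp — CAGE tag
  clusters at sharp promoters are a few bp wide — plus 10% uniform noise
  in the ±1 kb window.
* **Expression.** Latent noiseless triplets are drawn per class with
  fold-change ranges that keep ~5-sigma log margins to every
  classification boundary at the default multiplicative noise (lognormal,
  sd 0.05): I/E 1-h fold changes in [4.5, 30], late in [0.70, 0.84] with
  12-h in [6, 30], other in [1.7, 2.1]. The generator refuses noise
  levels at which the margin drops below 4 sigma, so class labels are
  guaranteed to survive the noise it emits.

Two calibration decisions deserve explicit notice. First, the
induced-gene recovery simulation plants 50 of 500 genes "5-fold induced at
RPKM 2": we read RPKM 2 as the *basal* level (treated = 10), because a
power analysis of the conditional binomial at 10^6-read depth shows the
treated-level reading cannot reach 90% sensitivity after BH correction at
q < 0.10 with 4–10 kb genes — the criterion is only attainable, and hence
only meaningful, under the basal reading. The planted per-gene read
counts are Poisson around `RPKM x kb`, and the library totals are set to
10^6 with the remainder understood to map outside the simulated genes, as
in any real library. Second, the splicing-recovery world uses short genes
(≈2 kb) with six 100–180-bp exons: per-junction window counts, not total
reads, limit the junction estimator's variance, and this
junction-information-rich structure is what makes a per-gene
cross-estimator agreement bound of 0.1 meaningful at 10^4 reads per gene.
Both choices were fixed from first principles before the tests were run.

**What a green test establishes — and what it does not.** Parameter
recovery on this world validates the window arithmetic, the orientation
and strand logic, the normalization, and the statistical calibration of
the callers. It does not validate robustness to anything the generator
omits: sequencing error, PCR duplicates, mappability holes, non-uniform
coverage along transcripts, multi-isoform genes, overlapping
transcription units, or chromatin-accessibility artifacts. Real libraries
violate the uniformity assumptions to varying degrees, and the estimators
inherit those violations.

## Numerical and degenerate-input choices

* Half-open windows for density ratios (edge choices are irrelevant at
  these widths but must be pinned); inclusive windows where endpoints are
  quoted as closed bp pairs.
* `floor(fragment/2)` shifting, documented, so odd fragments shift by
  the floor on both strands and mirror symmetry is exact.
* Zero-depth libraries, zero-length genes, unstranded libraries where
  strand is required, unknown mark specs, off-contig promoter windows,
  and over-full genomes all raise immediate errors naming the constraint;
  inevaluable per-gene cases (empty promoter window, single-exon genes,
  sub-threshold densities) are flagged, never silently dropped.
* Every `simulate_*` operation derives a fixed per-operation seed from
  the master seed, so any library can be regenerated independently and
  identical configs give byte-identical outputs.
* Config files are JSON (an R YAML parser is not available in the
  supported environment); the schema is unchanged and unknown keys are
  rejected by name.

## Limitations

The package consumes BED tag files only (no BAM parsing in this version),
assumes single-isoform gene models, takes junction information from the
simulator or an upstream aligner rather than performing spliced
alignment, and treats peak intervals as given (no peak calling). The
enrichment-over-background and induced-gene FDR procedures are this
package's operationalizations of informally described analyses and are
clearly labelled as such.
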