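# nascentmetrics

Genome-wide quantification of how signal-responsive genes are activated,
from sequencing tag libraries: promoter-proximal RNA polymerase II
pausing, transcriptional elongation efficiency, splicing efficiency of
nascent transcripts, kinetic classification of induced genes, CAGE-based
TSS refinement, and core-promoter sequence analysis (GC content, TATA
boxes, known-motif enrichment). The package is aimed at regulatory
genomicists analysing ChIP-Seq / GRO-Seq / RNA-Seq / CAGE tag data around
transcription start sites — the setting in which immediate/early
inflammatory genes are distinguished from late ones by paused polymerase
that stimulation releases into productive elongation.

## Core quantities

All assays reduce to libraries of uniquely mapped read 5' ends ("tags"),
depth-normalized so each tag carries weight `1e7 / total_mapped`, with
ChIP tags shifted by half the fragment length. With the TSS at 0 and
downstream positive along the gene strand:

* **Elongation efficiency** (per gene, strand-specific GRO-Seq):

  `EE = density[+500, +2500) / density[-25, +175)`

  Low EE = paused polymerase; stimulation raises EE when pausing is
  released.

* **Splicing efficiency**, two independent estimators from total RNA
  tags: `SE_density = 1 - intron_density / exon_density` (evaluable when
  both raw densities exceed 1 read/kb), and, at 5' splice junctions
  (position 0 = first intronic base, 32-bp tags),
  `SE_junction = 1 - density(3' ends in [+7, +25]) / density(3' ends in
  [-25, -7])`.

* **Kinetic classes** from three-timepoint expression: immediate/early
  iff `fc_1h > 3`; late iff `fc_1h < 1.2` and `fc_12h > 4`; otherwise
  other (strict inequalities).

* **Induced genes** from paired GRO-Seq gene-body counts: fold change
  (pseudocount 0.5, depth-corrected) > 3, treated RPKM > 0.25, and
  BH q < 0.10 from a conditional binomial test.

* **Refined TSS**: the max-density 100-bp CAGE window within ±1 kb of
  the annotated TSS, then the max-count bp inside it.

A seeded synthetic-data generator (`sim_config()`, `build_annotation()`,
`simulate_*()`) plants every one of these parameters per gene and records
them in a truth table, so each estimator is verified by parameter
recovery; see the methods vignette
(`vignettes/nascent-transcription-metrics.Rmd`) for the generative model
and its limits.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic world (300 genes, seed 1) and write tables under `results/`.
For example:

```sh
Rscript analysis/03_elongation_splicing.R
```

prints

```
EE recovery over 200 genes, EE in [0.05, 2], 1000 sense reads/gene:
  median relative error 5.2% (200/200 genes evaluable)
median elongation efficiency by class (basal -> stimulated):
  IE    0.10 -> 1.00
  late  0.30 -> 0.31
  other 0.50 -> 0.51
SE recovery over 100 genes (SE in {0.5, 0.9, 0.99}, 1e4 reads/gene):
  max |density SE - truth| = 0.040; max |density - junction| = 0.100
  aggregate junction-based SE: 0.839
```

i.e. the elongation estimator recovers planted efficiencies to ~5%
median error at 1000 reads/gene; immediate/early genes sit paused at
baseline (EE 0.10) and are released on stimulation (EE 1.00) while other
classes barely move; and the two splicing estimators agree with truth and
with each other. Similarly `analysis/05_promoters.R` prints

```
CAGE refinement: 100% of genes within 5 bp of the planted TSS
GC cutoff 0.57 discriminates IE from late (discrimination 0.53);
  71% of IE and 18% of late promoters exceed it
TATA in [-35, -20]: 38% of IE vs 4% of late promoters (planted 38% / 11%)
```

— the positional TATA scan at the CAGE-refined TSS recovers the planted
class asymmetry, which it cannot do at the annotated TSS because the true
start sites are offset by up to ±80 bp.

In code, the same machinery is three calls:

```r
library(nascentmetrics)
cfg   <- sim_config(n_genes = 300, library_size = 1e6, seed = 1)
world <- build_annotation(cfg)
gro   <- simulate_gro_library(world$annotation, world$truth, "basal", cfg)
ee    <- elongation_efficiency(gro, world$annotation)
head(ee[, c("gene_id", "promoter_density", "body_density", "efficiency")])
```

Real data enter through `read_tag_bed()` (BED6 tag files),
`read_annotation_bed12()` and a genome `DNAStringSet`; every estimator
takes the same objects regardless of origin.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the config-driven pipeline (`validate_config()` + `run_pipeline()`)
end-to-end on a fresh synthetic world — simulation, TSS profiles,
elongation/splicing metrics, enrichment calls, kinetic classification,
induced-gene calls, CAGE refinement and promoter sequence analysis — and
writes its JSON report to `--out`, with all pipeline tables under
`results/pipeline/`. The parameter-recovery checks themselves live in
`tests/testthat/test-acceptance.R`.
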