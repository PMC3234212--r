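#' Elongation efficiency from stranded nascent-transcription tags
#'
#' The ratio of sense-strand tag density in the gene body window
#' (`[+500, +2500)` bp downstream of the TSS) to the density at the proximal
#' promoter (`[-25, +175)` bp). Low values indicate promoter-proximal
#' polymerase pausing; the ratio rises when paused polymerase is released
#' into productive elongation. Windows are gene-oriented and half-open;
#' densities are weighted tags per bp.
#'
#' @param gro A stranded [tag_library()] of nascent-transcription (GRO-Seq)
#'   tags, unshifted.
#' @param annotation A [gene_annotation()].
#' @param prom_window,body_window Gene-oriented half-open windows in bp.
#' @param condition Optional condition label copied into the output.
#' @param target Normalization target.
#' @return data.frame with per-gene `promoter_density`, `body_density`,
#'   `efficiency` and `evaluable`. Efficiency is `NA` (not evaluable) when
#'   the promoter density is 0 or the gene span is shorter than the body
#'   window end; it is 0 when the body is empty but the promoter is not.
#' @export
elongation_efficiency <- function(gro, annotation,
                                  prom_window = c(-25L, 175L),
                                  body_window = c(500L, 2500L),
                                  condition = NA_character_, target = 1e7) {
  if (!gro$stranded)
    stop("elongation efficiency requires a stranded library")
  w <- tag_weight(gro, target)
  g <- annotation$genes
  idx <- tag_index(gro, stranded = TRUE)
  pw <- diff(prom_window)
  bw <- diff(body_window)
  res <- lapply(seq_len(nrow(g)), function(i) {
    sp <- idx[[paste(g$chrom[i], g$strand[i])]]
    pb <- window_bounds_halfopen(g$tss[i], g$strand[i],
                                 prom_window[1], prom_window[2])
    bb <- window_bounds_halfopen(g$tss[i], g$strand[i],
                                 body_window[1], body_window[2])
    pd <- count_sorted(sp, pb[1], pb[2]) * w / pw
    bd <- count_sorted(sp, bb[1], bb[2]) * w / bw
    span <- g$tx_end[i] - g$tx_start[i]
    ok <- pd > 0 && span >= body_window[2]
    data.frame(gene_id = g$gene_id[i], condition = condition,
               promoter_density = pd, body_density = bd,
               efficiency = if (ok) bd / pd else NA_real_, evaluable = ok)
  })
  do.call(rbind, res)
}

#' Splicing efficiency from intron/exon tag densities
#'
#' One minus the ratio of intronic to exonic sense-strand tag density,
#' per gene. Unspliced transcripts deposit tags in introns at the same
#' per-bp rate as in exons, so the intron/exon density ratio estimates the
#' unspliced fraction. A gene is evaluable only when both raw (unweighted)
#' exon and intron densities exceed `min_raw_per_kb` reads per kb -- an
#' information filter, applied before depth normalization.
#'
#' @param rna A stranded [tag_library()] of total-RNA tags.
#' @param annotation A [gene_annotation()]; genes should have >= 1 intron.
#' @param min_raw_per_kb Evaluability filter on raw read densities.
#' @param condition Optional condition label.
#' @param target Normalization target.
#' @return data.frame with per-gene exon/intron densities,
#'   `efficiency_density` (`1 - intron/exon`) and `evaluable_density`.
#' @export
splicing_efficiency_density <- function(rna, annotation, min_raw_per_kb = 1,
                                        condition = NA_character_,
                                        target = 1e7) {
  d <- exon_intron_density(rna, annotation, target = target)
  ok <- !is.na(d$intron_raw_per_kb) &
    d$exon_raw_per_kb > min_raw_per_kb &
    d$intron_raw_per_kb > min_raw_per_kb
  # the ratio itself is reported whenever defined; `evaluable_density`
  # carries the information filter
  eff <- ifelse(!is.na(d$intron_density) & d$exon_density > 0,
                1 - d$intron_density / d$exon_density, NA_real_)
  data.frame(gene_id = d$gene_id, condition = condition,
             exon_density = d$exon_density,
             intron_density = d$intron_density,
             efficiency_density = eff, evaluable_density = ok)
}

# genomic 3'-end positions; simulator-provided end3 wins (it is correct for
# spliced reads), otherwise assume genomic-contiguous reads
read_end3 <- function(lib) {
  if (!is.null(lib$tags$end3)) return(lib$tags$end3)
  L <- lib$read_length
  if (is.na(L)) stop("read_length unset; cannot locate 3' ends")
  ifelse(lib$tags$strand == "+", lib$tags$pos + L - 1L, lib$tags$pos - L + 1L)
}

#' Splicing efficiency from 5' splice-junction 3'-end depletion
#'
#' Reads from unspliced templates extend past 5' splice junctions into the
#' intron, so their 3' ends populate the junction-relative window
#' `[+7, +25]` (inclusive; position 0 is the first intronic base). Spliced
#' reads cannot end there -- their 3' ends map to the exonic side. Splicing
#' efficiency is one minus the ratio of 3'-end density in the spanning
#' window to that in the exonic window `[-25, -7]`; both windows are 19 bp,
#' as forced by the printed endpoints for 32-bp tags.
#'
#' @param rna A stranded [tag_library()]; a warning is issued when the read
#'   length is not 32 bp (the windows were derived for 32-bp tags).
#' @param annotation A [gene_annotation()]; single-exon genes are skipped.
#' @param span_window,exon_window Inclusive junction-relative 3'-end windows.
#' @param condition Optional condition label.
#' @return list with `per_gene` (junction counts, per-gene
#'   `efficiency_junction` averaging junctions, `evaluable_junction`) and
#'   `aggregate` (efficiency pooling all junctions of the gene set).
#' @export
splicing_efficiency_junction <- function(rna, annotation,
                                         span_window = c(7L, 25L),
                                         exon_window = c(-25L, -7L),
                                         condition = NA_character_) {
  if (!rna$stranded)
    stop("junction analysis requires a stranded library")
  if (!is.na(rna$read_length) && rna$read_length != 32L)
    warning("junction windows were derived for 32-bp tags; read length is ",
            rna$read_length)
  g <- annotation$genes
  t <- rna$tags
  end3 <- read_end3(rna)
  sw <- span_window[2] - span_window[1] + 1L
  ew <- exon_window[2] - exon_window[1] + 1L
  # per (chrom, strand) sorted 3'-end index
  key <- paste(t$chrom, t$strand)
  idx <- lapply(split(end3, key), sort)
  per <- lapply(seq_len(nrow(g)), function(i) {
    jx <- splice_junctions(annotation, g$gene_id[i])
    if (length(jx) == 0L)
      return(data.frame(gene_id = g$gene_id[i], condition = condition,
                        n_junctions = 0L, spanning_count = 0,
                        exonic_count = 0,
                        junction_spanning_density = NA_real_,
                        junction_exon_density = NA_real_,
                        efficiency_junction = NA_real_,
                        evaluable_junction = FALSE))
    sp <- idx[[paste(g$chrom[i], g$strand[i])]]
    cnt <- vapply(jx, function(J) {
      sb <- window_bounds_inclusive(J, g$strand[i],
                                    span_window[1], span_window[2])
      eb <- window_bounds_inclusive(J, g$strand[i],
                                    exon_window[1], exon_window[2])
      c(count_sorted(sp, sb[1], sb[2]), count_sorted(sp, eb[1], eb[2]))
    }, numeric(2))
    span_n <- cnt[1, ]
    exon_n <- cnt[2, ]
    ok <- exon_n > 0
    eff_j <- 1 - (span_n[ok] / sw) / (exon_n[ok] / ew)
    data.frame(gene_id = g$gene_id[i], condition = condition,
               n_junctions = length(jx),
               spanning_count = sum(span_n), exonic_count = sum(exon_n),
               junction_spanning_density = sum(span_n) / (sw * length(jx)),
               junction_exon_density = sum(exon_n) / (ew * length(jx)),
               efficiency_junction = if (any(ok)) mean(eff_j) else NA_real_,
               evaluable_junction = any(ok))
  })
  per <- do.call(rbind, per)
  tot_span <- sum(per$spanning_count)
  tot_exon <- sum(per$exonic_count)
  agg <- if (tot_exon > 0) 1 - (tot_span / sw) / (tot_exon / ew) else NA_real_
  list(per_gene = per, aggregate = agg)
}

#' Promoter enrichment over genomic background
#'
#' Calls a promoter enriched for a mark when its raw tag count in the
#' `|d| <= window` TSS window exceeds what a uniform genomic background
#' would give, by an upper-tail Poisson test with mean
#' `total_mapped * window_length / genome_length`, Benjamini-Hochberg
#' corrected across the tested gene set. The enrichment criterion itself is
#' not prescribed by any reference method; this Poisson-vs-background
#' operationalization is this package's choice.
#'
#' @param lib A [tag_library()] (shift ChIP libraries first).
#' @param annotation A [gene_annotation()].
#' @param genome_length Total genome length in bp (background denominator).
#' @param window Promoter half-width in bp (inclusive bounds).
#' @param alpha BH-adjusted significance threshold.
#' @param target Normalization target.
#' @return data.frame with per-gene `observed` (normalized count),
#'   `expected_background`, `p_value`, `q_value` and `enriched`.
#' @export
promoter_enrichment_call <- function(lib, annotation, genome_length,
                                     window = 1000L, alpha = 0.001,
                                     target = 1e7) {
  if (missing(genome_length) || is.null(genome_length) ||
      is.na(genome_length) || genome_length <= 0)
    stop("genome_length must be set for the background model")
  pc <- promoter_tag_count(lib, annotation, window = window, target = target)
  w <- tag_weight(lib, target)
  lambda <- lib$total_mapped * (2 * window + 1) / genome_length
  p <- ppois(pc$count - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  data.frame(gene_id = pc$gene_id, observed = pc$normalized_count,
             expected_background = lambda * w, p_value = p, q_value = q,
             enriched = q < alpha & pc$count > lambda)
}
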