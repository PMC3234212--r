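#' @name counting
#' @title Weighted tag counting around genes
#' @description All counting operations weight every tag by
#'   `target / total_mapped` ([tag_weight()]) so that results are comparable
#'   across libraries of different depth. Gene-oriented offsets place the TSS
#'   at 0 with downstream positive along the gene strand.
NULL

# genomic inclusive bounds of a gene-oriented half-open window [a, b)
window_bounds_halfopen <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b - 1L) else c(tss - b + 1L, tss - a)
}

# genomic inclusive bounds of a gene-oriented inclusive window [a, b]
window_bounds_inclusive <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b, tss - a)
}

# per-gene sorted-position lookup honoring sense_only
gene_sorted_pos <- function(idx_all, idx_str, chrom, strand, sense_only) {
  if (sense_only) idx_str[[paste(chrom, strand)]] else idx_all[[chrom]]
}

#' Promoter tag count
#'
#' Weighted tag count within `window` bp of the TSS, inclusive at both
#' bounds ("within 1 kb" is read as `|d| <= window`). ChIP libraries should
#' be passed through [shift_tags()] first.
#'
#' @param lib A [tag_library()].
#' @param annotation A [gene_annotation()].
#' @param window Half-width of the promoter window in bp (default 1000).
#' @param sense_only Count only tags on the gene's strand.
#' @param target Normalization target (tags).
#' @return data.frame with `gene_id`, raw `count`, and `normalized_count`
#'   (weighted tags per `target` mapped).
#' @export
promoter_tag_count <- function(lib, annotation, window = 1000L,
                               sense_only = FALSE, target = 1e7) {
  if (window <= 0L) stop("promoter window must be positive")
  if (sense_only && !lib$stranded)
    stop("sense_only counting requires a stranded library")
  w <- tag_weight(lib, target)
  g <- annotation$genes
  idx_all <- tag_index(lib, stranded = FALSE)
  idx_str <- if (sense_only) tag_index(lib, stranded = TRUE) else NULL
  raw <- vapply(seq_len(nrow(g)), function(i) {
    sp <- gene_sorted_pos(idx_all, idx_str, g$chrom[i], g$strand[i], sense_only)
    count_sorted(sp, g$tss[i] - window, g$tss[i] + window)
  }, numeric(1))
  data.frame(gene_id = g$gene_id, count = raw, normalized_count = raw * w)
}

#' TSS-anchored density profile
#'
#' Cumulative position-specific tag density around the TSS, summed over all
#' genes. Minus-strand genes are mirrored so offsets are gene-oriented.
#' Densities are weighted tags per bp per `target` mapped tags.
#'
#' @param lib A [tag_library()] (shift ChIP libraries first).
#' @param annotation A [gene_annotation()].
#' @param range Profile half-width in bp; offsets cover `[-range, range)`.
#' @param bin Bin width in bp; must divide `range`.
#' @param sense_only Count only tags on each gene's strand.
#' @param target Normalization target.
#' @return data.frame with `offset` (bin start, gene-oriented) and `density`.
#' @export
tss_profile <- function(lib, annotation, range = 2000L, bin = 25L,
                        sense_only = FALSE, target = 1e7) {
  if (range %% bin != 0L)
    stop("bin width ", bin, " does not divide profile range ", range)
  if (sense_only && !lib$stranded)
    stop("sense_only profiles require a stranded library")
  w <- tag_weight(lib, target)
  g <- annotation$genes
  nb <- 2L * (range %/% bin)
  counts <- numeric(nb)
  t <- lib$tags
  for (i in seq_len(nrow(g))) {
    keep <- t$chrom == g$chrom[i]
    if (sense_only) keep <- keep & t$strand == g$strand[i]
    pos <- t$pos[keep]
    rel <- if (g$strand[i] == "+") pos - g$tss[i] else g$tss[i] - pos
    rel <- rel[rel >= -range & rel < range]
    if (length(rel) > 0L)
      counts <- counts + tabulate((rel + range) %/% bin + 1L, nbins = nb)
  }
  data.frame(offset = seq(-range, range - bin, by = bin),
             density = counts * w / bin)
}

#' Gene-body tag density
#'
#' Weighted tag count within the transcript span `[tx_start, tx_end)`,
#' divided by the span in kb.
#'
#' @inheritParams promoter_tag_count
#' @param sense_only Count only tags on the gene's strand.
#' @return data.frame with `gene_id`, raw `count`, and `density`
#'   (weighted tags per kb per `target` mapped).
#' @export
gene_body_density <- function(lib, annotation, sense_only = FALSE,
                              target = 1e7) {
  if (sense_only && !lib$stranded)
    stop("sense_only counting requires a stranded library")
  w <- tag_weight(lib, target)
  g <- annotation$genes
  if (any(g$tx_end <= g$tx_start)) stop("zero-length gene span")
  idx_all <- tag_index(lib, stranded = FALSE)
  idx_str <- if (sense_only) tag_index(lib, stranded = TRUE) else NULL
  raw <- vapply(seq_len(nrow(g)), function(i) {
    sp <- gene_sorted_pos(idx_all, idx_str, g$chrom[i], g$strand[i], sense_only)
    count_sorted(sp, g$tx_start[i], g$tx_end[i] - 1L)
  }, numeric(1))
  data.frame(gene_id = g$gene_id, count = raw,
             density = raw * w / ((g$tx_end - g$tx_start) / 1000))
}

#' Exon and intron tag densities
#'
#' Strand-specific: a tag is assigned to exon or intron by its unshifted
#' 5'-end position, counting sense-strand tags only. Densities are weighted
#' counts divided by total exonic (resp. intronic) length in kb. Single-exon
#' genes get `NA` intron density.
#'
#' @inheritParams promoter_tag_count
#' @return data.frame with per-gene raw counts, feature lengths (bp) and
#'   weighted densities per kb (`exon_density`, `intron_density`), plus raw
#'   per-kb read densities (`exon_raw_per_kb`, `intron_raw_per_kb`) used by
#'   evaluability filters.
#' @export
exon_intron_density <- function(lib, annotation, target = 1e7) {
  if (!lib$stranded)
    stop("exon/intron densities require a stranded library")
  w <- tag_weight(lib, target)
  g <- annotation$genes
  idx_str <- tag_index(lib, stranded = TRUE)
  res <- lapply(seq_len(nrow(g)), function(i) {
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    sp <- idx_str[[paste(g$chrom[i], g$strand[i])]]
    ex_count <- sum(vapply(seq_len(nrow(ex)), function(j)
      count_sorted(sp, ex$start[j], ex$end[j] - 1L), numeric(1)))
    body <- count_sorted(sp, g$tx_start[i], g$tx_end[i] - 1L)
    in_count <- body - ex_count
    ex_len <- sum(ex$end - ex$start)
    in_len <- (g$tx_end[i] - g$tx_start[i]) - ex_len
    data.frame(gene_id = g$gene_id[i],
               exon_count = ex_count, intron_count = in_count,
               exon_len = ex_len, intron_len = in_len,
               exon_density = ex_count * w / (ex_len / 1000),
               intron_density = if (in_len > 0L)
                 in_count * w / (in_len / 1000) else NA_real_,
               exon_raw_per_kb = ex_count / (ex_len / 1000),
               intron_raw_per_kb = if (in_len > 0L)
                 in_count / (in_len / 1000) else NA_real_)
  })
  do.call(rbind, res)
}

#' RPKM from gene-body counts
#'
#' Reads per kb of gene model per million mapped reads:
#' `(count / gene_kb) / (total_mapped / 1e6)`.
#'
#' @inheritParams gene_body_density
#' @return data.frame with `gene_id`, raw `count`, `rpkm`.
#' @export
rpkm <- function(lib, annotation, sense_only = FALSE) {
  if (lib$total_mapped <= 0) stop("cannot compute RPKM: total_mapped = 0")
  gb <- gene_body_density(lib, annotation, sense_only = sense_only)
  g <- annotation$genes
  data.frame(gene_id = gb$gene_id, count = gb$count,
             rpkm = (gb$count / ((g$tx_end - g$tx_start) / 1000)) /
               (lib$total_mapped / 1e6))
}

#' Write a bedGraph track of normalized tag coverage
#'
#' Single-bp intervals at tag positions with the per-position weighted tag
#' count, for genome-browser inspection. ChIP libraries should be shifted
#' first.
#'
#' @inheritParams promoter_tag_count
#' @param path Output file.
#' @param name Track name.
#' @export
write_bedgraph <- function(lib, path, name = "tags", target = 1e7) {
  w <- tag_weight(lib, target)
  t <- lib$tags
  agg <- stats::aggregate(list(n = rep(1L, nrow(t))),
                          by = list(chrom = t$chrom, pos = t$pos), FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", agg$chrom, agg$pos, agg$pos + 1L,
                     agg$n * w), con)
  invisible(path)
}
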