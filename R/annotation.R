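#' Gene annotation container
#'
#' Bundles a gene table and an exon table into a `GeneAnnotation` object.
#' All coordinates are 0-based, half-open. The TSS is `tx_start` for
#' plus-strand genes and `tx_end - 1` for minus-strand genes; gene-oriented
#' offsets place the TSS at 0 with downstream positive along the gene strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`. Exons of a
#'   gene must be disjoint and lie within its transcript span.
#' @return A `GeneAnnotation` object: a list with elements `genes` (with a
#'   derived `tss` column) and `exons` (sorted by genomic start within gene).
#' @export
gene_annotation <- function(genes, exons) {
  genes <- as.data.frame(genes)
  exons <- as.data.frame(exons)
  need_g <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need_g %in% names(genes)))
    stop("genes table must have columns: ", paste(need_g, collapse = ", "))
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stop("exons table must have columns: gene_id, start, end")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in genes table")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$tx_end <= genes$tx_start))
    stop("zero- or negative-length gene span")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon rows for unknown gene_id")
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  structure(list(genes = genes, exons = exons), class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d genes, %d exons on %d contig(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

# exons of one gene in transcription order (list of start/end vectors)
gene_exons <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  if (g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Enumerate 5' splice junctions of a gene
#'
#' Returns the genomic coordinate of the first intronic base after each exon
#' (in transcription order, excluding the last exon). Gene-oriented offsets
#' around a junction place that base at 0, the last exonic base at -1.
#'
#' @param annotation A [gene_annotation()] object.
#' @param gene_id Single gene id.
#' @return Integer vector of genomic positions (0-based), length
#'   `n_exons - 1`; empty for single-exon genes.
#' @export
splice_junctions <- function(annotation, gene_id) {
  ex <- gene_exons(annotation, gene_id)
  if (nrow(ex) < 2L) return(integer(0))
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  ex <- ex[-nrow(ex), , drop = FALSE]
  if (g$strand == "+") as.integer(ex$end) else as.integer(ex$start - 1L)
}

# convert genomic positions to gene-oriented offsets relative to an anchor
# (strand is a scalar: one gene at a time)
rel_offset <- function(pos, anchor, strand) {
  if (strand == "+") pos - anchor else anchor - pos
}

# genomic positions of gene-oriented offsets (scalar strand)
oriented_pos <- function(tss, strand, rel) {
  if (strand == "+") tss + rel else tss - rel
}

#' Write annotation as BED12
#'
#' @param annotation A [gene_annotation()] object.
#' @param path Output file.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  g <- annotation$genes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(g$chrom[i], g$tx_start[i], g$tx_end[i], g$gene_id[i], 0,
          g$strand[i], g$tx_start[i], g$tx_end[i], "0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - g$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read annotation from BED12
#'
#' @param path BED12 file.
#' @return A [gene_annotation()] object.
#' @export
read_annotation_bed12 <- function(path) {
  b <- fread(path, header = FALSE, sep = "\t")
  if (ncol(b) < 12L) stop("BED12 requires 12 columns, got ", ncol(b))
  genes <- data.frame(gene_id = as.character(b[[4]]), chrom = b[[1]],
                      strand = b[[6]], tx_start = b[[2]], tx_end = b[[3]])
  exons <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    sizes <- as.integer(strsplit(b[[11]][i], ",")[[1]])
    offs <- as.integer(strsplit(b[[12]][i], ",")[[1]])
    data.frame(gene_id = as.character(b[[4]][i]),
               start = b[[2]][i] + offs, end = b[[2]][i] + offs + sizes)
  }))
  gene_annotation(genes, exons)
}

#' Write annotation as GTF (1-based, closed intervals)
#'
#' @param annotation A [gene_annotation()] object.
#' @param path Output file.
#' @param source Source tag for column 2.
#' @export
write_annotation_gtf <- function(annotation, path, source = "nascentmetrics") {
  g <- annotation$genes
  ex <- annotation$exons
  gi <- match(ex$gene_id, g$gene_id)
  lines <- c(
    sprintf('%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
            g$chrom, source, g$tx_start + 1L, g$tx_end, g$strand,
            g$gene_id, g$gene_id),
    sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
            g$chrom[gi], source, ex$start + 1L, ex$end, g$strand[gi],
            ex$gene_id, ex$gene_id))
  writeLines(lines, path)
  invisible(path)
}
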