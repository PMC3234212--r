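# Fixtures are built in code; oracles are deliberately naive per-tag loops,
# independent of the package's sorted-index counters.

# two hand-laid genes on one contig: g_plus (3 exons) and g_minus (2 exons)
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("g_plus", "g_minus"),
    chrom = "chrT",
    strand = c("+", "-"),
    tx_start = c(5000L, 20000L),
    tx_end = c(11000L, 26000L))
  exons <- data.frame(
    gene_id = c("g_plus", "g_plus", "g_plus", "g_minus", "g_minus"),
    start = c(5000L, 7000L, 10000L, 20000L, 25000L),
    end = c(5600L, 7600L, 11000L, 21000L, 26000L))
  gene_annotation(genes, exons)
}

# a tag library built from explicit positions (weight 1 by default)
toy_library <- function(pos, strand = "+", chrom = "chrT",
                        total_mapped = 1e7, read_length = 32L,
                        fragment_length = NA_integer_, stranded = TRUE,
                        ...) {
  n <- length(pos)
  tag_library(data.frame(chrom = rep_len(chrom, n),
                         pos = as.integer(pos),
                         strand = rep_len(strand, n), ...),
              read_length = read_length, fragment_length = fragment_length,
              stranded = stranded, total_mapped = total_mapped)
}

# uniform random tags over a window, for oracle-equality checks
random_library <- function(n, lo, hi, seed, chrom = "chrT",
                           total_mapped = 1e7) {
  set.seed(seed)
  toy_library(sample(seq(lo, hi), n, replace = TRUE),
              strand = sample(c("+", "-"), n, replace = TRUE),
              chrom = chrom, total_mapped = total_mapped)
}

# O(n_tags) scan: tags with position in [lo, hi], optional strand filter
oracle_window_count <- function(lib, chrom, lo, hi, strand = NULL) {
  t <- lib$tags
  n <- 0L
  for (k in seq_len(nrow(t))) {
    if (t$chrom[k] != chrom) next
    if (!is.null(strand) && t$strand[k] != strand) next
    if (t$pos[k] >= lo && t$pos[k] <= hi) n <- n + 1L
  }
  n
}

# per-tag exon/intron assignment oracle (sense strand, 5' ends)
oracle_exon_intron <- function(lib, annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  t <- lib$tags
  exn <- 0L; inn <- 0L
  for (k in seq_len(nrow(t))) {
    if (t$chrom[k] != g$chrom || t$strand[k] != g$strand) next
    p <- t$pos[k]
    if (p < g$tx_start || p >= g$tx_end) next
    in_exon <- any(p >= ex$start & p < ex$end)
    if (in_exon) exn <- exn + 1L else inn <- inn + 1L
  }
  c(exon = exn, intron = inn)
}

# coordinate-mirror of a library and annotation: pos' = L - 1 - pos, strands
# flipped, gene/exon intervals reflected
mirror_world <- function(lib, annotation, L) {
  t <- lib$tags
  t$pos <- L - 1L - t$pos
  t$strand <- ifelse(t$strand == "+", "-", "+")
  mlib <- tag_library(t, read_length = lib$read_length,
                      fragment_length = lib$fragment_length,
                      stranded = lib$stranded,
                      total_mapped = lib$total_mapped)
  g <- annotation$genes
  mg <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                   strand = ifelse(g$strand == "+", "-", "+"),
                   tx_start = L - g$tx_end, tx_end = L - g$tx_start)
  ex <- annotation$exons
  mex <- data.frame(gene_id = ex$gene_id, start = L - ex$end,
                    end = L - ex$start)
  list(lib = mlib, annotation = gene_annotation(mg, mex))
}

# access to the internal PWM scorer for statistical checks
pwm_scores_for_test <- function(pwm, s) nascentmetrics:::pwm_scores(pwm, s)

# small synthetic world shared by several tests
small_world <- function(n_genes = 20, seed = 11, library_size = 5e4, ...) {
  cfg <- sim_config(n_genes = n_genes, library_size = library_size,
                    seed = seed, ...)
  w <- build_annotation(cfg)
  w$config <- cfg
  w
}
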