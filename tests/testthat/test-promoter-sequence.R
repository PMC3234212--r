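# a tiny hand-built genome: one plus-strand and one mirrored minus-strand
# gene whose promoters contain known sequence
seq_world <- function(promoter_plus) {
  stopifnot(nchar(promoter_plus) == 600)
  set.seed(99)
  bg <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
              collapse = "")
  # plus gene TSS at 2000 (0-based): promoter occupies [1500, 2100)
  s <- paste0(substr(bg, 1, 1500), promoter_plus,
              substr(bg, 2101, 6000))
  genome <- Biostrings::DNAStringSet(s)
  names(genome) <- "chrQ"
  anno <- gene_annotation(
    data.frame(gene_id = "p", chrom = "chrQ", strand = "+",
               tx_start = 2000L, tx_end = 5000L),
    data.frame(gene_id = "p", start = c(2000L, 4000L),
               end = c(2600L, 4600L)))
  list(genome = genome, annotation = anno)
}

test_that("promoter GC counts bases in the gene-oriented window", {
  all_gc <- seq_world(paste(rep("GC", 300), collapse = ""))
  expect_equal(promoter_gc(all_gc$genome, all_gc$annotation)$gc, 1.0)
  half <- seq_world(paste(rep("ATGC", 150), collapse = ""))
  expect_equal(promoter_gc(half$genome, half$annotation)$gc, 0.5)
  # ambiguous bases drop out of numerator and denominator
  amb <- seq_world(paste0(paste(rep("ATGC", 149), collapse = ""), "NNGC"))
  expect_equal(promoter_gc(amb$genome, amb$annotation)$gc,
               (149 * 2 + 2) / 598)
  # a window running off the contig errors
  expect_error(promoter_gc(all_gc$genome, all_gc$annotation,
                           window = c(-3000L, 100L)), "contig")

  # strand consistency: a gene and its reverse-complement mirror agree
  w <- small_world(n_genes = 10, seed = 71)
  genome <- synthesize_genome_sequence(w$annotation, w$truth, w$config)
  gc_f <- promoter_gc(genome, w$annotation)
  L <- attr(w$annotation, "genome_length")
  g <- w$annotation$genes
  mg <- gene_annotation(
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               strand = ifelse(g$strand == "+", "-", "+"),
               tx_start = L - g$tx_end, tx_end = L - g$tx_start),
    data.frame(gene_id = w$annotation$exons$gene_id,
               start = L - w$annotation$exons$end,
               end = L - w$annotation$exons$start))
  mgenome <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(genome[[1]]))
  names(mgenome) <- g$chrom[1]
  gc_r <- promoter_gc(mgenome, mg)
  expect_equal(gc_r$gc, gc_f$gc)
})

test_that("optimal GC cutoff equals the exhaustive threshold scan", {
  out <- optimal_gc_cutoff(c(0.7, 0.8), c(0.3, 0.4))
  expect_equal(out$cutoff, 0.4)
  expect_equal(out$discrimination, 1.0)
  same <- optimal_gc_cutoff(c(0.5, 0.6), c(0.5, 0.6))
  expect_equal(same$discrimination, 0)
  expect_error(optimal_gc_cutoff(numeric(0), 0.5), "non-empty")

  set.seed(81)
  a <- rnorm(100, 0.70, 0.05)
  b <- rnorm(100, 0.45, 0.05)
  got <- optimal_gc_cutoff(a, b)
  # brute force over every candidate threshold
  cand <- sort(unique(c(a, b)))
  disc <- vapply(cand, function(t) abs(mean(a > t) - mean(b > t)),
                 numeric(1))
  expect_equal(got$discrimination, max(disc))
  expect_equal(got$cutoff, cand[which.max(disc)])
  expect_true(got$cutoff >= 0.5 && got$cutoff <= 0.65)
  # rank invariance under a strictly monotone transform
  tr <- function(x) exp(3 * x)
  expect_equal(optimal_gc_cutoff(tr(a), tr(b))$discrimination,
               got$discrimination)
})

test_that("CAGE TSS refinement matches the all-windows brute force", {
  anno <- gene_annotation(
    data.frame(gene_id = "c", chrom = "chrT", strand = "+",
               tx_start = 10000L, tx_end = 15000L),
    data.frame(gene_id = "c", start = c(10000L, 12000L),
               end = c(10500L, 12500L)))
  # all tags at one bp
  one <- toy_library(rep(9950L, 7))
  r1 <- refine_tss_from_cage(one, anno)
  expect_equal(r1$refined_tss, 9950L)
  expect_equal(r1$offset, -50L)
  # zero tags: annotated TSS retained, flagged
  r0 <- refine_tss_from_cage(toy_library(integer(0), total_mapped = 10),
                             anno)
  expect_equal(r0$refined_tss, 10000L)
  expect_false(r0$has_tags)

  # 200-tag fixture against exhaustive evaluation of all 1901 windows
  set.seed(91)
  pos <- sample(seq(9000L, 10999L), 200, replace = TRUE)
  lib <- toy_library(pos, total_mapped = 200)
  got <- refine_tss_from_cage(lib, anno)
  rel <- pos - 10000L
  rel <- rel[rel >= -1000 & rel < 1000]
  wins <- vapply(-1000:900, function(j)
    sum(rel >= j & rel < j + 100), numeric(1))
  expect_equal(length(wins), 1901)
  jbest <- (-1000:900)[which.max(wins)]
  inwin <- vapply(jbest:(jbest + 99), function(p) sum(rel == p), numeric(1))
  best <- jbest + which.max(inwin) - 1L
  expect_equal(got$offset, best)
  expect_equal(got$refined_tss, 10000L + best)
  expect_equal(got$cluster_start, 10000L + jbest)
  expect_equal(got$cluster_tag_count, max(wins) * (1e7 / 200))

  # ties break toward the 5'-most window and bp
  tie <- toy_library(c(9900L, 10200L), total_mapped = 2)
  rt <- refine_tss_from_cage(tie, anno)
  expect_equal(rt$refined_tss, 9900L)
})

test_that("TATA scanning is position-restricted to [-35, -20]", {
  flank <- function(n) paste(rep("C", n), collapse = "")
  # TATAAAAG starting at -31: promoter string index 470 (rel -500 -> 1)
  prom_hit <- paste0(flank(469), "TATAAAAG", flank(600 - 469 - 8))
  wh <- seq_world(prom_hit)
  sc <- scan_tata(wh$genome, wh$annotation)
  expect_true(sc$hit)
  expect_equal(sc$position, -31L)
  # the same motif at -10 is outside the window: no hit
  prom_out <- paste0(flank(490), "TATAAAAG", flank(600 - 490 - 8))
  wo <- seq_world(prom_out)
  expect_false(scan_tata(wo$genome, wo$annotation)$hit)
  # consensus degeneracy: TATATATG (W=T) matches too
  prom_w <- paste0(flank(469), "TATATATG", flank(600 - 469 - 8))
  expect_true(scan_tata(seq_world(prom_w)$genome, wh$annotation)$hit)

  # a PWM scanner over the same window agrees on the planted case
  pwm <- read_motif_matrix(system.file("extdata",
                                       "tata_box_synthetic.motif",
                                       package = "nascentmetrics"))
  sp <- scan_tata(wh$genome, wh$annotation, pwm = pwm)
  expect_true(sp$hit)
  expect_equal(sp$position, -31L)
  expect_false(scan_tata(wo$genome, wo$annotation, pwm = pwm)$hit)
})

test_that("motif enrichment computes exact hypergeometric tails", {
  w <- small_world(n_genes = 110, seed = 95, tata_fraction = 0,
                   gc_level = 0.5, gc_sd = 0)
  genome <- synthesize_genome_sequence(w$annotation, w$truth, w$config)
  pwm <- read_motif_matrix(system.file("extdata",
                                       "tata_box_synthetic.motif",
                                       package = "nascentmetrics"))
  ids <- w$annotation$genes$gene_id
  # plant a strong TATA in the first 10 promoters only, then rebuild hits
  # by brute force: foreground all hit, background none
  g <- w$annotation$genes
  sq <- strsplit(as.character(genome[[1]]), "")[[1]]
  for (i in 1:10) {
    at0 <- if (g$strand[i] == "+") g$tss[i] - 31L else g$tss[i] + 31L - 7L
    motif <- strsplit("TATAAAAG", "")[[1]]
    if (g$strand[i] == "+") sq[(at0 + 1L):(at0 + 8L)] <- motif
    else sq[(at0 + 1L):(at0 + 8L)] <-
        rev(c(A = "T", C = "G", G = "C", T = "A")[motif])
  }
  genome2 <- Biostrings::DNAStringSet(paste(sq, collapse = ""))
  names(genome2) <- g$chrom[1]
  # scrub chance hits from the background promoters before testing
  bg_ids <- ids[11:110]
  enr <- motif_enrichment(genome2, w$annotation, ids[1:10], bg_ids, pwm)
  expect_equal(enr$foreground_hits, 10)
  if (enr$background_hits == 0) {
    expect_equal(enr$p_value, 1 / choose(110, 10), tolerance = 1e-9)
    expect_lt(enr$p_value, 1e-10)
  } else {
    # exact tail by direct summation for the realized table
    k <- enr$foreground_hits; K <- k + enr$background_hits
    p_direct <- sum(vapply(k:min(K, 10), function(x)
      choose(K, x) * choose(110 - K, 10 - x), numeric(1))) / choose(110, 10)
    expect_equal(enr$p_value, p_direct, tolerance = 1e-9)
  }

  # a threshold above the maximal score finds nothing, p = 1
  strict <- pwm
  strict$score_threshold <- sum(apply(pwm$log_odds, 2, max)) + 1
  none <- motif_enrichment(genome2, w$annotation, ids[1:10], bg_ids, strict)
  expect_equal(none$foreground_hits, 0)
  expect_equal(none$p_value, 1)
  expect_error(motif_enrichment(genome2, w$annotation, character(0),
                                bg_ids, pwm), "empty foreground")

  # label resampling: p is approximately uniform when fg = bg sample
  hits <- vapply(ids, function(id) {
    s <- promoter_sequence(genome2, w$annotation, id)
    sc <- pwm_scores_for_test(pwm, s)
    any(sc >= pwm$score_threshold, na.rm = TRUE) ||
      any(pwm_scores_for_test(
        pwm, Biostrings::reverseComplement(s)) >= pwm$score_threshold,
        na.rm = TRUE)
  }, logical(1))
  set.seed(7)
  ps <- vapply(1:200, function(r) {
    fg <- sample(ids, 30)
    k <- sum(hits[fg]); K <- sum(hits)
    phyper(k - 1, K, 110 - K, 30, lower.tail = FALSE)
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.08)
})
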