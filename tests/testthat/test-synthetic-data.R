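test_that("config invariants are enforced", {
  expect_error(sim_config(class_fractions = c(IE = 0.5, late = 0.5,
                                              other = 0.2)), "sum to 1")
  expect_error(sim_config(splicing_efficiency = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(elongation_efficiency = list(
    basal = -1, KLA_1h = 1)), ">= 0")
  expect_error(sim_config(read_length_rna = 0L), "positive")
  expect_error(sim_config(tss_offset_range = c(-990L, 990L)), "CAGE")
})

test_that("the world is seeded-deterministic, per operation", {
  run <- function() {
    cfg <- sim_config(n_genes = 8, library_size = 2e4, seed = 5)
    w <- build_annotation(cfg)
    list(w = w,
         genome = as.character(synthesize_genome_sequence(
           w$annotation, w$truth, cfg)),
         chip = simulate_chip_library(w$annotation, w$truth,
                                      "histone_bimodal", "basal", cfg)$tags,
         gro = simulate_gro_library(w$annotation, w$truth, "basal",
                                    cfg)$tags,
         rna = simulate_rna_library(w$annotation, w$truth, "basal",
                                    cfg)$tags,
         cage = simulate_cage_library(w$annotation, w$truth, cfg)$tags,
         expr = simulate_expression_table(w$truth, cfg))
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("degenerate class mixture labels every gene IE", {
  cfg <- sim_config(n_genes = 10,
                    class_fractions = c(IE = 1, late = 0, other = 0),
                    seed = 2)
  w <- build_annotation(cfg)
  expect_true(all(w$truth$kinetic_class == "IE"))
})

test_that("gene placement is pairwise non-overlapping (interval sweep)", {
  cfg <- sim_config(n_genes = 50, genome_length = 5e6, seed = 3)
  w <- build_annotation(cfg)
  g <- w$annotation$genes
  expect_equal(nrow(g), 50)
  for (i in seq_len(nrow(g) - 1L))
    for (j in seq(i + 1L, nrow(g)))
      expect_true(g$tx_end[i] <= g$tx_start[j] ||
                    g$tx_end[j] <= g$tx_start[i])
  # placement failure is loud and names the constraint
  expect_error(build_annotation(
    sim_config(n_genes = 50, genome_length = 1e5, seed = 3)),
    "cannot place 50 genes")
})

test_that("promoter GC and TATA planting are recovered from the sequence", {
  # degenerate composition: all-GC promoters (true TSS = annotated here)
  cfg1 <- sim_config(n_genes = 4, gc_level = 1.0, gc_sd = 0,
                     tata_fraction = 0, tss_offset_range = c(0L, 0L),
                     seed = 4)
  w1 <- build_annotation(cfg1)
  gen1 <- synthesize_genome_sequence(w1$annotation, w1$truth, cfg1)
  gc1 <- promoter_gc(gen1, w1$annotation)
  expect_equal(gc1$gc, rep(1, 4))

  # 100 genes at target 0.63: recompute GC by direct base counting
  cfg2 <- sim_config(n_genes = 100, gc_level = 0.63, gc_sd = 0,
                     tss_offset_range = c(0L, 0L), seed = 6)
  w2 <- build_annotation(cfg2)
  gen2 <- synthesize_genome_sequence(w2$annotation, w2$truth, cfg2)
  counted <- vapply(w2$annotation$genes$gene_id, function(id) {
    s <- strsplit(as.character(
      promoter_sequence(gen2, w2$annotation, id)), "")[[1]]
    mean(s %in% c("G", "C"))
  }, numeric(1))
  expect_true(mean(counted) > 0.60 && mean(counted) < 0.66)
  expect_true(all(abs(w2$truth$promoter_gc - counted) <= 0.03))

  # planted-motif round trip: scan agrees with the truth flag exactly
  hits <- scan_tata(gen2, w2$annotation)
  expect_identical(hits$hit, w2$truth$has_tata)
})

test_that("ChIP libraries have the specified shape and exact size", {
  w <- small_world(n_genes = 15, seed = 8,
                   background_fraction = 0, library_size = 1e5)
  cfg <- w$config
  expect_error(simulate_chip_library(w$annotation, w$truth, "h3k4",
                                     "basal", cfg), "unknown mark_spec")

  # count conservation is exact
  pol <- simulate_chip_library(w$annotation, w$truth, "polII_paused",
                               "basal", cfg)
  expect_equal(nrow(pol$tags), 1e5)
  expect_equal(pol$total_mapped, 1e5)

  # shifted aggregate profile: mode within one 25-bp bin of +40
  prof <- tss_profile(shift_tags(pol), w$annotation)
  mode_at <- prof$offset[which.max(prof$density)]
  expect_true(abs(mode_at + 12.5 - 40) <= 25)

  # bimodal histone mark, zero background: local minimum near -50
  his <- simulate_chip_library(w$annotation, w$truth, "histone_bimodal",
                               "basal", cfg)
  ph <- tss_profile(shift_tags(his), w$annotation)
  inner <- ph[ph$offset >= -300 & ph$offset < 200, ]
  nadir <- inner$offset[which.min(inner$density)]
  expect_true(abs(nadir + 12.5 - (-50)) <= 25)
})

test_that("GRO libraries encode the planted elongation efficiency", {
  # EE = 0: no gene-body tags at all (background and antisense off)
  w0 <- small_world(n_genes = 5, seed = 10, background_fraction = 0,
                    antisense_fraction = 0,
                    elongation_efficiency = list(basal = 0, KLA_1h = 0))
  gro0 <- simulate_gro_library(w0$annotation, w0$truth, "basal", w0$config)
  g <- w0$annotation$genes
  for (i in seq_len(nrow(g))) {
    b <- if (g$strand[i] == "+")
      c(g$tss[i] + 500L, g$tss[i] + 2499L) else
        c(g$tss[i] - 2499L, g$tss[i] - 500L)
    expect_equal(oracle_window_count(gro0, g$chrom[i], b[1], b[2],
                                     strand = g$strand[i]), 0L)
    # antisense weight 0: no opposite-strand tags anywhere near the gene
    opp <- if (g$strand[i] == "+") "-" else "+"
    expect_equal(oracle_window_count(gro0, g$chrom[i],
                                     g$tx_start[i] - 600L,
                                     g$tx_end[i] + 600L, strand = opp), 0L)
  }

  # EE = 1 at 1e4 sense reads: window-count estimate lands in [0.9, 1.1]
  w1 <- small_world(n_genes = 1, seed = 12, background_fraction = 0,
                    antisense_fraction = 0,
                    elongation_efficiency = list(basal = 1, KLA_1h = 1))
  gro1 <- simulate_gro_library(w1$annotation, w1$truth, "basal", w1$config,
                               sense_reads_per_gene = 1e4)
  g1 <- w1$annotation$genes
  pb <- if (g1$strand == "+") c(g1$tss - 25L, g1$tss + 174L) else
    c(g1$tss - 174L, g1$tss + 25L)
  bb <- if (g1$strand == "+") c(g1$tss + 500L, g1$tss + 2499L) else
    c(g1$tss - 2499L, g1$tss - 500L)
  np <- oracle_window_count(gro1, g1$chrom, pb[1], pb[2], g1$strand)
  nb <- oracle_window_count(gro1, g1$chrom, bb[1], bb[2], g1$strand)
  est <- (nb / 2000) / (np / 200)
  expect_true(est >= 0.9 && est <= 1.1)

  # genes too short for the body window are refused by name
  short <- gene_annotation(
    data.frame(gene_id = "tiny", chrom = "chrS", strand = "+",
               tx_start = 3000L, tx_end = 5000L),
    data.frame(gene_id = "tiny", start = c(3000L, 4000L),
               end = c(3400L, 4400L)))
  attr(short, "genome_length") <- 10000L
  truth <- w1$truth; truth$gene_id <- "tiny"
  expect_error(simulate_gro_library(short, truth, "basal", w1$config,
                                    sense_reads_per_gene = 100),
               "tiny")
})

test_that("RNA libraries encode the planted splicing efficiency", {
  # SE = 1: all reads mature, none with >= 7 intronic bases
  w1 <- small_world(n_genes = 5, seed = 14, splicing_efficiency = 1)
  rna1 <- simulate_rna_library(w1$annotation, w1$truth, "basal", w1$config,
                               reads_per_gene = 500)
  expect_true(all(rna1$tags$spliced))
  ei <- exon_intron_density(rna1, w1$annotation)
  expect_true(all(ei$intron_count == 0))

  # SE = 0: no junction-spanning (spliced) reads exist
  w0 <- small_world(n_genes = 5, seed = 14, splicing_efficiency = 0)
  rna0 <- simulate_rna_library(w0$annotation, w0$truth, "basal", w0$config,
                               reads_per_gene = 500)
  expect_equal(sum(rna0$tags$crosses_junction), 0)
  expect_equal(sum(rna0$tags$spliced), 0)

  # SE = 0.9 at 1e4 reads: independent per-tag recount recovers it
  w9 <- small_world(n_genes = 3, seed = 15, splicing_efficiency = 0.9)
  rna9 <- simulate_rna_library(w9$annotation, w9$truth, "basal", w9$config,
                               reads_per_gene = 1e4)
  for (id in w9$annotation$genes$gene_id) {
    cnt <- oracle_exon_intron(rna9, w9$annotation, id)
    ex <- w9$annotation$exons[w9$annotation$exons$gene_id == id, ]
    g <- w9$annotation$genes[w9$annotation$genes$gene_id == id, ]
    exlen <- sum(ex$end - ex$start)
    inlen <- (g$tx_end - g$tx_start) - exlen
    est <- 1 - (cnt["intron"] / inlen) / (cnt["exon"] / exlen)
    expect_true(abs(est - 0.9) <= 0.05)
  }
})

test_that("CAGE libraries concentrate at the planted TSS", {
  # zero dispersion, zero noise: every tag exactly at TSS + offset
  w <- small_world(n_genes = 10, seed = 16, cage_cluster_sd = 0,
                   cage_noise_fraction = 0)
  cage <- simulate_cage_library(w$annotation, w$truth, w$config,
                                tags_per_gene = 50)
  g <- w$annotation$genes
  for (i in seq_len(nrow(g))) {
    expected <- if (g$strand[i] == "+")
      g$tss[i] + w$truth$true_tss_offset[i] else
        g$tss[i] - w$truth$true_tss_offset[i]
    got <- cage$tags$pos[cage$tags$chrom == g$chrom[i] &
                           cage$tags$strand == g$strand[i]]
    got <- got[abs(got - expected) < 1500]
    expect_true(all(got == expected))
  }
  # noise-free round trip through refinement, planted offset -80
  wp <- small_world(n_genes = 6, seed = 17, cage_cluster_sd = 0,
                    cage_noise_fraction = 0,
                    tss_offset_range = c(-80L, -80L))
  cg <- simulate_cage_library(wp$annotation, wp$truth, wp$config,
                              tags_per_gene = 100)
  ref <- refine_tss_from_cage(cg, wp$annotation)
  gp <- wp$annotation$genes
  plus <- which(gp$strand == "+")
  expect_true(length(plus) > 0)
  expect_equal(ref$refined_tss[plus], gp$tss[plus] - 80L)
  expect_equal(ref$offset, rep(-80L, 6))
})

test_that("expression tables respect the kinetic rules and the noise guard", {
  w <- small_world(n_genes = 30, seed = 18)
  noiseless <- simulate_expression_table(w$truth, w$config, noise_sd = 0)
  cls <- classify_kinetics(noiseless)
  expect_equal(as.character(cls$kinetic_class), w$truth$kinetic_class)
  expect_error(simulate_expression_table(w$truth, w$config, noise_sd = 0.3),
               "too large")
})

test_that("annotation survives BED12 and GTF round trips", {
  w <- small_world(n_genes = 6, seed = 19)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed12(w$annotation, bed)
  back <- read_annotation_bed12(bed)
  expect_equal(back$genes[, c("gene_id", "chrom", "strand", "tx_start",
                              "tx_end", "tss")],
               w$annotation$genes[, c("gene_id", "chrom", "strand",
                                      "tx_start", "tx_end", "tss")])
  expect_equal(back$exons, w$annotation$exons, ignore_attr = TRUE)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(w$annotation, gtf)
  lines <- readLines(gtf)
  expect_equal(sum(grepl("\ttranscript\t", lines)), 6)
  # GTF is 1-based closed: starts shifted by +1 relative to BED
  first_exon <- strsplit(grep("\texon\t", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(first_exon[4]),
               w$annotation$exons$start[1] + 1L)
})
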