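#' Synthetic-world configuration
#'
#' Collects every parameter of the synthetic genome, annotation, tag
#' libraries and expression tables. Defaults encode the observed promoter
#' architecture the analysis assumes: a paused-polymerase peak at +40 bp, a
#' bimodal histone-mark profile with a nadir at -50 bp, 25-bp ChIP tags and
#' 32-bp RNA/GRO tags, immediate/early promoters with elevated GC and a
#' ~38% TATA-box fraction versus ~11% on late promoters. Distributional
#' shapes (Gaussian peaks, uniform gene bodies and background) are
#' analytically tractable stand-ins, not measured quantities.
#'
#' @param n_genes Number of genes.
#' @param genome_length Genome length in bp; `NULL` sizes the contig to fit.
#' @param gene_length_range,gene_exon_range,exon_length_range,
#'   intergenic_gap_range Integer ranges (bp or counts) for gene structure.
#' @param class_fractions Named proportions over `IE`, `late`, `other`.
#' @param pause_peak_center,pause_peak_sd Paused-polymerase peak (bp).
#' @param histone_nadir,histone_peak_halfdist,histone_peak_sd Bimodal
#'   histone profile: peaks at `nadir +/- halfdist`.
#' @param tf_peak_sd Point-source factor peak width.
#' @param elongation_efficiency List with `basal` and `KLA_1h` entries; each
#'   either a class-named vector, a single value, a length-2 unnamed range
#'   (per-gene log-uniform draw) or a per-gene vector.
#' @param splicing_efficiency Same resolution rules; fractions in `[0, 1]`.
#' @param tss_offset_range True-TSS offset range (bp from annotated TSS).
#' @param cage_cluster_sd,cage_noise_fraction CAGE cluster dispersion (bp)
#'   and uniform-noise share within the +/-1 kb window.
#' @param gc_level,gc_sd Class promoter GC means and per-gene spread.
#' @param tata_fraction Class fractions of promoters with a planted TATA.
#' @param background_fraction Uniform genomic background share of ChIP/GRO
#'   library mass.
#' @param antisense_fraction Divergent (antisense, upstream) share of each
#'   gene's GRO reads.
#' @param library_size Reads per simulated library.
#' @param read_length_chip,read_length_rna Read lengths (bp).
#' @param fragment_length True ChIP fragment length, stored in library
#'   metadata so the downstream half-fragment shift is exact.
#' @param polII_ie_basal,chip_kla_ie_boost Relative ChIP amplitudes: basal
#'   paused-polymerase excess on IE promoters, and the IE gain after
#'   stimulation.
#' @param expr_base_meanlog,expr_base_sdlog Lognormal basal expression.
#' @param expr_noise_sd Multiplicative lognormal noise sd (log scale) on
#'   every expression value.
#' @param fc_ranges Per-class fold-change draw ranges (log-uniform), chosen
#'   so labels survive `expr_noise_sd` with wide margins.
#' @param contig_name Name of the single simulated contig.
#' @param seed Integer master seed; every `simulate_*` operation derives a
#'   fixed per-operation seed from it, so identical configs give
#'   byte-identical outputs.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 300L,
                       genome_length = NULL,
                       gene_length_range = c(4000L, 10000L),
                       gene_exon_range = c(2L, 6L),
                       exon_length_range = c(150L, 400L),
                       intergenic_gap_range = c(1200L, 3000L),
                       class_fractions = c(IE = 0.15, late = 0.15,
                                           other = 0.70),
                       pause_peak_center = 40L, pause_peak_sd = 50,
                       histone_nadir = -50L, histone_peak_halfdist = 300L,
                       histone_peak_sd = 150, tf_peak_sd = 50,
                       elongation_efficiency = list(
                         basal = c(IE = 0.1, late = 0.3, other = 0.5),
                         KLA_1h = c(IE = 1.0, late = 0.3, other = 0.5)),
                       splicing_efficiency = 0.9,
                       tss_offset_range = c(-80L, 80L),
                       cage_cluster_sd = 2, cage_noise_fraction = 0.1,
                       gc_level = c(IE = 0.60, late = 0.50, other = 0.50),
                       gc_sd = 0.10,
                       tata_fraction = c(IE = 0.38, late = 0.11,
                                         other = 0.20),
                       background_fraction = 0.05,
                       antisense_fraction = 0.10,
                       library_size = 1e6,
                       read_length_chip = 25L, read_length_rna = 32L,
                       fragment_length = 200L,
                       polII_ie_basal = 3, chip_kla_ie_boost = 2,
                       expr_base_meanlog = log(20), expr_base_sdlog = 0.5,
                       expr_noise_sd = 0.05,
                       fc_ranges = list(IE_1h = c(4.5, 30),
                                        IE_12h = c(3, 30),
                                        late_1h = c(0.70, 0.84),
                                        late_12h = c(6, 30),
                                        other_1h = c(1.7, 2.1),
                                        other_12h = c(0.8, 3)),
                       contig_name = "chrS",
                       seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0))
    stop("class_fractions must be non-negative and sum to 1")
  if (!all(c("IE", "late", "other") %in% names(class_fractions)))
    stop("class_fractions must be named IE, late, other")
  chk_eff <- function(x) {
    v <- unlist(x)
    if (any(!is.finite(v)) || any(v < 0))
      stop("efficiencies must be finite and >= 0")
  }
  chk_eff(elongation_efficiency)
  se <- unlist(splicing_efficiency)
  if (any(se < 0 | se > 1)) stop("splicing efficiencies must lie in [0, 1]")
  if (read_length_chip <= 0L || read_length_rna <= 0L)
    stop("read lengths must be positive")
  if (max(abs(tss_offset_range)) > 1000L - 50L)
    stop("tss_offset_range must stay within +/-(1000 - 50) bp so the CAGE ",
         "cluster fits the search window")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  if (fc_ranges$IE_1h[1] <= 3 || fc_ranges$late_1h[2] >= 1.2 ||
      fc_ranges$late_12h[1] <= 4 ||
      fc_ranges$other_1h[1] <= 1.2 || fc_ranges$other_1h[2] >= 3)
    stop("fc_ranges must respect the kinetic classification boundaries")
  structure(cfg, class = "SimConfig")
}

# fixed per-operation seed so every simulate_* call is independently
# reproducible from one master seed
op_seed <- function(config, key) {
  (config$seed + sum(utf8ToInt(key))) %% .Machine$integer.max
}

# resolve a class map / scalar / range / per-gene vector to one value per gene
resolve_per_gene <- function(x, classes, log_uniform = TRUE) {
  n <- length(classes)
  if (!is.null(names(x)) && all(names(x) %in% c("IE", "late", "other"))) {
    if (!all(classes %in% names(x)))
      stop("per-class parameter lacks entries for some classes")
    return(unname(unlist(x)[classes]))
  }
  x <- unlist(x)
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) == 2L) {
    if (log_uniform && all(x > 0))
      return(exp(runif(n, log(x[1]), log(x[2]))))
    return(runif(n, x[1], x[2]))
  }
  if (length(x) == n) return(as.numeric(x))
  stop("parameter must be a class map, scalar, range, or per-gene vector")
}

#' Build a synthetic annotation with a planted-truth table
#'
#' Places `n_genes` non-overlapping multi-exon genes on both strands of one
#' contig, separated by intergenic gaps wide enough that promoter windows
#' never collide, and draws every planted per-gene parameter: kinetic
#' class, per-condition elongation efficiency, splicing efficiency, true
#' TSS offset, promoter GC, TATA flag, and a latent noiseless expression
#' triplet consistent with the class under the kinetic classification
#' rules. Deterministic for a fixed config (including seed).
#'
#' @param config A [sim_config()].
#' @return list with `annotation` (a [gene_annotation()], carrying the
#'   realized genome length as attribute `genome_length`), `truth`
#'   (one row per gene), and `genome_length`.
#' @export
build_annotation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(op_seed(config, "annotation"))
  n <- config$n_genes
  cf <- config$class_fractions[c("IE", "late", "other")]
  counts <- floor(cf * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(cf * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  classes <- sample(rep(names(counts), counts))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  min_intron <- 200L
  glr <- config$gene_length_range
  ker <- config$gene_exon_range
  elr <- config$exon_length_range
  structures <- lapply(seq_len(n), function(i) {
    L <- sample(seq(glr[1], glr[2]), 1L)
    k <- if (ker[1] == ker[2]) ker[1] else sample(seq(ker[1], ker[2]), 1L)
    repeat {
      ex_len <- sample(seq(elr[1], elr[2]), k, replace = TRUE)
      budget <- L - sum(ex_len)
      if (budget >= min_intron * (k - 1L)) break
      if (k > 2L) k <- k - 1L
      else stop("cannot fit ", k, " exons of ", elr[1], "-", elr[2],
                " bp plus ", min_intron, "-bp introns into a ", L,
                " bp gene; widen gene_length_range")
    }
    if (k > 1L) {
      wts <- runif(k - 1L)
      spare <- budget - min_intron * (k - 1L)
      in_len <- min_intron + floor(wts / sum(wts) * spare)
      in_len[1L] <- in_len[1L] + (budget - sum(in_len))
    } else in_len <- integer(0)
    list(exon_len = ex_len, intron_len = in_len, L = L)
  })
  lens <- vapply(structures, `[[`, numeric(1), "L")
  gaps <- sample(seq(config$intergenic_gap_range[1],
                     config$intergenic_gap_range[2]), n + 1L, replace = TRUE)
  margin <- 2500L
  needed <- 2L * margin + sum(lens) + sum(gaps)
  gl <- config$genome_length
  if (is.null(gl)) gl <- as.integer(needed)
  if (gl < needed)
    stop("cannot place ", n, " genes: genome_length ", gl,
         " < required ", needed, " bp (gene spans + intergenic gaps)")
  extra <- gl - needed
  if (extra > 0)
    gaps <- gaps + drop(rmultinom(1L, extra, rep(1, n + 1L)))
  # sequential layout: margin, gap1, gene1, gap2, gene2, ..., gap(n+1), margin
  tx_start <- margin + cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens[-n]))
  tx_end <- tx_start + lens

  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                      chrom = config$contig_name, strand = strand,
                      tx_start = as.integer(tx_start),
                      tx_end = as.integer(tx_end))
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- structures[[i]]
    k <- length(st$exon_len)
    starts <- tx_start[i] +
      c(0, cumsum(st$exon_len[-k] + st$intron_len))[seq_len(k)]
    data.frame(gene_id = genes$gene_id[i], start = as.integer(starts),
               end = as.integer(starts + st$exon_len))
  }))
  annotation <- gene_annotation(genes, exons)
  attr(annotation, "genome_length") <- gl

  ee_b <- resolve_per_gene(config$elongation_efficiency$basal, classes)
  ee_k <- resolve_per_gene(config$elongation_efficiency$KLA_1h, classes)
  sp <- resolve_per_gene(config$splicing_efficiency, classes,
                         log_uniform = FALSE)
  tor <- config$tss_offset_range
  offs <- if (tor[1] == tor[2]) rep(tor[1], n) else
    sample(seq(tor[1], tor[2]), n, replace = TRUE)
  gc_mean <- resolve_per_gene(config$gc_level, classes, log_uniform = FALSE)
  gc <- pmin(1, pmax(0, rnorm(n, gc_mean, config$gc_sd)))
  tata <- runif(n) < resolve_per_gene(config$tata_fraction, classes,
                                      log_uniform = FALSE)
  e0 <- rlnorm(n, config$expr_base_meanlog, config$expr_base_sdlog)
  fr <- config$fc_ranges
  draw_fc <- function(rng, m) exp(runif(m, log(rng[1]), log(rng[2])))
  fc1 <- numeric(n); fc12 <- numeric(n)
  for (cl in c("IE", "late", "other")) {
    j <- classes == cl
    fc1[j] <- draw_fc(fr[[paste0(cl, "_1h")]], sum(j))
    fc12[j] <- draw_fc(fr[[paste0(cl, "_12h")]], sum(j))
  }
  truth <- data.frame(gene_id = genes$gene_id, kinetic_class = classes,
                      true_ee_basal = ee_b, true_ee_kla = ee_k,
                      true_splicing_efficiency = sp,
                      true_tss_offset = as.integer(offs),
                      promoter_gc = gc, has_tata = tata,
                      expr_0h = e0, expr_1h = e0 * fc1, expr_12h = e0 * fc12)
  list(annotation = annotation, truth = truth, genome_length = gl)
}

#' Synthesize the genome sequence
#'
#' I.i.d. uniform A/C/G/T background; each gene's promoter window
#' `[-500, +100)` (gene-oriented) is rebuilt with exactly
#' `round(gc * 600)` G/C bases so the realized GC matches the planted value
#' to within one base in 600. Genes flagged `has_tata` get the motif
#' `TATAAAAG` planted at a start position in `[-35, -20]`; promoters
#' without the flag are scrubbed of any chance `TATAWAWR` match in that
#' window, so the planted TATA fraction is recovered exactly by a
#' noise-free positional scan. All sequence features are anchored at the
#' TRUE TSS (annotated TSS plus the planted offset) -- core-promoter
#' elements sit where transcription actually starts, which is what makes
#' CAGE-based TSS refinement worthwhile before sequence analysis.
#'
#' @param annotation,truth From [build_annotation()].
#' @param config The same [sim_config()].
#' @return A [Biostrings::DNAStringSet] with one contig.
#' @export
synthesize_genome_sequence <- function(annotation, truth, config) {
  set.seed(op_seed(config, "genome"))
  gl <- attr(annotation, "genome_length")
  if (is.null(gl)) stop("annotation lacks a genome_length attribute")
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, gl, replace = TRUE)
  g <- annotation$genes
  if (!all(truth$gene_id == g$gene_id))
    stop("annotation and truth are not aligned by gene_id")
  win <- c(-500L, 100L)
  wlen <- win[2] - win[1]
  tata_win <- c(-35L, -20L)
  motif <- "TATAAAAG"
  mchars <- strsplit(motif, "")[[1]]
  consensus_re <- "TATA[AT]A[AT][AG]"
  for (i in seq_len(nrow(g))) {
    ngc <- round(truth$promoter_gc[i] * wlen)
    prom <- character(wlen)
    gc_at <- sample.int(wlen, ngc)
    prom[gc_at] <- sample(c("G", "C"), ngc, replace = TRUE)
    prom[-gc_at] <- sample(c("A", "T"), wlen - ngc, replace = TRUE)
    if (ngc == 0L) prom <- sample(c("A", "T"), wlen, replace = TRUE)
    if (ngc == wlen) prom <- sample(c("G", "C"), wlen, replace = TRUE)
    if (truth$has_tata[i]) {
      start_rel <- sample(seq(tata_win[1], tata_win[2]), 1L)
      at <- start_rel - win[1] + 1L
      prom[at:(at + length(mchars) - 1L)] <- mchars
    } else {
      # remove chance consensus hits whose start falls in the scan window
      reg_from <- tata_win[1] - win[1] + 1L
      reg_to <- tata_win[2] - win[1] + nchar(motif)
      for (pass in 1:10) {
        s <- paste(prom[reg_from:reg_to], collapse = "")
        m <- regexpr(consensus_re, s)
        if (m < 0) break
        prom[reg_from + m] <- "C"   # break the motif at its second base
      }
    }
    # place the gene-oriented promoter onto the genome, anchored at the
    # true TSS (annotated + planted offset): core-promoter elements sit
    # where transcription actually starts, which is what makes CAGE-based
    # refinement worthwhile before sequence analysis
    true_tss <- oriented_pos(g$tss[i], g$strand[i],
                             truth$true_tss_offset[i])
    if (g$strand[i] == "+") {
      at0 <- true_tss + win[1]            # 0-based genomic start
      if (at0 < 0L || at0 + wlen > gl)
        stop("promoter window of ", g$gene_id[i], " extends past contig")
      genome[(at0 + 1L):(at0 + wlen)] <- prom
    } else {
      at0 <- true_tss - win[2] + 1L
      if (at0 < 0L || at0 + wlen > gl)
        stop("promoter window of ", g$gene_id[i], " extends past contig")
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      genome[(at0 + 1L):(at0 + wlen)] <- rev(unname(comp[prom]))
    }
  }
  out <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(out) <- config$contig_name
  out
}

# allocate signal reads across genes (multinomial over weights)
allocate_reads <- function(n_total, weights) {
  if (n_total <= 0) return(integer(length(weights)))
  drop(rmultinom(1L, n_total, weights))
}

# split a per-gene allocation off the configured library size
split_background <- function(config, library_size = config$library_size) {
  n_bg <- round(config$background_fraction * library_size)
  c(signal = library_size - n_bg, background = n_bg)
}

#' Simulate a ChIP tag library
#'
#' Tags are 5' ends of fragments whose centers are drawn from a
#' mark-specific mixture around each TSS plus a uniform genomic background:
#' `histone_bimodal` (two Gaussians at `nadir +/- halfdist`),
#' `polII_paused` (one Gaussian at the pause peak center, amplified on IE
#' promoters), or `tf_point` (one Gaussian at the TSS). Fragment 5' ends
#' sit half a fragment upstream of the center on each strand, so after
#' [shift_tags()] the density mode returns to the specified center.
#' The emitted tag count equals the configured library size exactly.
#'
#' @param annotation,truth From [build_annotation()].
#' @param mark_spec One of `"histone_bimodal"`, `"polII_paused"`,
#'   `"tf_point"`.
#' @param condition `"basal"` or `"KLA_1h"`.
#' @param config A [sim_config()].
#' @param reads_per_gene Optional exact per-gene signal tag counts
#'   (background is then added on top at the configured fraction).
#' @return An unshifted, unstranded [tag_library()].
#' @export
simulate_chip_library <- function(annotation, truth, mark_spec,
                                  condition = "basal", config,
                                  reads_per_gene = NULL) {
  marks <- c("histone_bimodal", "polII_paused", "tf_point")
  if (!mark_spec %in% marks)
    stop("unknown mark_spec '", mark_spec, "'; expected one of: ",
         paste(marks, collapse = ", "))
  if (!condition %in% c("basal", "KLA_1h"))
    stop("unknown condition '", condition, "'")
  set.seed(op_seed(config, paste("chip", mark_spec, condition)))
  g <- annotation$genes
  gl <- attr(annotation, "genome_length")
  n <- nrow(g)
  amp <- rep(1, n)
  if (mark_spec == "polII_paused")
    amp[truth$kinetic_class == "IE"] <- config$polII_ie_basal
  if (condition == "KLA_1h")
    amp[truth$kinetic_class == "IE"] <-
      amp[truth$kinetic_class == "IE"] * config$chip_kla_ie_boost
  if (is.null(reads_per_gene)) {
    parts <- split_background(config)
    n_i <- allocate_reads(parts["signal"], amp)
    n_bg <- parts["background"]
  } else {
    n_i <- rep_len(reads_per_gene, n)
    bf <- config$background_fraction
    n_bg <- round(bf / (1 - bf) * sum(n_i))
  }
  half <- config$fragment_length %/% 2L
  draw_rel <- switch(mark_spec,
    histone_bimodal = function(m)
      config$histone_nadir +
        sample(c(-1, 1), m, replace = TRUE) * config$histone_peak_halfdist +
        rnorm(m, 0, config$histone_peak_sd),
    polII_paused = function(m)
      rnorm(m, config$pause_peak_center, config$pause_peak_sd),
    tf_point = function(m) rnorm(m, 0, config$tf_peak_sd))
  tabs <- lapply(seq_len(n), function(i) {
    m <- n_i[i]
    if (m == 0L) return(NULL)
    centers <- round(oriented_pos(g$tss[i], g$strand[i], draw_rel(m)))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    pos <- ifelse(strand == "+", centers - half, centers + half)
    data.frame(chrom = g$chrom[i],
               pos = pmin.int(pmax.int(pos, 0L), gl - 1L), strand = strand)
  })
  if (n_bg > 0L) {
    centers <- sample.int(gl, n_bg, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    pos <- ifelse(strand == "+", centers - half, centers + half)
    tabs <- c(tabs, list(data.frame(chrom = config$contig_name,
                                    pos = pmin.int(pmax.int(pos, 0L),
                                                   gl - 1L),
                                    strand = strand)))
  }
  tags <- do.call(rbind, tabs)
  tag_library(tags, read_length = config$read_length_chip,
              fragment_length = config$fragment_length, stranded = FALSE)
}

#' Simulate a stranded GRO-Seq library
#'
#' Sense-strand reads per gene mix a promoter-proximal component (uniform
#' over the gene-oriented window `[-25, +175)`) and a gene-body component
#' (uniform over `[+500, +2500)`), with mixture weights chosen so the
#' expected body/promoter window-density ratio equals the planted
#' elongation efficiency for the requested condition. A divergent
#' antisense component (uniform over `[-500, -50)` on the opposite strand)
#' and a uniform genomic background are added at their configured
#' fractions.
#'
#' @param annotation,truth From [build_annotation()].
#' @param condition `"basal"` or `"KLA_1h"`; selects the planted efficiency
#'   and the expression values that weight read allocation.
#' @param config A [sim_config()].
#' @param sense_reads_per_gene Optional exact per-gene sense read counts
#'   (antisense and background are added at configured fractions).
#' @return A stranded [tag_library()] of 5'-end tags.
#' @export
simulate_gro_library <- function(annotation, truth, condition = "basal",
                                 config, sense_reads_per_gene = NULL) {
  if (!condition %in% c("basal", "KLA_1h"))
    stop("unknown condition '", condition, "'")
  set.seed(op_seed(config, paste("gro", condition)))
  g <- annotation$genes
  gl <- attr(annotation, "genome_length")
  n <- nrow(g)
  ee <- if (condition == "basal") truth$true_ee_basal else truth$true_ee_kla
  pw <- c(-25L, 175L)
  bw <- c(500L, 2500L)
  plen <- diff(pw)
  blen <- diff(bw)
  if (is.null(sense_reads_per_gene)) {
    parts <- split_background(config)
    expr <- if (condition == "basal") truth$expr_0h else truth$expr_1h
    wts <- expr * (g$tx_end - g$tx_start) / 1000
    n_i <- allocate_reads(parts["signal"], wts)
    n_as <- rbinom(n, n_i, config$antisense_fraction)
    n_sense <- n_i - n_as
    n_bg <- parts["background"]
  } else {
    n_sense <- rep_len(sense_reads_per_gene, n)
    n_as <- round(config$antisense_fraction * n_sense)
    bf <- config$background_fraction
    n_bg <- round(bf / (1 - bf) * sum(n_sense + n_as))
  }
  short <- which(n_sense > 0L & ee > 0 & (g$tx_end - g$tx_start) < bw[2])
  if (length(short) > 0L)
    stop("gene body window [+", bw[1], ",+", bw[2], ") requested for ",
         "gene(s) shorter than ", bw[2], " bp: ",
         paste(g$gene_id[short], collapse = ", "))
  tabs <- lapply(seq_len(n), function(i) {
    out <- NULL
    if (n_sense[i] > 0L) {
      r <- ee[i] * blen / plen
      p_body <- r / (1 + r)
      nb <- rbinom(1L, n_sense[i], p_body)
      rel <- c(bw[1] + sample.int(blen, nb, replace = TRUE) - 1L,
               pw[1] + sample.int(plen, n_sense[i] - nb, replace = TRUE) - 1L)
      out <- data.frame(chrom = g$chrom[i],
                        pos = oriented_pos(g$tss[i], g$strand[i], rel),
                        strand = g$strand[i])
    }
    if (n_as[i] > 0L) {
      rel <- -500L + sample.int(450L, n_as[i], replace = TRUE) - 1L
      out <- rbind(out, data.frame(
        chrom = g$chrom[i],
        pos = oriented_pos(g$tss[i], g$strand[i], rel),
        strand = if (g$strand[i] == "+") "-" else "+"))
    }
    out
  })
  if (n_bg > 0L)
    tabs <- c(tabs, list(data.frame(
      chrom = config$contig_name,
      pos = sample.int(gl, n_bg, replace = TRUE) - 1L,
      strand = sample(c("+", "-"), n_bg, replace = TRUE))))
  tags <- do.call(rbind, tabs)
  tags$pos <- pmin.int(pmax.int(tags$pos, 0L), gl - 1L)
  tag_library(tags, read_length = config$read_length_rna,
              stranded = TRUE)
}

# map spliced-transcript indices (0-based, transcription order) to genomic
# positions for one gene; exons in transcription order
spliced_to_genomic <- function(ex, strand, idx) {
  len <- ex$end - ex$start
  cum <- c(0L, cumsum(len))
  j <- findInterval(idx, cum, rightmost.closed = FALSE)  # exon number
  within <- idx - cum[j]
  if (strand == "+") ex$start[j] + within else ex$end[j] - 1L - within
}

#' Simulate a stranded total-RNA tag library
#'
#' Reads are drawn from mature (spliced) and unspliced (genomic-contiguous)
#' templates. The planted splicing efficiency is the molar fraction of
#' spliced transcripts, so templates are chosen with probability
#' proportional to `SE x (mature length)` versus `(1 - SE) x (genomic
#' length)`; per-bp tag density is then `SE`-weighted in exons and
#' `(1 - SE)`-weighted in introns, which is exactly what both downstream
#' splicing estimators measure. Each read records its genomic 5' end,
#' strand, genomic 3'-end position (`end3`), whether it is from the
#' spliced template (`spliced`), whether it spans an exon-exon junction
#' (`crosses_junction`), and the junction-relative 3'-end offset (`j3off`,
#' spliced bp past the last crossed junction).
#'
#' @param annotation,truth From [build_annotation()]; genes need >= 1
#'   intron.
#' @param condition `"basal"` or `"KLA_1h"` (weights read allocation).
#' @param config A [sim_config()].
#' @param reads_per_gene Optional exact per-gene read counts.
#' @return A stranded 32-bp [tag_library()] with the extra columns above.
#' @export
simulate_rna_library <- function(annotation, truth, condition = "basal",
                                 config, reads_per_gene = NULL) {
  set.seed(op_seed(config, paste("rna", condition)))
  g <- annotation$genes
  n <- nrow(g)
  L <- config$read_length_rna
  if (is.null(reads_per_gene)) {
    expr <- if (condition == "basal") truth$expr_0h else truth$expr_1h
    wts <- expr * (g$tx_end - g$tx_start) / 1000
    n_i <- allocate_reads(config$library_size, wts)
  } else n_i <- rep_len(reads_per_gene, n)
  tabs <- lapply(seq_len(n), function(i) {
    m <- n_i[i]
    if (m == 0L) return(NULL)
    ex <- gene_exons(annotation, g$gene_id[i])
    E <- sum(ex$end - ex$start)
    G <- g$tx_end[i] - g$tx_start[i]
    if (E < L) stop("mature transcript of ", g$gene_id[i],
                    " is shorter than the read length")
    s <- truth$true_splicing_efficiency[i]
    Evs <- E - L + 1L
    Gvs <- G - L + 1L
    p_m <- s * Evs / (s * Evs + (1 - s) * Gvs)
    n_m <- rbinom(1L, m, p_m)
    rows <- NULL
    if (n_m > 0L) {
      t0 <- sample.int(Evs, n_m, replace = TRUE) - 1L
      t3 <- t0 + L - 1L
      p5 <- spliced_to_genomic(ex, g$strand[i], t0)
      p3 <- spliced_to_genomic(ex, g$strand[i], t3)
      cum <- c(0L, cumsum(ex$end - ex$start))
      e5 <- findInterval(t0, cum)       # exon holding each end
      e3 <- findInterval(t3, cum)
      crosses <- e3 > e5
      # spliced bp past the last crossed junction (= start of exon e3)
      j3 <- ifelse(crosses, t3 - cum[e3] + 1L, NA_integer_)
      rows <- data.frame(chrom = g$chrom[i], pos = p5,
                         strand = g$strand[i], end3 = p3,
                         spliced = TRUE, crosses_junction = crosses,
                         j3off = j3)
    }
    if (m - n_m > 0L) {
      u0 <- sample.int(Gvs, m - n_m, replace = TRUE) - 1L
      p5 <- if (g$strand[i] == "+") g$tx_start[i] + u0 else
        g$tx_end[i] - 1L - u0
      p3 <- if (g$strand[i] == "+") p5 + L - 1L else p5 - L + 1L
      rows <- rbind(rows, data.frame(chrom = g$chrom[i], pos = p5,
                                     strand = g$strand[i], end3 = p3,
                                     spliced = FALSE,
                                     crosses_junction = FALSE,
                                     j3off = NA_integer_))
    }
    rows
  })
  tags <- do.call(rbind, tabs)
  if (is.null(tags))
    tags <- data.frame(chrom = character(0), pos = integer(0),
                       strand = character(0), end3 = integer(0),
                       spliced = logical(0), crosses_junction = logical(0),
                       j3off = integer(0))
  tag_library(tags, read_length = L, stranded = TRUE)
}

#' Simulate a stranded CAGE tag library
#'
#' CAGE 5' ends concentrate at the planted true TSS (annotated TSS plus the
#' gene-oriented offset) with Gaussian dispersion, plus uniform noise
#' within the +/-1 kb search window. With zero dispersion and zero noise
#' every tag sits exactly at the true TSS.
#'
#' @param annotation,truth From [build_annotation()].
#' @param config A [sim_config()].
#' @param tags_per_gene Optional exact per-gene tag counts (scalar or
#'   vector); default splits `library_size` evenly.
#' @return A stranded [tag_library()].
#' @export
simulate_cage_library <- function(annotation, truth, config,
                                  tags_per_gene = NULL) {
  set.seed(op_seed(config, "cage"))
  g <- annotation$genes
  n <- nrow(g)
  n_i <- if (is.null(tags_per_gene))
    allocate_reads(config$library_size, rep(1, n)) else
      rep_len(tags_per_gene, n)
  tabs <- lapply(seq_len(n), function(i) {
    m <- n_i[i]
    if (m == 0L) return(NULL)
    n_noise <- round(config$cage_noise_fraction * m)
    n_cl <- m - n_noise
    rel <- c(truth$true_tss_offset[i] +
               round(rnorm(n_cl, 0, config$cage_cluster_sd)),
             if (n_noise > 0L)
               sample(seq(-1000L, 999L), n_noise, replace = TRUE))
    rel <- pmin.int(pmax.int(rel, -1000L), 999L)
    data.frame(chrom = g$chrom[i],
               pos = oriented_pos(g$tss[i], g$strand[i], rel),
               strand = g$strand[i])
  })
  tags <- do.call(rbind, tabs)
  tag_library(tags, read_length = config$read_length_chip, stranded = TRUE)
}

#' Simulate a three-timepoint expression table
#'
#' Applies multiplicative lognormal noise to the latent noiseless
#' expression triplets drawn by [build_annotation()]. The per-class
#' fold-change ranges leave wide log margins to every classification
#' boundary; the generator refuses noise levels at which those margins
#' shrink below four standard deviations of a fold-change estimate, so
#' class labels survive the noise.
#'
#' @param truth From [build_annotation()].
#' @param config A [sim_config()].
#' @param noise_sd Override for `config$expr_noise_sd`.
#' @return data.frame with `gene_id`, `expr_0h`, `expr_1h`, `expr_12h`.
#' @export
simulate_expression_table <- function(truth, config,
                                      noise_sd = config$expr_noise_sd) {
  set.seed(op_seed(config, "expression"))
  fr <- config$fc_ranges
  margin <- min(log(fr$IE_1h[1] / 3), log(1.2 / fr$late_1h[2]),
                log(fr$late_12h[1] / 4), log(fr$other_1h[1] / 1.2),
                log(3 / fr$other_1h[2]))
  if (noise_sd * sqrt(2) * 4 > margin)
    stop("expression noise sd ", noise_sd, " is too large to guarantee ",
         "kinetic class labels (log margin ", signif(margin, 3),
         " < 4 sd of a fold change)")
  n <- nrow(truth)
  jitter <- function(x) x * exp(rnorm(n, 0, noise_sd))
  data.frame(gene_id = truth$gene_id,
             expr_0h = jitter(truth$expr_0h),
             expr_1h = jitter(truth$expr_1h),
             expr_12h = jitter(truth$expr_12h))
}
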