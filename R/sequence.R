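#' Extract a gene-oriented promoter sequence
#'
#' Returns the sequence of the gene-oriented window `[from, to)` around the
#' TSS (reverse-complemented for minus-strand genes), so that character `i`
#' of the result sits at offset `from + i - 1`.
#'
#' @param genome A [Biostrings::DNAStringSet] named by contig.
#' @param annotation A [gene_annotation()].
#' @param gene_id Single gene id.
#' @param from,to Gene-oriented half-open window in bp relative to the TSS.
#' @param tss Optional genomic TSS override (e.g. a CAGE-refined position).
#' @return A [Biostrings::DNAString].
#' @export
promoter_sequence <- function(genome, annotation, gene_id, from = -500L,
                              to = 100L, tss = NULL) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  if (!g$chrom %in% names(genome)) stop("contig not in genome: ", g$chrom)
  contig <- genome[[g$chrom]]
  anchor <- if (is.null(tss)) g$tss else as.integer(tss)
  if (g$strand == "+") {
    lo <- anchor + from + 1L   # 1-based
    hi <- anchor + to
  } else {
    lo <- anchor - to + 2L
    hi <- anchor - from + 1L
  }
  if (lo < 1L || hi > length(contig))
    stop("promoter window of ", gene_id, " extends past the contig edge")
  s <- Biostrings::subseq(contig, lo, hi)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Promoter GC content
#'
#' Fraction of G+C in the gene-oriented promoter window, with ambiguous
#' bases excluded from both numerator and denominator. GC is
#' strand-symmetric, so the reverse complement of a window reports the same
#' value.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation A [gene_annotation()].
#' @param window Gene-oriented half-open window (default `[-500, +100)`).
#' @param tss Optional named vector of genomic TSS overrides by gene id.
#' @return data.frame with `gene_id` and `gc`.
#' @export
promoter_gc <- function(genome, annotation, window = c(-500L, 100L),
                        tss = NULL) {
  g <- annotation$genes
  gc <- vapply(seq_len(nrow(g)), function(i) {
    anchor <- if (!is.null(tss) && g$gene_id[i] %in% names(tss))
      tss[[g$gene_id[i]]] else NULL
    s <- promoter_sequence(genome, annotation, g$gene_id[i],
                           window[1], window[2], tss = anchor)
    f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    unamb <- sum(f)
    if (unamb == 0) return(NA_real_)
    (f[["C"]] + f[["G"]]) / unamb
  }, numeric(1))
  data.frame(gene_id = g$gene_id, gc = gc)
}

#' Optimal GC-content cutoff between two promoter classes
#'
#' Scans every observed GC value as a candidate threshold `t` and returns
#' the one maximizing `|P(a > t) - P(b > t)|`, ties broken toward the
#' smallest `t`. The discrimination achieved is reported alongside. The
#' statistic depends only on ranks, so it is invariant under strictly
#' monotone transforms applied to both sets.
#'
#' @param gc_a,gc_b Numeric GC values for the two classes (non-empty).
#' @return list with `cutoff` and `discrimination`.
#' @export
optimal_gc_cutoff <- function(gc_a, gc_b) {
  gc_a <- gc_a[!is.na(gc_a)]
  gc_b <- gc_b[!is.na(gc_b)]
  if (length(gc_a) == 0L || length(gc_b) == 0L)
    stop("both GC classes must be non-empty")
  cand <- sort(unique(c(gc_a, gc_b)))
  disc <- vapply(cand, function(t)
    abs(mean(gc_a > t) - mean(gc_b > t)), numeric(1))
  best <- which(disc == max(disc))[1L]   # candidates sorted: smallest t wins
  list(cutoff = cand[best], discrimination = disc[best])
}

#' Refine TSS positions from CAGE tags
#'
#' For each gene, sense-strand CAGE 5' ends at gene-oriented offsets in
#' `[-1000, 1000)` are collected; a 100-bp window slides at 1-bp steps over
#' that region (1901 windows) and the window with the highest tag count is
#' the primary TSS cluster; the single bp with the most tags inside it is
#' the refined TSS. Ties go to the 5'-most window, then the 5'-most bp
#' (gene orientation). Genes with zero tags keep the annotated TSS, flagged.
#'
#' @param cage A stranded [tag_library()] of CAGE tags.
#' @param annotation A [gene_annotation()].
#' @param flank Search half-width in bp (offsets span `[-flank, flank)`).
#' @param cluster_width Cluster window width in bp.
#' @param target Normalization target for `cluster_tag_count`.
#' @return data.frame with per-gene `cluster_start`, `cluster_end` (genomic,
#'   half-open), `refined_tss` (genomic bp), `offset` (gene-oriented bp from
#'   the annotated TSS), `cluster_tag_count` (weighted) and `has_tags`.
#' @export
refine_tss_from_cage <- function(cage, annotation, flank = 1000L,
                                 cluster_width = 100L, target = 1e7) {
  if (!cage$stranded) stop("CAGE refinement requires a stranded library")
  w <- tag_weight(cage, target)
  g <- annotation$genes
  t <- cage$tags
  span <- 2L * flank
  nwin <- span - cluster_width + 1L
  res <- lapply(seq_len(nrow(g)), function(i) {
    keep <- t$chrom == g$chrom[i] & t$strand == g$strand[i]
    rel <- rel_offset(t$pos[keep], g$tss[i], g$strand[i])
    rel <- rel[rel >= -flank & rel < flank]
    if (length(rel) == 0L)
      return(data.frame(gene_id = g$gene_id[i], cluster_start = NA_integer_,
                        cluster_end = NA_integer_, refined_tss = g$tss[i],
                        offset = 0L, cluster_tag_count = 0, has_tags = FALSE))
    percnt <- tabulate(rel + flank + 1L, nbins = span)
    winsum <- cumsum(percnt)
    winsum <- winsum[cluster_width:span] -
      c(0, winsum[seq_len(span - cluster_width)])
    jbest <- which.max(winsum)          # first max = 5'-most window
    inwin <- percnt[jbest:(jbest + cluster_width - 1L)]
    kbest <- which.max(inwin)           # first max = 5'-most bp
    off <- (jbest - 1L) + (kbest - 1L) - flank
    woff <- (jbest - 1L) - flank        # gene-oriented window start
    if (g$strand[i] == "+") {
      cs <- g$tss[i] + woff
      rt <- g$tss[i] + off
    } else {
      cs <- g$tss[i] - woff - cluster_width + 1L
      rt <- g$tss[i] - off
    }
    stopifnot(jbest <= nwin)
    data.frame(gene_id = g$gene_id[i], cluster_start = cs,
               cluster_end = cs + cluster_width, refined_tss = rt,
               offset = off, cluster_tag_count = winsum[jbest] * w,
               has_tags = TRUE)
  })
  do.call(rbind, res)
}

#' Read a position weight matrix from a JASPAR-style text file
#'
#' Accepts the plain-text count format: an optional `>id name` header line
#' followed by four rows (A, C, G, T), each optionally prefixed by the base
#' letter and with counts optionally bracketed.
#'
#' @param path Matrix file.
#' @param pseudocount Added to every count before normalization.
#' @param threshold_fraction Hit threshold as a fraction of the maximal
#'   attainable log-odds score (the usual "80-90% of best score" rule;
#'   default 0.9).
#' @return A `Pwm` object: list with `id`, `prob` (4 x L), `log_odds`
#'   (log2 vs uniform background), `length`, `score_threshold`.
#' @export
read_motif_matrix <- function(path, pseudocount = 0.5,
                              threshold_fraction = 0.9) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  id <- "motif"
  if (startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop("motif matrix needs 4 base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][ACGTacgt]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("motif matrix rows have unequal lengths")
  counts <- do.call(rbind, rows) + pseudocount
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts, 2, colSums(counts), "/")
  lo <- log2(prob / 0.25)
  maxs <- sum(apply(lo, 2, max))
  structure(list(id = id, prob = prob, log_odds = lo, length = ncol(prob),
                 score_threshold = threshold_fraction * maxs),
            class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm '%s': %d bp, hit threshold %.2f bits\n",
              x$id, x$length, x$score_threshold))
  invisible(x)
}

# log-odds scores of a Pwm at every start of a DNAString (NA where ambiguous)
pwm_scores <- function(pwm, seq) {
  n <- length(seq) - pwm$length + 1L
  if (n < 1L) return(numeric(0))
  Biostrings::PWMscoreStartingAt(pwm$log_odds, seq, starting.at = seq_len(n))
}

#' Positional TATA-box scan
#'
#' Scans for a TATA motif whose start lies in the gene-oriented window
#' `[-35, -20]` (inclusive) on the sense strand. The default matcher is the
#' consensus `TATAWAWR` (IUPAC, W = A/T, R = A/G); a [read_motif_matrix()]
#' PWM with its score threshold can be supplied instead. Only hits starting
#' inside the window count, so a motif shifted out of it flips the flag.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation A [gene_annotation()].
#' @param window Inclusive start-position window relative to the TSS.
#' @param consensus IUPAC consensus used when `pwm` is `NULL`.
#' @param pwm Optional `Pwm` object.
#' @param tss Optional named vector of genomic TSS overrides by gene id.
#' @return data.frame with per-gene `hit`, `position` (gene-oriented start
#'   of the best hit, `NA` if none) and `score` (`NA` for consensus hits).
#' @export
scan_tata <- function(genome, annotation, window = c(-35L, -20L),
                      consensus = "TATAWAWR", pwm = NULL, tss = NULL) {
  g <- annotation$genes
  mlen <- if (is.null(pwm)) nchar(consensus) else pwm$length
  res <- lapply(seq_len(nrow(g)), function(i) {
    anchor <- if (!is.null(tss) && g$gene_id[i] %in% names(tss))
      tss[[g$gene_id[i]]] else NULL
    s <- promoter_sequence(genome, annotation, g$gene_id[i],
                           from = window[1], to = window[2] + mlen,
                           tss = anchor)
    if (is.null(pwm)) {
      m <- Biostrings::matchPattern(consensus, s, fixed = FALSE)
      starts <- Biostrings::start(m)
      starts <- starts[starts <= window[2] - window[1] + 1L]
      data.frame(gene_id = g$gene_id[i], hit = length(starts) > 0L,
                 position = if (length(starts) > 0L)
                   window[1] + min(starts) - 1L else NA_integer_,
                 score = NA_real_)
    } else {
      sc <- pwm_scores(pwm, s)
      sc <- sc[seq_len(min(length(sc), window[2] - window[1] + 1L))]
      ok <- which(!is.na(sc) & sc >= pwm$score_threshold)
      best <- if (length(ok) > 0L) ok[which.max(sc[ok])] else NA_integer_
      data.frame(gene_id = g$gene_id[i], hit = length(ok) > 0L,
                 position = if (!is.na(best))
                   window[1] + best - 1L else NA_integer_,
                 score = if (!is.na(best)) sc[best] else NA_real_)
    }
  })
  do.call(rbind, res)
}

#' Known-motif enrichment in promoter sets
#'
#' Per-gene motif presence (zero-or-one occurrence: any PWM hit at or above
#' threshold in the gene-oriented region, both strands by default), then an
#' exact hypergeometric upper-tail test for the foreground hit count given
#' the pooled counts.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation A [gene_annotation()].
#' @param foreground,background Character vectors of gene ids.
#' @param pwm A `Pwm` from [read_motif_matrix()].
#' @param region Gene-oriented half-open scan window (default `[-500, +100)`).
#' @param both_strands Scan the reverse complement too.
#' @param tss Optional named vector of genomic TSS overrides.
#' @return list with hit counts and fractions for both sets, the
#'   hypergeometric `p_value`, and `disjoint` (whether the sets share genes).
#' @export
motif_enrichment <- function(genome, annotation, foreground, background,
                             pwm, region = c(-500L, 100L),
                             both_strands = TRUE, tss = NULL) {
  if (length(foreground) == 0L) stop("empty foreground gene set")
  present <- function(gene_id) {
    anchor <- if (!is.null(tss) && gene_id %in% names(tss))
      tss[[gene_id]] else NULL
    s <- promoter_sequence(genome, annotation, gene_id,
                           from = region[1], to = region[2], tss = anchor)
    sc <- pwm_scores(pwm, s)
    hit <- any(!is.na(sc) & sc >= pwm$score_threshold)
    if (!hit && both_strands) {
      sc <- pwm_scores(pwm, Biostrings::reverseComplement(s))
      hit <- any(!is.na(sc) & sc >= pwm$score_threshold)
    }
    hit
  }
  fg_hit <- vapply(foreground, present, logical(1))
  bg_hit <- vapply(background, present, logical(1))
  k <- sum(fg_hit)
  K <- k + sum(bg_hit)
  N <- length(foreground) + length(background)
  p <- phyper(k - 1, K, N - K, length(foreground), lower.tail = FALSE)
  list(n_foreground = length(foreground), n_background = length(background),
       foreground_hits = k, background_hits = sum(bg_hit),
       foreground_fraction = mean(fg_hit),
       background_fraction = if (length(background)) mean(bg_hit) else NA_real_,
       p_value = p,
       disjoint = length(intersect(foreground, background)) == 0L)
}
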