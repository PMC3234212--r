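#' Classify genes by induction kinetics
#'
#' Immediate/early (IE) genes are induced more than 3-fold at 1 h after
#' stimulation; late genes are induced less than 1.2-fold at 1 h but more
#' than 4-fold at 12 h; everything else is "other". All inequalities are
#' strict, so fold changes of exactly 3 (or exactly 1.2) do not qualify.
#' The two predicates are mutually exclusive by construction.
#'
#' @param expr data.frame with columns `gene_id`, `expr_0h`, `expr_1h`,
#'   `expr_12h` (normalized expression, positive at 0 h).
#' @param fc_ie 1 h fold-change threshold for the IE call (default 3).
#' @param fc_late_1h,fc_late_12h Late-gene thresholds (defaults 1.2 and 4).
#' @return The input with `fc_1h`, `fc_12h` and `kinetic_class`
#'   (factor with levels IE, late, other) appended.
#' @export
classify_kinetics <- function(expr, fc_ie = 3, fc_late_1h = 1.2,
                              fc_late_12h = 4) {
  if (any(expr$expr_0h <= 0))
    stop("expr_0h must be positive for fold-change classification")
  fc1 <- expr$expr_1h / expr$expr_0h
  fc12 <- expr$expr_12h / expr$expr_0h
  cls <- ifelse(fc1 > fc_ie, "IE",
                ifelse(fc1 < fc_late_1h & fc12 > fc_late_12h, "late",
                       "other"))
  out <- expr
  out$fc_1h <- fc1
  out$fc_12h <- fc12
  out$kinetic_class <- factor(cls, levels = c("IE", "late", "other"))
  out
}

#' Call induced genes from two gene-body tag libraries
#'
#' Uses depth-normalized sense-strand gene-body counts as the transcription
#' measure. The fold change adds a pseudocount to both raw counts before
#' taking the depth-corrected ratio. Significance is a one-sided conditional
#' binomial test on the raw counts (treated count given the two-library
#' total, expected split by library depths), Benjamini-Hochberg corrected.
#' A gene is induced when fold change > `fc_threshold` (strict), treated
#' RPKM > `rpkm_min` (strict), and q < `fdr` (strict).
#'
#' @param gro_basal,gro_treated Stranded [tag_library()] objects.
#' @param annotation A [gene_annotation()].
#' @param fc_threshold Fold-change cutoff (default 3).
#' @param rpkm_min Treated-library RPKM floor (default 0.25).
#' @param fdr BH-adjusted q-value cutoff (default 0.10).
#' @param pseudocount Added to both raw counts before the ratio.
#' @return data.frame with per-gene counts, `rpkm_basal`, `rpkm_treated`,
#'   `fold_change`, `p_value`, `fdr_q` and `induced`.
#' @export
call_induced_genes <- function(gro_basal, gro_treated, annotation,
                               fc_threshold = 3, rpkm_min = 0.25,
                               fdr = 0.10, pseudocount = 0.5) {
  if (gro_basal$total_mapped <= 0 || gro_treated$total_mapped <= 0)
    stop("cannot call induced genes from a zero-depth library")
  kb <- gene_body_density(gro_basal, annotation, sense_only = TRUE)$count
  kt <- gene_body_density(gro_treated, annotation, sense_only = TRUE)$count
  nb <- gro_basal$total_mapped
  nt <- gro_treated$total_mapped
  fc <- ((kt + pseudocount) / nt) / ((kb + pseudocount) / nb)
  g <- annotation$genes
  gene_kb <- (g$tx_end - g$tx_start) / 1000
  rpkm_b <- (kb / gene_kb) / (nb / 1e6)
  rpkm_t <- (kt / gene_kb) / (nt / 1e6)
  n <- kb + kt
  p0 <- nt / (nt + nb)
  p <- ifelse(n == 0, 1, pbinom(kt - 1, n, p0, lower.tail = FALSE))
  q <- p.adjust(p, method = "BH")
  data.frame(gene_id = g$gene_id, count_basal = kb, count_treated = kt,
             rpkm_basal = rpkm_b, rpkm_treated = rpkm_t, fold_change = fc,
             p_value = p, fdr_q = q,
             induced = fc > fc_threshold & rpkm_t > rpkm_min & q < fdr)
}

#' Cross-genotype overlap of induced gene sets
#'
#' For the genes called induced in condition/genotype A, reports how their
#' fold changes in B partition into: also induced (> 3-fold in B),
#' unresponsive (B fold change < 2, or inevaluable), and an intermediate
#' `[2, 3]` band, so the three bins are exhaustive.
#'
#' @param calls_a,calls_b Outputs of [call_induced_genes()] over a shared
#'   gene universe.
#' @param fc_induced,fc_unresponsive Bin edges (defaults 3 and 2).
#' @return list with `n_induced_a`, `also_induced`, `unresponsive`,
#'   `intermediate`, and the per-gene table `genes`.
#' @export
overlap_by_genotype <- function(calls_a, calls_b, fc_induced = 3,
                                fc_unresponsive = 2) {
  common <- intersect(calls_a$gene_id, calls_b$gene_id)
  if (length(common) == 0L)
    stop("induced-call tables share no genes (disjoint gene universes)")
  a <- calls_a[match(common, calls_a$gene_id), ]
  b <- calls_b[match(common, calls_b$gene_id), ]
  ind <- which(a$induced)
  fcb <- b$fold_change[ind]
  also <- !is.na(fcb) & fcb > fc_induced
  unresp <- is.na(fcb) | fcb < fc_unresponsive
  inter <- !also & !unresp
  list(n_induced_a = length(ind),
       also_induced = sum(also),
       unresponsive = sum(unresp),
       intermediate = sum(inter),
       genes = data.frame(gene_id = a$gene_id[ind], fold_change_b = fcb,
                          bin = ifelse(also, "induced",
                                       ifelse(unresp, "unresponsive",
                                              "intermediate"))))
}

#' TSS-proximal factor binding
#'
#' Flags a gene when any peak center (interval midpoint) lies within
#' `radius` bp of its TSS, inclusive; also reports the flagged fraction.
#'
#' @param peaks data.frame of peak intervals with columns `chrom`, `start`,
#'   `end` (0-based, half-open).
#' @param annotation A [gene_annotation()].
#' @param radius Distance cutoff in bp (default 500).
#' @return list with per-gene data.frame (`gene_id`, `bound`) and `fraction`.
#' @export
tss_proximal_binding <- function(peaks, annotation, radius = 500L) {
  if (radius < 0L) stop("radius must be non-negative")
  centers <- (peaks$start + peaks$end) %/% 2L
  idx <- lapply(split(centers, peaks$chrom), sort)
  g <- annotation$genes
  bound <- vapply(seq_len(nrow(g)), function(i) {
    count_sorted(idx[[g$chrom[i]]], g$tss[i] - radius, g$tss[i] + radius) > 0L
  }, logical(1))
  list(per_gene = data.frame(gene_id = g$gene_id, bound = bound),
       fraction = mean(bound))
}
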