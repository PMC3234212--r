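#' Validate a pipeline configuration
#'
#' Accepts an R list or a path to a JSON file. Unknown keys are rejected by
#' name; defaults are filled for every analysis parameter (normalization
#' target 1e7 tags, +/-1 kb promoter window, the elongation and junction
#' windows, the `[-500, +100)` promoter sequence window, the `[-35, -20]`
#' TATA window, enrichment alpha 0.001, 500-bp binding radius).
#'
#' @param x A list, or a path to a JSON config file.
#' @return A validated `RunConfig` list with elements `sim` (a
#'   [sim_config()]), `params`, `stages`, `outdir`, `seed`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- read_json(x, simplifyVector = TRUE)
  }
  if (!is.list(x)) stop("config must be a list or a JSON file path")
  known_top <- c("sim", "params", "stages", "outdir", "seed")
  unknown <- setdiff(names(x), known_top)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  default_params <- list(
    normalization_target = 1e7,
    promoter_window = 1000L,
    profile_range = 2000L, profile_bin = 25L,
    ee_promoter_window = c(-25L, 175L),
    ee_body_window = c(500L, 2500L),
    junction_span_window = c(7L, 25L),
    junction_exon_window = c(-25L, -7L),
    splicing_min_raw_per_kb = 1,
    gc_window = c(-500L, 100L),
    tata_window = c(-35L, -20L),
    enrichment_alpha = 0.001,
    binding_radius = 500L,
    induced_fc = 3, induced_rpkm_min = 0.25, induced_fdr = 0.10,
    cage_tags_per_gene = 500L)
  params <- x$params
  if (is.null(params)) params <- list()
  unknown <- setdiff(names(params), names(default_params))
  if (length(unknown) > 0L)
    stop("unknown params key(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(default_params, params)
  sim_args <- x$sim
  if (is.null(sim_args)) sim_args <- list()
  if (!is.null(x$seed)) sim_args$seed <- as.integer(x$seed)
  known_sim <- names(formals(sim_config))
  unknown <- setdiff(names(sim_args), known_sim)
  if (length(unknown) > 0L)
    stop("unknown sim key(s): ", paste(unknown, collapse = ", "))
  sim <- do.call(sim_config, sim_args)
  stages_all <- c("simulate", "profile", "metrics", "classify",
                  "seqanalysis")
  stages <- x$stages
  if (is.null(stages)) stages <- stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown) > 0L)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  structure(list(sim = sim, params = params,
                 stages = intersect(stages_all, stages),
                 outdir = if (is.null(x$outdir)) "results" else x$outdir,
                 seed = sim$seed),
            class = "RunConfig")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order over a fully synthetic
#' world: `simulate` (annotation, truth, genome, libraries, expression),
#' `profile` (TSS-anchored densities for the paused-polymerase and histone
#' marks), `metrics` (elongation efficiency per condition, both splicing
#' estimators, promoter enrichment calls), `classify` (kinetic classes and
#' induced-gene calls), `seqanalysis` (promoter GC + optimal cutoff, CAGE
#' TSS refinement, positional TATA scan). Every table is written as TSV
#' under `outdir`, and a JSON run manifest lists the resolved config,
#' library depths and per-stage outputs. Identical config and seed give
#' identical table content.
#'
#' @param config A `RunConfig` from [validate_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The run manifest, invisibly (also written to
#'   `outdir/run_manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  t_start <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  p <- config$params
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[nascentmetrics] ", ...)
  outputs <- character(0)
  emit <- function(d, name) {
    path <- file.path(config$outdir, name)
    write_tsv(d, path)
    outputs <<- c(outputs, path)
    path
  }

  say("simulate: building world with ", config$sim$n_genes, " genes, seed ",
      config$sim$seed)
  world <- build_annotation(config$sim)
  anno <- world$annotation
  truth <- world$truth
  genome <- synthesize_genome_sequence(anno, truth, config$sim)
  libs <- list(
    polII_basal = shift_tags(simulate_chip_library(
      anno, truth, "polII_paused", "basal", config$sim)),
    polII_kla = shift_tags(simulate_chip_library(
      anno, truth, "polII_paused", "KLA_1h", config$sim)),
    histone_basal = shift_tags(simulate_chip_library(
      anno, truth, "histone_bimodal", "basal", config$sim)),
    gro_basal = simulate_gro_library(anno, truth, "basal", config$sim),
    gro_kla = simulate_gro_library(anno, truth, "KLA_1h", config$sim),
    rna_basal = simulate_rna_library(anno, truth, "basal", config$sim),
    cage = simulate_cage_library(anno, truth, config$sim,
                                 tags_per_gene = p$cage_tags_per_gene))
  expr <- simulate_expression_table(truth, config$sim)
  if ("simulate" %in% config$stages) {
    emit(truth, "sim_truth.tsv")
    emit(expr, "expression.tsv")
    emit(anno$genes, "genes.tsv")
    say("simulate: ", nrow(truth), " truth records, ",
        length(libs), " libraries of ",
        format(config$sim$library_size, big.mark = ","), " tags")
  }

  if ("profile" %in% config$stages) {
    prof_pol <- tss_profile(libs$polII_basal, anno, range = p$profile_range,
                            bin = p$profile_bin,
                            target = p$normalization_target)
    prof_his <- tss_profile(libs$histone_basal, anno,
                            range = p$profile_range, bin = p$profile_bin,
                            target = p$normalization_target)
    emit(prof_pol, "profile_polII_basal.tsv")
    emit(prof_his, "profile_histone_basal.tsv")
    say("profile: polII mode at ",
        prof_pol$offset[which.max(prof_pol$density)], " bp")
  }

  if ("metrics" %in% config$stages) {
    ee_b <- elongation_efficiency(libs$gro_basal, anno,
                                  p$ee_promoter_window, p$ee_body_window,
                                  condition = "basal",
                                  target = p$normalization_target)
    ee_k <- elongation_efficiency(libs$gro_kla, anno,
                                  p$ee_promoter_window, p$ee_body_window,
                                  condition = "KLA_1h",
                                  target = p$normalization_target)
    emit(rbind(ee_b, ee_k), "elongation_efficiency.tsv")
    sed <- splicing_efficiency_density(libs$rna_basal, anno,
                                       p$splicing_min_raw_per_kb,
                                       condition = "basal",
                                       target = p$normalization_target)
    sej <- splicing_efficiency_junction(libs$rna_basal, anno,
                                        p$junction_span_window,
                                        p$junction_exon_window,
                                        condition = "basal")
    emit(merge(sed, sej$per_gene[, c("gene_id", "efficiency_junction",
                                     "evaluable_junction")],
               by = "gene_id"), "splicing_efficiency.tsv")
    enr <- promoter_enrichment_call(libs$histone_basal, anno,
                                    genome_length = world$genome_length,
                                    window = p$promoter_window,
                                    alpha = p$enrichment_alpha,
                                    target = p$normalization_target)
    emit(enr, "promoter_enrichment.tsv")
    say("metrics: median basal elongation efficiency ",
        signif(stats::median(ee_b$efficiency, na.rm = TRUE), 3),
        "; aggregate junction splicing efficiency ",
        signif(sej$aggregate, 3))
  }

  if ("classify" %in% config$stages) {
    cls <- classify_kinetics(expr)
    emit(cls, "kinetic_classes.tsv")
    ind <- call_induced_genes(libs$gro_basal, libs$gro_kla, anno,
                              fc_threshold = p$induced_fc,
                              rpkm_min = p$induced_rpkm_min,
                              fdr = p$induced_fdr)
    emit(ind, "induced_calls.tsv")
    say("classify: ", sum(cls$kinetic_class == "IE"), " IE / ",
        sum(cls$kinetic_class == "late"), " late; ",
        sum(ind$induced), " genes called induced")
  }

  if ("seqanalysis" %in% config$stages) {
    ref <- refine_tss_from_cage(libs$cage, anno,
                                target = p$normalization_target)
    emit(ref, "refined_tss.tsv")
    rtss <- setNames(ref$refined_tss, ref$gene_id)
    gc <- promoter_gc(genome, anno, window = p$gc_window, tss = rtss)
    cls <- classify_kinetics(expr)
    gc$kinetic_class <- cls$kinetic_class[match(gc$gene_id, cls$gene_id)]
    emit(gc, "promoter_gc.tsv")
    cut <- optimal_gc_cutoff(gc$gc[gc$kinetic_class == "IE"],
                             gc$gc[gc$kinetic_class == "late"])
    tata <- scan_tata(genome, anno, window = p$tata_window, tss = rtss)
    tata$kinetic_class <- cls$kinetic_class[match(tata$gene_id,
                                                  cls$gene_id)]
    emit(tata, "tata_scan.tsv")
    say("seqanalysis: GC cutoff ", signif(cut$cutoff, 3),
        " (discrimination ", signif(cut$discrimination, 3), "); TATA on ",
        round(100 * mean(tata$hit[tata$kinetic_class == "IE"])),
        "% of IE vs ",
        round(100 * mean(tata$hit[tata$kinetic_class == "late"])),
        "% of late promoters")
  }

  manifest <- list(
    config = list(seed = config$seed, stages = config$stages,
                  n_genes = config$sim$n_genes,
                  library_size = config$sim$library_size,
                  params = p),
    libraries = lapply(libs, function(l)
      list(total_mapped = l$total_mapped,
           weight = p$normalization_target / l$total_mapped)),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("nascentmetrics")),
    started = t_start, finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  write_json(manifest, file.path(config$outdir, "run_manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bad <- outputs[!file.exists(outputs) | file.size(outputs) == 0]
  if (length(bad) > 0L)
    stop("pipeline produced missing/empty outputs: ",
         paste(bad, collapse = ", "))
  invisible(manifest)
}
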