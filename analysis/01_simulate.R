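#!/usr/bin/env Rscript
# Build the synthetic world used across the analysis scripts: a single
# contig carrying 300 non-overlapping multi-exon genes with planted kinetic
# classes, elongation/splicing efficiencies, TSS offsets, promoter GC and
# TATA flags, plus a three-timepoint expression table. Everything downstream
# is parameter recovery against the truth table written here.

library(nascentmetrics)

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 300, library_size = 1e6, seed = 1)
world <- build_annotation(cfg)
truth <- world$truth
expr <- simulate_expression_table(truth, cfg)

cat(sprintf("genome: %s bp on one contig; %d genes (%d +, %d -)\n",
            format(world$genome_length, big.mark = ","),
            nrow(world$annotation$genes),
            sum(world$annotation$genes$strand == "+"),
            sum(world$annotation$genes$strand == "-")))
cat("kinetic classes planted:\n")
print(table(truth$kinetic_class))
cat(sprintf("TATA planted on %.0f%% of IE and %.0f%% of late promoters\n",
            100 * mean(truth$has_tata[truth$kinetic_class == "IE"]),
            100 * mean(truth$has_tata[truth$kinetic_class == "late"])))

write.table(truth, file.path(outdir, "sim_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr, file.path(outdir, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_annotation_bed12(world$annotation, file.path(outdir, "genes.bed12"))
cat("wrote", file.path(outdir, c("sim_truth.tsv", "expression.tsv",
                                 "genes.bed12")), sep = "\n  ")
cat("\n")
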