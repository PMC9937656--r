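#!/usr/bin/env Rscript
# In vivo SILAC branch: localization filter, protein normalization,
# replicate filters, imputation, random-effects fits, inhibitor-contrast
# t-tests with BH FDR, and class I/II calls.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

design <- read_design(file.path(OUT, "sim", "invivo_design.tsv"))
sites <- read_site_table(file.path(OUT, "sim", "invivo_sites.tsv"), design)

praw <- utils::read.delim(file.path(OUT, "sim", "invivo_proteins.tsv"),
                          check.names = FALSE, na.strings = "NaN")
proteins <- protein_table(praw$protein_id,
                          as.matrix(praw[, design$sample_id]), design)

res <- run_silac(sites, proteins, pipeline_config(seed = MASTER_SEED))
write_stats(res$stats, file.path(OUT, "silac_stats.tsv"))
write_site_table(res$table, file.path(OUT, "silac_table_final.tsv"))

cnt <- res$stage_counts
cat("Stage counts:\n")
print(cnt)
tab <- table(res$stats$class_label)
cat(sprintf(paste0(
  "\nOf %d tested sites, %d are class I (starvation-induced AND\n",
  "inhibitor-sensitive) and %d class II (inhibitor-sensitive only,\n",
  "the constitutively phosphorylated pattern). Stats in %s/silac_stats.tsv.\n"),
  cnt[["tested"]], tab[["class_I"]],
  if ("class_II" %in% names(tab)) tab[["class_II"]] else 0, OUT))
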