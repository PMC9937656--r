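#!/usr/bin/env Rscript
# In vitro OBIKA branch and its intersection with the in vivo calls into the
# bona fide direct-target set; recovery is scored against the ground truth.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

odesign <- read_design(file.path(OUT, "sim", "obika_design.tsv"))
osites <- read_site_table(file.path(OUT, "sim", "obika_sites.tsv"), odesign)
silac_stats <- utils::read.delim(file.path(OUT, "silac_stats.tsv"))
truth <- utils::read.delim(file.path(OUT, "sim", "ground_truth.tsv"))

ob <- run_obika(osites, pipeline_config(seed = MASTER_SEED))
write_stats(ob$stats, file.path(OUT, "obika_stats.tsv"))

ts <- intersect_targets(silac_stats, ob$stats)
write_stats(ts$targets, file.path(OUT, "targets.tsv"))

# score against the planted truth, conditional on the common universe
common <- intersect(silac_stats$site_key, ob$stats$site_key)
subs <- intersect(truth$site_key[truth$is_direct_substrate], common)
recall <- mean(subs %in% ts$targets$site_key)
precision <- mean(ts$targets$site_key %in% truth$site_key[truth$is_direct_substrate])

# overlap bookkeeping against the planted responder list, as one would
# compare with previously published target-site lists
ov <- compare_with_published(
  ts, list(planted_responders = truth$site_key[truth$is_invivo_responder],
           planted_substrates = truth$site_key[truth$is_direct_substrate]))
write_stats(ov, file.path(OUT, "target_overlap.tsv"))

cat(sprintf(paste0(
  "OBIKA: %d sites tested, %d significant (WT > kinase-dead).\n",
  "Common universe with the in vivo branch: %d sites; bona fide targets:\n",
  "%d sites on %d proteins. Timing: %s.\n",
  "Against ground truth: substrate recall %.2f, precision %.2f.\n"),
  nrow(ob$stats), sum(ob$stats$significant), ts$n_common, ts$n_targets,
  ts$n_proteins,
  paste(sprintf("%s=%d", names(table(ts$targets$timing)),
                table(ts$targets$timing)), collapse = ", "),
  recall, precision))
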