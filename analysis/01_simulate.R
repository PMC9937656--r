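#!/usr/bin/env Rscript
# Generate the synthetic study: in vivo SILAC tables (sites + proteins),
# the parallel OBIKA assay, the proteome FASTA, and the ground-truth ledger.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

cfg <- study_config()
sim <- generate_invivo(cfg)
ob <- generate_obika(cfg, sim$truth)
prot <- generate_proteome(cfg, sim$truth)

write_site_table(sim$sites, file.path(OUT, "sim", "invivo_sites.tsv"))
write_design(sim$design, file.path(OUT, "sim", "invivo_design.tsv"))
utils::write.table(
  cbind(protein_id = sim$proteins$meta$protein_id,
        as.data.frame(ifelse(is.na(sim$proteins$values), "NaN",
                             sprintf("%.10g", sim$proteins$values)))),
  file.path(OUT, "sim", "invivo_proteins.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
write_site_table(ob$sites, file.path(OUT, "sim", "obika_sites.tsv"))
write_design(ob$design, file.path(OUT, "sim", "obika_design.tsv"))
Biostrings::writeXStringSet(prot, file.path(OUT, "sim", "proteome.fasta"))
utils::write.table(sim$truth, file.path(OUT, "sim", "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "Simulated %d phosphosites on %d proteins (%.1f%% missing cells),\n",
  "%d planted responders of which %d are direct substrates.\n",
  "Outputs in %s/sim/.\n"),
  n_sites(sim$sites), cfg$n_proteins, 100 * mean(is.na(sim$sites$values)),
  sum(sim$truth$is_invivo_responder), sum(sim$truth$is_direct_substrate),
  OUT))
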