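#!/usr/bin/env Rscript
# Sequence-motif characterization of the bona fide target sites: 15-mer
# windows, position-specific enrichment against all other tested sites,
# consensus calls (expected for an AMPK-family kinase: basic residues at
# -3/-4 and leucine at +4).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

targets <- utils::read.delim(file.path(OUT, "targets.tsv"))
stats <- utils::read.delim(file.path(OUT, "silac_stats.tsv"))
proteome <- file.path(OUT, "sim", "proteome.fasta")

fg <- extract_windows(targets[, c("protein_id", "position", "residue")],
                      proteome, flank = 7)
bg_meta <- stats[!stats$site_key %in% targets$site_key,
                 c("protein_id", "position", "residue")]
bg <- extract_windows(bg_meta, proteome, flank = 7)

profile <- position_enrichment(fg, bg)
calls <- consensus_call(profile, q_threshold = 0.01, enrichment_threshold = 1)
write_stats(profile, file.path(OUT, "motif_profile.tsv"))
write_stats(calls, file.path(OUT, "motif_consensus.tsv"))

cat(sprintf(paste0("Motif analysis of %d target windows against %d ",
                   "background windows.\nConsensus calls:\n"),
            length(fg), length(bg)))
print(calls)
cat(sprintf("\nProfile in %s/motif_profile.tsv.\n", OUT))
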