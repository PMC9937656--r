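#!/usr/bin/env Rscript
# Kinetic clustering of the class I/II sites: z-normalized per-timepoint
# replicate means, Euclidean distance, average-linkage tree cut at k = 5.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

design <- read_design(file.path(OUT, "sim", "invivo_design.tsv"))
tab <- read_site_table(file.path(OUT, "silac_table_final.tsv"), design)
stats <- utils::read.delim(file.path(OUT, "silac_stats.tsv"))

km <- kinetic_matrix(tab, stats, include_inhibitor = TRUE)
kz <- znormalize_rows(km)
cl <- hierarchical_cluster(kz, k = 5, linkage = "average")
labels <- label_cluster_kinetics(cl, kz)

out <- data.frame(site_key = names(cl$assignment),
                  cluster = unname(cl$assignment),
                  kinetic_label = unname(labels[as.character(cl$assignment)]))
write_stats(out, file.path(OUT, "kinetic_clusters.tsv"))

cat(sprintf("Clustered %d class I/II sites into %d clusters:\n",
            nrow(out), cl$k))
print(table(cluster = out$cluster, label = out$kinetic_label))
cat(sprintf("\nAssignments in %s/kinetic_clusters.tsv.\n", OUT))
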