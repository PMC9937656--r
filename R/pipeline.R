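#' Pipeline configuration
#'
#' Bundles the thresholds and mode flags of every stage, with the standard
#' defaults: localization probability > 0.75, protein filter >= 2
#' replicates, site filter >= 3 vehicle replicates at either timepoint,
#' Perseus-default imputation constants, alpha 0.05 throughout, k = 5
#' clusters, flank 7.
#'
#' @param loc_threshold localization probability cutoff (strict `>`).
#' @param protein_min_replicates protein-filter replicate minimum.
#' @param protein_filter_mode `"per_cell"` or `"pooled"`.
#' @param site_min_replicates site-filter replicate minimum.
#' @param site_filter_mode `"any_timepoint"` or `"all_timepoints"`.
#' @param alpha_re,alpha_fdr,obika_alpha significance levels.
#' @param t_variant `"student"` or `"welch"`.
#' @param timepoint_family BH family layout, `"separate"` or `"pooled"`.
#' @param impute_width,impute_downshift down-shift imputation constants (in
#'   observed-sd units).
#' @param impute_scope `"per_sample_column"` or `"whole_matrix"`.
#' @param obika_min_wt minimum observed WT replicates in the OBIKA branch.
#' @param cluster_k number of kinetic clusters.
#' @param cluster_linkage `"average"`, `"complete"` or `"ward"`.
#' @param cluster_include_inhibitor cluster on all four condition columns
#'   instead of the vehicle arm only.
#' @param flank motif window flank.
#' @param motif_q,motif_enrichment consensus-call thresholds.
#' @param seed master seed for the imputation RNG streams.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(loc_threshold = 0.75,
                            protein_min_replicates = 2,
                            protein_filter_mode = "per_cell",
                            site_min_replicates = 3,
                            site_filter_mode = "any_timepoint",
                            alpha_re = 0.05, alpha_fdr = 0.05,
                            obika_alpha = 0.05,
                            t_variant = "student",
                            timepoint_family = "separate",
                            impute_width = 0.3, impute_downshift = 1.8,
                            impute_scope = "per_sample_column",
                            obika_min_wt = 3,
                            cluster_k = 5, cluster_linkage = "average",
                            cluster_include_inhibitor = FALSE,
                            flank = 7, motif_q = 0.01,
                            motif_enrichment = 1,
                            seed = 1L) {
  stopifnot(loc_threshold >= 0, loc_threshold <= 1,
            alpha_re > 0, alpha_re < 1, alpha_fdr > 0, alpha_fdr < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the in vivo SILAC branch
#'
#' Executes, in order: localization filter; protein replicate filter plus
#' down-shifted-normal imputation of the protein table; protein
#' normalization of the site values; site replicate filter (vehicle arm);
#' MLE imputation of the inhibitor-arm groups; random-effects fits,
#' per-timepoint t-tests, BH adjustment and classification
#' ([silac_stats()]). Row counts are logged after every stage.
#'
#' @param sites a [site_table()] (in vivo design).
#' @param proteins the matching [protein_table()].
#' @param config a [pipeline_config()].
#' @return list: `stats` (the [silac_stats()] data.frame), `table` (the
#'   final filtered/normalized/imputed `site_table`), `stage_counts`.
#' @export
run_silac <- function(sites, proteins, config = pipeline_config()) {
  stopifnot(inherits(sites, "site_table"), inherits(proteins, "protein_table"))
  counts <- c(input = n_sites(sites))
  ip <- impute_params(width = config$impute_width,
                      downshift = config$impute_downshift,
                      seed = config$seed, scope = config$impute_scope)

  sites <- filter_localization(sites, config$loc_threshold)
  counts["localization"] <- n_sites(sites)

  proteins <- filter_protein_min_replicates(
    proteins, config$protein_min_replicates, config$protein_filter_mode)
  proteins <- impute_downshift(proteins, ip)

  sites <- normalize_to_protein(sites, proteins)
  counts["protein_normalized"] <- n_sites(sites)

  sites <- filter_site_min_quantified(
    sites, arm = "vehicle", timepoints = sort(unique(sites$design$timepoint_min)),
    min_replicates = config$site_min_replicates,
    mode = config$site_filter_mode)
  counts["site_min_quantified"] <- n_sites(sites)

  for (tp in sort(unique(sites$design$timepoint_min)))
    sites <- impute_mle(sites,
                        samples_for(sites$design, arm = "inhibitor",
                                    timepoint = tp))

  stats <- silac_stats(sites, alpha_re = config$alpha_re,
                       alpha_fdr = config$alpha_fdr,
                       t_variant = config$t_variant,
                       timepoint_family = config$timepoint_family)
  counts["tested"] <- nrow(stats)
  counts["significant"] <- sum(stats$class_label %in% c("class_I", "class_II"))
  log_stage("run_silac done", counts[["significant"]], "class I/II sites")
  list(stats = stats, table = sites, stage_counts = counts)
}

#' Run the in vitro OBIKA branch
#'
#' Thin wrapper over [process_obika()] with the configured thresholds.
#'
#' @param sites a [site_table()] with an OBIKA design.
#' @param config a [pipeline_config()].
#' @return list: `stats` (the [process_obika()] data.frame),
#'   `stage_counts`.
#' @export
run_obika <- function(sites, config = pipeline_config()) {
  counts <- c(input = n_sites(sites))
  if (counts[["input"]] == 0) warning("empty OBIKA input table")
  ip <- impute_params(width = config$impute_width,
                      downshift = config$impute_downshift,
                      seed = config$seed, scope = config$impute_scope)
  stats <- process_obika(sites, alpha = config$obika_alpha,
                         min_wt = config$obika_min_wt, params = ip,
                         t_variant = config$t_variant)
  counts["tested"] <- nrow(stats)
  counts["significant"] <- sum(stats$significant)
  list(stats = stats, stage_counts = counts)
}

#' Run the full pipeline
#'
#' Both branches, their intersection into the bona fide target set, kinetic
#' clustering of the class I/II sites, and motif analysis of the bona fide
#' sites against all other quantified sites as background. Emits a run
#' manifest (config hash, seed, package version, stage counts) sufficient
#' to re-execute an identical run.
#'
#' @param sites,proteins in vivo [site_table()] / [protein_table()].
#' @param obika_sites OBIKA [site_table()].
#' @param proteome optional `AAStringSet` (or FASTA path) for the motif
#'   stage; skipped when `NULL`.
#' @param config a [pipeline_config()].
#' @return list of class `kinsub_run`: `silac`, `obika`, `targets`
#'   ([intersect_targets()]), `clusters`, `cluster_labels`, `motif`
#'   (profile + consensus), `manifest`.
#' @export
run_all <- function(sites, proteins, obika_sites, proteome = NULL,
                    config = pipeline_config()) {
  silac <- run_silac(sites, proteins, config)
  obika <- run_obika(obika_sites, config)
  targets <- intersect_targets(silac$stats, obika$stats,
                               alpha_fdr = config$alpha_fdr)

  clusters <- NULL
  cluster_labels <- NULL
  n_sig <- sum(silac$stats$class_label %in% c("class_I", "class_II"))
  if (n_sig >= config$cluster_k) {
    km <- kinetic_matrix(silac$table, silac$stats,
                         include_inhibitor = config$cluster_include_inhibitor)
    kz <- znormalize_rows(km)
    clusters <- hierarchical_cluster(kz, k = config$cluster_k,
                                     linkage = config$cluster_linkage)
    cluster_labels <- label_cluster_kinetics(clusters, kz)
  }

  motif <- NULL
  if (!is.null(proteome) && targets$n_targets > 0) {
    fg_meta <- targets$targets[, c("protein_id", "position", "residue")]
    bg_keys <- setdiff(silac$stats$site_key, targets$targets$site_key)
    bg_rows <- silac$stats$site_key %in% bg_keys
    bg_meta <- silac$stats[bg_rows, c("protein_id", "position", "residue")]
    fg_win <- extract_windows(fg_meta, proteome, config$flank)
    bg_win <- extract_windows(bg_meta, proteome, config$flank)
    profile <- position_enrichment(fg_win, bg_win)
    motif <- list(profile = profile,
                  consensus = consensus_call(profile,
                                             q_threshold = config$motif_q,
                                             enrichment_threshold =
                                               config$motif_enrichment))
  }

  manifest <- list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("kinsub")),
    stage_counts = list(silac = silac$stage_counts,
                        obika = obika$stage_counts),
    n_common = targets$n_common,
    n_targets = targets$n_targets,
    n_proteins = targets$n_proteins)

  structure(list(silac = silac, obika = obika, targets = targets,
                 clusters = clusters, cluster_labels = cluster_labels,
                 motif = motif, manifest = manifest),
            class = "kinsub_run")
}

#' @export
print.kinsub_run <- function(x, ...) {
  cat("kinsub pipeline run\n")
  cat(sprintf("  in vivo: %d tested, %d class I, %d class II\n",
              nrow(x$silac$stats),
              sum(x$silac$stats$class_label == "class_I"),
              sum(x$silac$stats$class_label == "class_II")))
  cat(sprintf("  OBIKA:   %d tested, %d significant\n",
              nrow(x$obika$stats), sum(x$obika$stats$significant)))
  cat(sprintf("  bona fide targets: %d sites on %d proteins (universe %d)\n",
              x$targets$n_targets, x$targets$n_proteins, x$targets$n_common))
  invisible(x)
}
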