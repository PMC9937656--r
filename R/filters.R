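#' Filter sites on localization probability
#'
#' Retains sites whose phosphate localizes to the stated residue with
#' probability strictly greater than the threshold (strict `>`: a site at
#' exactly the threshold is dropped). Row order is preserved and retained
#' values are untouched.
#'
#' @param x a [site_table()].
#' @param threshold probability cutoff in \[0, 1\] (default 0.75).
#' @return filtered `site_table`.
#' @export
filter_localization <- function(x, threshold = 0.75) {
  stopifnot(inherits(x, "site_table"), threshold >= 0, threshold <= 1)
  keep <- x$meta$localization_probability > threshold
  log_stage("filter_localization", sum(keep))
  subset_sites(x, keep)
}

#' Filter proteins on replicate coverage
#'
#' Keeps proteins quantified in at least `min_replicates` biological
#' replicates. With `mode = "per_cell"` (default) the requirement must hold
#' within at least one design cell (arm x timepoint); with `mode = "pooled"`
#' the non-missing count is taken across all samples.
#'
#' @param x a [protein_table()].
#' @param min_replicates minimum non-missing replicate count (default 2).
#' @param mode `"per_cell"` or `"pooled"`.
#' @return filtered `protein_table`.
#' @export
filter_protein_min_replicates <- function(x, min_replicates = 2,
                                          mode = c("per_cell", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "protein_table"), min_replicates >= 1)
  if (nrow(x$values) == 0) return(x)
  if (mode == "pooled") {
    keep <- rowSums(!is.na(x$values)) >= min_replicates
  } else {
    d <- x$design
    cell <- if (all(c("arm", "timepoint_min") %in% names(d))) {
      interaction(d$arm, d$timepoint_min, drop = TRUE)
    } else if ("genotype" %in% names(d)) {
      factor(d$genotype)
    } else {
      factor(rep("all", nrow(d)))
    }
    keep <- rep(FALSE, nrow(x$values))
    for (lv in levels(cell)) {
      cols <- which(cell == lv)
      keep <- keep |
        rowSums(!is.na(x$values[, cols, drop = FALSE])) >= min_replicates
    }
  }
  log_stage("filter_protein_min_reps", sum(keep), "proteins")
  x$meta <- x$meta[keep, , drop = FALSE]
  rownames(x$meta) <- NULL
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Normalize phosphosite ratios to protein levels
#'
#' Subtracts, per sample, the protein-level log2 ratio from each site's log2
#' ratio, removing protein-abundance drift so that the remaining signal is
#' phosphorylation-specific. Sites whose protein is absent from the
#' (filtered, imputed) protein table are kept unnormalized and flagged via
#' the `protein_normalized` metadata column. Protein cells still missing
#' (imputation skipped) leave the corresponding site cells unchanged.
#'
#' @param site_tab a [site_table()].
#' @param protein_tab a [protein_table()] with the same sample axis,
#'   normally already imputed with [impute_downshift()].
#' @return `site_table` with normalized values and a `protein_normalized`
#'   flag column in `meta`.
#' @export
normalize_to_protein <- function(site_tab, protein_tab) {
  stopifnot(inherits(site_tab, "site_table"),
            inherits(protein_tab, "protein_table"))
  if (!identical(site_tab$design$sample_id, protein_tab$design$sample_id))
    stop("site and protein tables have different sample axes")
  idx <- match(site_tab$meta$protein_id, protein_tab$meta$protein_id)
  matched <- !is.na(idx)
  corr <- matrix(0, nrow = n_sites(site_tab), ncol = n_samples(site_tab))
  corr[matched, ] <- protein_tab$values[idx[matched], , drop = FALSE]
  corr[is.na(corr)] <- 0
  site_tab$values <- site_tab$values - corr
  site_tab$meta$protein_normalized <- matched
  log_stage("normalize_to_protein", sum(matched), "sites normalized")
  site_tab
}

#' Filter sites on replicate coverage within an arm
#'
#' Keeps sites quantified in at least `min_replicates` replicates in the
#' given arm, in any one of the timepoints (`mode = "any_timepoint"`, the
#' default "either 5 min or 15 min" reading) or in all of them
#' (`mode = "all_timepoints"`).
#'
#' @param x a [site_table()].
#' @param arm arm whose coverage is assessed (default `"vehicle"`).
#' @param timepoints timepoints considered (default `c(5, 15)`).
#' @param min_replicates minimum non-missing count (default 3).
#' @param mode `"any_timepoint"` or `"all_timepoints"`.
#' @return filtered `site_table`.
#' @export
filter_site_min_quantified <- function(x, arm = "vehicle",
                                       timepoints = c(5, 15),
                                       min_replicates = 3,
                                       mode = c("any_timepoint",
                                                "all_timepoints")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "site_table"))
  ok <- NULL
  for (tp in timepoints) {
    cols <- samples_for(x$design, arm = arm, timepoint = tp)
    cnt <- rowSums(!is.na(x$values[, cols, drop = FALSE]))
    pass <- cnt >= min_replicates
    ok <- if (is.null(ok)) pass
          else if (mode == "any_timepoint") ok | pass else ok & pass
  }
  log_stage("filter_site_min_quant", sum(ok))
  subset_sites(x, ok)
}

#' Filter OBIKA sites on wild-type replicate coverage
#'
#' @param x a `site_table` with an OBIKA design.
#' @param min_replicates minimum observed WT replicates (default 3).
#' @return filtered `site_table`.
#' @export
filter_obika_min_wt <- function(x, min_replicates = 3) {
  stopifnot(inherits(x, "site_table"))
  wt <- samples_for(x$design, genotype = "WT")
  keep <- rowSums(!is.na(x$values[, wt, drop = FALSE])) >= min_replicates
  log_stage("filter_obika_min_wt", sum(keep))
  subset_sites(x, keep)
}
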