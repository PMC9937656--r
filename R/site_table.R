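#' Phosphosite quantification table
#'
#' Container for a sites-by-samples matrix of log2 SILAC ratios together with
#' per-site metadata and the experiment design the sample axis is bound to.
#' One row per phosphosite; sites are keyed by (protein, position) and that
#' key must be unique.
#'
#' @param meta data.frame with columns `protein_id`, `position` (1-based),
#'   `residue` (one of S/T/Y) and `localization_probability` in \[0, 1\].
#' @param values numeric matrix, one row per site (same order as `meta`),
#'   one column per design sample. Missing values are `NA`.
#' @param design data.frame describing the samples; see [design_invivo()] and
#'   [design_obika()]. Column order of `values` must match
#'   `design$sample_id` exactly.
#' @return an object of class `site_table` with elements `meta`, `values`,
#'   `design`.
#' @export
site_table <- function(meta, values, design) {
  stopifnot(is.data.frame(meta), is.data.frame(design))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  required <- c("protein_id", "position", "residue", "localization_probability")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("meta lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(meta) != nrow(values))
    stop("meta and values disagree on the number of sites")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample IDs in design")
  if (ncol(values) != nrow(design) ||
      !identical(colnames(values), design$sample_id))
    stop("value columns must match design sample IDs exactly (same order)")
  if (any(meta$position < 1) || any(meta$position != round(meta$position)))
    stop("positions must be positive integers")
  bad_res <- setdiff(unique(meta$residue), c("S", "T", "Y"))
  if (length(bad_res) > 0)
    stop("residues outside {S, T, Y}: ", paste(bad_res, collapse = ", "))
  lp <- meta$localization_probability
  if (any(is.na(lp)) || any(lp < 0 | lp > 1))
    stop("localization_probability must lie in [0, 1]")
  keys <- site_key(meta$protein_id, meta$position)
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0)
    stop("duplicated site key(s): ", paste(unique(dup), collapse = ", "))
  if (any(is.infinite(values)))
    stop("values must be finite or missing")
  rownames(values) <- keys
  rownames(meta) <- NULL
  structure(list(meta = meta, values = values, design = design),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Number of sites / samples in a table
#' @param x a `site_table` or `protein_table`.
#' @return integer scalar.
#' @export
n_sites <- function(x) nrow(x$values)

#' @rdname n_sites
#' @export
n_samples <- function(x) ncol(x$values)

#' Protein quantification table
#'
#' Protein-level analogue of [site_table()]: one row per protein, same sample
#' layout as the site table it accompanies.
#'
#' @param protein_id character vector of unique protein IDs.
#' @param values numeric matrix, rows in `protein_id` order, columns matching
#'   `design$sample_id`.
#' @param design experiment design data.frame.
#' @return an object of class `protein_table`.
#' @export
protein_table <- function(protein_id, values, design) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(protein_id))
    stop("duplicated protein IDs")
  if (nrow(values) != length(protein_id))
    stop("protein_id and values disagree on the number of proteins")
  if (ncol(values) != nrow(design) ||
      !identical(colnames(values), design$sample_id))
    stop("value columns must match design sample IDs exactly (same order)")
  rownames(values) <- protein_id
  structure(list(meta = data.frame(protein_id = protein_id,
                                   stringsAsFactors = FALSE),
                 values = values, design = design),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("protein_table: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Standard in vivo SILAC experiment design
#'
#' Samples are per-arm log2 ratios of starved versus unstarved cells: two
#' arms (vehicle DMSO, kinase-inhibitor) crossed with two starvation
#' timepoints and `n_replicates` biological replicates.
#'
#' @param n_replicates replicates per arm x timepoint cell (default 5).
#' @param timepoints starvation timepoints in minutes (default `c(5, 15)`).
#' @param arms arm labels (default `c("vehicle", "inhibitor")`).
#' @return data.frame with columns `sample_id`, `arm`, `timepoint_min`,
#'   `replicate`.
#' @export
design_invivo <- function(n_replicates = 5, timepoints = c(5, 15),
                          arms = c("vehicle", "inhibitor")) {
  g <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint_min = timepoints, arm = arms,
                   stringsAsFactors = FALSE)
  g <- g[, c("arm", "timepoint_min", "replicate")]
  g$sample_id <- sprintf("%s_%dmin_r%d", g$arm, g$timepoint_min, g$replicate)
  g[, c("sample_id", "arm", "timepoint_min", "replicate")]
}

#' Standard OBIKA experiment design
#'
#' On-beads in vitro kinase assay samples: immobilized proteome incubated
#' with purified wild-type kinase versus a kinase-dead mutant.
#'
#' @param n_replicates replicates per genotype (default 5).
#' @return data.frame with columns `sample_id`, `genotype`, `replicate`.
#' @export
design_obika <- function(n_replicates = 5) {
  g <- expand.grid(replicate = seq_len(n_replicates),
                   genotype = c("WT", "kinase_dead"), stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_r%d",
                         ifelse(g$genotype == "WT", "WT", "dead"), g$replicate)
  g[, c("sample_id", "genotype", "replicate")]
}

#' Select sample IDs from a design
#'
#' @param design a design data.frame.
#' @param arm,timepoint,genotype optional filters; omitted filters match all.
#' @return character vector of sample IDs, in design order.
#' @export
samples_for <- function(design, arm = NULL, timepoint = NULL, genotype = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(arm)) {
    if (!all(arm %in% design$arm)) stop("unknown arm: ", paste(arm, collapse = ","))
    keep <- keep & design$arm %in% arm
  }
  if (!is.null(timepoint)) {
    if (!all(timepoint %in% design$timepoint_min))
      stop("unknown timepoint: ", paste(timepoint, collapse = ","))
    keep <- keep & design$timepoint_min %in% timepoint
  }
  if (!is.null(genotype)) {
    if (!all(genotype %in% design$genotype))
      stop("unknown genotype: ", paste(genotype, collapse = ","))
    keep <- keep & design$genotype %in% genotype
  }
  design$sample_id[keep]
}

# row-subset helper shared by all filters; never alters retained values
subset_sites <- function(x, keep) {
  x$meta <- x$meta[keep, , drop = FALSE]
  rownames(x$meta) <- NULL
  x$values <- x$values[keep, , drop = FALSE]
  x
}
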