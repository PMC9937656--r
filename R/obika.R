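#' Process the in vitro kinase-assay (OBIKA) branch
#'
#' Filters sites to those quantified in at least `min_wt` wild-type
#' replicates, applies the OBIKA imputation policy
#' ([impute_obika_policy()]), tests WT versus kinase-dead with a Student's
#' t-test, and adjusts with Benjamini-Hochberg across the retained sites.
#' A site is significant when `q <= alpha` (`<=` is the in vitro
#' convention) with a positive WT - dead difference: a kinase cannot remove
#' phosphate, so only gains count.
#'
#' @param x a [site_table()] with an OBIKA design.
#' @param alpha FDR level (default 0.05).
#' @param min_wt minimum observed WT replicates (default 3).
#' @param params [impute_params()] for the down-shift branch.
#' @param t_variant `"student"` (default) or `"welch"`.
#' @param fdr_strict use strict `<` instead of `<=` (default FALSE).
#' @return data.frame, one row per retained site: site key and metadata,
#'   `n_wt_obs`, `n_dead_obs` (pre-imputation counts), `mean_difference`
#'   (WT - dead), `statistic`, `p_value`, `q_value`, `significant`,
#'   `impute_branch`.
#' @export
process_obika <- function(x, alpha = 0.05, min_wt = 3,
                          params = impute_params(),
                          t_variant = c("student", "welch"),
                          fdr_strict = FALSE) {
  t_variant <- match.arg(t_variant)
  stopifnot(inherits(x, "site_table"))
  if (!all(c("WT", "kinase_dead") %in% x$design$genotype))
    stop("OBIKA design must contain WT and kinase_dead genotypes")
  wt_cols <- samples_for(x$design, genotype = "WT")
  dead_cols <- samples_for(x$design, genotype = "kinase_dead")

  x <- filter_obika_min_wt(x, min_replicates = min_wt)
  n_wt_obs <- rowSums(!is.na(x$values[, wt_cols, drop = FALSE]))
  n_dead_obs <- rowSums(!is.na(x$values[, dead_cols, drop = FALSE]))
  x <- impute_obika_policy(x, params)
  tt <- matrix_t_test(x$values, wt_cols, dead_cols, variant = t_variant)
  q <- bh_fdr(tt$p_value)
  cmp <- if (fdr_strict) `<` else `<=`
  sig <- !is.na(q) & cmp(q, alpha) & !is.na(tt$mean_difference) &
    tt$mean_difference > 0
  data.frame(
    site_key = site_key(x$meta$protein_id, x$meta$position),
    protein_id = x$meta$protein_id,
    position = x$meta$position,
    residue = x$meta$residue,
    n_wt_obs = n_wt_obs, n_dead_obs = n_dead_obs,
    mean_difference = tt$mean_difference,
    statistic = tt$statistic, p_value = tt$p_value, q_value = q,
    significant = sig,
    impute_branch = attr(x, "obika_branch"),
    stringsAsFactors = FALSE)
}

#' Intersect in vivo and in vitro significant sites
#'
#' The common universe is the set of site keys retained (quantified and
#' filtered) by both branches. Bona fide targets are sites that are class I
#' or class II in vivo and significant in the OBIKA branch. Each bona fide
#' site carries its timing category ([timing_category()]).
#'
#' @param invivo_stats output of [silac_stats()].
#' @param obika_stats output of [process_obika()].
#' @param alpha_fdr FDR level used for the timing categories (default 0.05).
#' @return object of class `target_set`: list with `targets` (data.frame),
#'   `n_common` (common-universe size), `n_targets`, `n_proteins`, and the
#'   significant key sets of each branch.
#' @export
intersect_targets <- function(invivo_stats, obika_stats, alpha_fdr = 0.05) {
  common <- intersect(invivo_stats$site_key, obika_stats$site_key)
  if (length(common) == 0)
    warning("no commonly quantified sites between the two branches")
  iv <- invivo_stats[match(common, invivo_stats$site_key), , drop = FALSE]
  ob <- obika_stats[match(common, obika_stats$site_key), , drop = FALSE]
  iv_sig <- iv$class_label %in% c("class_I", "class_II")
  bona <- iv_sig & ob$significant
  targets <- data.frame(
    site_key = common[bona],
    protein_id = iv$protein_id[bona],
    position = iv$position[bona],
    residue = iv$residue[bona],
    class_label = iv$class_label[bona],
    timing = timing_category(iv[bona, , drop = FALSE], alpha_fdr),
    invivo_effect = iv$effect[bona],
    obika_mean_difference = ob$mean_difference[bona],
    obika_q = ob$q_value[bona],
    stringsAsFactors = FALSE)
  structure(list(targets = targets,
                 n_common = length(common),
                 n_targets = nrow(targets),
                 n_proteins = length(unique(targets$protein_id)),
                 invivo_significant =
                   invivo_stats$site_key[invivo_stats$class_label %in%
                                           c("class_I", "class_II")],
                 obika_significant =
                   obika_stats$site_key[obika_stats$significant]),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf(paste0("target_set: %d bona fide sites on %d proteins ",
                     "(common universe %d sites)\n"),
              x$n_targets, x$n_proteins, x$n_common))
  if (x$n_targets > 0) print(table(x$targets$timing))
  invisible(x)
}

#' Overlap of a target set with published reference site lists
#'
#' For each reference list, reports the Venn-style partition against the
#' target list: sizes of the intersection and the two set differences, and
#' overlap fractions relative to each side.
#'
#' @param target_keys character vector of site keys (or a `target_set`).
#' @param reference_lists named list of character vectors of site keys
#'   (see [read_site_list()]).
#' @return data.frame, one row per reference list: `reference`, `n_targets`,
#'   `n_reference`, `n_overlap`, `n_targets_only`, `n_reference_only`,
#'   `frac_of_reference`, `frac_of_targets`.
#' @export
compare_with_published <- function(target_keys, reference_lists) {
  if (inherits(target_keys, "target_set"))
    target_keys <- target_keys$targets$site_key
  target_keys <- unique(target_keys)
  if (is.null(names(reference_lists)) || any(names(reference_lists) == ""))
    names(reference_lists) <- paste0("reference_", seq_along(reference_lists))
  rows <- lapply(names(reference_lists), function(nm) {
    ref <- unique(reference_lists[[nm]])
    ov <- intersect(target_keys, ref)
    data.frame(reference = nm,
               n_targets = length(target_keys),
               n_reference = length(ref),
               n_overlap = length(ov),
               n_targets_only = length(setdiff(target_keys, ref)),
               n_reference_only = length(setdiff(ref, target_keys)),
               frac_of_reference = if (length(ref) > 0)
                 length(ov) / length(ref) else NA_real_,
               frac_of_targets = if (length(target_keys) > 0)
                 length(ov) / length(target_keys) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
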