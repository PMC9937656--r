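#' Per-site SILAC differential statistics
#'
#' Computes, for every site of an in vivo table: the combined random-effects
#' starvation effect over the vehicle arm (both timepoints, replicates as
#' random intercepts; [fit_random_effects_matrix()]); per-timepoint Student's
#' t-tests of vehicle versus inhibitor; Benjamini-Hochberg q-values (by
#' default within each timepoint's test family); and the class I/II label
#' (see [classify_sites()]).
#'
#' @param x a [site_table()] with an in vivo design, normally the output of
#'   the filtering/normalization/imputation stages.
#' @param alpha_re significance level for the random-effects criterion
#'   (default 0.05).
#' @param alpha_fdr FDR level for the inhibitor-contrast criterion
#'   (default 0.05).
#' @param t_variant `"student"` (default, pooled variance) or `"welch"`.
#' @param timepoint_family `"separate"` (default; BH within each timepoint)
#'   or `"pooled"` (one family across both timepoints).
#' @param arm_treated,arm_control arm labels (defaults `"vehicle"`,
#'   `"inhibitor"`).
#' @return data.frame (one row per site): site key and metadata, random
#'   effects fields (`effect`, `ci_low`, `ci_high`, `tau2`, `re_p`,
#'   `n_obs`), `t_p_5`, `t_p_15`, `q_5`, `q_15`, `direction_5`,
#'   `direction_15`, `class_label`, `label_reason`.
#' @export
silac_stats <- function(x, alpha_re = 0.05, alpha_fdr = 0.05,
                        t_variant = c("student", "welch"),
                        timepoint_family = c("separate", "pooled"),
                        arm_treated = "vehicle", arm_control = "inhibitor") {
  t_variant <- match.arg(t_variant)
  timepoint_family <- match.arg(timepoint_family)
  stopifnot(inherits(x, "site_table"))
  d <- x$design
  tps <- sort(unique(d$timepoint_min))
  stopifnot(length(tps) == 2)

  veh_cols <- samples_for(d, arm = arm_treated)
  veh_rep <- d$replicate[match(veh_cols, d$sample_id)]
  re <- fit_random_effects_matrix(x$values[, veh_cols, drop = FALSE], veh_rep)

  tt <- lapply(tps, function(tp) {
    matrix_t_test(x$values,
                  samples_for(d, arm = arm_treated, timepoint = tp),
                  samples_for(d, arm = arm_control, timepoint = tp),
                  variant = t_variant)
  })
  p5 <- tt[[1]]$p_value; p15 <- tt[[2]]$p_value
  if (timepoint_family == "separate") {
    q5 <- bh_fdr(p5); q15 <- bh_fdr(p15)
  } else {
    q <- bh_fdr(c(p5, p15))
    q5 <- q[seq_along(p5)]
    q15 <- q[length(p5) + seq_along(p15)]
  }

  stats <- data.frame(
    site_key = site_key(x$meta$protein_id, x$meta$position),
    protein_id = x$meta$protein_id,
    position = x$meta$position,
    residue = x$meta$residue,
    effect = re$effect, ci_low = re$ci_low, ci_high = re$ci_high,
    tau2 = re$tau2, re_p = re$p_value, n_obs = re$n_obs,
    t_p_5 = p5, t_p_15 = p15, q_5 = q5, q_15 = q15,
    direction_5 = sign(tt[[1]]$mean_difference),
    direction_15 = sign(tt[[2]]$mean_difference),
    stringsAsFactors = FALSE)
  classify_sites(stats, alpha_re = alpha_re, alpha_fdr = alpha_fdr)
}

#' Classify sites into class I / class II target candidates
#'
#' Criterion (i): significant starvation upregulation under the
#' random-effects model (`re_p < alpha_re` and positive effect).
#' Criterion (ii): significant kinase-activity dependence at either
#' timepoint (`q < alpha_fdr` with positive vehicle-minus-inhibitor
#' difference; strict `<` by default). `class_I` requires both criteria,
#' `class_II` only criterion (ii); otherwise `not_significant`. Sites whose
#' inputs are missing are labeled `missing` with a reason code. Only
#' upregulation counts: the kinase adds phosphate.
#'
#' @param stats data.frame with columns `re_p`, `effect`, `q_5`, `q_15`,
#'   `direction_5`, `direction_15` (as produced by [silac_stats()]).
#' @param alpha_re random-effects significance level (default 0.05).
#' @param alpha_fdr FDR level for the inhibitor contrast (default 0.05).
#' @param fdr_strict use strict `<` for the FDR comparison (default TRUE,
#'   the in vivo convention; OBIKA uses `<=`).
#' @return `stats` with `class_label` and `label_reason` columns
#'   (re)computed.
#' @export
classify_sites <- function(stats, alpha_re = 0.05, alpha_fdr = 0.05,
                           fdr_strict = TRUE) {
  cmp <- if (fdr_strict) `<` else `<=`
  sig_q <- function(q, dir) !is.na(q) & cmp(q, alpha_fdr) & !is.na(dir) & dir > 0
  crit_i <- !is.na(stats$re_p) & stats$re_p < alpha_re & stats$effect > 0
  crit_ii <- sig_q(stats$q_5, stats$direction_5) |
             sig_q(stats$q_15, stats$direction_15)
  no_t <- is.na(stats$q_5) & is.na(stats$q_15)
  label <- ifelse(crit_i & crit_ii, "class_I",
           ifelse(crit_ii, "class_II", "not_significant"))
  label[no_t] <- "missing"
  reason <- rep("", nrow(stats))
  reason[no_t] <- "no_inhibitor_contrast"
  reason[is.na(stats$re_p) & !no_t] <- "no_random_effects_fit"
  stats$class_label <- label
  stats$label_reason <- reason
  stats
}

#' Timing category of significant sites
#'
#' Classifies each site by the timepoint(s) at which the inhibitor contrast
#' is significant and upregulated: `both`, `early_only` (5 min),
#' `late_only` (15 min), or `none`.
#'
#' @param stats data.frame with `q_5`, `q_15`, `direction_5`, `direction_15`.
#' @param alpha_fdr FDR level (default 0.05).
#' @param fdr_strict strict `<` comparison (default TRUE).
#' @return character vector of categories, one per row of `stats`.
#' @export
timing_category <- function(stats, alpha_fdr = 0.05, fdr_strict = TRUE) {
  cmp <- if (fdr_strict) `<` else `<=`
  s5 <- !is.na(stats$q_5) & cmp(stats$q_5, alpha_fdr) &
    !is.na(stats$direction_5) & stats$direction_5 > 0
  s15 <- !is.na(stats$q_15) & cmp(stats$q_15, alpha_fdr) &
    !is.na(stats$direction_15) & stats$direction_15 > 0
  ifelse(s5 & s15, "both",
         ifelse(s5, "early_only", ifelse(s15, "late_only", "none")))
}
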