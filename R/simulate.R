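#' Simulation configuration
#'
#' Parameterizes the synthetic study: an in vivo SILAC design (two arms x
#' two starvation timepoints x `n_replicates` per-site log2 ratios versus
#' unstarved control) with planted kinase-target sites, a parallel OBIKA
#' design (wild-type versus kinase-dead kinase), protein-level drift,
#' MNAR/MCAR missingness, localization probabilities, and consensus-motif
#' planting in the generated proteome. Values are simulated directly on the
#' log2-ratio scale, which is the scale the whole pipeline operates on.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein mean sites per protein (counts are
#'   `1 + Poisson(sites_per_protein - 1)`).
#' @param n_targets number of planted in vivo responder sites.
#' @param effect_size_mean,effect_size_sd log2 starvation effect of planted
#'   targets (clamped below at `min_effect`).
#' @param min_effect lower clamp for planted effects (targets are
#'   upregulated by construction).
#' @param inhibitor_attenuation fraction of the effect remaining under
#'   kinase inhibition (0 = full inhibition).
#' @param kinetic_mix proportions of early-transient / sustained / late
#'   kinetics among targets; must sum to 1.
#' @param transient_factor fraction of the effect present at the "off"
#'   timepoint of early/late kinetics (default 0.25).
#' @param noise_sd replicate residual sd (log2 units), > 0.
#' @param replicate_tau between-replicate random-intercept sd, shared across
#'   the two timepoints within an arm (matching the random-effects model).
#' @param protein_drift_sd protein-level log2 drift sd (what protein
#'   normalization removes).
#' @param protein_noise_sd measurement noise of the protein-level table.
#' @param n_replicates biological replicates per design cell.
#' @param timepoints starvation timepoints in minutes.
#' @param mnar_slope,mnar_midpoint logistic intensity-dependent missingness:
#'   `P(missing) = plogis(-(value - midpoint) * slope)`; slope 0 disables
#'   MNAR.
#' @param mcar_rate completely-at-random missingness fraction.
#' @param loc_prob_alpha,loc_prob_beta Beta parameters of the localization
#'   probability distribution.
#' @param prop_direct fraction of targets that are direct substrates
#'   (OBIKA-positive).
#' @param obika_effect_mean,obika_effect_sd planted WT - kinase-dead log2
#'   difference for direct substrates.
#' @param obika_dead_center latent kinase-dead level of direct substrates
#'   (below baseline: the site barely exists without active kinase, which
#'   concentrates MNAR missingness in those cells).
#' @param obika_noise_sd residual sd of OBIKA values.
#' @param motif_fidelity per-position probability that a motif-carrying
#'   target window has the consensus residue; scalar or length-3 vector for
#'   positions (-3, -4, +4).
#' @param flank flanking length used when sizing generated proteins.
#' @param seed master integer seed; all generator streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 400, sites_per_protein = 3,
                       n_targets = 100,
                       effect_size_mean = 2, effect_size_sd = 0.5,
                       min_effect = 0.25,
                       inhibitor_attenuation = 0.1,
                       kinetic_mix = c(early = 0.2, sustained = 0.6,
                                       late = 0.2),
                       transient_factor = 0.25,
                       noise_sd = 0.5, replicate_tau = 0.3,
                       protein_drift_sd = 0.4, protein_noise_sd = 0.1,
                       n_replicates = 5, timepoints = c(5, 15),
                       mnar_slope = 0.8, mnar_midpoint = -2.5,
                       mcar_rate = 0.02,
                       loc_prob_alpha = 9, loc_prob_beta = 1,
                       prop_direct = 0.8,
                       obika_effect_mean = 3, obika_effect_sd = 0.5,
                       obika_dead_center = -2, obika_noise_sd = 0.5,
                       motif_fidelity = 0.9, flank = 7, seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
      stop(nm, " must be a non-negative integer")
  }
  chk_frac <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0 | x > 1))
      stop(nm, " must lie in [0, 1]")
  }
  chk_count(n_proteins, "n_proteins")
  chk_count(n_targets, "n_targets")
  chk_count(n_replicates, "n_replicates")
  if (n_proteins < 1) stop("n_proteins must be positive")
  if (sites_per_protein < 1) stop("sites_per_protein must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  chk_frac(inhibitor_attenuation, "inhibitor_attenuation")
  chk_frac(mcar_rate, "mcar_rate")
  chk_frac(prop_direct, "prop_direct")
  chk_frac(motif_fidelity, "motif_fidelity")
  if (length(kinetic_mix) != 3 || abs(sum(kinetic_mix) - 1) > 1e-8)
    stop("kinetic_mix must be 3 proportions summing to 1")
  names(kinetic_mix) <- c("early", "sustained", "late")
  if (length(motif_fidelity) == 1) motif_fidelity <- rep(motif_fidelity, 3)
  if (length(motif_fidelity) != 3)
    stop("motif_fidelity must have length 1 or 3 (positions -3, -4, +4)")
  names(motif_fidelity) <- c("minus3", "minus4", "plus4")
  structure(list(
    n_proteins = as.integer(n_proteins),
    sites_per_protein = sites_per_protein,
    n_targets = as.integer(n_targets),
    effect_size_mean = effect_size_mean, effect_size_sd = effect_size_sd,
    min_effect = min_effect,
    inhibitor_attenuation = inhibitor_attenuation,
    kinetic_mix = kinetic_mix, transient_factor = transient_factor,
    noise_sd = noise_sd, replicate_tau = replicate_tau,
    protein_drift_sd = protein_drift_sd,
    protein_noise_sd = protein_noise_sd,
    n_replicates = as.integer(n_replicates), timepoints = timepoints,
    mnar_slope = mnar_slope, mnar_midpoint = mnar_midpoint,
    mcar_rate = mcar_rate,
    loc_prob_alpha = loc_prob_alpha, loc_prob_beta = loc_prob_beta,
    prop_direct = prop_direct,
    obika_effect_mean = obika_effect_mean,
    obika_effect_sd = obika_effect_sd,
    obika_dead_center = obika_dead_center,
    obika_noise_sd = obika_noise_sd,
    motif_fidelity = motif_fidelity,
    flank = as.integer(flank), seed = as.integer(seed)),
    class = "sim_config")
}

# intensity-dependent + completely-at-random missingness on latent values
apply_missingness <- function(latent, cfg) {
  p_mnar <- if (cfg$mnar_slope > 0)
    stats::plogis(-(latent - cfg$mnar_midpoint) * cfg$mnar_slope) else 0
  miss <- matrix(stats::runif(length(latent)) < p_mnar, nrow = nrow(latent)) |
    matrix(stats::runif(length(latent)) < cfg$mcar_rate, nrow = nrow(latent))
  out <- latent
  out[miss] <- NA_real_
  out
}

#' Generate the in vivo SILAC dataset with ground truth
#'
#' Simulates per-site log2 ratios versus unstarved control for two arms
#' (vehicle, inhibitor) x two timepoints x `n_replicates`, as
#' `true_effect * arm_attenuation + replicate intercept + protein drift +
#' residual noise`, plus a matching protein-level table (drift + measurement
#' noise; site effects never leak into it). Missingness (MNAR logistic on
#' the latent value, then MCAR) is applied after value generation;
#' localization probabilities are Beta draws. The ground-truth ledger and
#' the latent (pre-missingness) matrices are returned for testing.
#'
#' @param config a [sim_config()].
#' @return list of class `invivo_sim`: `sites` ([site_table()]), `proteins`
#'   ([protein_table()]), `design`, `truth` (data.frame), `latent` (list of
#'   the two latent matrices).
#' @export
generate_invivo <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(stream_seed(cfg$seed, "invivo"))

  n_per <- 1L + stats::rpois(cfg$n_proteins, max(0, cfg$sites_per_protein - 1))
  total <- sum(n_per)
  if (cfg$n_targets > total)
    stop(sprintf("n_targets (%d) exceeds total sites (%d)",
                 cfg$n_targets, total))
  protein_ids <- sprintf("P%05d", seq_len(cfg$n_proteins))
  site_protein <- rep(protein_ids, n_per)
  position <- unlist(lapply(n_per, function(k) {
    sort(sample(seq(2L, 30L * k + 10L), k))
  }), use.names = FALSE)
  loc_prob <- stats::rbeta(total, cfg$loc_prob_alpha, cfg$loc_prob_beta)

  targets <- sort(sample.int(total, cfg$n_targets))
  is_target <- seq_len(total) %in% targets
  residue <- ifelse(is_target,
                    sample(c("S", "T"), total, TRUE, prob = c(0.75, 0.25)),
                    sample(c("S", "T", "Y"), total, TRUE,
                           prob = c(0.65, 0.3, 0.05)))

  kinetic <- rep("none", total)
  kinetic[targets] <- sample(names(cfg$kinetic_mix), cfg$n_targets,
                             replace = TRUE, prob = cfg$kinetic_mix)
  base_eff <- numeric(total)
  base_eff[targets] <- pmax(cfg$min_effect,
                            stats::rnorm(cfg$n_targets, cfg$effect_size_mean,
                                         cfg$effect_size_sd))
  effect_5 <- base_eff * ifelse(kinetic == "late", cfg$transient_factor, 1)
  effect_15 <- base_eff * ifelse(kinetic == "early", cfg$transient_factor, 1)
  effect_5[!is_target] <- 0
  effect_15[!is_target] <- 0

  design <- design_invivo(cfg$n_replicates, cfg$timepoints)
  ns <- nrow(design)
  drift <- matrix(stats::rnorm(cfg$n_proteins * ns, 0, cfg$protein_drift_sd),
                  nrow = cfg$n_proteins,
                  dimnames = list(protein_ids, design$sample_id))
  latent <- matrix(0, total, ns, dimnames = list(NULL, design$sample_id))
  for (arm in unique(design$arm)) {
    atten <- if (arm == "inhibitor") cfg$inhibitor_attenuation else 1
    b <- matrix(stats::rnorm(total * cfg$n_replicates, 0, cfg$replicate_tau),
                total, cfg$n_replicates)
    for (tp in cfg$timepoints) {
      eff <- if (tp == cfg$timepoints[1]) effect_5 else effect_15
      for (r in seq_len(cfg$n_replicates)) {
        col <- sprintf("%s_%dmin_r%d", arm, tp, r)
        latent[, col] <- eff * atten + b[, r] +
          drift[site_protein, col] +
          stats::rnorm(total, 0, cfg$noise_sd)
      }
    }
  }
  prot_latent <- drift + matrix(stats::rnorm(length(drift), 0,
                                             cfg$protein_noise_sd),
                                nrow = nrow(drift))

  vals <- apply_missingness(latent, cfg)
  prot_vals <- apply_missingness(prot_latent, cfg)

  is_sub <- rep(FALSE, total)
  n_sub <- round(cfg$prop_direct * cfg$n_targets)
  if (n_sub > 0)
    is_sub[targets[sample.int(length(targets), n_sub)]] <- TRUE
  obika_eff <- numeric(total)
  obika_eff[is_sub] <- pmax(0.5, stats::rnorm(sum(is_sub),
                                              cfg$obika_effect_mean,
                                              cfg$obika_effect_sd))

  meta <- data.frame(protein_id = site_protein, position = position,
                     residue = residue, localization_probability = loc_prob,
                     stringsAsFactors = FALSE)
  truth <- data.frame(
    site_key = site_key(site_protein, position),
    protein_id = site_protein, position = position, residue = residue,
    is_invivo_responder = is_target,
    is_direct_substrate = is_sub,
    effect_5 = effect_5, effect_15 = effect_15,
    kinetic_class = kinetic,
    obika_effect = obika_eff,
    carries_motif = is_sub,
    stringsAsFactors = FALSE)

  structure(list(
    sites = site_table(meta, vals, design),
    proteins = protein_table(protein_ids, prot_vals, design),
    design = design,
    truth = truth,
    latent = list(sites = latent, proteins = prot_latent)),
    class = "invivo_sim")
}

#' Generate the OBIKA dataset for an existing ground truth
#'
#' Simulates WT and kinase-dead log2 intensities on the same site universe
#' as the in vivo table. Direct substrates have the planted WT - dead
#' difference (`obika_effect` from the truth ledger), with kinase-dead
#' values at a low latent level (`obika_dead_center`), so the logistic MNAR
#' mechanism concentrates missingness exactly where phosphorylation is
#' absent; all other sites sit at baseline 0 in both genotypes.
#'
#' @param config the same [sim_config()] used for [generate_invivo()].
#' @param truth the `truth` data.frame from [generate_invivo()].
#' @return list of class `obika_sim`: `sites` ([site_table()]), `design`,
#'   `latent`.
#' @export
generate_obika <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  if (!all(c("site_key", "is_direct_substrate", "obika_effect") %in%
           names(truth)))
    stop("truth is not a generate_invivo ground-truth ledger")
  cfg <- config
  set.seed(stream_seed(cfg$seed, "obika"))
  total <- nrow(truth)
  design <- design_obika(cfg$n_replicates)
  wt_cols <- samples_for(design, genotype = "WT")
  dead_cols <- samples_for(design, genotype = "kinase_dead")

  center_dead <- ifelse(truth$is_direct_substrate, cfg$obika_dead_center, 0)
  center_wt <- center_dead + ifelse(truth$is_direct_substrate,
                                    truth$obika_effect, 0)
  latent <- matrix(0, total, nrow(design),
                   dimnames = list(NULL, design$sample_id))
  for (col in wt_cols)
    latent[, col] <- center_wt + stats::rnorm(total, 0, cfg$obika_noise_sd)
  for (col in dead_cols)
    latent[, col] <- center_dead + stats::rnorm(total, 0, cfg$obika_noise_sd)
  vals <- apply_missingness(latent, cfg)

  meta <- data.frame(protein_id = truth$protein_id,
                     position = truth$position,
                     residue = truth$residue,
                     localization_probability =
                       stats::rbeta(total, cfg$loc_prob_alpha,
                                    cfg$loc_prob_beta),
                     stringsAsFactors = FALSE)
  structure(list(sites = site_table(meta, vals, design),
                 design = design, latent = latent),
            class = "obika_sim")
}

#' Generate a proteome with planted consensus motifs
#'
#' Random amino-acid sequences (uniform composition) long enough for every
#' site plus the flank, with the phosphoacceptor residue placed at each site
#' position. Motif-carrying sites (direct substrates in the truth ledger)
#' receive, independently per position with probability `motif_fidelity`,
#' Arg at -3, Arg or Lys at -4, and Leu at +4 relative to the
#' phosphoacceptor; positions colliding with another phosphosite of the
#' same protein are left untouched.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` data.frame from [generate_invivo()].
#' @return a `Biostrings::AAStringSet` named by protein ID.
#' @export
generate_proteome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(stream_seed(cfg$seed, "proteome"))
  prot_ids <- unique(truth$protein_id)
  seqs <- character(length(prot_ids))
  names(seqs) <- prot_ids
  site_pos_by_prot <- split(truth$position, truth$protein_id)
  residue_by_prot <- split(truth$residue, truth$protein_id)
  fid <- cfg$motif_fidelity
  for (i in seq_along(prot_ids)) {
    pid <- prot_ids[i]
    pos <- site_pos_by_prot[[pid]]
    len <- max(30L, max(pos) + cfg$flank + 5L)
    chars <- sample(AA20, len, replace = TRUE)
    chars[pos] <- residue_by_prot[[pid]]
    carriers <- truth$position[truth$protein_id == pid & truth$carries_motif]
    for (p in carriers) {
      plant <- list(
        list(off = -3L, res = "R", pr = fid[["minus3"]]),
        list(off = -4L, res = sample(c("R", "K"), 1), pr = fid[["minus4"]]),
        list(off = +4L, res = "L", pr = fid[["plus4"]]))
      for (pl in plant) {
        at <- p + pl$off
        if (at < 1L || at > len || at %in% pos) next
        if (stats::runif(1) < pl$pr) chars[at] <- pl$res
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  Biostrings::AAStringSet(seqs)
}
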