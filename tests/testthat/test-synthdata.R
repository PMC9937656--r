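test_that("generation is reproducible and conserves the site bookkeeping", {
  cfg <- sim_config(n_proteins = 80, n_targets = 20, seed = 31)
  a <- generate_invivo(cfg)
  b <- generate_invivo(cfg)
  expect_identical(a$sites$values, b$sites$values)
  expect_identical(a$proteins$values, b$proteins$values)
  expect_identical(a$truth, b$truth)
  # conservation: one row per generated site, keys unique and aligned
  expect_equal(n_sites(a$sites), nrow(a$truth))
  expect_false(anyDuplicated(a$truth$site_key) > 0)
  expect_identical(rownames(a$sites$values), a$truth$site_key)
  # every protein in the site table has a protein-level row
  expect_true(all(a$sites$meta$protein_id %in% a$proteins$meta$protein_id))
  # OBIKA truth/table alignment
  ob <- generate_obika(cfg, a$truth)
  expect_identical(rownames(ob$sites$values), a$truth$site_key)
  expect_error(generate_obika(cfg, data.frame(x = 1)), "ground-truth")
})

test_that("null configuration produces zero effects and centered ratios", {
  cfg <- sim_config(n_proteins = 200, n_targets = 0, noise_sd = 0.3,
                    seed = 32)
  sim <- generate_invivo(cfg)
  expect_true(all(sim$truth$effect_5 == 0))
  expect_true(all(sim$truth$effect_15 == 0))
  expect_true(all(sim$truth$kinetic_class == "none"))
  # MNAR removes low cells, shifting the observed mean slightly up;
  # the latent (pre-missingness) values are centered at zero
  expect_lt(abs(mean(sim$latent$sites)), 0.05)
  expect_lt(abs(mean(sim$sites$values, na.rm = TRUE)), 0.15)
})

test_that("full inhibition leaves planted targets at baseline in the inhibitor arm", {
  cfg <- sim_config(n_proteins = 300, n_targets = 100,
                    inhibitor_attenuation = 0, protein_drift_sd = 0,
                    mnar_slope = 0, mcar_rate = 0, seed = 33)
  sim <- generate_invivo(cfg)
  inh <- samples_for(sim$design, arm = "inhibitor")
  tgt <- sim$truth$is_invivo_responder
  m <- mean(sim$sites$values[tgt, inh])
  # replicate intercept + noise only: mean 0 within ~3 SE
  se <- sd(sim$sites$values[tgt, inh]) / sqrt(sum(tgt) * length(inh) / 2)
  expect_lt(abs(m), 3 * se + 0.02)
})

test_that("planted effect recovered at its nominal size (sampling-distribution oracle)", {
  mk <- function(seed) sim_config(n_proteins = 200, n_targets = 50,
                                  effect_size_mean = 2.0, effect_size_sd = 0,
                                  kinetic_mix = c(0, 1, 0), noise_sd = 0.5,
                                  mnar_slope = 0, mcar_rate = 0, seed = seed)
  stat <- function(seed) {
    sim <- generate_invivo(mk(seed))
    veh <- samples_for(sim$design, arm = "vehicle")
    tgt <- sim$truth$is_invivo_responder
    mean(sim$sites$values[tgt, veh]) - mean(sim$sites$values[!tgt, veh])
  }
  # Monte-Carlo oracle: sampling sd of the statistic over 100 seeds
  draws <- vapply(101:200, stat, 0)
  expect_lt(abs(stat(1) - 2.0), 3 * sd(draws))
  expect_lt(abs(mean(draws) - 2.0), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("planted-effect regression on complete data has slope 1", {
  cfg <- sim_config(n_proteins = 400, n_targets = 150, protein_drift_sd = 0,
                    mnar_slope = 0, mcar_rate = 0, seed = 34)
  sim <- generate_invivo(cfg)
  veh5 <- samples_for(sim$design, arm = "vehicle", timepoint = 5)
  y <- rowMeans(sim$sites$values[, veh5])
  fit <- summary(lm(y ~ sim$truth$effect_5))
  slope <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se)
})

test_that("missingness mechanisms behave as configured", {
  # disabled -> no missing cells
  cfg0 <- sim_config(n_proteins = 100, n_targets = 10, mnar_slope = 0,
                     mcar_rate = 0, seed = 35)
  sim0 <- generate_invivo(cfg0)
  expect_false(anyNA(sim0$sites$values))
  expect_false(anyNA(generate_obika(cfg0, sim0$truth)$sites$values))
  # MNAR: missing cells have lower latent values than observed cells
  cfg1 <- sim_config(n_proteins = 300, n_targets = 30, mnar_slope = 1,
                     mcar_rate = 0, seed = 36)
  sim1 <- generate_invivo(cfg1)
  miss <- is.na(sim1$sites$values)
  expect_gt(mean(miss), 0.01)
  expect_lt(mean(sim1$latent$sites[miss]), mean(sim1$latent$sites[!miss]))
})

test_that("OBIKA generator plants detectable substrate differences", {
  cfg <- sim_config(n_proteins = 150, n_targets = 40, prop_direct = 0.8,
                    obika_effect_mean = 3, obika_effect_sd = 0,
                    obika_noise_sd = 0.5, mnar_slope = 0, mcar_rate = 0,
                    seed = 37)
  sim <- generate_invivo(cfg)
  ob <- generate_obika(cfg, sim$truth)
  wt <- samples_for(ob$design, genotype = "WT")
  dead <- samples_for(ob$design, genotype = "kinase_dead")
  dif <- rowMeans(ob$sites$values[, wt]) - rowMeans(ob$sites$values[, dead])
  sub <- sim$truth$is_direct_substrate
  expect_equal(mean(dif[sub]), 3, tolerance = 0.15)
  expect_equal(mean(dif[!sub]), 0, tolerance = 0.1)

  # power oracle by direct simulation: planted difference 3.0, sd 0.5,
  # 5 vs 5 Student's t-test significant at p < 0.01 in >= 95% of 1000 seeds
  set.seed(38)
  p <- replicate(1000, {
    t.test(rnorm(5, 3, 0.5), rnorm(5, 0, 0.5), var.equal = TRUE)$p.value
  })
  expect_gte(mean(p < 0.01), 0.95)
  # and the generated substrates reach the same power
  pv <- vapply(which(sub), function(i) {
    t.test(ob$sites$values[i, wt], ob$sites$values[i, dead],
           var.equal = TRUE)$p.value
  }, 0)
  expect_gte(mean(pv < 0.01), 0.95)

  # zero substrates -> WT - dead differences centered at zero
  cfg0 <- sim_config(n_proteins = 150, n_targets = 40, prop_direct = 0,
                     mnar_slope = 0, mcar_rate = 0, seed = 39)
  sim0 <- generate_invivo(cfg0)
  ob0 <- generate_obika(cfg0, sim0$truth)
  dif0 <- rowMeans(ob0$sites$values[, wt]) - rowMeans(ob0$sites$values[, dead])
  expect_lt(abs(mean(dif0)), 0.05)
})

test_that("MNAR concentrates in kinase-dead samples of true substrates", {
  cfg <- sim_config(n_proteins = 300, n_targets = 80, prop_direct = 1,
                    mnar_slope = 1, mcar_rate = 0, seed = 40)
  sim <- generate_invivo(cfg)
  ob <- generate_obika(cfg, sim$truth)
  dead <- samples_for(ob$design, genotype = "kinase_dead")
  wt <- samples_for(ob$design, genotype = "WT")
  sub <- sim$truth$is_direct_substrate
  miss_dead_sub <- mean(is.na(ob$sites$values[sub, dead]))
  miss_dead_non <- mean(is.na(ob$sites$values[!sub, dead]))
  miss_wt_sub <- mean(is.na(ob$sites$values[sub, wt]))
  expect_gt(miss_dead_sub, 2 * miss_dead_non)
  expect_gt(miss_dead_sub, 2 * miss_wt_sub)
})

test_that("generated proteome carries phosphoacceptors and planted motifs", {
  cfg <- sim_config(n_proteins = 120, n_targets = 60, prop_direct = 1,
                    motif_fidelity = 1, seed = 41)
  sim <- generate_invivo(cfg)
  prot <- generate_proteome(cfg, sim$truth)
  seqs <- as.character(prot)
  # center residue always matches the site's stated residue
  for (i in sample(nrow(sim$truth), 50)) {
    s <- seqs[[sim$truth$protein_id[i]]]
    expect_equal(substr(s, sim$truth$position[i], sim$truth$position[i]),
                 sim$truth$residue[i])
  }
  # fidelity 1: every carrier has R at -3 and L at +4 (skipping positions
  # that collide with another phosphosite of the same protein)
  carriers <- sim$truth[sim$truth$carries_motif, ]
  pos_by_prot <- split(sim$truth$position, sim$truth$protein_id)
  for (i in seq_len(nrow(carriers))) {
    s <- seqs[[carriers$protein_id[i]]]
    p <- carriers$position[i]
    others <- pos_by_prot[[carriers$protein_id[i]]]
    if (p - 3 >= 1 && !(p - 3) %in% others)
      expect_equal(substr(s, p - 3, p - 3), "R")
    if (p - 4 >= 1 && !(p - 4) %in% others)
      expect_true(substr(s, p - 4, p - 4) %in% c("R", "K"))
    if (p + 4 <= nchar(s) && !(p + 4) %in% others)
      expect_equal(substr(s, p + 4, p + 4), "L")
  }
})

test_that("fidelity 0 leaves motif positions at background composition", {
  cfg <- sim_config(n_proteins = 400, n_targets = 300, prop_direct = 1,
                    sites_per_protein = 1, motif_fidelity = 0, seed = 42)
  sim <- generate_invivo(cfg)
  prot <- generate_proteome(cfg, sim$truth)
  seqs <- as.character(prot)
  carriers <- sim$truth[sim$truth$carries_motif, ]
  at <- function(off, res) {
    hits <- 0; n <- 0
    for (i in seq_len(nrow(carriers))) {
      p <- carriers$position[i] + off
      s <- seqs[[carriers$protein_id[i]]]
      if (p < 1 || p > nchar(s)) next
      n <- n + 1
      if (substr(s, p, p) %in% res) hits <- hits + 1
    }
    c(hits = hits, n = n)
  }
  # uniform background: each residue has frequency 1/20
  for (spec in list(list(-3, "R", 1 / 20), list(4, "L", 1 / 20))) {
    h <- at(spec[[1]], spec[[2]])
    bounds <- qbinom(c(0.005, 0.995), h["n"], spec[[3]])
    expect_gte(h["hits"], bounds[1])
    expect_lte(h["hits"], bounds[2])
  }
})

test_that("a site near the N-terminus still fits in the generated protein", {
  truth <- data.frame(site_key = "Z|2", protein_id = "Z", position = 2L,
                      residue = "S", is_invivo_responder = TRUE,
                      is_direct_substrate = TRUE, effect_5 = 2,
                      effect_15 = 2, kinetic_class = "sustained",
                      obika_effect = 3, carries_motif = TRUE,
                      stringsAsFactors = FALSE)
  cfg <- sim_config(n_proteins = 1, n_targets = 1, seed = 43)
  prot <- generate_proteome(cfg, truth)
  s <- as.character(prot)[["Z"]]
  expect_gte(nchar(s), 2 + cfg$flank)
  expect_equal(substr(s, 2, 2), "S")
  w <- unname(extract_windows(truth, prot, flank = 7))
  expect_equal(nchar(w), 15)
  expect_equal(substr(w, 1, 6), "______")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(kinetic_mix = c(0.5, 0.2, 0.2)), "sum")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(mcar_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_targets = -1), "integer")
  expect_error(sim_config(n_targets = 2.5), "integer")
  cfg <- sim_config(n_proteins = 5, sites_per_protein = 1, n_targets = 500)
  expect_error(generate_invivo(cfg), "exceeds")
})
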