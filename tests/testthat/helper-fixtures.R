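# fixture builders shared across test files; all data is generated in code

# random in vivo site table with controllable missingness
rand_invivo_table <- function(n, design = design_invivo(), miss = 0.3,
                              seed = 1, loc_prob = NULL) {
  set.seed(seed)
  if (is.null(loc_prob)) loc_prob <- runif(n)
  meta <- data.frame(protein_id = sprintf("P%04d", seq_len(n)),
                     position = sample(5:500, n, replace = TRUE),
                     residue = sample(c("S", "T", "Y"), n, replace = TRUE),
                     localization_probability = loc_prob,
                     stringsAsFactors = FALSE)
  vals <- matrix(rnorm(n * nrow(design)), n,
                 dimnames = list(NULL, design$sample_id))
  vals[matrix(runif(length(vals)) < miss, n)] <- NA
  site_table(meta, vals, design)
}

rand_obika_table <- function(n, design = design_obika(), miss = 0.3,
                             seed = 1) {
  set.seed(seed)
  meta <- data.frame(protein_id = sprintf("Q%04d", seq_len(n)),
                     position = sample(5:500, n, replace = TRUE),
                     residue = sample(c("S", "T"), n, replace = TRUE),
                     localization_probability = runif(n),
                     stringsAsFactors = FALSE)
  vals <- matrix(rnorm(n * nrow(design)), n,
                 dimnames = list(NULL, design$sample_id))
  vals[matrix(runif(length(vals)) < miss, n)] <- NA
  site_table(meta, vals, design)
}

# minimal in vivo stats frame for classification/intersection tests
make_invivo_stats <- function(keys, class_label = "not_significant",
                              q_5 = 1, q_15 = 1,
                              direction_5 = 1, direction_15 = 1) {
  n <- length(keys)
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(site_key = keys,
             protein_id = vapply(parts, `[`, "", 1),
             position = as.integer(vapply(parts, `[`, "", 2)),
             residue = "S",
             effect = 1, ci_low = 0.5, ci_high = 1.5, tau2 = 0,
             re_p = 0.01, n_obs = 10,
             t_p_5 = q_5, t_p_15 = q_15,
             q_5 = rep_len(q_5, n), q_15 = rep_len(q_15, n),
             direction_5 = rep_len(direction_5, n),
             direction_15 = rep_len(direction_15, n),
             class_label = rep_len(class_label, n),
             label_reason = "",
             stringsAsFactors = FALSE)
}

make_obika_stats <- function(keys, significant = TRUE) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(site_key = keys,
             protein_id = vapply(parts, `[`, "", 1),
             position = as.integer(vapply(parts, `[`, "", 2)),
             residue = "S",
             n_wt_obs = 5, n_dead_obs = 5,
             mean_difference = 3, statistic = 10,
             p_value = 1e-6, q_value = 1e-5,
             significant = rep_len(significant, length(keys)),
             impute_branch = "complete",
             stringsAsFactors = FALSE)
}

# independent single-site random-effects oracle (method of moments,
# written from the ANOVA decomposition, not shared with the implementation)
re_oracle <- function(y, rep_id) {
  keep <- !is.na(y)
  y <- y[keep]; rep_id <- rep_id[keep]
  reps <- unique(rep_id)
  k <- length(reps)
  rm <- vapply(reps, function(r) mean(y[rep_id == r]), 0)
  nr <- vapply(reps, function(r) sum(rep_id == r), 0)
  mu <- mean(rm)
  th <- k / sum(1 / nr)
  msb <- th * sum((rm - mu)^2) / (k - 1)
  ssw <- sum(vapply(reps, function(r) sum((y[rep_id == r] -
                                             mean(y[rep_id == r]))^2), 0))
  msw <- if (sum(nr - 1) > 0) ssw / sum(nr - 1) else 0
  tau2 <- max(0, (msb - msw) / th)
  se <- sqrt(msb / (k * th))
  p <- if (se > 0) 2 * pt(-abs(mu / se), k - 1) else
    if (mu == 0) 1 else .Machine$double.xmin
  c(mu = mu, se = se, tau2 = tau2, p = p)
}

# hand-coded BH step-up, loop form
bh_oracle <- function(p) {
  ok <- !is.na(p)
  ps <- p[ok]
  m <- length(ps)
  o <- order(ps)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[o[i]] * m / i)
    q_sorted[i] <- min(1, running)
  }
  q <- rep(NA_real_, length(p))
  q[ok][o] <- q_sorted
  q
}

# naive agglomerative average-linkage oracle on raw points (<= 8 rows);
# returns merge heights and the partition at every cluster count
avg_linkage_oracle <- function(m) {
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    nc <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(heights = heights, partitions = partitions)
}
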