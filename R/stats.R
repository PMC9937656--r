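#' Per-site random-effects effect estimation (matrix form)
#'
#' Fits, independently for every site, the one-way random-intercept model
#' \deqn{y_{tr} = \mu + b_r + e_{tr}} where `r` indexes biological replicates
#' (random intercepts, variance `tau2`) and `t` the starvation timepoints
#' measured within a replicate. Estimation is by method of moments on the
#' replicate means: with `k` replicates carrying data and `t_h` the harmonic
#' mean of per-replicate observation counts,
#' `MS_between = t_h * var(replicate means)`,
#' `tau2 = max(0, (MS_between - MS_within) / t_h)`, and
#' `SE(mu) = sqrt(MS_between / (k * t_h))`. Under normality `mu / SE` is
#' exactly t-distributed with `k - 1` degrees of freedom for balanced data,
#' which gives the p-value and the 95% confidence interval.
#'
#' Zero-variance degeneracy (all replicate means identical): the p-value is
#' returned at the machine floor when the effect is non-zero (1 otherwise)
#' and the CI collapses to the point estimate; such sites are flagged.
#'
#' @param vals numeric matrix, sites x samples (the samples to be combined,
#'   e.g. the vehicle arm at both timepoints).
#' @param replicate integer/character vector assigning each column to a
#'   biological replicate.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame with one row per site: `effect`, `se`, `ci_low`,
#'   `ci_high`, `tau2`, `p_value`, `n_obs`, `k_replicates`, `degenerate`.
#' @export
fit_random_effects_matrix <- function(vals, replicate, conf_level = 0.95) {
  stopifnot(is.matrix(vals), length(replicate) == ncol(vals))
  reps <- unique(replicate)
  ns <- nrow(vals)
  k_total <- length(reps)
  rep_mean <- matrix(NA_real_, ns, k_total)
  n_r <- matrix(0L, ns, k_total)
  ssw <- numeric(ns)
  for (j in seq_len(k_total)) {
    cols <- which(replicate == reps[j])
    sub <- vals[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n == 0] <- NA_real_
    rep_mean[, j] <- m
    n_r[, j] <- n
    dev <- sub - m
    ssw <- ssw + rowSums(dev^2, na.rm = TRUE)
  }
  k <- rowSums(n_r > 0)
  mu <- rowMeans(rep_mean, na.rm = TRUE)
  ssb <- rowSums((rep_mean - mu)^2, na.rm = TRUE)
  inv_n <- ifelse(n_r > 0, 1 / n_r, 0)
  t_h <- k / rowSums(inv_n)               # harmonic mean of per-rep counts
  df_b <- k - 1
  df_w <- rowSums(pmax(n_r - 1L, 0L))
  ms_between <- ifelse(df_b > 0, t_h * ssb / df_b, NA_real_)
  ms_within <- ifelse(df_w > 0, ssw / df_w, 0)
  tau2 <- pmax(0, (ms_between - ms_within) / t_h)
  se <- sqrt(ms_between / (k * t_h))
  n_obs <- rowSums(n_r)

  p <- rep(NA_real_, ns)
  lo <- rep(NA_real_, ns)
  hi <- rep(NA_real_, ns)
  usable <- k >= 2
  degen <- usable & se == 0
  reg <- usable & se > 0
  p[reg] <- 2 * stats::pt(-abs(mu[reg] / se[reg]), df = df_b[reg])
  tq <- rep(NA_real_, ns)
  tq[reg] <- stats::qt(1 - (1 - conf_level) / 2, df = df_b[reg])
  lo[reg] <- mu[reg] - tq[reg] * se[reg]
  hi[reg] <- mu[reg] + tq[reg] * se[reg]
  p[degen] <- ifelse(mu[degen] == 0, 1, .Machine$double.xmin)
  lo[degen] <- mu[degen]
  hi[degen] <- mu[degen]
  data.frame(effect = mu, se = se, ci_low = lo, ci_high = hi, tau2 = tau2,
             p_value = p, n_obs = n_obs, k_replicates = k,
             degenerate = degen)
}

#' Random-effects fit for a single site
#'
#' Convenience wrapper around [fit_random_effects_matrix()] for one site's
#' measurements.
#'
#' @param values numeric vector of log2 ratios, one per design row (missing
#'   allowed).
#' @param design data.frame with a `replicate` column (and typically
#'   `timepoint_min`), one row per element of `values`.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame as in [fit_random_effects_matrix()].
#' @export
random_effects_fit <- function(values, design, conf_level = 0.95) {
  stopifnot(length(values) == nrow(design))
  m <- matrix(values, nrow = 1,
              dimnames = list(NULL, design$sample_id))
  reps_with_data <- unique(design$replicate[!is.na(values)])
  if (length(reps_with_data) < 2)
    stop("random-effects model unidentifiable with a single replicate")
  fit_random_effects_matrix(m, design$replicate, conf_level)
}

#' Two-sample t-test with degenerate-variance contracts
#'
#' Student's pooled-variance t-test by default (`variant = "student"`), or
#' Welch. Two-sided. Zero pooled variance with unequal means returns the
#' machine-floor p-value; zero variance with equal means returns p = 1.
#'
#' @param a,b numeric vectors (missing values dropped; >= 2 observed values
#'   required per group).
#' @param variant `"student"` or `"welch"`.
#' @return list with `statistic`, `p_value`, `mean_difference` (a - b), `df`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observed values per group")
  d <- mean(a) - mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (d == 0) return(list(statistic = 0, p_value = 1,
                            mean_difference = 0, df = df))
    return(list(statistic = sign(d) * Inf, p_value = .Machine$double.xmin,
                mean_difference = d, df = df))
  }
  stat <- d / se
  list(statistic = stat, p_value = 2 * stats::pt(-abs(stat), df),
       mean_difference = d, df = df)
}

# vectorized rowwise two-sample t-test; rows with < 2 observed values in
# either group yield NA
matrix_t_test <- function(vals, cols_a, cols_b,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  A <- vals[, cols_a, drop = FALSE]
  B <- vals[, cols_b, drop = FALSE]
  n1 <- rowSums(!is.na(A)); n2 <- rowSums(!is.na(B))
  m1 <- rowMeans(A, na.rm = TRUE); m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- rowSums((A - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((B - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  d <- m1 - m2
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1))
  }
  ok <- n1 >= 2 & n2 >= 2
  p <- rep(NA_real_, nrow(vals))
  stat <- rep(NA_real_, nrow(vals))
  reg <- ok & se > 0
  stat[reg] <- d[reg] / se[reg]
  p[reg] <- 2 * stats::pt(-abs(stat[reg]), df[reg])
  degen <- ok & se == 0
  stat[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
  p[degen] <- ifelse(d[degen] == 0, 1, .Machine$double.xmin)
  d[!ok] <- NA_real_
  data.frame(statistic = stat, p_value = p, mean_difference = d,
             n_a = n1, n_b = n2)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' where `m` counts the non-missing p-values; missing entries propagate as
#' missing and do not enter `m`. Delegates to [stats::p.adjust()] on the
#' non-missing subset.
#'
#' @param p numeric vector of p-values in (0, 1\]; `NA` allowed.
#' @return numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
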