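#' Imputation parameters
#'
#' `width` and `downshift` are expressed in multiples of the observed
#' standard deviation of the scope unit, following the Perseus convention
#' for left-censored label-ratio data; the defaults (0.3 / 1.8) are the
#' Perseus defaults.
#'
#' @param width sd of the imputation distribution, as a fraction of the
#'   observed sd (> 0).
#' @param downshift shift below the observed mean, in observed-sd multiples
#'   (>= 0).
#' @param seed integer RNG seed for the draws.
#' @param scope `"per_sample_column"` (Perseus default) or `"whole_matrix"`.
#' @return an object of class `impute_params`.
#' @export
impute_params <- function(width = 0.3, downshift = 1.8, seed = 1L,
                          scope = c("per_sample_column", "whole_matrix")) {
  scope <- match.arg(scope)
  stopifnot(width > 0, downshift >= 0)
  structure(list(width = width, downshift = downshift,
                 seed = as.integer(seed), scope = scope),
            class = "impute_params")
}

# internal: matrix-level down-shifted-normal imputation
downshift_matrix <- function(vals, params, rng_label = "downshift") {
  set.seed(stream_seed(params$seed, rng_label))
  skipped <- character(0)
  if (params$scope == "whole_matrix") {
    obs <- vals[!is.na(vals)]
    if (length(obs) < 2) {
      warning("whole-matrix scope has < 2 observed values; nothing imputed")
      return(vals)
    }
    m <- mean(obs); s <- stats::sd(obs)
    miss <- which(is.na(vals))
    vals[miss] <- stats::rnorm(length(miss),
                               mean = m - params$downshift * s,
                               sd = params$width * s)
  } else {
    for (j in seq_len(ncol(vals))) {
      col <- vals[, j]
      obs <- col[!is.na(col)]
      if (length(obs) < 2) {
        skipped <- c(skipped, colnames(vals)[j])
        next
      }
      m <- mean(obs); s <- stats::sd(obs)
      miss <- which(is.na(col))
      if (length(miss) > 0)
        vals[miss, j] <- stats::rnorm(length(miss),
                                      mean = m - params$downshift * s,
                                      sd = params$width * s)
    }
    if (length(skipped) > 0)
      warning("columns with < 2 observed values left unimputed: ",
              paste(skipped, collapse = ", "))
  }
  vals
}

#' Down-shifted normal imputation of missing values
#'
#' Replaces every missing cell by a draw from
#' `Normal(m - downshift * s, width * s)`, where `m` and `s` are the mean and
#' sd of the observed values of the scope unit (sample column by default).
#' This mimics low-abundance measurements censored at the detection limit.
#' Observed cells are never modified; scope units with fewer than two
#' observed values are left untouched with a warning. Draws are reproducible
#' given the seed: columns are processed in table order.
#'
#' @param x a [site_table()], [protein_table()], or bare numeric matrix.
#' @param params an [impute_params()] object.
#' @return object of the same class with missing cells imputed; the matrix of
#'   pre-imputation missingness is attached as attribute `"imputed_mask"`.
#' @export
impute_downshift <- function(x, params = impute_params()) {
  stopifnot(inherits(params, "impute_params"))
  if (is.matrix(x)) {
    mask <- is.na(x)
    out <- downshift_matrix(x, params)
    attr(out, "imputed_mask") <- mask
    return(out)
  }
  mask <- is.na(x$values)
  x$values <- downshift_matrix(x$values, params)
  attr(x, "imputed_mask") <- mask
  x
}

# internal: rowwise observed-mean imputation within a column group
mle_matrix <- function(vals, group_cols) {
  sub <- vals[, group_cols, drop = FALSE]
  n_obs <- rowSums(!is.na(sub))
  gmean <- rowMeans(sub, na.rm = TRUE)
  for (j in seq_along(group_cols)) {
    col <- group_cols[j]
    miss <- is.na(vals[, col]) & n_obs > 0
    vals[miss, col] <- gmean[miss]
  }
  attr(vals, "mle_unimputed") <- n_obs == 0
  vals
}

#' Maximum-likelihood imputation within a replicate group
#'
#' Under a normal model with ignorable missingness, the MLE of a site's group
#' mean given the observed replicates is the observed mean; missing cells in
#' the group are replaced by it. Deterministic; sites with no observed value
#' in the group are left missing and flagged.
#'
#' @param x a [site_table()] or numeric matrix.
#' @param group_cols character vector of sample IDs (or column indices)
#'   forming the group.
#' @return same class as `x`; logical attribute `"mle_unimputed"` marks rows
#'   the group could not be imputed for.
#' @export
impute_mle <- function(x, group_cols) {
  if (is.matrix(x)) return(mle_matrix(x, group_cols))
  stopifnot(inherits(x, "site_table"))
  vals <- mle_matrix(x$values, group_cols)
  flag <- attr(vals, "mle_unimputed")
  attr(vals, "mle_unimputed") <- NULL
  x$values <- vals
  attr(x, "mle_unimputed") <- flag
  x
}

#' OBIKA missing-value policy
#'
#' Per site: if none of the kinase-dead replicates was quantified, the dead
#' cells are filled with down-shifted normal draws (the site is presumed
#' unphosphorylated without active kinase, i.e. below the detection limit);
#' if at least one was quantified, missing dead cells get the observed-mean
#' MLE. Missing wild-type cells always get the MLE from observed WT values.
#' Column statistics for the down-shift draws are computed per sample column
#' from the observed values before any imputation.
#'
#' @param x a `site_table` with an OBIKA design (callers normally filter to
#'   >= 3 observed WT replicates first, see [filter_obika_min_wt()]).
#' @param params an [impute_params()] object.
#' @return `site_table` with imputed values; attribute `"obika_branch"` is a
#'   character vector per site, one of `"downshift"`, `"mle"`, `"complete"`.
#' @export
impute_obika_policy <- function(x, params = impute_params()) {
  stopifnot(inherits(x, "site_table"), inherits(params, "impute_params"))
  wt_cols <- samples_for(x$design, genotype = "WT")
  dead_cols <- samples_for(x$design, genotype = "kinase_dead")
  vals <- x$values
  n_dead_obs <- rowSums(!is.na(vals[, dead_cols, drop = FALSE]))
  any_missing <- rowSums(is.na(vals)) > 0
  branch <- ifelse(!any_missing, "complete",
                   ifelse(n_dead_obs == 0, "downshift", "mle"))

  # column stats from observed values only (pre-imputation)
  col_m <- apply(vals[, dead_cols, drop = FALSE], 2, mean, na.rm = TRUE)
  col_s <- apply(vals[, dead_cols, drop = FALSE], 2, stats::sd, na.rm = TRUE)

  set.seed(stream_seed(params$seed, "obika_downshift"))
  ds_rows <- which(n_dead_obs == 0)
  for (j in seq_along(dead_cols)) {
    col <- dead_cols[j]
    if (is.na(col_s[j]) || length(ds_rows) == 0) next
    vals[ds_rows, col] <- stats::rnorm(length(ds_rows),
                                       mean = col_m[j] - params$downshift * col_s[j],
                                       sd = params$width * col_s[j])
  }
  vals <- mle_matrix(vals, dead_cols)   # fills rows with >= 1 observed dead
  vals <- mle_matrix(vals, wt_cols)
  attr(vals, "mle_unimputed") <- NULL
  x$values <- vals
  attr(x, "obika_branch") <- branch
  x
}
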