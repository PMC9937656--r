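#' Build the kinetic matrix for clustering
#'
#' Rows are the selected sites (by default the class I/II sites of a stats
#' table), columns are replicate-averaged log2 ratios per arm x timepoint
#' (`vehicle_5`, `vehicle_15`, and with `include_inhibitor = TRUE` also
#' `inhibitor_5`, `inhibitor_15`), or the individual replicate columns with
#' `per_replicate = TRUE`. Cells that end up all-missing fall back to the
#' row mean so that Euclidean distances stay defined.
#'
#' @param x a [site_table()] with an in vivo design.
#' @param stats optional [silac_stats()] output; when given, only class I/II
#'   sites are used.
#' @param include_inhibitor also include the inhibitor-arm columns
#'   (default FALSE: vehicle only).
#' @param per_replicate keep individual replicate columns instead of
#'   replicate means (default FALSE).
#' @return numeric matrix, rows named by site key.
#' @export
kinetic_matrix <- function(x, stats = NULL, include_inhibitor = FALSE,
                           per_replicate = FALSE) {
  stopifnot(inherits(x, "site_table"))
  keys <- rownames(x$values)
  if (!is.null(stats)) {
    keep_keys <- stats$site_key[stats$class_label %in% c("class_I", "class_II")]
    keep <- keys %in% keep_keys
  } else {
    keep <- rep(TRUE, length(keys))
  }
  arms <- if (include_inhibitor) c("vehicle", "inhibitor") else "vehicle"
  tps <- sort(unique(x$design$timepoint_min))
  cols <- list()
  for (a in arms) for (tp in tps) {
    ids <- samples_for(x$design, arm = a, timepoint = tp)
    if (per_replicate) {
      sub <- x$values[keep, ids, drop = FALSE]
      colnames(sub) <- ids
      cols[[length(cols) + 1]] <- sub
    } else {
      m <- rowMeans(x$values[keep, ids, drop = FALSE], na.rm = TRUE)
      cols[[length(cols) + 1]] <-
        matrix(m, ncol = 1, dimnames = list(NULL, sprintf("%s_%d", a, tp)))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- keys[keep]
  rm_na <- is.na(out) | is.nan(out)
  if (any(rm_na)) {
    rmean <- rowMeans(out, na.rm = TRUE)
    rmean[is.nan(rmean)] <- 0
    out[rm_na] <- rmean[row(out)[rm_na]]
  }
  out
}

#' Z-normalize matrix rows
#'
#' Per row: subtract the mean, divide by the sd (n - 1 denominator). Rows
#' with zero variance are set to all-zero and flagged via the
#' `"degenerate_rows"` attribute. Idempotent on non-degenerate rows.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return z-normalized matrix with attribute `"degenerate_rows"` (logical).
#' @export
znormalize_rows <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  degen <- s == 0
  s[degen] <- 1
  z <- (m - mu) / s
  z[degen, ] <- 0
  attr(z, "degenerate_rows") <- degen
  z
}

#' Agglomerative clustering of kinetic profiles
#'
#' Hierarchical clustering on Euclidean row distances ([stats::hclust()]),
#' tree cut to exactly `k` clusters ([stats::cutree()]). Cluster ids are
#' relabeled to be contiguous in order of first appearance, so the
#' assignment is deterministic given the input row order.
#'
#' @param m numeric matrix (rows = sites).
#' @param k number of clusters (default 5).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward's D2 on Euclidean distances).
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (named integer vector), `tree` (the `hclust` object), `k`, `heights`.
#' @export
hierarchical_cluster <- function(m, k = 5,
                                 linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(m), k >= 1)
  if (k > nrow(m)) stop("k exceeds the number of rows")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
  raw <- stats::cutree(hc, k = k)
  # contiguous ids in order of first appearance
  lev <- unique(raw)
  assignment <- match(raw, lev)
  names(assignment) <- rownames(m)
  structure(list(assignment = assignment, tree = hc, k = k,
                 heights = hc$height),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d rows in %d clusters\n",
              length(x$assignment), x$k))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Label clusters by their kinetic shape
#'
#' Compares each cluster's mean z-profile at 5 versus 15 min (vehicle-arm
#' columns): `early_transient` when the 5-min mean exceeds the 15-min mean
#' by more than `margin`, `late` for the reverse, `sustained` otherwise.
#'
#' @param assignment a [hierarchical_cluster()] result (or a bare integer
#'   vector of cluster ids).
#' @param m the (z-normalized) matrix that was clustered; 5- and 15-min
#'   vehicle columns are identified from the column names.
#' @param margin z-score margin separating transient/late from sustained
#'   (default 0.5).
#' @return named character vector, one label per cluster id.
#' @export
label_cluster_kinetics <- function(assignment, m, margin = 0.5) {
  if (inherits(assignment, "cluster_assignment"))
    assignment <- assignment$assignment
  cn <- colnames(m)
  c5 <- grep("(^|_)5$|_5min", cn)
  c15 <- grep("(^|_)15$|_15min", cn)
  c5 <- setdiff(c5, grep("inhibitor", cn))
  c15 <- setdiff(c15, grep("inhibitor", cn))
  if (length(c5) == 0 || length(c15) == 0)
    stop("cannot identify 5-min / 15-min vehicle columns from column names")
  ids <- sort(unique(assignment))
  labels <- vapply(ids, function(cl) {
    rows <- assignment == cl
    z5 <- mean(m[rows, c5, drop = FALSE])
    z15 <- mean(m[rows, c15, drop = FALSE])
    if (z5 - z15 > margin) "early_transient"
    else if (z15 - z5 > margin) "late"
    else "sustained"
  }, character(1))
  names(labels) <- ids
  labels
}
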