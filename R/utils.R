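#' Build site keys from protein and position
#'
#' A phosphosite is identified by its source protein and its 1-based residue
#' position; the pair must be unique within a table.
#'
#' @param protein_id character vector of protein identifiers.
#' @param position integer vector of 1-based residue positions.
#' @return character vector of keys of the form `"protein|position"`.
#' @export
site_key <- function(protein_id, position) {
  paste(protein_id, position, sep = "|")
}

#' Derive a per-stage RNG seed from a master seed
#'
#' Each stochastic stage draws from its own stream, derived from the master
#' seed and a stage label, so adding a stage never perturbs the draws of
#' earlier stages.
#'
#' @param seed master integer seed.
#' @param label character stage label (e.g. `"invivo"`, `"downshift"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  b <- utf8ToInt(label)
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483629
  as.integer((abs(seed) * 1009 + h) %% 2147483629)
}

# polynomial rolling hash of a string; used for run-manifest config hashes
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# stage logging goes to stderr; results only ever go to files/return values
log_stage <- function(stage, n, what = "sites") {
  message(sprintf("[kinsub] %-28s %6d %s", stage, n, what))
}

#' Adjusted Rand index between two labelings
#'
#' Closed-form contingency computation; permutation-invariant agreement
#' between two partitions of the same objects (1 = identical up to label
#' names, ~0 = chance).
#'
#' @param a,b vectors of cluster/class labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
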