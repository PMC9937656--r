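AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract sequence windows around phosphosites
#'
#' Returns the `(2 * flank + 1)`-mer centered on each phosphoacceptor;
#' positions beyond the protein termini are padded with `"_"`. The residue
#' stated in the site list must match the sequence at that position — a
#' mismatch aborts with the offending site named, which guards against
#' coordinate-convention bugs.
#'
#' @param sites data.frame with `protein_id`, `position`, `residue`.
#' @param proteome a `Biostrings::AAStringSet`, a named character vector of
#'   sequences, or a FASTA file path.
#' @param flank number of residues on each side (default 7).
#' @return character vector of windows, named by site key.
#' @export
extract_windows <- function(sites, proteome, flank = 7) {
  if (is.character(proteome) && length(proteome) == 1 && file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  if (methods::is(proteome, "AAStringSet")) {
    seqs <- as.character(proteome)
    names(seqs) <- sub("\\s.*$", "", names(proteome))
  } else {
    seqs <- proteome
  }
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    if (!pid %in% names(seqs))
      stop("protein absent from proteome: ", pid)
    s <- seqs[[pid]]
    len <- nchar(s)
    if (pos > len)
      stop(sprintf("site %s|%d beyond sequence end (%d)", pid, pos, len))
    got <- substr(s, pos, pos)
    if (got != sites$residue[i])
      stop(sprintf("residue mismatch at %s|%d: expected %s, sequence has %s",
                   pid, pos, sites$residue[i], got))
    lo <- max(1, pos - flank)
    hi <- min(len, pos + flank)
    out[i] <- paste0(strrep("_", lo - (pos - flank)),
                     substr(s, lo, hi),
                     strrep("_", (pos + flank) - hi))
  }
  names(out) <- site_key(sites$protein_id, sites$position)
  out
}

# internal: position x residue count matrix over windows ('_' excluded)
window_counts <- function(windows) {
  width <- unique(nchar(windows))
  if (length(width) != 1) stop("windows of unequal width")
  flank <- (width - 1) / 2
  positions <- -flank:flank
  chars <- do.call(rbind, strsplit(windows, ""))
  counts <- matrix(0L, nrow = width, ncol = length(AA20),
                   dimnames = list(positions, AA20))
  n_at <- integer(width)
  for (p in seq_len(width)) {
    v <- chars[, p]
    v <- v[v != "_"]
    n_at[p] <- length(v)
    tab <- table(factor(v, levels = AA20))
    counts[p, ] <- as.integer(tab)
  }
  list(counts = counts, n_at = n_at, positions = positions, flank = flank)
}

#' Position-specific residue enrichment around phosphosites
#'
#' For every (position, residue) cell, compares the foreground count to the
#' background frequency with a two-sided binomial test and computes the
#' pseudocounted log2 enrichment
#' `log2(((count + 0.5) / (n + 1)) / bg_freq)`. The background is either a
#' window set (typically all quantified, non-shortlisted sites; per-position
#' frequencies, same pseudocount) or a residue frequency table (recycled
#' across positions). Benjamini-Hochberg adjustment runs across all tested
#' cells; the center position (always the phosphoacceptor) is excluded, as
#' are padding characters on both sides of the comparison.
#'
#' @param foreground character vector of equal-width windows.
#' @param background either a character vector of windows or a named numeric
#'   frequency vector over the 20 amino acids summing to 1.
#' @param pseudocount added to foreground (and window-derived background)
#'   counts (default 0.5).
#' @return data.frame of class `motif_profile`: `position`, `residue`,
#'   `fg_count`, `fg_n`, `bg_count`, `bg_n`, `bg_freq`, `log2_enrichment`,
#'   `p_value`, `q_value`, `is_center`.
#' @export
position_enrichment <- function(foreground, background, pseudocount = 0.5) {
  if (length(foreground) < 1) stop("empty foreground")
  fg <- window_counts(foreground)
  if (is.character(background)) {
    if (length(background) < 1) stop("empty background")
    bg <- window_counts(background)
    if (bg$flank != fg$flank) stop("foreground/background widths differ")
    bg_counts <- bg$counts
    bg_n <- bg$n_at
    bg_freq <- (bg_counts + pseudocount) /
      (bg_n + 2 * pseudocount * 1)          # (c + 0.5) / (n + 1)
  } else {
    if (is.null(names(background)) || abs(sum(background) - 1) > 1e-6)
      stop("frequency background must be a named vector summing to 1")
    freq <- background[AA20]
    freq[is.na(freq)] <- 0
    bg_counts <- matrix(NA_integer_, nrow = length(fg$positions),
                        ncol = length(AA20),
                        dimnames = list(fg$positions, AA20))
    bg_n <- rep(NA_integer_, length(fg$positions))
    bg_freq <- matrix(rep(freq, each = length(fg$positions)),
                      nrow = length(fg$positions),
                      dimnames = list(fg$positions, AA20))
  }
  grid <- expand.grid(pi = seq_along(fg$positions), ai = seq_along(AA20))
  position <- fg$positions[grid$pi]
  residue <- AA20[grid$ai]
  fg_count <- fg$counts[cbind(grid$pi, grid$ai)]
  fg_n <- fg$n_at[grid$pi]
  bgf <- bg_freq[cbind(grid$pi, grid$ai)]
  log2e <- ifelse(bgf > 0 & fg_n > 0,
                  log2(((fg_count + pseudocount) / (fg_n + 2 * pseudocount)) / bgf),
                  NA_real_)
  is_center <- position == 0
  p <- rep(NA_real_, length(position))
  testable <- !is_center & fg_n > 0 & bgf > 0 & bgf < 1
  p[testable] <- vapply(which(testable), function(i) {
    stats::binom.test(fg_count[i], fg_n[i], p = bgf[i],
                      alternative = "two.sided")$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_fdr(p[testable])
  out <- data.frame(position = position, residue = residue,
                    fg_count = fg_count, fg_n = fg_n,
                    bg_count = bg_counts[cbind(grid$pi, grid$ai)],
                    bg_n = bg_n[grid$pi],
                    bg_freq = bgf, log2_enrichment = log2e,
                    p_value = p, q_value = q, is_center = is_center,
                    stringsAsFactors = FALSE)
  class(out) <- c("motif_profile", "data.frame")
  attr(out, "pseudocount") <- pseudocount
  attr(out, "n_foreground") <- length(foreground)
  out
}

#' Call consensus motif positions
#'
#' Reports (position, residue) cells passing both the FDR and the
#' enrichment thresholds, plus pooled residue-class calls (basic = K/R,
#' hydrophobic = L/I/V/M/F by default): class counts and background
#' frequencies are summed per position and re-tested, so two individually
#' sub-threshold residues of the same class can jointly reach significance.
#'
#' @param profile a [position_enrichment()] result.
#' @param q_threshold FDR threshold (default 0.01).
#' @param enrichment_threshold minimum log2 enrichment (default 1).
#' @param classes named list of residue classes to pool.
#' @return data.frame with `position`, `call` (residue or class name),
#'   `type` (`"residue"`/`"class"`), `log2_enrichment`, `q_value`.
#' @export
consensus_call <- function(profile, q_threshold = 0.01,
                           enrichment_threshold = 1,
                           classes = list(basic = c("K", "R"),
                                          hydrophobic = c("L", "I", "V",
                                                          "M", "F"))) {
  pc <- attr(profile, "pseudocount")
  hit <- !profile$is_center & !is.na(profile$q_value) &
    profile$q_value < q_threshold &
    !is.na(profile$log2_enrichment) &
    profile$log2_enrichment > enrichment_threshold
  res_calls <- data.frame(position = profile$position[hit],
                          call = profile$residue[hit],
                          type = rep("residue", sum(hit)),
                          log2_enrichment = profile$log2_enrichment[hit],
                          q_value = profile$q_value[hit],
                          stringsAsFactors = FALSE)
  # pooled residue classes
  pooled <- list()
  for (cls in names(classes)) {
    members <- classes[[cls]]
    for (pos in setdiff(unique(profile$position), 0)) {
      rows <- profile$position == pos & profile$residue %in% members
      n <- unique(profile$fg_n[rows])
      if (length(n) != 1 || n == 0) next
      cnt <- sum(profile$fg_count[rows])
      bgf <- sum(profile$bg_freq[rows])
      if (bgf <= 0 || bgf >= 1) next
      le <- log2(((cnt + pc) / (n + 2 * pc)) / bgf)
      p <- stats::binom.test(cnt, n, p = bgf,
                             alternative = "two.sided")$p.value
      pooled[[length(pooled) + 1]] <-
        data.frame(position = pos, call = cls, type = "class",
                   log2_enrichment = le, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  cls_calls <- NULL
  if (length(pooled) > 0) {
    pooled <- do.call(rbind, pooled)
    pooled$q_value <- bh_fdr(pooled$p_value)
    keep <- pooled$q_value < q_threshold &
      pooled$log2_enrichment > enrichment_threshold
    cls_calls <- pooled[keep, c("position", "call", "type",
                                "log2_enrichment", "q_value")]
  }
  out <- rbind(res_calls, cls_calls)
  out <- out[order(out$position, out$type, out$call), , drop = FALSE]
  rownames(out) <- NULL
  out
}
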