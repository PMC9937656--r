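#' Read a phosphosite (or protein) quantification table
#'
#' Expects a tab-separated file with a header containing the metadata columns
#' and one column per design sample. Decimal point is `.`; missing values are
#' encoded as empty cells or `"NaN"`. Rows with malformed numeric cells
#' (e.g. comma decimals) are dropped with a warning; duplicated site keys and
#' design samples missing from the header are hard errors.
#'
#' @param path file path.
#' @param design experiment design the sample columns are validated against.
#' @return a [site_table()].
#' @seealso [write_site_table()] for the inverse operation.
#' @export
read_site_table <- function(path, design) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "")
  required <- c("protein_id", "position", "residue", "localization_probability")
  missing_meta <- setdiff(required, names(raw))
  if (length(missing_meta) > 0)
    stop("file lacks metadata column(s): ", paste(missing_meta, collapse = ", "))
  missing_samples <- setdiff(design$sample_id, names(raw))
  if (length(missing_samples) > 0)
    stop("design sample(s) missing from file header: ",
         paste(missing_samples, collapse = ", "))

  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  parse_num <- function(v) {
    miss <- is.na(v) | v == "" | v == "NaN" | v == "NA"
    ok <- miss | grepl(num_re, v)
    out <- rep(NA_real_, length(v))
    out[!miss & ok] <- as.numeric(v[!miss & ok])
    list(value = out, valid = ok)
  }

  numeric_cols <- c("localization_probability", design$sample_id)
  valid <- rep(TRUE, nrow(raw))
  parsed <- list()
  for (cn in c("position", numeric_cols)) {
    p <- parse_num(raw[[cn]])
    parsed[[cn]] <- p$value
    valid <- valid & p$valid
  }
  # key/metadata sanity: these are structural, not per-row recoverable
  valid <- valid & !is.na(parsed$position) & parsed$position >= 1 &
    parsed$position == round(parsed$position) &
    raw$residue %in% c("S", "T", "Y") &
    !is.na(parsed$localization_probability) &
    parsed$localization_probability >= 0 & parsed$localization_probability <= 1
  n_dropped <- sum(!valid)
  if (n_dropped > 0)
    warning(sprintf("dropped %d malformed row(s) while reading %s",
                    n_dropped, path))
  keys <- site_key(raw$protein_id[valid], parsed$position[valid])
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0)
    stop("duplicated site key(s) in ", path, ": ", paste(dup, collapse = ", "))

  meta <- data.frame(protein_id = raw$protein_id[valid],
                     position = as.integer(parsed$position[valid]),
                     residue = raw$residue[valid],
                     localization_probability =
                       parsed$localization_probability[valid],
                     stringsAsFactors = FALSE)
  values <- vapply(design$sample_id, function(cn) parsed[[cn]][valid],
                   numeric(sum(valid)))
  if (sum(valid) == 1L) values <- matrix(values, nrow = 1,
                                         dimnames = list(NULL, design$sample_id))
  log_stage("read_site_table", nrow(meta), sprintf("rows (%d dropped)", n_dropped))
  site_table(meta, values, design)
}

#' Write a site table (round-trip safe)
#'
#' Tab-separated with a header; missing cells are serialized as `"NaN"`.
#' Column order is deterministic given the design order, so two writes of the
#' same table are byte-identical.
#'
#' @param x a [site_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  vals <- x$values
  chr <- matrix(sprintf("%.10g", vals), nrow = nrow(vals),
                dimnames = dimnames(vals))
  chr[is.na(vals)] <- "NaN"
  out <- cbind(x$meta[, c("protein_id", "position", "residue",
                          "localization_probability")],
               as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an experiment design
#'
#' Tab-separated, one row per sample (`sample_id`, then `arm`,
#' `timepoint_min`, `replicate` in vivo or `genotype`, `replicate` for
#' OBIKA).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("design lacks sample_id column")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample IDs in design file")
  d
}

#' @rdname read_design
#' @param design design data.frame to serialize.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-site statistics (or any data.frame result) as TSV
#'
#' @param stats a data.frame (e.g. from [silac_stats()] or [process_obika()]).
#' @param path output path.
#' @export
write_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference phosphosite list
#'
#' Format: `protein_id<TAB>position<TAB>residue`, with or without a header
#' line naming those columns.
#'
#' @param path file path.
#' @return character vector of site keys.
#' @export
read_site_list <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  d <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(d)[1:2] <- c("protein_id", "position")
  if (ncol(d) < 2) stop("malformed site list: need protein and position columns")
  pos <- suppressWarnings(as.integer(d[[2]]))
  if (any(is.na(pos))) stop("malformed site list: non-integer positions in ", path)
  site_key(d[[1]], pos)
}
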