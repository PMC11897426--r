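# Plain-text readers and writers for the tabular interchange formats used
# around the pipeline. All files are UTF-8, tab-delimited.

#' Read plasmid-to-genus host labels from TSV
#'
#' @param path TSV with header columns `plasmid_id`, `genus`.
#' @return Named character vector mapping plasmid id to genus.
#' @export
read_plasmid_hosts <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("plasmid_id", "genus") %in% names(df)))
    stop_("host label file needs columns plasmid_id, genus: %s", path)
  if (anyDuplicated(df$plasmid_id))
    stop_("duplicate plasmid_id in %s", path)
  stats::setNames(df$genus, df$plasmid_id)
}

#' Read protein-to-cluster assignments from TSV
#'
#' @param path TSV with header columns `protein_id`, `plasmid_id`, `pc_id`.
#' @return data.frame with those three character columns.
#' @export
read_protein_assignments <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  req <- c("protein_id", "plasmid_id", "pc_id")
  if (!all(req %in% names(df)))
    stop_("assignment file needs columns %s: %s", paste(req, collapse = ", "), path)
  df[req]
}

#' Read per-plasmid protein-cluster profiles from TSV
#'
#' Each row describes one plasmid: its observed host genus and the
#' comma-separated list of PC ids of its encoded proteins (one entry per
#' protein, repeats allowed).
#'
#' @param path TSV with header columns `plasmid_id`, `genus`, `pc_ids`.
#' @return List of profiles as used by [plasmid_mean_weights()]: each a
#'   list with `plasmid_id`, `observed_host`, `protein_pcs`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  req <- c("plasmid_id", "genus", "pc_ids")
  if (!all(req %in% names(df)))
    stop_("profile file needs columns %s: %s", paste(req, collapse = ", "), path)
  lapply(seq_len(nrow(df)), function(i) {
    list(plasmid_id = df$plasmid_id[i],
         observed_host = df$genus[i],
         protein_pcs = strsplit(df$pc_ids[i], ",", fixed = TRUE)[[1L]])
  })
}

#' Write a score or count matrix as TSV
#'
#' Row labels go in a leading `pc_id` column; scores are written in fixed
#' notation with 6 decimals, counts as integers.
#'
#' @param x matrix with dimnames (a `pc_count_table` or
#'   `significance_matrix`).
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- unclass(x)
  vals <- if (is.integer(m) || all(m == round(m))) format(m, trim = TRUE)
          else formatC(m, format = "f", digits = 6)
  out <- cbind(pc_id = rownames(m), matrix(vals, nrow = nrow(m)))
  colnames(out) <- c("pc_id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a significance matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path with a `pc_id` first column and one column per genus.
#' @param method score method tag to attach (`"tfidf"` or `"tfidf_pro"`).
#' @return A `significance_matrix`.
#' @export
read_significance_tsv <- function(path, method = "tfidf_pro") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  new_significance_matrix(m, method)
}
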