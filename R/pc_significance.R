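#' Build the protein-cluster x genus count table
#'
#' Tallies, for every protein cluster (PC), how many member proteins come
#' from plasmids observed in each host genus. The resulting contingency
#' table is the substrate of the significance scores
#' ([compute_tfidf()], [compute_tfidf_pro()]): cell \eqn{|P_{i,j}|} counts
#' the proteins of PC \eqn{i} whose source plasmid is labelled with genus
#' \eqn{j}.
#'
#' @param assignments data.frame with columns `protein_id`, `plasmid_id`,
#'   `pc_id`; one row per protein. Each protein must map to exactly one PC
#'   and one plasmid.
#' @param plasmid_hosts named character vector mapping `plasmid_id` to its
#'   observed host genus.
#' @return An integer matrix of class `pc_count_table` with PCs as rows and
#'   genera as columns, both in lexicographic order. Rows or columns whose
#'   total is zero are dropped (they cannot arise from a tally but are
#'   filtered defensively).
#' @seealso [parse_cdhit_clusters()] to obtain PC assignments from CD-HIT
#'   output.
#' @export
build_pc_count_table <- function(assignments, plasmid_hosts) {
  if (is.null(assignments) || nrow(as.data.frame(assignments)) == 0L)
    stop_("empty protein assignment collection")
  assignments <- as.data.frame(assignments)
  req <- c("protein_id", "plasmid_id", "pc_id")
  miss <- setdiff(req, names(assignments))
  if (length(miss))
    stop_("assignments lack column(s): %s", paste(miss, collapse = ", "))
  if (is.null(names(plasmid_hosts)) || any(!nzchar(plasmid_hosts)))
    stop_("plasmid_hosts must be a named character vector of non-empty genus ids")
  if (anyDuplicated(assignments$protein_id))
    stop_("duplicate protein_id in assignments: %s",
          assignments$protein_id[duplicated(assignments$protein_id)][1L])
  unknown <- setdiff(unique(assignments$plasmid_id), names(plasmid_hosts))
  if (length(unknown))
    stop_("plasmid id(s) absent from plasmid_hosts: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  genus <- unname(plasmid_hosts[assignments$plasmid_id])
  pcs <- sort_c(unique(as.character(assignments$pc_id)))
  genera <- sort_c(unique(genus))
  counts <- table(factor(assignments$pc_id, levels = pcs),
                  factor(genus, levels = genera))
  counts <- matrix(as.integer(counts), nrow = length(pcs),
                   dimnames = list(pc_id = pcs, genus = genera))
  counts <- counts[rowSums(counts) > 0L, colSums(counts) > 0L, drop = FALSE]
  class(counts) <- c("pc_count_table", class(counts))
  counts
}

validate_count_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_("count table must be a numeric matrix")
  if (any(table < 0) || any(table != round(table)))
    stop_("count table entries must be non-negative integers")
  if (nrow(table) == 0L || ncol(table) == 0L)
    stop_("count table has no rows or columns")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_("count table has an all-zero row or column")
  invisible(table)
}

new_significance_matrix <- function(scores, method) {
  structure(scores, method = method,
            class = c("significance_matrix", "matrix", "array"))
}

#' TF-IDF significance of protein clusters to host genera
#'
#' Classic term-frequency x inverse-document-frequency weighting with PCs
#' as words and genera as documents:
#' \deqn{\mathrm{score}_{i,j} = \frac{|P_{i,j}|}{|P_{\cdot j}|}
#'       \log\frac{|G|}{|G_i|}}
#' where \eqn{|P_{\cdot j}|} is the total protein count of genus \eqn{j},
#' \eqn{|G|} the number of genera and \eqn{|G_i|} the number of genera in
#' which PC \eqn{i} occurs. A PC present in every genus scores 0 for all of
#' them; natural logarithm throughout.
#'
#' @param table a `pc_count_table` from [build_pc_count_table()].
#' @return A numeric matrix of class `significance_matrix` (attribute
#'   `method = "tfidf"`), same dimnames as `table`.
#' @export
compute_tfidf <- function(table) {
  validate_count_table(table)
  g_total <- ncol(table)
  g_i <- rowSums(table > 0)
  tf <- sweep(unclass(table), 2L, colSums(table), "/")
  scores <- tf * log(g_total / g_i)
  new_significance_matrix(scores, "tfidf")
}

#' Augmented TF-IDF significance rescuing small genus-specific clusters
#'
#' Plain TF-IDF under-scores small PCs: a cluster private to one genus but
#' with few members is dwarfed by the genus's large shared clusters. This
#' variant multiplies the within-genus frequency by the cluster's relative
#' frequency across genera and uses a smoothed, shifted IDF so that even
#' ubiquitous clusters keep a positive score where they occur:
#' \deqn{\mathrm{score}_{i,j} = \frac{|P_{i,j}|}{|P_{\cdot j}|}\,
#'       \frac{|P_{i,j}|}{|P_{i\cdot}|}
#'       \left(\log\frac{|G|+1}{|G_i|+1} + 1\right)}
#' with \eqn{|P_{i\cdot}|} the total size of PC \eqn{i}. This is the score
#' used for pseudo-label generation ([generate_pseudo_labels()]).
#'
#' @inheritParams compute_tfidf
#' @return A `significance_matrix` with attribute `method = "tfidf_pro"`.
#' @export
compute_tfidf_pro <- function(table) {
  validate_count_table(table)
  g_total <- ncol(table)
  g_i <- rowSums(table > 0)
  m <- unclass(table)
  tf <- sweep(m, 2L, colSums(m), "/")
  rf <- m / rowSums(m)
  scores <- tf * rf * (log((g_total + 1) / (g_i + 1)) + 1)
  new_significance_matrix(scores, "tfidf_pro")
}

#' Rank protein clusters by cross-genus score variance
#'
#' PCs whose significance differs most across genera are the most
#' host-informative; this returns the `k` PCs with the largest row variance
#' of their scores, descending, with ties broken lexicographically by
#' `pc_id`.
#'
#' @param sig a `significance_matrix`.
#' @param k number of PCs to return; must be positive and at most
#'   `nrow(sig)`.
#' @return Character vector of `k` pc ids.
#' @export
top_variance_pcs <- function(sig, k) {
  if (!is_count(k) || k <= 0) stop_("k must be a positive integer")
  if (k > nrow(sig)) stop_("k (%d) exceeds the number of PCs (%d)", k, nrow(sig))
  v <- apply(unclass(sig), 1L, stats::var)
  rownames(sig)[order_c(-v, rownames(sig))][seq_len(k)]
}

#' Parse a CD-HIT `.clstr` file into protein-to-cluster assignments
#'
#' Reads the cluster output dialect of CD-HIT: headers `>Cluster N`
#' followed by member lines whose protein id sits between `>` and the
#' terminating `...`. The representative marker `*` is ignored; cluster ids
#' are derived from the header ordinal (`PC<N>`).
#'
#' @param input path to a `.clstr` file, or a character vector of its lines.
#' @return data.frame with columns `protein_id`, `pc_id`, one row per
#'   member line, in file order.
#' @export
parse_cdhit_clusters <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else as.character(input)
  lines <- sub("\r$", "", lines)
  protein <- character(0)
  pc <- character(0)
  current <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^>Cluster\\s+\\d+", ln)) {
      current <- paste0("PC", sub("^>Cluster\\s+(\\d+).*$", "\\1", ln))
      next
    }
    if (is.null(current))
      stop_("line %d: member line before any '>Cluster' header", i)
    m <- regmatches(ln, regexec(">(.+?)\\.\\.\\.", ln))[[1L]]
    if (length(m) < 2L)
      stop_("line %d: malformed member line (no '>id...' token): %s", i, ln)
    protein <- c(protein, m[2L])
    pc <- c(pc, current)
  }
  if (anyDuplicated(protein))
    stop_("duplicate protein id in .clstr input: %s",
          protein[duplicated(protein)][1L])
  data.frame(protein_id = protein, pc_id = pc)
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("significance_matrix [%s]: %d PCs x %d genera\n",
              attr(x, "method"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]), ...)
  invisible(x)
}
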