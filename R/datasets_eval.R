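# Corpus filters, multi-host test-set construction from near-identical
# cross-genus alignment pairs, and macro-averaged evaluation metrics.

#' Drop genera with too few plasmids
#'
#' Genera represented by fewer than `min_count` plasmids carry too little
#' signal for model training and are removed together with their plasmids
#' (strictly fewer: a genus with exactly `min_count` plasmids is kept).
#'
#' @param labels named character vector: plasmid id -> genus.
#' @param min_count minimum plasmids per retained genus (default 10).
#' @return List with `labels` (retained mapping) and `dropped_genera`.
#' @export
filter_genera <- function(labels, min_count = 10) {
  if (!is_count(min_count) || min_count < 1)
    stop_("min_count must be a positive integer")
  tab <- table(labels)
  dropped <- sort_c(names(tab)[tab < min_count])
  list(labels = labels[!labels %in% dropped], dropped_genera = dropped)
}

#' Read BLAST tabular (outfmt-6-style) alignment hits
#'
#' Parses a headerless tab-separated alignment table. The default column
#' layout is `qseqid sseqid pident length qlen slen`; pass the actual
#' layout via `columns` when the file carries more or reordered fields
#' (names other than the six required ones are ignored). Self-hits are
#' dropped with a message.
#'
#' @param path TSV path.
#' @param columns character vector naming every column in file order; must
#'   include `qseqid`, `sseqid`, `pident`, `length`, `qlen`, `slen`.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `query_length`,
#'   `subject_length`.
#' @export
read_blast_tabular <- function(path,
    columns = c("qseqid", "sseqid", "pident", "length", "qlen", "slen")) {
  req <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen")
  if (!all(req %in% columns))
    stop_("columns must include: %s", paste(req, collapse = " "))
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = columns, check.names = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0),
                      alignment_length = integer(0),
                      query_length = integer(0), subject_length = integer(0)))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop_("non-numeric %s at line %d of %s", col, which(is.na(v))[1L], path)
    v
  }
  hits <- data.frame(query_id = df$qseqid, subject_id = df$sseqid,
                     percent_identity = num("pident"),
                     alignment_length = as.integer(num("length")),
                     query_length = as.integer(num("qlen")),
                     subject_length = as.integer(num("slen")))
  self <- hits$query_id == hits$subject_id
  if (any(self))
    message(sprintf("dropped %d self-hit(s)", sum(self)))
  hits[!self, , drop = FALSE]
}

#' Build the multi-host test set from near-identical cross-genus pairs
#'
#' Databases record a single isolation host per plasmid, but two
#' near-identical sequences annotated with different genera are evidence
#' that the plasmid occupies both. A hit qualifies when identity and the
#' coverage of BOTH sequences (alignment length over each sequence length,
#' as percentages) are strictly above the thresholds; qualifying pairs
#' with different genus labels become edges, connected components are
#' merged transitively, and every member plasmid receives the union of the
#' labels in its component. Plasmids with fewer than `min_genes` encoded
#' genes are then removed.
#'
#' @param hits data.frame of alignment hits (see [read_blast_tabular()]).
#' @param labels named character vector: plasmid id -> observed genus.
#' @param gene_counts named integer vector: plasmid id -> number of
#'   encoded genes.
#' @param identity_min,coverage_min qualification thresholds in percent
#'   (default 99, strict `>`).
#' @param min_genes minimum encoded genes for a retained record (default 2).
#' @return data.frame with one row per multi-host plasmid: `plasmid_id`,
#'   `component_id` (named after the lexicographically smallest member),
#'   `host_genera` (semicolon-joined sorted union), `n_genes`; ordered by
#'   plasmid id. Empty when no pair qualifies.
#' @export
build_multihost_testset <- function(hits, labels, gene_counts,
                                    identity_min = 99, coverage_min = 99,
                                    min_genes = 2) {
  empty <- data.frame(plasmid_id = character(0), component_id = character(0),
                      host_genera = character(0), n_genes = integer(0))
  if (nrow(hits) == 0L) return(empty)
  referenced <- unique(c(hits$query_id, hits$subject_id))
  unlabeled <- setdiff(referenced, names(labels))
  if (length(unlabeled))
    stop_("plasmid(s) in hits without a host label: %s",
          paste(utils::head(unlabeled, 5L), collapse = ", "))
  missing_genes <- setdiff(referenced, names(gene_counts))
  if (length(missing_genes))
    stop_("plasmid(s) in hits without a gene count: %s",
          paste(utils::head(missing_genes, 5L), collapse = ", "))
  cov_q <- 100 * hits$alignment_length / hits$query_length
  cov_s <- 100 * hits$alignment_length / hits$subject_length
  qual <- hits$query_id != hits$subject_id &
    hits$percent_identity > identity_min &
    cov_q > coverage_min & cov_s > coverage_min &
    labels[hits$query_id] != labels[hits$subject_id]
  edges <- hits[qual, c("query_id", "subject_id"), drop = FALSE]
  if (nrow(edges) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  member <- names(comp$membership)
  records <- do.call(rbind, lapply(split(member, comp$membership),
    function(ids) {
      hosts <- sort_c(unique(unname(labels[ids])))
      data.frame(plasmid_id = ids,
                 component_id = paste0("comp_", sort_c(ids)[1L]),
                 host_genera = paste(hosts, collapse = ";"),
                 n_genes = unname(gene_counts[ids]))
    }))
  records <- records[records$n_genes >= min_genes, , drop = FALSE]
  records <- records[order_c(records$plasmid_id), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Macro-averaged multi-label evaluation metrics
#'
#' Per-genus recall `tp/(tp+fn)` and precision `tp/(tp+fp)` (a genus with
#' no predicted positives gets precision 0), macro-averaged without
#' weighting over the genera that have at least one true instance, and an
#' F1 score taken as the harmonic mean of the two macro averages:
#' \deqn{F1 = 2RP/(R+P)} (0 when both are 0). All values are percentages.
#'
#' @param predictions named list: plasmid id -> called genus set
#'   (character vectors, possibly empty).
#' @param truths named list: plasmid id -> true genus set (non-empty).
#' @return Object of class `eval_report`: `macro_recall`,
#'   `macro_precision`, `f1` (percentages) and a `per_genus` data.frame
#'   with tp/fp/fn counts and rates.
#' @export
macro_metrics <- function(predictions, truths) {
  extra <- setdiff(names(predictions), names(truths))
  if (length(extra))
    stop_("plasmid(s) in predictions but not truths: %s",
          paste(utils::head(extra, 5L), collapse = ", "))
  if (any(lengths(truths) == 0L)) stop_("every truth set must be non-empty")
  genera <- sort_c(unique(c(unlist(truths), unlist(predictions))))
  tally <- vapply(genera, function(g) {
    truth_has <- vapply(truths, function(s) g %in% s, logical(1))
    pred_has <- vapply(names(truths), function(id)
      g %in% (predictions[[id]] %||% character(0)), logical(1))
    c(tp = sum(truth_has & pred_has), fp = sum(!truth_has & pred_has),
      fn = sum(truth_has & !pred_has))
  }, numeric(3))
  per_genus <- data.frame(genus = genera, tp = tally["tp", ],
                          fp = tally["fp", ], fn = tally["fn", ])
  per_genus$recall <- with(per_genus,
    ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_))
  per_genus$precision <- with(per_genus,
    ifelse(tp + fp > 0, 100 * tp / (tp + fp), 0))
  rownames(per_genus) <- NULL
  testable <- per_genus$tp + per_genus$fn > 0
  r <- mean(per_genus$recall[testable])
  p <- mean(per_genus$precision[testable])
  structure(list(macro_recall = r, macro_precision = p,
                 f1 = f1_harmonic(r, p), per_genus = per_genus),
            class = "eval_report")
}

#' Harmonic-mean F1 from macro recall and precision
#'
#' @param recall,precision macro averages (percentages or fractions, any
#'   common scale).
#' @return `2*R*P/(R+P)` on the same scale; 0 when both inputs are 0.
#' @export
f1_harmonic <- function(recall, precision) {
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: macro-recall %.3f, macro-precision %.3f, F1 %.3f (%% over %d genera)\n",
              x$macro_recall, x$macro_precision, x$f1, nrow(x$per_genus)))
  invisible(x)
}

#' Top-k accuracy of genus probability rankings
#'
#' Fraction of plasmids for which at least one true host genus appears
#' among the k highest-probability genera. Ties are broken
#' lexicographically by genus id so the ranking is deterministic.
#'
#' @param probabilities numeric matrix plasmid x genus (e.g. from
#'   [predict.host_classifier()]), or named list of named score vectors.
#' @param truths named list: plasmid id -> true genus set.
#' @param k rank cutoff; must not exceed the number of genera.
#' @return Fraction in \\[0, 1\\].
#' @export
top_k_accuracy <- function(probabilities, truths, k) {
  if (!is_count(k) || k < 1) stop_("k must be a positive integer")
  score_row <- function(id) {
    if (is.matrix(probabilities)) probabilities[id, ]
    else unlist(probabilities[[id]])
  }
  ids <- names(truths)
  hits <- vapply(ids, function(id) {
    s <- score_row(id)
    if (k > length(s)) stop_("k (%d) exceeds the number of genera (%d)",
                             k, length(s))
    top <- names(s)[order_c(-s, names(s))][seq_len(k)]
    length(intersect(top, truths[[id]])) > 0
  }, logical(1))
  mean(hits)
}
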