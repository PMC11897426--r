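# Pseudo host-label assignment for single-labelled training plasmids.
#
# Training corpora record only the genus a plasmid was isolated from, yet
# broad-host-range plasmids replicate in several genera. Each plasmid's
# protein-cluster content is scored against every genus with the augmented
# TF-IDF significance matrix, and when the normalized evidence for a single
# non-host genus dominates, that genus is added as one pseudo label.

#' Mean per-genus significance weight of a plasmid's proteins
#'
#' Averages, over all encoded proteins of a plasmid, the augmented TF-IDF
#' score of each protein's PC towards every genus:
#' \deqn{\bar W_j = \frac{1}{|P_s|} \sum_{i \in P_s} \mathrm{score}_{i,j}}
#' where \eqn{P_s} is the multiset of the plasmid's protein PCs (a protein
#' counts with its multiplicity). Proteins whose PC is absent from the
#' score matrix contribute zero weight but still count in the denominator;
#' a warning reports how many.
#'
#' @param profile list with `plasmid_id`, `observed_host` and `protein_pcs`
#'   (character vector, one entry per encoded protein).
#' @param sig a `significance_matrix` with method `"tfidf_pro"`.
#' @return Named numeric vector of mean weights, one per genus column of
#'   `sig`.
#' @export
plasmid_mean_weights <- function(profile, sig) {
  if (!identical(attr(sig, "method"), "tfidf_pro"))
    stop_("pseudo-labelling requires tfidf_pro scores, got method '%s'",
          attr(sig, "method") %||% "none")
  pcs <- profile$protein_pcs
  if (length(pcs) == 0L)
    stop_("plasmid %s has no encoded proteins", profile$plasmid_id %||% "?")
  idx <- match(pcs, rownames(sig))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L)
    warn_("plasmid %s: %d protein(s) map to PCs absent from the score matrix; counted with zero weight",
          profile$plasmid_id %||% "?", n_missing)
  rows <- idx[!is.na(idx)]
  w <- if (length(rows)) colSums(unclass(sig)[rows, , drop = FALSE])
       else stats::setNames(numeric(ncol(sig)), colnames(sig))
  w / length(pcs)
}

#' Normalize mean weights over non-host genera
#'
#' Rescales the mean weights of every genus other than the observed host to
#' sum to one:
#' \deqn{W'_j = \bar W_j / \sum_{j \ne H_s} \bar W_j}
#' The observed host is excluded from numerator candidates and denominator
#' alike; when all non-host weights are zero the normalization is
#' undefined and `NULL` is returned (the plasmid carries no cross-genus
#' evidence).
#'
#' @param mean_weights named numeric vector from [plasmid_mean_weights()].
#' @param observed_host genus id of the plasmid's observed host; must be a
#'   name of `mean_weights`.
#' @return Named numeric vector over non-host genera summing to 1, or
#'   `NULL` when undefined.
#' @export
normalize_weights <- function(mean_weights, observed_host) {
  if (!observed_host %in% names(mean_weights))
    stop_("observed host '%s' is not in the genus universe", observed_host)
  if (any(mean_weights < 0))
    stop_("negative mean weight: significance scores must be non-negative")
  w <- mean_weights[setdiff(names(mean_weights), observed_host)]
  denom <- sum(w)
  if (denom == 0) return(NULL)
  w / denom
}

#' Assign at most one pseudo host label
#'
#' A non-host genus becomes the pseudo label when its normalized weight
#' reaches the threshold:
#' \deqn{H_s^{pseudo} = \{H_s, j\} \text{ if } W'_j \ge \mathrm{threshold},
#'       \text{ else } \{H_s\}}
#' With the default threshold of 0.5 at most one genus can qualify; an
#' exact two-way tie at 0.5 is ambiguous evidence and assigns no pseudo
#' label (with a warning), keeping the at-most-one contract and favouring
#' precision.
#'
#' @param normalized output of [normalize_weights()] (may be `NULL`).
#' @param observed_host observed host genus id.
#' @param threshold qualification threshold in (0, 1]; default 0.5.
#' @return Character vector of final labels; always contains
#'   `observed_host`, length at most 2.
#' @export
assign_pseudo_label <- function(normalized, observed_host, threshold = 0.5) {
  if (!is_prob(threshold) || threshold <= 0 || threshold > 1)
    stop_("threshold must lie in (0, 1]")
  if (is.null(normalized)) return(observed_host)
  qual <- names(normalized)[normalized >= threshold]
  if (length(qual) == 1L) return(c(observed_host, qual))
  if (length(qual) > 1L)
    warn_("tie at threshold %g for host %s: no pseudo label assigned",
          threshold, observed_host)
  observed_host
}

#' Generate pseudo labels for a training corpus
#'
#' Runs [plasmid_mean_weights()], [normalize_weights()] and
#' [assign_pseudo_label()] for every plasmid profile and summarizes the
#' outcome. Pseudo-labelling is a training-time augmentation only; it is
#' never applied to prediction inputs.
#'
#' @param profiles list of plasmid profiles (see [read_profiles()]).
#' @param sig `significance_matrix` with method `"tfidf_pro"`.
#' @param threshold qualification threshold, default 0.5.
#' @return Object of class `pseudo_label_set`: list with
#'   \describe{
#'     \item{results}{data.frame (`plasmid_id`, `observed_host`,
#'       `pseudo_host` or NA, `pseudo_weight`, `n_proteins`), ordered by
#'       plasmid id}
#'     \item{summary}{list with `n_plasmids`, `n_pseudo`, per-genus pseudo
#'       counts, `n_undefined`, `n_tie`}
#'   }
#' @export
generate_pseudo_labels <- function(profiles, sig, threshold = 0.5) {
  if (length(profiles) == 0L) stop_("empty profile collection")
  ids <- vapply(profiles, function(p) p$plasmid_id, character(1))
  profiles <- profiles[order_c(ids)]
  n_tie <- 0L
  rows <- lapply(profiles, function(p) {
    res <- withCallingHandlers(
      {
        w <- plasmid_mean_weights(p, sig)
        norm <- normalize_weights(w, p$observed_host)
        labels <- assign_pseudo_label(norm, p$observed_host, threshold)
        pseudo <- setdiff(labels, p$observed_host)
        list(pseudo = if (length(pseudo)) pseudo else NA_character_,
             weight = if (length(pseudo)) unname(norm[pseudo]) else NA_real_,
             undefined = is.null(norm))
      },
      warning = function(w) {
        if (grepl("tie at threshold", conditionMessage(w)))
          n_tie <<- n_tie + 1L
        invokeRestart("muffleWarning")
      },
      error = function(e) stop_("plasmid %s: %s", p$plasmid_id,
                                conditionMessage(e))
    )
    data.frame(plasmid_id = p$plasmid_id, observed_host = p$observed_host,
               pseudo_host = res$pseudo, pseudo_weight = res$weight,
               n_proteins = length(p$protein_pcs), undefined = res$undefined)
  })
  results <- do.call(rbind, rows)
  per_genus <- table(results$pseudo_host[!is.na(results$pseudo_host)])
  out <- list(
    results = results[setdiff(names(results), "undefined")],
    summary = list(
      n_plasmids = nrow(results),
      n_pseudo = sum(!is.na(results$pseudo_host)),
      per_genus = as.list(per_genus),
      n_undefined = sum(results$undefined),
      n_tie = n_tie,
      threshold = threshold))
  class(out) <- "pseudo_label_set"
  out
}

#' @export
print.pseudo_label_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "pseudo_label_set: %d plasmids, %d pseudo labels (threshold %g), %d without cross-genus evidence, %d ties\n",
    s$n_plasmids, s$n_pseudo, s$threshold, s$n_undefined, s$n_tie))
  invisible(x)
}

#' Write pseudo-label results as TSV plus a JSON summary
#'
#' @param x `pseudo_label_set` from [generate_pseudo_labels()].
#' @param path output TSV path; the summary goes to `<path>.summary.json`.
#' @export
write_pseudo_labels <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(x$summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
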