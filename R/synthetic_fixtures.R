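# Synthetic plasmid corpora with planted genus-specific marker protein
# clusters, shared backbone clusters, genus-biased nucleotide composition,
# and a hidden fraction of dual-host plasmids whose observed label is a
# single genus. Every algorithmic stage of the package is testable against
# the sealed ground truth these corpora carry.

#' Configuration of the synthetic corpus generator
#'
#' @param n_genera number of host genera (>= 2).
#' @param markers_per_genus genus-exclusive marker PCs per genus.
#' @param n_backbone_pcs backbone PCs shared across all genera.
#' @param plasmids_per_genus plasmids generated per (primary) genus.
#' @param dual_host_fraction fraction of plasmids with a hidden second
#'   host genus (in \\[0, 1)).
#' @param genes_per_plasmid integer range (length-2 vector, min >= 2) of
#'   encoded genes per plasmid.
#' @param marker_gene_fraction fraction of a plasmid's genes drawn from
#'   marker PCs (the rest are backbone).
#' @param gene_length integer range of gene segment lengths in bases.
#' @param kmer_bias_strength strength of the per-genus tilt of nucleotide
#'   composition (0 = identical composition everywhere; ~1 = clearly
#'   learnable genus signal).
#' @param seed integer seed; the corpus is byte-identical for equal seeds.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genera = 20, markers_per_genus = 30,
                              n_backbone_pcs = 120, plasmids_per_genus = 100,
                              dual_host_fraction = 0.1,
                              genes_per_plasmid = c(6, 24),
                              marker_gene_fraction = 0.4,
                              gene_length = c(200, 800),
                              kmer_bias_strength = 1, seed = 1) {
  if (!is_count(n_genera) || n_genera < 2) stop_("n_genera must be >= 2")
  if (dual_host_fraction < 0 || dual_host_fraction >= 1)
    stop_("dual_host_fraction must lie in [0, 1)")
  if (markers_per_genus == 0 && marker_gene_fraction > 0)
    stop_("infeasible config: marker_gene_fraction > 0 with no marker PCs")
  if (length(genes_per_plasmid) != 2L || genes_per_plasmid[1L] < 2)
    stop_("genes_per_plasmid must be a range with minimum >= 2")
  if (length(gene_length) != 2L || gene_length[1L] < 10)
    stop_("gene_length must be a range with minimum >= 10")
  if (any(c(markers_per_genus, n_backbone_pcs, plasmids_per_genus) < 1) &&
      !(markers_per_genus == 0 && marker_gene_fraction == 0))
    stop_("all counts must be positive")
  if (marker_gene_fraction < 0 || marker_gene_fraction > 1 ||
      kmer_bias_strength < 0)
    stop_("invalid fraction or bias strength")
  structure(list(n_genera = as.integer(n_genera),
                 markers_per_genus = as.integer(markers_per_genus),
                 n_backbone_pcs = as.integer(n_backbone_pcs),
                 plasmids_per_genus = as.integer(plasmids_per_genus),
                 dual_host_fraction = dual_host_fraction,
                 genes_per_plasmid = as.integer(genes_per_plasmid),
                 marker_gene_fraction = marker_gene_fraction,
                 gene_length = as.integer(gene_length),
                 kmer_bias_strength = kmer_bias_strength,
                 seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate a plasmid corpus with hidden dual-host plasmids
#'
#' Each genus gets an exclusive set of marker PCs and a private nucleotide
#' composition (a multiplicative tilt of the uniform base distribution);
#' backbone PCs are shared by everyone. Single-host plasmids draw marker
#' genes only from their own genus; dual-host plasmids (a
#' `dual_host_fraction` of the corpus) carry at least one marker from EACH
#' of their two true hosts and a sequence whose gene segments mix the two
#' compositions. The observed label is sampled uniformly from the true
#' hosts, so a dual-host plasmid looks single-labelled to the training
#' pipeline.
#'
#' @param config a [simulation_config()].
#' @return Object of class `synthetic_corpus`: list with
#'   \describe{
#'     \item{truths}{data.frame `plasmid_id`, `observed_host`,
#'       `true_hosts` (semicolon-joined), `n_genes`}
#'     \item{hosts}{named character vector of observed labels (the
#'       training-visible view)}
#'     \item{sequences}{named character vector of nucleotide sequences}
#'     \item{profiles}{list of plasmid protein-cluster profiles}
#'     \item{assignments}{data.frame `protein_id`, `plasmid_id`, `pc_id`}
#'     \item{config}{the generating configuration}
#'   }
#' @export
simulate_corpus <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  genera <- sprintf("genus%02d", seq_len(config$n_genera))
  markers <- lapply(genera, function(g)
    sprintf("PCm_%s_%03d", g, seq_len(config$markers_per_genus)))
  names(markers) <- genera
  backbone <- sprintf("PCb_%03d", seq_len(config$n_backbone_pcs))
  bases <- c("A", "C", "G", "T")
  comp <- vapply(genera, function(g) {
    w <- exp(config$kmer_bias_strength * stats::rnorm(4))
    w / sum(w)
  }, numeric(4))

  n_total <- config$n_genera * config$plasmids_per_genus
  truths <- vector("list", n_total)
  sequences <- character(n_total)
  profiles <- vector("list", n_total)
  assign_rows <- vector("list", n_total)
  idx <- 0L
  for (g in genera) {
    for (i in seq_len(config$plasmids_per_genus)) {
      idx <- idx + 1L
      id <- sprintf("plasmid_%05d", idx)
      dual <- stats::runif(1) < config$dual_host_fraction
      true_hosts <- if (dual) c(g, sample(setdiff(genera, g), 1L)) else g
      observed <- if (dual) sample(true_hosts, 1L) else g
      n_genes <- sample(config$genes_per_plasmid[1L]:config$genes_per_plasmid[2L], 1L)
      is_marker <- stats::runif(n_genes) < config$marker_gene_fraction
      if (dual && sum(is_marker) < 2L) is_marker[1:2] <- TRUE
      n_mark <- sum(is_marker)
      marker_src <- if (dual && n_mark > 0L) {
        src <- sample(true_hosts, n_mark, replace = TRUE)
        for (h in true_hosts) if (!h %in% src) src[sample.int(n_mark, 1L)] <- h
        src
      } else rep(g, n_mark)
      src_per_gene <- character(n_genes)
      src_per_gene[is_marker] <- marker_src
      src_per_gene[!is_marker] <- sample(true_hosts, n_genes - n_mark,
                                         replace = TRUE)
      pcs <- character(n_genes)
      pcs[is_marker] <- vapply(marker_src, function(h)
        sample(markers[[h]], 1L), character(1))
      pcs[!is_marker] <- sample(backbone, n_genes - n_mark, replace = TRUE)
      genes <- vapply(src_per_gene, function(h) {
        len <- sample(config$gene_length[1L]:config$gene_length[2L], 1L)
        paste(sample(bases, len, replace = TRUE, prob = comp[, h]),
              collapse = "")
      }, character(1))
      truths[[idx]] <- data.frame(
        plasmid_id = id, observed_host = observed,
        true_hosts = paste(sort_c(true_hosts), collapse = ";"),
        n_genes = n_genes)
      sequences[idx] <- paste(genes, collapse = "")
      profiles[[idx]] <- list(plasmid_id = id, observed_host = observed,
                              protein_pcs = pcs)
      assign_rows[[idx]] <- data.frame(
        protein_id = sprintf("%s_p%03d", id, seq_len(n_genes)),
        plasmid_id = id, pc_id = pcs)
    }
  }
  truths <- do.call(rbind, truths)
  names(sequences) <- truths$plasmid_id
  structure(list(
    truths = truths,
    hosts = stats::setNames(truths$observed_host, truths$plasmid_id),
    sequences = sequences, profiles = profiles,
    assignments = do.call(rbind, assign_rows),
    config = config), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  n_dual <- sum(grepl(";", x$truths$true_hosts, fixed = TRUE))
  cat(sprintf("synthetic_corpus: %d plasmids, %d genera, %d hidden dual-host (seed %d)\n",
              nrow(x$truths), x$config$n_genera, n_dual, x$config$seed))
  invisible(x)
}

#' Split a corpus into the training-visible labels and a sealed answer key
#'
#' The visible view is exactly the single observed label per plasmid and
#' carries no information about hidden second hosts; the key records the
#' full true host sets for scoring.
#'
#' @param corpus a `synthetic_corpus` (or its `truths` data.frame).
#' @return List with `observed` (named character vector) and `key`
#'   (data.frame `plasmid_id`, `observed_host`, `true_hosts`).
#' @export
mask_labels <- function(corpus) {
  truths <- if (inherits(corpus, "synthetic_corpus")) corpus$truths else corpus
  if (is.null(truths) || nrow(truths) == 0L) stop_("empty truth table")
  list(observed = stats::setNames(truths$observed_host, truths$plasmid_id),
       key = truths[c("plasmid_id", "observed_host", "true_hosts")])
}

key_hidden_sets <- function(key) {
  hidden <- mapply(function(th, obs)
    setdiff(strsplit(th, ";", fixed = TRUE)[[1L]], obs),
    key$true_hosts, key$observed_host, SIMPLIFY = FALSE)
  names(hidden) <- key$plasmid_id
  hidden
}

#' Score recovered extra host labels against the sealed key
#'
#' An assigned extra genus counts as correct iff it is a hidden true host
#' of that plasmid (in `true_hosts` but not the observed label). Accepts
#' pseudo-label results, prediction objects (extra calls are the called
#' genera minus the observed host), or a plain named vector/list of extra
#' genus assignments.
#'
#' @param x a `pseudo_label_set`, a `host_predictions`, a named character
#'   vector (plasmid -> one extra genus) or a named list of extra genus
#'   sets.
#' @param key answer key from [mask_labels()].
#' @return List with `precision` (NA when nothing was assigned), `recall`,
#'   `n_assigned`, `n_correct`, `n_hidden`.
#' @export
score_against_truth <- function(x, key) {
  observed <- stats::setNames(key$observed_host, key$plasmid_id)
  extras <- if (inherits(x, "pseudo_label_set")) {
    res <- x$results[!is.na(x$results$pseudo_host), , drop = FALSE]
    stats::setNames(as.list(res$pseudo_host), res$plasmid_id)
  } else if (inherits(x, "host_predictions")) {
    ids <- rownames(x$probabilities)
    stats::setNames(lapply(ids, function(id)
      setdiff(x$calls[[id]], observed[id])), ids)
  } else if (is.character(x)) {
    as.list(x[!is.na(x)])
  } else as.list(x)
  unknown <- setdiff(names(extras), key$plasmid_id)
  if (length(unknown))
    stop_("unknown plasmid id(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  hidden <- key_hidden_sets(key)
  n_hidden <- sum(lengths(hidden))
  n_assigned <- sum(lengths(extras))
  n_correct <- sum(vapply(names(extras), function(id)
    length(intersect(extras[[id]], hidden[[id]])), numeric(1)))
  list(precision = if (n_assigned > 0) n_correct / n_assigned else NA_real_,
       recall = if (n_hidden > 0) n_correct / n_hidden else NA_real_,
       n_assigned = n_assigned, n_correct = n_correct, n_hidden = n_hidden)
}

#' Write a corpus to plain-text files
#'
#' Emits the plasmid FASTA, observed-label TSV, profile TSV, sealed truth
#' key TSV and the generating configuration as JSON, for use by the
#' command-line interface.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "plasmids.fasta")
  writeLines(paste0(">", names(corpus$sequences), "\n", corpus$sequences), fa)
  utils::write.table(
    data.frame(plasmid_id = names(corpus$hosts), genus = unname(corpus$hosts)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(plasmid_id = vapply(corpus$profiles, `[[`, character(1), "plasmid_id"),
               genus = vapply(corpus$profiles, `[[`, character(1), "observed_host"),
               pc_ids = vapply(corpus$profiles, function(p)
                 paste(p$protein_pcs, collapse = ","), character(1))),
    file.path(dir, "profiles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$truths, file.path(dir, "truth_key.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(corpus$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
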