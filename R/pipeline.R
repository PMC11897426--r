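# End-to-end convenience wrappers: fit one model from raw inputs, or run
# the three-stage ablation (plain benchmark, + pseudo labels, + pseudo
# labels and self-correction asymmetric loss).

#' Expand plasmid profiles into per-protein assignments
#'
#' @param profiles list of plasmid profiles (`plasmid_id`, `observed_host`,
#'   `protein_pcs`).
#' @return data.frame `protein_id`, `plasmid_id`, `pc_id` with generated
#'   protein ids.
#' @export
profiles_to_assignments <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(protein_id = sprintf("%s_p%03d", p$plasmid_id,
                                    seq_along(p$protein_pcs)),
               plasmid_id = p$plasmid_id, pc_id = p$protein_pcs)))
}

#' Fit a host-range classifier from sequences, labels and protein profiles
#'
#' Runs the full training pipeline: protein-cluster count table and
#' augmented TF-IDF scores from the profiles, pseudo-label generation,
#' label matrix assembly, featurization and classifier training. With
#' `pseudo = FALSE` and `self_correction = FALSE` this is the plain
#' multi-label benchmark (binary cross-entropy on the observed labels).
#'
#' @param sequences named character vector of plasmid sequences.
#' @param hosts named character vector of observed host genera (names must
#'   match `sequences`).
#' @param profiles plasmid protein-cluster profiles (required when
#'   `pseudo = TRUE`).
#' @param config a [train_config()].
#' @param pseudo augment training labels with pseudo host labels.
#' @param self_correction keep the self-correction asymmetric loss; when
#'   `FALSE` the loss is reduced to binary cross-entropy
#'   (`gamma_pos = gamma_neg = 0`, `tau = "off"`).
#' @return List of class `host_range_fit`: `model`, `pseudo` (the
#'   `pseudo_label_set` or `NULL`), `significance` (the score matrix or
#'   `NULL`), `genus_ids`.
#' @export
host_range_pipeline <- function(sequences, hosts, profiles = NULL,
                                config = train_config(), pseudo = TRUE,
                                self_correction = TRUE) {
  if (!setequal(names(sequences), names(hosts)))
    stop_("sequences and hosts must cover the same plasmids")
  hosts <- hosts[order_c(names(hosts))]
  sequences <- sequences[names(hosts)]
  if (!self_correction) {
    config$gamma_pos <- 0
    config$gamma_neg <- 0
    config$tau <- "off"
  }
  genus_ids <- sort_c(unique(unname(hosts)))
  sig <- NULL
  pl <- NULL
  if (pseudo) {
    if (is.null(profiles)) stop_("pseudo labelling requires protein profiles")
    sig <- compute_tfidf_pro(
      build_pc_count_table(profiles_to_assignments(profiles), hosts))
    pl <- generate_pseudo_labels(profiles, sig, config$pseudo_threshold)
  }
  labels <- build_label_matrix(hosts, genus_ids, pl)
  features <- featurize(sequences, config)
  model <- train_model(features, labels, config)
  structure(list(model = model, pseudo = pl, significance = sig,
                 genus_ids = genus_ids),
            class = "host_range_fit")
}

#' Three-stage ablation on a synthetic corpus
#'
#' Trains the plain benchmark (observed labels, binary cross-entropy), the
#' benchmark plus pseudo labels, and the full model (pseudo labels plus
#' self-correction asymmetric loss) on one corpus, then scores how well
#' each stage recovers the hidden second hosts of the planted dual-host
#' plasmids at the decision threshold.
#'
#' @param corpus a `synthetic_corpus` from [simulate_corpus()].
#' @param config a [train_config()]; the same seed and optimizer settings
#'   are used for all three stages.
#' @return data.frame with one row per stage (`benchmark`, `pseudo`,
#'   `full`): hidden-host `recall` and `precision`, counts, and the
#'   pseudo-label precision where applicable.
#' @export
ablation_study <- function(corpus, config = train_config()) {
  masked <- mask_labels(corpus)
  hosts <- masked$observed[order_c(names(masked$observed))]
  sequences <- corpus$sequences[names(hosts)]
  genus_ids <- sort_c(unique(unname(hosts)))
  features <- featurize(sequences, config)

  sig <- compute_tfidf_pro(
    build_pc_count_table(corpus$assignments, hosts))
  pl <- generate_pseudo_labels(corpus$profiles, sig, config$pseudo_threshold)

  bce <- config
  bce$gamma_pos <- 0
  bce$gamma_neg <- 0
  bce$tau <- "off"

  stages <- list(
    benchmark = list(cfg = bce, pseudo = NULL),
    pseudo = list(cfg = bce, pseudo = pl),
    full = list(cfg = config, pseudo = pl))
  rows <- lapply(names(stages), function(nm) {
    st <- stages[[nm]]
    labels <- build_label_matrix(hosts, genus_ids, st$pseudo)
    model <- train_model(features, labels, st$cfg)
    preds <- stats::predict(model, features)
    sc <- score_against_truth(preds, masked$key)
    data.frame(stage = nm, recall = sc$recall, precision = sc$precision,
               n_assigned = sc$n_assigned, n_correct = sc$n_correct,
               n_hidden = sc$n_hidden)
  })
  out <- do.call(rbind, rows)
  attr(out, "pseudo_precision") <- score_against_truth(pl, masked$key)$precision
  out
}
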