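# Multi-label genus classifier: dense and convolutional encoders with a
# sigmoid head, trained under a self-correction asymmetric loss. The
# network is a lightweight native implementation in base R matrix code
# (forward/backward passes and Adam written out explicitly), sized for
# corpora of a few thousand plasmids.

#' Training configuration
#'
#' Collects every tunable of the classifier and its loss. The loss
#' asymmetry requires `gamma_pos < gamma_neg` (unless both are 0, which
#' with `tau = "off"` reduces the loss to plain binary cross-entropy):
#' positive labels are rare, so easy negatives must be down-weighted
#' harder than easy positives. After `warmup_epochs` epochs the
#' self-correction mechanism treats any negative label predicted above
#' `tau` as a missing positive.
#'
#' @param gamma_pos focusing exponent for positive labels (default 1).
#' @param gamma_neg focusing exponent for negative labels (default 4).
#' @param tau self-correction threshold in (0, 1], or `"off"` to disable
#'   (default 0.9).
#' @param warmup_epochs epochs trained before self-correction activates
#'   (default 10); must be less than `epochs`.
#' @param pseudo_threshold pseudo-label qualification threshold (default 0.5).
#' @param decision_threshold prediction call threshold (default 0.4).
#' @param encoder `"nn"` (dense on k-mer frequencies), `"cnn"`
#'   (convolutional on one-hot windows), or `"nn+cnn"` (concatenated
#'   embeddings).
#' @param epochs,batch_size,learning_rate optimizer settings (Adam).
#' @param seed integer seed governing initialization and batch order.
#' @param eps probability clamp applied before logarithms (default 1e-8).
#' @param hidden_dim dense encoder width (default 64).
#' @param k k-mer size for the dense encoder input (default 4, a 256-d
#'   frequency vector).
#' @param window_len,stride one-hot window geometry for the convolutional
#'   encoder (default 2048/2048).
#' @param conv_filters,conv_width convolution filter count and width
#'   (defaults 32 and 8).
#' @return A list of class `train_config`.
#' @export
train_config <- function(gamma_pos = 1, gamma_neg = 4, tau = 0.9,
                         warmup_epochs = 10, pseudo_threshold = 0.5,
                         decision_threshold = 0.4, encoder = "nn",
                         epochs = 60, batch_size = 64, learning_rate = 1e-3,
                         seed = 1, eps = 1e-8, hidden_dim = 64, k = 4,
                         window_len = 2048, stride = 2048,
                         conv_filters = 32, conv_width = 8) {
  if (gamma_pos < 0 || gamma_neg < 0) stop_("focusing exponents must be >= 0")
  if (!(gamma_pos == 0 && gamma_neg == 0) && gamma_pos >= gamma_neg)
    stop_("asymmetry requires gamma_pos < gamma_neg (or both 0)")
  if (!identical(tau, "off") &&
      (!is_prob(tau) || tau <= 0 || tau > 1))
    stop_("tau must be in (0, 1] or \"off\"")
  if (!is_count(warmup_epochs) || warmup_epochs < 0)
    stop_("warmup_epochs must be a non-negative integer")
  if (!is_count(epochs) || epochs < 0) stop_("epochs must be >= 0")
  if (epochs > 0 && warmup_epochs >= epochs)
    stop_("warmup_epochs must be < epochs")
  if (!encoder %in% c("nn", "cnn", "nn+cnn"))
    stop_("unknown encoder '%s' (use nn, cnn, or nn+cnn)", encoder)
  if (batch_size < 1 || learning_rate <= 0) stop_("invalid optimizer settings")
  if (window_len < conv_width)
    stop_("window_len must be >= conv_width")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop_("decision_threshold must be in (0, 1)")
  structure(list(
    gamma_pos = gamma_pos, gamma_neg = gamma_neg, tau = tau,
    warmup_epochs = as.integer(warmup_epochs),
    pseudo_threshold = pseudo_threshold,
    decision_threshold = decision_threshold, encoder = encoder,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed), eps = eps,
    hidden_dim = as.integer(hidden_dim), k = as.integer(k),
    window_len = as.integer(window_len), stride = as.integer(stride),
    conv_filters = as.integer(conv_filters),
    conv_width = as.integer(conv_width)), class = "train_config")
}

#' Asymmetric focal loss terms for one probability
#'
#' The positive and negative building blocks of the loss:
#' \deqn{L^+ = (1-p)^{\gamma_+} \log p, \qquad
#'       L^- = p^{\gamma_-} \log(1-p)}
#' Both are non-positive; easy positives (p near 1) and easy negatives (p
#' near 0) contribute vanishing loss. Probabilities are clamped to
#' `[eps, 1-eps]` before the logarithms.
#'
#' @param p probability (vectorized).
#' @param gamma_pos,gamma_neg focusing exponents.
#' @param eps clamp (default 1e-8).
#' @return List with numeric `L_plus` and `L_minus`, same length as `p`.
#' @export
asymmetric_loss_terms <- function(p, gamma_pos, gamma_neg, eps = 1e-8) {
  p <- clamp_prob(p, eps)
  list(L_plus = (1 - p)^gamma_pos * log(p),
       L_minus = p^gamma_neg * log(1 - p))
}

#' Self-correction asymmetric loss for one label row
#'
#' \deqn{L = -\frac{1}{N}\sum_{i=1}^{N}
#'   \left[y_i L^+(p_i) + (1-y_i) L^-_{\mathrm{eff}}(p_i)\right]}
#' where for an active self-correction phase the effective negative term
#' switches to the positive branch once the model is confident:
#' \deqn{L^-_{\mathrm{eff}}(p_i) = \mathbb{1}(p_i < \tau) L^-(p_i) +
#'       \mathbb{1}(p_i \ge \tau) L^+(p_i)}
#' The indicator is a hard per-element switch on the current probability;
#' no gradient flows through the switch itself. With
#' `gamma_pos = gamma_neg = 0` and self-correction inactive this is mean
#' binary cross-entropy.
#'
#' @param p numeric probability row over the N genera.
#' @param y binary label row of the same length.
#' @param config a [train_config()].
#' @param self_correction_active whether the warm-up phase is over.
#' @return Scalar loss, non-negative.
#' @export
self_correction_loss <- function(p, y, config, self_correction_active = TRUE) {
  if (length(p) != length(y))
    stop_("probability and label rows differ in length (%d vs %d)",
          length(p), length(y))
  terms <- asymmetric_loss_terms(p, config$gamma_pos, config$gamma_neg,
                                 config$eps)
  neg_eff <- terms$L_minus
  if (self_correction_active && !identical(config$tau, "off")) {
    flip <- clamp_prob(p, config$eps) >= config$tau
    neg_eff[flip] <- terms$L_plus[flip]
  }
  -mean(y * terms$L_plus + (1 - y) * neg_eff)
}

# dL/dp for a probability/label matrix under the (self-correction)
# asymmetric loss with mean reduction over genera and batch. p must
# already be clamped.
loss_grad_p <- function(p, y, config, active) {
  gp <- config$gamma_pos
  gn <- config$gamma_neg
  d_plus <- (1 - p)^gp / p -
    (if (gp > 0) gp * (1 - p)^(gp - 1) * log(p) else 0)
  d_minus <- (if (gn > 0) gn * p^(gn - 1) * log(1 - p) else 0) -
    p^gn / (1 - p)
  d_neg <- d_minus
  if (active && !identical(config$tau, "off")) {
    flip <- p >= config$tau
    d_neg[flip] <- d_plus[flip]
  }
  -(y * d_plus + (1 - y) * d_neg) / length(p)
}

init_mat <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, sd = scale), nrow = nr, ncol = nc)
}

#' Build an untrained multi-label classifier
#'
#' Initializes the chosen encoder plus a sigmoid classifier head emitting
#' one independent probability per genus. Initialization is deterministic
#' given `config$seed` (He-scaled normal draws for ReLU layers, Glorot for
#' the head).
#'
#' @param config a [train_config()].
#' @param n_genera number of output genera (>= 2).
#' @param feature_dims list with `kmer_dim` (dense input width, default
#'   `4^config$k`); the convolutional input has 4 fixed channels.
#' @return Object of class `host_classifier` with untrained parameters and
#'   an empty genus vocabulary (filled by [train_model()]).
#' @export
build_model <- function(config, n_genera, feature_dims = list()) {
  if (!is_count(n_genera) || n_genera < 2) stop_("n_genera must be >= 2")
  kmer_dim <- feature_dims$kmer_dim %||% 4L^config$k
  set.seed(config$seed)
  params <- list()
  emb_dim <- 0L
  if (config$encoder %in% c("nn", "nn+cnn")) {
    params$W1 <- init_mat(kmer_dim, config$hidden_dim, sqrt(2 / kmer_dim))
    params$b1 <- numeric(config$hidden_dim)
    emb_dim <- emb_dim + config$hidden_dim
  }
  if (config$encoder %in% c("cnn", "nn+cnn")) {
    patch_dim <- 4L * config$conv_width
    params$Wc <- init_mat(patch_dim, config$conv_filters, sqrt(2 / patch_dim))
    params$bc <- numeric(config$conv_filters)
    emb_dim <- emb_dim + config$conv_filters
  }
  params$Wo <- init_mat(emb_dim, n_genera, sqrt(1 / emb_dim))
  params$bo <- numeric(n_genera)
  structure(list(config = config, n_genera = as.integer(n_genera),
                 kmer_dim = as.integer(kmer_dim), emb_dim = emb_dim,
                 genus_ids = NULL, params = params, history = NULL),
            class = "host_classifier")
}

#' Featurize sequences for a given encoder configuration
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param config a [train_config()]; determines which representations are
#'   built (`kmer` matrix for the dense encoder, `windows` list for the
#'   convolutional one).
#' @return List of class `host_features` with elements `kmer` and/or
#'   `windows`, plus `ids`.
#' @export
featurize <- function(sequences, config = train_config()) {
  out <- list(ids = names(sequences))
  if (config$encoder %in% c("nn", "nn+cnn"))
    out$kmer <- kmer_frequency_matrix(sequences, k = config$k)
  if (config$encoder %in% c("cnn", "nn+cnn"))
    out$windows <- lapply(sequences, one_hot_windows,
                          window_len = config$window_len,
                          stride = config$stride)
  structure(out, class = "host_features")
}

#' Build a multi-hot label matrix from observed and pseudo labels
#'
#' @param hosts named character vector: observed host genus per plasmid.
#' @param genus_ids genus universe (columns), lexicographically ordered.
#' @param pseudo optional `pseudo_label_set` from
#'   [generate_pseudo_labels()]; its pseudo hosts become additional
#'   positives with provenance `"pseudo"`.
#' @return Binary matrix plasmid x genus with a `provenance` attribute
#'   (character matrix: `""`, `"observed"` or `"pseudo"`).
#' @export
build_label_matrix <- function(hosts, genus_ids = sort_c(unique(hosts)),
                               pseudo = NULL) {
  ids <- names(hosts)
  y <- matrix(0, nrow = length(ids), ncol = length(genus_ids),
              dimnames = list(ids, genus_ids))
  prov <- matrix("", nrow = length(ids), ncol = length(genus_ids),
                 dimnames = list(ids, genus_ids))
  stopifnot(all(hosts %in% genus_ids))
  y[cbind(ids, unname(hosts))] <- 1
  prov[cbind(ids, unname(hosts))] <- "observed"
  if (!is.null(pseudo)) {
    res <- pseudo$results
    res <- res[!is.na(res$pseudo_host) & res$plasmid_id %in% ids &
                 res$pseudo_host %in% genus_ids, , drop = FALSE]
    if (nrow(res)) {
      y[cbind(res$plasmid_id, res$pseudo_host)] <- 1
      prov[cbind(res$plasmid_id, res$pseudo_host)] <- "pseudo"
    }
  }
  attr(y, "provenance") <- prov
  y
}

# ---- forward / backward -----------------------------------------------

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Unfold a 4 x L one-hot window into an (L - cw + 1) x (4 * cw) patch
# matrix for the convolution-as-matmul trick.
unfold_window <- function(w, cw) {
  L <- ncol(w)
  npos <- L - cw + 1L
  tw <- t(w)
  P <- matrix(0, nrow = npos, ncol = 4L * cw)
  for (o in seq_len(cw) - 1L)
    P[, (4L * o + 1L):(4L * o + 4L)] <- tw[(1L + o):(npos + o), , drop = FALSE]
  P
}

cnn_embed_sample <- function(stack, params, cw, want_grad = FALSE) {
  pres <- lapply(stack, function(w) {
    P <- unfold_window(w, min(cw, ncol(w)))
    A <- sweep(P %*% params$Wc, 2L, params$bc, "+")
    list(P = P, A = A)
  })
  embs <- vapply(pres, function(x) colMeans(relu(x$A)),
                 numeric(ncol(params$Wc)))
  emb <- if (is.matrix(embs)) rowMeans(embs) else embs
  if (want_grad) list(emb = emb, pres = pres) else list(emb = emb)
}

forward_pass <- function(model, features, rows, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  parts <- list()
  cache <- list()
  if (!is.null(p$W1)) {
    X <- features$kmer[rows, , drop = FALSE]
    H <- relu(sweep(X %*% p$W1, 2L, p$b1, "+"))
    parts$nn <- H
    if (want_cache) cache$X <- X
  }
  if (!is.null(p$Wc)) {
    cnn <- lapply(features$windows[rows], cnn_embed_sample, params = p,
                  cw = cfg$conv_width, want_grad = want_cache)
    parts$cnn <- do.call(rbind, lapply(cnn, function(x) x$emb))
    if (want_cache) cache$cnn <- cnn
  }
  E <- do.call(cbind, parts)
  Z <- sweep(E %*% p$Wo, 2L, p$bo, "+")
  P <- sigmoid(Z)
  list(P = P, E = E, cache = cache)
}

backward_pass <- function(model, fwd, Y, active) {
  cfg <- model$config
  p <- model$params
  Pc <- clamp_prob(fwd$P, cfg$eps)
  dP <- loss_grad_p(Pc, Y, cfg, active)
  dZ <- dP * Pc * (1 - Pc)
  grads <- list(Wo = crossprod(fwd$E, dZ), bo = colSums(dZ))
  dE <- dZ %*% t(p$Wo)
  offset <- 0L
  if (!is.null(p$W1)) {
    h <- ncol(p$W1)
    dH <- dE[, seq_len(h), drop = FALSE] * (fwd$E[, seq_len(h)] > 0)
    grads$W1 <- crossprod(fwd$cache$X, dH)
    grads$b1 <- colSums(dH)
    offset <- h
  }
  if (!is.null(p$Wc)) {
    f <- ncol(p$Wc)
    dWc <- matrix(0, nrow = nrow(p$Wc), ncol = f)
    dbc <- numeric(f)
    for (b in seq_along(fwd$cache$cnn)) {
      samp <- fwd$cache$cnn[[b]]
      demb <- dE[b, offset + seq_len(f)]
      nwin <- length(samp$pres)
      for (wn in samp$pres) {
        npos <- nrow(wn$A)
        dA <- (wn$A > 0) * matrix(demb / (nwin * npos), nrow = npos,
                                  ncol = f, byrow = TRUE)
        dWc <- dWc + crossprod(wn$P, dA)
        dbc <- dbc + colSums(dA)
      }
    }
    grads$Wc <- dWc
    grads$bc <- dbc
  }
  grads
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  list(params = params, state = state)
}

#' Train the multi-label host-genus classifier
#'
#' Mini-batch Adam under the self-correction asymmetric loss. Epochs
#' before `warmup_epochs` run with self-correction inactive (the plain
#' asymmetric loss, or binary cross-entropy when both gammas are 0);
#' afterwards negative labels predicted above `tau` are re-treated as
#' missing positives. Fully reproducible given `config$seed`.
#'
#' @param features a `host_features` object from [featurize()].
#' @param labels binary label matrix from [build_label_matrix()]; every
#'   row must have at least one positive.
#' @param config a [train_config()].
#' @return A trained `host_classifier` whose `history` data.frame records
#'   the mean loss and self-correction state per epoch.
#' @export
train_model <- function(features, labels, config = train_config()) {
  if (is.null(dim(labels)) || nrow(labels) == 0L) stop_("empty training set")
  if (any(rowSums(labels) < 1)) stop_("every plasmid needs >= 1 positive label")
  if (!is.null(features$ids) && !is.null(rownames(labels)) &&
      !identical(features$ids, rownames(labels)))
    stop_("feature ids and label matrix rows are not aligned")
  n <- nrow(labels)
  model <- build_model(config, ncol(labels),
                       list(kmer_dim = if (!is.null(features$kmer))
                         ncol(features$kmer) else NULL))
  model$genus_ids <- colnames(labels)
  if (config$epochs == 0L) return(model)
  state <- list(m = lapply(model$params, function(x) x * 0),
                v = lapply(model$params, function(x) x * 0))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        self_correction = logical(0))
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    active <- (epoch > config$warmup_epochs) && !identical(config$tau, "off")
    perm <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      rows <- perm[start:min(start + config$batch_size - 1L, n)]
      fwd <- forward_pass(model, features, rows, want_cache = TRUE)
      Y <- labels[rows, , drop = FALSE]
      Pc <- clamp_prob(fwd$P, config$eps)
      batch_losses <- c(batch_losses, mean(vapply(seq_along(rows), function(i)
        self_correction_loss(Pc[i, ], Y[i, ], config, active), numeric(1))))
      grads <- backward_pass(model, fwd, Y, active)
      t <- t + 1L
      upd <- adam_step(model$params, grads, state, config$learning_rate, t)
      model$params <- upd$params
      state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(batch_losses),
                                         self_correction = active))
  }
  model$history <- history
  model
}

#' Predict host genera for new plasmids
#'
#' Runs the trained classifier and calls every genus whose probability is
#' strictly above the decision threshold. By default a plasmid can receive
#' an empty call set; `min_one = TRUE` falls back to the single
#' highest-probability genus (flagged in the result) when nothing clears
#' the threshold.
#'
#' @param object a trained `host_classifier`.
#' @param features `host_features` for the query sequences.
#' @param decision_threshold call threshold in (0, 1); defaults to the
#'   model's configured value (0.4).
#' @param min_one guarantee at least one called genus per plasmid.
#' @param ... unused.
#' @return List of class `host_predictions`: `probabilities` (matrix
#'   plasmid x genus), `calls` (named list of genus sets) and `fallback`
#'   (logical, `TRUE` where `min_one` had to fill in).
#' @export
predict.host_classifier <- function(object, features,
                                    decision_threshold = NULL,
                                    min_one = FALSE, ...) {
  thr <- decision_threshold %||% object$config$decision_threshold
  if (thr <= 0 || thr >= 1) stop_("decision_threshold must be in (0, 1)")
  if (!is.null(object$params$W1) &&
      ncol(features$kmer) != object$kmer_dim)
    stop_("feature dimension %d does not match model input %d",
          ncol(features$kmer), object$kmer_dim)
  n <- length(features$ids)
  fwd <- forward_pass(object, features, seq_len(n))
  P <- fwd$P
  dimnames(P) <- list(features$ids, object$genus_ids)
  fallback <- logical(n)
  calls <- lapply(seq_len(n), function(i) {
    called <- object$genus_ids[P[i, ] > thr]
    if (!length(called) && min_one) {
      fallback[i] <<- TRUE
      called <- object$genus_ids[which.max(P[i, ])]
    }
    called
  })
  names(calls) <- features$ids
  structure(list(probabilities = P, calls = calls,
                 fallback = stats::setNames(fallback, features$ids),
                 decision_threshold = thr),
            class = "host_predictions")
}

#' @export
print.host_classifier <- function(x, ...) {
  cat(sprintf("host_classifier [%s encoder]: %d genera, %s\n",
              x$config$encoder, x$n_genera,
              if (is.null(x$history)) "untrained"
              else sprintf("%d epochs (final loss %.4f)",
                           max(x$history$epoch),
                           utils::tail(x$history$loss, 1L))))
  invisible(x)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a plain-text JSON archive holding the parameters, the
#' full training configuration and the genus vocabulary, so predictions
#' from a reloaded model are self-describing.
#'
#' @param model a `host_classifier`.
#' @param path checkpoint path (`.json`).
#' @return `save_model` the path, invisibly; `load_model` the restored
#'   `host_classifier`.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              n_genera = model$n_genera, kmer_dim = model$kmer_dim,
              emb_dim = model$emb_dim, genus_ids = model$genus_ids,
              params = lapply(model$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(train_config, obj$config[names(obj$config) %in%
    names(formals(train_config))])
  params <- lapply(obj$params, function(p)
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data))
  structure(list(config = cfg, n_genera = obj$n_genera,
                 kmer_dim = obj$kmer_dim, emb_dim = obj$emb_dim,
                 genus_ids = obj$genus_ids, params = params, history = NULL),
            class = "host_classifier")
}
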