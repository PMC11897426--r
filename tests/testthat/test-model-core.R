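test_that("asymmetric loss terms match their closed forms", {
  t0 <- asymmetric_loss_terms(0.5, 0, 0)
  expect_equal(t0$L_plus, log(0.5))
  expect_equal(t0$L_minus, log(0.5))

  # easy positive vanishes
  t1 <- asymmetric_loss_terms(1 - 1e-8, 1, 4)
  expect_lt(abs(t1$L_plus), 1e-7)
  expect_lte(t1$L_plus, 0)

  t2 <- asymmetric_loss_terms(0.8, 1, 4)
  expect_equal(t2$L_plus, 0.2 * log(0.8), tolerance = 1e-12)
  expect_equal(t2$L_minus, 0.8^4 * log(0.2), tolerance = 1e-12)
})

test_that("loss reduces to mean binary cross-entropy when unfocused", {
  cfg <- train_config(gamma_pos = 0, gamma_neg = 0, tau = "off")
  expect_equal(self_correction_loss(0.5, 1, cfg, FALSE), -log(0.5),
               tolerance = 1e-12)
  set.seed(41)
  for (rep_i in 1:20) {
    n <- sample(2:30, 1)
    p <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.3)
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(self_correction_loss(p, y, cfg, FALSE), bce,
                 tolerance = 1e-9)
    expect_equal(self_correction_loss(p, y, cfg, TRUE), bce,
                 tolerance = 1e-9)  # tau off: activation is a no-op
  }
})

test_that("self-correction flips confident negatives to the positive branch", {
  cfg <- train_config(gamma_pos = 1, gamma_neg = 4, tau = 0.9)
  # y = 0, p = 0.95 >= tau: the loss must use L_plus(0.95)
  expect_equal(self_correction_loss(0.95, 0, cfg, TRUE),
               -(1 - 0.95)^1 * log(0.95), tolerance = 1e-12)
  # inactive phase keeps the plain negative branch
  expect_equal(self_correction_loss(0.95, 0, cfg, FALSE),
               -0.95^4 * log(0.05), tolerance = 1e-12)

  cfg_off <- train_config(gamma_pos = 1, gamma_neg = 4, tau = "off")
  expect_equal(self_correction_loss(c(0.8, 0.6), c(1, 0), cfg_off, TRUE),
               -0.5 * (0.2 * log(0.8) + 0.6^4 * log(0.4)),
               tolerance = 1e-12)
  expect_error(self_correction_loss(c(0.5, 0.5), 1, cfg, TRUE), "length")
})

test_that("loss is non-negative and finite everywhere", {
  set.seed(42)
  cfg <- train_config()
  for (rep_i in 1:30) {
    n <- sample(1:20, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.5)
    for (active in c(TRUE, FALSE)) {
      l <- self_correction_loss(p, y, cfg, active)
      expect_gte(l, 0)
      expect_true(is.finite(l))
    }
  }
})

test_that("easy negatives are down-weighted more as gamma_neg grows", {
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    mags <- vapply(c(0, 1, 2, 4, 8), function(gn)
      abs(asymmetric_loss_terms(p, 0, gn)$L_minus), numeric(1))
    expect_true(all(diff(mags) <= 1e-15))
  }
})

test_that("for a confident negative the loss gradient pushes p upward", {
  cfg <- train_config(gamma_pos = 1, gamma_neg = 4, tau = 0.9)
  h <- 1e-6
  for (p in c(0.9, 0.95, 0.99)) {
    fd <- (self_correction_loss(p + h, 0, cfg, TRUE) -
           self_correction_loss(p - h, 0, cfg, TRUE)) / (2 * h)
    expect_lt(fd, 0)  # decreasing in p: raising p lowers the loss
  }
  # sanity: below tau the gradient still pushes a negative down
  fd_low <- (self_correction_loss(0.5 + h, 0, cfg, TRUE) -
             self_correction_loss(0.5 - h, 0, cfg, TRUE)) / (2 * h)
  expect_gt(fd_low, 0)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(43)
  cfg <- train_config(gamma_pos = 1, gamma_neg = 4, tau = 0.9)
  h <- 1e-6
  for (rep_i in 1:10) {
    p <- matrix(runif(6, 0.05, 0.95), 2, 3)
    p[abs(p - cfg$tau) < 1e-3] <- 0.8  # keep clear of the branch switch
    y <- matrix(rbinom(6, 1, 0.5), 2, 3)
    for (active in c(TRUE, FALSE)) {
      g <- plasmidhostr:::loss_grad_p(p, y, cfg, active)
      for (idx in seq_along(p)) {
        pp <- p; pp[idx] <- p[idx] + h
        pm <- p; pm[idx] <- p[idx] - h
        # total loss over the matrix, mean over genera then samples
        lt <- function(pm_) mean(vapply(1:2, function(r)
          self_correction_loss(pm_[r, ], y[r, ], cfg, active), numeric(1)))
        fd <- (lt(pp) - lt(pm)) / (2 * h)
        expect_equal(g[idx], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("model construction is deterministic and shaped by the encoder", {
  cfg <- train_config(seed = 7, encoder = "nn+cnn", window_len = 16,
                      stride = 16, conv_width = 4, conv_filters = 8,
                      hidden_dim = 12)
  m1 <- build_model(cfg, 4)
  m2 <- build_model(cfg, 4)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$emb_dim, 12 + 8)
  expect_equal(dim(m1$params$Wo), c(20L, 4L))
  expect_error(build_model(cfg, 1), "n_genera")
  expect_error(train_config(encoder = "transformer"), "unknown encoder")
  expect_error(train_config(gamma_pos = 4, gamma_neg = 1), "asymmetry")
  expect_error(train_config(warmup_epochs = 60, epochs = 60), "warmup")
})

test_that("untrained forward pass emits sigmoid probabilities per genus", {
  set.seed(44)
  seqs <- setNames(replicate(6, paste(sample(c("A", "C", "G", "T"), 80, TRUE),
                                      collapse = "")), paste0("p", 1:6))
  hosts <- setNames(rep(c("gA", "gB"), 3), names(seqs))
  for (enc in c("nn", "cnn", "nn+cnn")) {
    cfg <- train_config(encoder = enc, epochs = 0, window_len = 16,
                        stride = 16, conv_width = 4, conv_filters = 6,
                        seed = 9)
    feats <- featurize(seqs, cfg)
    model <- train_model(feats, build_label_matrix(hosts), cfg)
    preds <- predict(model, feats)
    expect_equal(dim(preds$probabilities), c(6L, 2L))
    expect_true(all(preds$probabilities > 0 & preds$probabilities < 1))
  }
})

test_that("zero-epoch training returns the initialized model unchanged", {
  cfg <- train_config(epochs = 0, seed = 13)
  set.seed(99)
  feats <- list(ids = paste0("p", 1:4),
                kmer = matrix(runif(4 * 256), 4, 256,
                              dimnames = list(paste0("p", 1:4), NULL)))
  class(feats) <- "host_features"
  labels <- build_label_matrix(setNames(c("a", "a", "b", "b"), feats$ids))
  m <- train_model(feats, labels, cfg)
  ref <- build_model(cfg, 2, list(kmer_dim = 256))
  expect_identical(m$params, ref$params)
  expect_null(m$history)
})

test_that("training loss stays finite on random data", {
  set.seed(45)
  ids <- paste0("p", 1:30)
  feats <- structure(list(ids = ids,
    kmer = matrix(runif(30 * 16), 30, 16, dimnames = list(ids, NULL))),
    class = "host_features")
  labels <- build_label_matrix(setNames(sample(c("a", "b", "c"), 30, TRUE),
                                        ids))
  cfg <- train_config(epochs = 10, warmup_epochs = 2, batch_size = 8,
                      k = 2, seed = 3)
  m <- train_model(feats, labels, cfg)
  expect_equal(nrow(m$history), 10L)
  expect_true(all(is.finite(m$history$loss)))
  expect_equal(m$history$self_correction, c(rep(FALSE, 2), rep(TRUE, 8)))
})

test_that("training is reproducible and separates a two-genus corpus", {
  corpus <- simulate_corpus(simulation_config(
    n_genera = 2, plasmids_per_genus = 30, dual_host_fraction = 0,
    kmer_bias_strength = 2, markers_per_genus = 10, n_backbone_pcs = 40,
    seed = 5))
  cfg <- train_config(gamma_pos = 0, gamma_neg = 0, tau = "off",
                      epochs = 50, warmup_epochs = 0, batch_size = 16,
                      seed = 5)
  feats <- featurize(corpus$sequences, cfg)
  labels <- build_label_matrix(corpus$hosts)
  m <- train_model(feats, labels, cfg)
  m_again <- train_model(feats, labels, cfg)
  expect_identical(m$params, m_again$params)

  preds <- predict(m, feats)
  rep <- macro_metrics(preds$calls, lapply(corpus$hosts, identity))
  expect_equal(rep$f1, 100)
})

test_that("prediction thresholding is strict with an argmax fallback", {
  cfg <- train_config(seed = 1, hidden_dim = 2, k = 2)
  model <- build_model(cfg, 3, list(kmer_dim = 16))
  model$genus_ids <- c("A", "B", "C")
  # zero the network so probabilities equal sigmoid(bo): fully controlled
  model$params$W1[] <- 0
  model$params$b1[] <- 0
  model$params$Wo[] <- 0
  ids <- "p1"
  feats <- structure(list(ids = ids,
    kmer = matrix(runif(16), 1, 16, dimnames = list(ids, NULL))),
    class = "host_features")

  model$params$bo <- qlogis(c(0.9, 0.41, 0.1))
  got <- predict(model, feats, decision_threshold = 0.4)
  expect_equal(got$calls$p1, c("A", "B"))

  model$params$bo <- qlogis(c(0.2, 0.35, 0.1))
  expect_equal(predict(model, feats)$calls$p1, character(0))
  fb <- predict(model, feats, min_one = TRUE)
  expect_equal(fb$calls$p1, "B")
  expect_true(fb$fallback[["p1"]])

  # threshold is strict: probability exactly at the threshold is not called
  model$params$bo <- c(0, 0, 0)  # sigmoid(0) = 0.5 exactly
  expect_equal(predict(model, feats, decision_threshold = 0.5)$calls$p1,
               character(0))
  expect_error(predict(model, feats, decision_threshold = 1.2), "decision")
})

test_that("checkpoints round-trip through plain-text JSON", {
  set.seed(46)
  ids <- paste0("p", 1:10)
  feats <- structure(list(ids = ids,
    kmer = matrix(runif(10 * 16), 10, 16, dimnames = list(ids, NULL))),
    class = "host_features")
  labels <- build_label_matrix(setNames(rep(c("a", "b"), 5), ids))
  cfg <- train_config(epochs = 5, warmup_epochs = 1, batch_size = 4,
                      k = 2, seed = 8)
  m <- train_model(feats, labels, cfg)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, feats)$probabilities,
               predict(m, feats)$probabilities, tolerance = 1e-12)
  expect_equal(m2$genus_ids, m$genus_ids)
})

test_that("pseudo positives enter the label matrix with provenance", {
  hosts <- c(p1 = "gA", p2 = "gB", p3 = "gA")
  pl <- list(results = data.frame(
    plasmid_id = c("p1", "p2", "p3"),
    observed_host = c("gA", "gB", "gA"),
    pseudo_host = c("gB", NA, NA),
    pseudo_weight = c(0.8, NA, NA), n_proteins = c(3L, 2L, 4L)))
  class(pl) <- "pseudo_label_set"
  y <- build_label_matrix(hosts, c("gA", "gB"), pl)
  expect_equal(unname(rowSums(y)), c(2, 1, 1))
  expect_equal(attr(y, "provenance")["p1", "gB"], "pseudo")
  expect_equal(attr(y, "provenance")["p1", "gA"], "observed")
})
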