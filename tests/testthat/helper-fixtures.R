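# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain nested loops so they stay independent of the vectorized
# implementation paths they check.

# Random PC x genus count table with no all-zero rows/columns.
random_count_table <- function(n_pc, n_genus, max_count = 9) {
  repeat {
    m <- matrix(sample(0:max_count, n_pc * n_genus, replace = TRUE),
                nrow = n_pc,
                dimnames = list(sprintf("PC%02d", seq_len(n_pc)),
                                sprintf("g%02d", seq_len(n_genus))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  class(m) <- c("pc_count_table", class(m))
  m
}

oracle_tfidf <- function(tab) {
  tab <- unclass(tab)
  G <- ncol(tab)
  out <- tab * 0
  for (i in seq_len(nrow(tab))) {
    gi <- sum(tab[i, ] > 0)
    for (j in seq_len(ncol(tab)))
      out[i, j] <- tab[i, j] / sum(tab[, j]) * log(G / gi)
  }
  out
}

oracle_tfidf_pro <- function(tab) {
  tab <- unclass(tab)
  G <- ncol(tab)
  out <- tab * 0
  for (i in seq_len(nrow(tab))) {
    gi <- sum(tab[i, ] > 0)
    for (j in seq_len(ncol(tab)))
      out[i, j] <- tab[i, j] / sum(tab[, j]) * tab[i, j] / sum(tab[i, ]) *
        (log((G + 1) / (gi + 1)) + 1)
  }
  out
}

# Naive sliding-window k-mer counter over a character vector; skips words
# containing non-ACGT symbols.
oracle_kmer_counts <- function(sequence, k) {
  sequence <- toupper(sequence)
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1],
                      1, paste, collapse = ""), method = "radix")
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  n <- nchar(sequence)
  if (n >= k) {
    for (s in 1:(n - k + 1)) {
      w <- substr(sequence, s, s + k - 1)
      if (w %in% kmers) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# Union-find connected components over an edge list (two-column matrix of
# ids); returns a named membership vector.
oracle_components <- function(edges) {
  ids <- unique(c(edges[, 1], edges[, 2]))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1])
    b <- find(edges[r, 2])
    if (a != b) parent[[a]] <- b
  }
  stats::setNames(vapply(ids, find, character(1)), ids)
}

# Nested-loop confusion counts per genus.
oracle_confusion <- function(predictions, truths, genera) {
  out <- list()
  for (g in genera) {
    tp <- fp <- fn <- 0
    for (id in names(truths)) {
      in_t <- g %in% truths[[id]]
      in_p <- g %in% predictions[[id]]
      if (in_t && in_p) tp <- tp + 1
      if (!in_t && in_p) fp <- fp + 1
      if (in_t && !in_p) fn <- fn + 1
    }
    out[[g]] <- c(tp = tp, fp = fp, fn = fn)
  }
  out
}

# Tiny deterministic profile set over a fixed significance matrix.
toy_significance <- function() {
  m <- matrix(c(0.9, 0.0, 0.1,
                0.0, 0.6, 0.2,
                0.1, 0.2, 0.8,
                0.2, 0.2, 0.2),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("PC1", "PC2", "PC3", "PC4"),
                              c("gA", "gB", "gC")))
  plasmidhostr:::new_significance_matrix(m, "tfidf_pro")
}

small_corpus <- function(seed = 3, ...) {
  args <- list(n_genera = 5, plasmids_per_genus = 30,
               markers_per_genus = 10, n_backbone_pcs = 40, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_corpus(do.call(simulation_config, args))
}
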