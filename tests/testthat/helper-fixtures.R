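# Shared fixtures and independent oracles for the test suite.

make_landscape <- function(seed = 1, dims = c(30, 30), n_vars = 4,
                           autocorr_scale = 4) {
  generate_landscape(seed = seed, grid_shape = dims, n_vars = n_vars,
                     autocorr_scale = autocorr_scale)
}

make_species <- function(land, seed = 1, range_cut = 0.35,
                         breadth = c(1, 1.2)) {
  vars <- names(land$layers)[1:2]
  np <- tibble::tibble(var = vars, optimum = c(0.3, -0.2), breadth = breadth)
  generate_virtual_species(land, np, range_cut = range_cut,
                           taxon_id = paste0("sp", seed))
}

# Brute-force AUC: pairwise concordance, ties counting one half.
bf_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold search over a dense grid of cuts in [0, 1] plus the
# observed scores: returns the maximum attainable Jaccard between
# (score >= t) and the presence labels.
bf_best_jaccard <- function(scores, labels) {
  cuts <- sort(unique(c(scores, seq(0, 1, by = 0.001))))
  best <- -Inf
  for (t in cuts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    den <- sum(pred | labels == 1L)
    j <- if (den == 0) 1 else tp / den
    if (j > best) best <- j
  }
  best
}

# Independent eigendecomposition route to PCA variance fractions.
bf_variance_fractions <- function(X) {
  Z <- scale(X)
  ev <- eigen(stats::cov(Z), symmetric = TRUE)$values
  ev / sum(ev)
}

# Richness field independent of any protected-area placement: a stack of
# virtual-species true ranges on their own landscape.
make_independent_richness <- function(seed, dims = c(80, 80), n_taxa = 15) {
  land <- generate_landscape(seed = seed, grid_shape = dims, n_vars = 3,
                             autocorr_scale = 4)
  ranges <- lapply(seq_len(n_taxa), function(i) {
    np <- tibble::tibble(
      var = names(land$layers),
      optimum = sin(seed + i * (1:3)),
      breadth = 0.8 + 0.1 * ((i + seq_len(3)) %% 4)
    )
    sp <- generate_virtual_species(land, np, range_cut = 0.3,
                                   taxon_id = paste0("t", i))
    binarize(sp$true_suitability, 0.3, taxon_id = sp$taxon_id,
             scenario_id = "calib")
  })
  stack_richness(ranges)
}
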