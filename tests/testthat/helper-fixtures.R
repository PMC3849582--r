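# Shared fixtures and independent oracles used across test files.

worm_small_gmt <- function() {
  system.file("extdata", "celegans_small_sets.gmt", package = "phenosets")
}

fly_small_gmt <- function() {
  system.file("extdata", "dmelanogaster_small_sets.gmt",
              package = "phenosets")
}

# A small collection built in code: three partially overlapping sets.
toy_collection <- function() {
  geneset_collection(list(
    gene_set("alpha", c("g1", "g2", "g3")),
    gene_set("beta", c("g3", "g4")),
    gene_set("gamma", c("g5", "g6", "g7", "g8"))
  ), label = "toy")
}

# Random unrooted binary tree with positive branch lengths and its additive
# distance matrix (independent of the package's fitting code).
random_additive <- function(n, seed) {
  withr::local_seed(seed)
  phy <- ape::unroot(ape::rtree(n, tip.label = paste0("L", seq_len(n))))
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.2, 1)
  list(tree = phy, D = as.matrix(ape::cophenetic.phylo(phy)))
}

# Symmetric noisy distance matrix for topology-search tests.
random_distance_matrix <- function(n, seed, noise = 0.1) {
  ra <- random_additive(n, seed)
  withr::local_seed(seed + 1000L)
  E <- matrix(stats::runif(n * n, 0, noise), n, n)
  D <- ra$D + (E + t(E)) / 2
  diag(D) <- 0
  D
}

# Brute-force double-loop evaluation of the weighted least-squares tree
# criterion, independent of the package's vectorized path.
brute_force_sos <- function(D, phy, P, eps = 1e-6, nrep = 1) {
  d_exp <- as.matrix(ape::cophenetic.phylo(phy))
  labs <- rownames(D)
  total <- 0
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i) next
      Dij <- D[labs[i], labs[j]]
      denom <- if (P == 0) 1 else max(Dij, eps)^P
      total <- total + nrep * (Dij - d_exp[labs[i], labs[j]])^2 / denom
    }
  }
  total
}

# Reference Benjamini-Hochberg step-up, written independently of p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Monte-Carlo p-value for the PAGE z of a random n-gene set drawn iid from
# the observed score distribution (the null the parametric reference models).
resampling_null_p <- function(scores, n_i, z_obs, draws = 1e4, seed = 1) {
  withr::local_seed(seed)
  sims <- matrix(sample(scores, n_i * draws, replace = TRUE), nrow = n_i)
  z_null <- sqrt(n_i) * (colMeans(sims) - mean(scores)) / stats::sd(scores)
  mean(abs(z_null) >= abs(z_obs))
}

# Collection of `n_sets` random gene sets over the names of a score vector.
random_set_collection <- function(score_names, n_sets, size_range, seed) {
  withr::local_seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    s <- sample(seq.int(size_range[1], size_range[2]), 1L)
    gene_set(sprintf("rand%04d", i), sample(score_names, s))
  })
  geneset_collection(sets, label = "random")
}
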