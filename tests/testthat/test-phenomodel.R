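test_that("overlap distance matches hand arithmetic and its bounds", {
  expect_equal(pairwise_distance(c("a", "b"), c("A", "B")), 0)
  expect_equal(pairwise_distance(c("a", "b"), c("c", "d")), 1)

  # the two printed neuron sets share exactly one gene (mig-2's locus tag)
  coll <- read_gmt(worm_small_gmt())
  expect_equal(
    pairwise_distance(coll$sets$neuron_morphology_variant,
                      coll$sets$ectopic_neurite_outgrowth),
    1 - 1 / 6
  )

  # a strict subset sits at distance zero (min-size denominator)
  expect_equal(pairwise_distance(c("a", "b"), c("a", "b", "c", "d")), 0)
  expect_error(pairwise_distance(character(), "a"), "empty")
})

test_that("distance matrices are symmetric, bounded, zero-diagonal", {
  sim <- simulate_association_table(planted_collection_spec(seed = 5))
  coll <- build_collection(
    data.frame(phenotype_term = sim$pairs$phenotype,
               gene_id = sim$pairs$gene), "syn")
  D <- distance_matrix(coll)
  expect_equal(rownames(D), sort(names(coll$sets)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))

  # three pairwise-disjoint sets: off-diagonals all one
  dj <- geneset_collection(list(gene_set("a", c("x1", "x2")),
                                gene_set("b", c("y1", "y2")),
                                gene_set("c", c("z1", "z2"))), "dj")
  Dd <- distance_matrix(dj)
  expect_equal(Dd[upper.tri(Dd)], rep(1, 3))

  # planted blocks: mean within-block distance below between-block
  blocks <- sim$ledger$blocks
  b1 <- sort(names(blocks)[blocks == 1])
  b2 <- sort(names(blocks)[blocks == 2])
  expect_lt(mean(D[b1, b1][upper.tri(D[b1, b1])]), mean(D[b1, b2]))
})

test_that("criterion matches a brute-force double-loop evaluation", {
  for (seed in 1:3) {
    ra <- random_additive(5, seed)
    D <- random_distance_matrix(5, seed + 50)
    phy <- ra$tree
    phy$tip.label <- rownames(D)  # relabel to match
    for (P in c(2, 0)) {
      cfg <- tree_fit_config(P = P)
      expect_equal(sum_of_squares(D, phy, cfg),
                   brute_force_sos(D, phy, P), tolerance = 1e-12)
    }
  }
})

test_that("criterion respects weights, replicates, and perfect fits", {
  ra <- random_additive(6, 42)
  cfg <- tree_fit_config(P = 2)
  # a tree whose path lengths reproduce D exactly scores zero
  expect_equal(sum_of_squares(ra$D, ra$tree, cfg), 0, tolerance = 1e-18)
  # P = 0 reduces to the unweighted residual sum of squares
  D <- random_distance_matrix(6, 9)
  phy <- ra$tree
  phy$tip.label <- rownames(D)
  d_exp <- as.matrix(ape::cophenetic.phylo(phy))[rownames(D), colnames(D)]
  expect_equal(sum_of_squares(D, phy, tree_fit_config(P = 0)),
               sum((D - d_exp)[upper.tri(D)]^2), tolerance = 1e-12)
  # n_ij scales the criterion linearly
  expect_equal(sum_of_squares(D, phy, tree_fit_config(P = 0,
                                                      n_replicates = 3)),
               3 * sum_of_squares(D, phy, tree_fit_config(P = 0)),
               tolerance = 1e-12)
  expect_error(sum_of_squares(D[1:4, 1:4], phy, cfg), "leaves")
})

test_that("criterion is invariant under consistent leaf relabeling", {
  ra <- random_additive(6, 13)
  D <- random_distance_matrix(6, 14)
  phy <- ra$tree
  phy$tip.label <- rownames(D)
  base <- sum_of_squares(D, phy, tree_fit_config())
  perm <- paste0("renamed_", seq_len(6))
  phy2 <- phy
  phy2$tip.label <- perm[match(phy$tip.label, rownames(D))]
  D2 <- D
  dimnames(D2) <- list(perm, perm)
  expect_equal(sum_of_squares(D2, phy2, tree_fit_config()), base,
               tolerance = 1e-12)
})

test_that("three-leaf branch lengths follow the closed-form solution", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.6
  D["a", "c"] <- D["c", "a"] <- 0.8
  D["b", "c"] <- D["c", "b"] <- 0.4
  ft <- fit_tree(D)
  expect_equal(ft$sum_of_squares, 0, tolerance = 1e-18)
  expect_equal(ft$fitted, D, tolerance = 1e-12)
  # x_a = (D_ab + D_ac - D_bc) / 2, etc.
  lens <- sort(ft$tree$edge.length)
  expect_equal(lens, sort(c((0.6 + 0.8 - 0.4) / 2,
                            (0.6 + 0.4 - 0.8) / 2,
                            (0.8 + 0.4 - 0.6) / 2)), tolerance = 1e-12)
})

test_that("branch-length fits recover additive matrices exactly", {
  for (seed in c(2, 21)) {
    ra <- random_additive(5, seed)
    ft <- fit_branch_lengths(ra$tree, ra$D, tree_fit_config())
    expect_equal(ft$sum_of_squares, 0, tolerance = 1e-15)
    expect_equal(ft$fitted[rownames(ra$D), colnames(ra$D)], ra$D,
                 tolerance = 1e-9)
    # branch-length multiset recovered
    expect_equal(sort(ft$tree$edge.length), sort(ra$tree$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("fitted branch lengths are nonnegative and locally optimal", {
  D <- random_distance_matrix(6, 31, noise = 0.3)
  ft <- fit_tree(D)
  expect_true(all(ft$tree$edge.length >= 0))
  expect_gt(ft$sum_of_squares, 0)
  # hand-perturbing any branch cannot beat the least-squares solution
  withr::local_seed(77)
  for (k in 1:10) {
    pert <- ft$tree
    i <- sample(length(pert$edge.length), 1)
    pert$edge.length[i] <- max(0, pert$edge.length[i] + rnorm(1, 0, 0.05))
    expect_gte(sum_of_squares(D, pert, ft$config),
               ft$sum_of_squares - 1e-12)
  }
  expect_error(
    fit_branch_lengths(structure(list(edge = cbind(4L, 1:3),
                                      tip.label = c("a", "a", "b"),
                                      Nnode = 1L), class = "phylo"),
                       D[1:3, 1:3]),
    "duplicate"
  )
})

test_that("topology search matches exhaustive enumeration on small trees", {
  for (case in list(list(n = 5, seed = 101), list(n = 6, seed = 202),
                    list(n = 6, seed = 303))) {
    D <- random_distance_matrix(case$n, case$seed, noise = 0.15)
    for (P in c(2, 0)) {
      cfg <- tree_fit_config(P = P)
      all_t <- phangorn::allTrees(case$n, rooted = FALSE,
                                  tip.label = rownames(D))
      best <- min(vapply(all_t, function(tt) {
        fit_branch_lengths(tt, D, cfg)$sum_of_squares
      }, numeric(1)))
      expect_equal(fit_tree(D, cfg)$sum_of_squares, best,
                   tolerance = 1e-8)
    }
  }
})

test_that("additive matrices from a known topology are recovered", {
  ra <- random_additive(6, 88)
  ft <- fit_tree(ra$D)
  expect_equal(ft$sum_of_squares, 0, tolerance = 1e-12)
  # recovered topology shares every bipartition with the generating tree
  want <- lapply(tree_bipartitions(ra$tree), sort)
  got <- tree_bipartitions(ft)
  n_all <- length(ra$tree$tip.label)
  norm_split <- function(s, labs) {
    if (labs[1] %in% s) sort(s) else sort(setdiff(labs, s))
  }
  labs <- sort(ra$tree$tip.label)
  expect_setequal(
    vapply(got, function(s) paste(norm_split(s, labs), collapse = "|"),
           character(1)),
    vapply(want, function(s) paste(norm_split(s, labs), collapse = "|"),
           character(1))
  )
})

test_that("three labels give the unique unrooted topology", {
  coll <- geneset_collection(list(gene_set("a", c("x", "y")),
                                  gene_set("b", c("y", "z")),
                                  gene_set("c", c("z", "w"))), "t3")
  ft <- fit_tree(distance_matrix(coll))
  expect_equal(sort(ft$tree$tip.label), c("a", "b", "c"))
  expect_equal(ft$tree$Nnode, 1L)
})

test_that("zero off-diagonal distances are handled via epsilon", {
  # a set and its strict subset: observed distance zero off the diagonal
  coll <- geneset_collection(list(
    gene_set("whole", c("g1", "g2", "g3", "g4")),
    gene_set("part", c("g1", "g2")),
    gene_set("other", c("h1", "h2", "h3")),
    gene_set("fourth", c("g4", "h1", "k1"))
  ), "nested")
  D <- distance_matrix(coll)
  expect_equal(D["whole", "part"], 0)
  expect_warning(ft <- fit_tree(D, tree_fit_config(P = 2)), "epsilon")
  expect_true(is.finite(ft$sum_of_squares))
})

test_that("planted two-block collections yield a block bipartition", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_association_table(
      planted_collection_spec(n_phenotypes = 12, seed = s))
    coll <- build_collection(
      data.frame(phenotype_term = sim$pairs$phenotype,
                 gene_id = sim$pairs$gene), "syn")
    tr <- fit_tree(distance_matrix(coll))
    blocks <- sim$ledger$blocks
    has_bipartition(tr, names(blocks)[blocks == 1])
  }, logical(1))
  expect_true(all(hits))
})

test_that("newick and distance TSV round-trips preserve the model", {
  D <- random_distance_matrix(6, 61)
  ft <- fit_tree(D)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(ft, tf)
  back <- read_newick(tf)
  expect_setequal(back$tip.label, rownames(D))
  d_back <- as.matrix(ape::cophenetic.phylo(back))
  labs <- rownames(ft$fitted)
  expect_equal(d_back[labs, labs], ft$fitted, tolerance = 1e-9)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(D, tsv, header = "# test header")
  expect_equal(read_distance_tsv(tsv), D, tolerance = 1e-12)
})
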