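# p-distances with pairwise deletion, Poisson correction, neighbor joining,
# bootstrap support and majority-rule consensus.

test_that("p-distance uses pairwise deletion and excludes X", {
  expect_equal(p_distance("ACDEF", "ACDEF"), 0)
  expect_equal(p_distance("AAAAAAAAAA", "AAAAACCCCC"), 0.5)
  expect_equal(p_distance("AC-X", "AG-A"), 0.5)  # 1 of 2 comparable differ
  expect_true(is.na(p_distance("--X", "AA-")))
})

test_that("Poisson correction matches its closed form and flags saturation", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2), tolerance = 1e-12)
  expect_equal(round(poisson_correct(0.5), 6), 0.693147)
  expect_equal(round(poisson_correct(0.99), 5), 4.60517)
  expect_error(poisson_correct(1), "saturated")
  expect_error(poisson_correct(1.2), "saturated")
})

test_that("NJ recovers the additive 4-taxon example with its branch lengths", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tree <- nj_tree(d)
  # split AB|CD recovered
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4));")
  expect_equal(ape::dist.topo(ape::unroot(truth), tree), 0, ignore_attr = TRUE)
  # path distances reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tree)[ids, ids], d, tolerance = 1e-9)
})

test_that("3 taxa resolve exactly from the closed form", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, dimnames = list(ids, ids))
  tree <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tree)[ids, ids], d, tolerance = 1e-12)
})

test_that("NJ is exact on random additive matrices up to 12 taxa", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(4:12, 1)
    truth <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    truth <- ape::unroot(truth)
    d <- ape::cophenetic.phylo(truth)
    tree <- nj_tree(d)
    expect_equal(ape::dist.topo(truth, tree), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # independent cross-check: agrees with ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(d), tree), 0, ignore_attr = TRUE)
  }
})

test_that("NJ equals UPGMA on an ultrametric matrix and rejects missing entries", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, dimnames = list(ids, ids))
  tree <- nj_tree(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  upgma <- ape::unroot(ape::as.phylo(hc))
  expect_equal(ape::dist.topo(tree, upgma), 0, ignore_attr = TRUE)

  d2 <- d; d2["A", "C"] <- d2["C", "A"] <- NA
  expect_error(nj_tree(d2), "missing distance for pair A, C")
})

test_that("negative branch lengths are clamped with the deficit recorded", {
  ids <- c("A", "B", "C", "D")
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 1, 9, 9,
                1, 0, 9.2, 8.8,
                9, 9.2, 0, 0.2,
                9, 8.8, 0.2, 0), 4, dimnames = list(ids, ids))
  tree <- nj_tree(d)
  expect_true(all(tree$edge.length >= 0))
  expect_gte(attr(tree, "negative_branch_deficit"), 0)
})

test_that("bootstrap supports a clean central split and is seed-deterministic", {
  tr <- read_newick("((A:0.05,B:0.05):0.4,(C:0.05,(D:0.05,E:0.05):0.05):0.4);")
  fam <- simulate_family(simulation_config(tr, n_sites = 500, seed = 7))
  boot <- bootstrap_support(fam$alignment, replicates = 100, seed = 11)
  expect_true(all(as.numeric(boot$node.label) >= 0 &
                    as.numeric(boot$node.label) <= 100))
  # the AB|CDE bipartition: support of the clade containing exactly A, B
  ab_node <- ape::getMRCA(boot, c("A", "B"))
  ab_support <- as.numeric(boot$node.label[ab_node - length(boot$tip.label)])
  expect_gte(ab_support, 95)

  boot2 <- bootstrap_support(fam$alignment, replicates = 100, seed = 11)
  expect_identical(boot$node.label, boot2$node.label)

  same <- stats::setNames(rep(strrep("ACDEF", 20), 4), paste0("t", 1:4))
  expect_error(bootstrap_support(same), "no variation")
})

test_that("majority consensus keeps >50% bipartitions with frequency supports", {
  t_ab <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t_ac <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  t_ad <- read_newick("((A:1,D:1):1,(B:1,C:1):1);")

  same3 <- majority_consensus(list(t_ab, t_ab, t_ab))
  expect_equal(ape::dist.topo(ape::unroot(same3), ape::unroot(t_ab)), 0,
               ignore_attr = TRUE)
  expect_true(all(as.numeric(same3$node.label) == 100, na.rm = TRUE))

  maj <- majority_consensus(list(t_ab, t_ab, t_ac))
  expect_equal(ape::dist.topo(ape::unroot(maj), ape::unroot(t_ab)), 0,
               ignore_attr = TRUE)
  labs <- as.numeric(maj$node.label)
  expect_true(67 %in% labs)

  star <- majority_consensus(list(t_ab, t_ac, t_ad))
  expect_equal(star$Nnode, 1)  # fully unresolved

  expect_error(majority_consensus(list()), "no trees")
})
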