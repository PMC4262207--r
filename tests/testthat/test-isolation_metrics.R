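test_that("metric values on the worked 3-tip tree match hand computation", {
  t3 <- tree_T3()
  expect_equal(pendant_edge(t3), c(A = 1, B = 1, C = 2))
  expect_equal(fair_proportion(t3), c(A = 1.5, B = 1.5, C = 2))
  expect_equal(equal_splits(t3), c(A = 1.5, B = 1.5, C = 2))
  expect_equal(shapley_value(t3), c(A = 4 / 3, B = 4 / 3, C = 7 / 3))
  expect_equal(vane_wright(t3), c(A = 0.5, B = 0.5, C = 1))
  expect_equal(may_vane_wright(t3), c(A = 0.25, B = 0.25, C = 0.5))
  expect_equal(nixon_wheeler_unweighted(t3), c(A = 0.5, B = 0.5, C = 1))
  expect_equal(nixon_wheeler_weighted(t3), c(A = 1 / 5, B = 1 / 5, C = 1 / 3))
  expect_equal(average_pairwise_distance(t3), c(A = 3, B = 3, C = 4))
  expect_equal(average_pairwise_distance(t3, standardise_by_pd = TRUE),
               c(A = 0.6, B = 0.6, C = 0.8))
  expect_equal(qe_index(t3), c(A = 2 / 7, B = 2 / 7, C = 3 / 7))
})

test_that("every metric is constant on the symmetric star tree", {
  s4 <- tree_S4()
  tab <- compute_all(s4)
  for (m in metric_ids()) {
    expect_lt(diff(range(tab[[m]])), 1e-12)
  }
  expect_equal(unname(pendant_edge(s4)), rep(1, 4))
  expect_equal(unname(fair_proportion(s4)), rep(1, 4))
  expect_equal(unname(may_vane_wright(s4)), rep(0.25, 4))
  expect_equal(unname(nixon_wheeler_unweighted(s4)), rep(1, 4))
  expect_equal(unname(qe_index(s4)), rep(0.25, 4))
})

test_that("node-count conventions behave on the caterpillar tree", {
  cat4 <- tree_cat4()
  expect_equal(vane_wright(cat4)[c("D", "C", "A")],
               c(D = 1, C = 0.5, A = 1 / 3))
  # the deepest tip is never on the larger side of a split
  expect_equal(nixon_wheeler_unweighted(cat4)[["D"]], 1)
  # a tip attached directly to the root maximises NWW
  nww <- nixon_wheeler_weighted(cat4)
  expect_equal(names(which.max(nww)), "D")
})

test_that("conservation identities hold on random trees", {
  for (phy in random_trees(20, n_tips = 15, seed = 21)) {
    pd <- sum(phy$edge.length)
    expect_equal(sum(fair_proportion(phy)), pd, tolerance = 1e-9)
    expect_equal(sum(equal_splits(phy)), pd, tolerance = 1e-9)
    expect_equal(sum(shapley_value(phy)), pd, tolerance = 1e-9)
    # bifurcating trees: MVW is exactly half of VW
    expect_equal(may_vane_wright(phy), vane_wright(phy) / 2)
  }
})

test_that("shapley closed form equals the brute-force game enumeration", {
  expect_equal(shapley_bruteforce(tree_T3()),
               c(A = 4 / 3, B = 4 / 3, C = 7 / 3))
  t2 <- tree_T2()
  expect_equal(shapley_bruteforce(t2), c(A = 1, B = 1))
  for (phy in random_trees(30, n_tips = 8, seed = 33)) {
    expect_equal(shapley_value(phy), shapley_bruteforce(phy),
                 tolerance = 1e-9)
  }
  # polytomies too
  expect_equal(shapley_value(tree_S4()), shapley_bruteforce(tree_S4()),
               tolerance = 1e-12)
  expect_error(shapley_bruteforce(random_trees(1, n_tips = 12)[[1]]),
               "refused")
})

test_that("QE weights satisfy simplex and KKT conditions and match the
           grid-search oracle", {
  # oracle agreement on 3- and 4-tip trees
  t3 <- tree_T3()
  expect_equal(unname(qe_index(t3)),
               qe_grid_oracle(patristic_matrix(t3), step = 0.001),
               tolerance = 2e-3)
  t4 <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  expect_equal(unname(qe_index(t4)),
               qe_grid_oracle(patristic_matrix(t4), step = 0.01),
               tolerance = 2e-2)
  # simplex + stationarity certificate on simulated trees
  for (phy in random_trees(15, n_tips = 20, seed = 44)) {
    p <- qe_index(phy)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    D <- patristic_matrix(phy)
    g <- as.vector(D %*% p)
    cval <- sum(p * g)
    on_support <- p > 1e-10
    expect_lt(max(abs(g[on_support] - cval)), 1e-8)
    expect_true(all(g[!on_support] <= cval + 1e-8))
  }
})

test_that("character rarity is the expected rare-character count", {
  # star tree: symmetry
  chr_s4 <- character_rarity(tree_S4())
  expect_lt(diff(range(chr_s4)), 1e-12)
  # perfect retention: exactly affine in APD on an ultrametric tree
  set.seed(3)
  phy <- simulate_bd_tree(40, 0.5, 0.25)
  v <- character_rarity(phy, chr_params(nu = 1, rho = 1))
  apd <- average_pairwise_distance(phy)
  fit <- lm(v ~ apd)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-12)
  # the documented redundancy with APD at default parameters
  sp <- vapply(random_trees(15, n_tips = 100, seed = 55), function(p)
    cor(character_rarity(p), average_pairwise_distance(p),
        method = "spearman"), 0)
  expect_gt(mean(sp), 0.9)
  # origination rate is a pure scale factor
  expect_equal(character_rarity(phy, chr_params(nu = 2, rho = 0.9)),
               2 * character_rarity(phy, chr_params(nu = 1, rho = 0.9)))
})

test_that("fair proportion and equal splits agree with picante", {
  skip_if_not_installed("picante")
  for (phy in random_trees(10, n_tips = 12, seed = 66)) {
    ed <- picante::evol.distinct(phy, type = "fair.proportion")
    es <- picante::evol.distinct(phy, type = "equal.splits")
    expect_equal(unname(fair_proportion(phy)[ed$Species]), ed$w,
                 tolerance = 1e-9)
    expect_equal(unname(equal_splits(phy)[es$Species]), es$w,
                 tolerance = 1e-9)
  }
})

test_that("metric scores are invariant to child-order rotation", {
  a <- compute_all(parse_newick("(((A:1,B:1):1,C:2):1,D:3);"))
  b <- compute_all(parse_newick("(D:3,(C:2,(B:1,A:1):1):1);"))
  b <- b[match(a$species, b$species), ]
  for (m in metric_ids()) expect_equal(a[[m]], b[[m]], tolerance = 1e-12)
})

test_that("automorphic tips receive equal scores under every metric", {
  # A,B exchangeable; and the (A,B) cherry exchangeable with the (D,E) cherry
  phy <- parse_newick("(((A:1,B:1):2,(D:1,E:1):2):1,C:4);")
  tab <- compute_all(phy)
  for (m in metric_ids()) {
    v <- stats::setNames(tab[[m]], tab$species)
    expect_equal(v[["A"]], v[["B"]])
    expect_equal(v[["A"]], v[["D"]])
    expect_equal(v[["B"]], v[["E"]])
  }
})

test_that("lengthening a pendant edge does not decrease length-based scores", {
  set.seed(77)
  phy <- simulate_bd_tree(12, 0.5, 0.125)
  for (tip_idx in c(1L, 5L, 9L)) {
    tip <- phy$tip.label[tip_idx]
    longer <- phy
    e <- which(longer$edge[, 2] == tip_idx)
    longer$edge.length[e] <- longer$edge.length[e] + 0.5
    for (fn in list(pendant_edge, fair_proportion, equal_splits,
                    shapley_value, average_pairwise_distance)) {
      expect_gte(fn(longer)[[tip]], fn(phy)[[tip]])
    }
  }
})

test_that("compute_all aggregates, standardises, and serialises", {
  t3 <- tree_T3()
  tab <- compute_all(t3)
  expect_s3_class(tab, "score_table")
  expect_named(tab, c("species", metric_ids()))
  expect_false(attr(tab, "standardised"))
  std <- compute_all(t3, standardise = TRUE)
  expect_equal(std$ED, c(0.9, 0.9, 1.2))
  for (m in metric_ids()) expect_equal(mean(std[[m]]), 1, tolerance = 1e-9)
  # FP alias and unknown ids
  expect_equal(isolation_score(t3, "FP"), isolation_score(t3, "ED"))
  expect_error(isolation_score(t3, "XX"), "unknown metric")
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$QE, tab$QE, tolerance = 1e-12)
})
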