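test_that("standardisation divides by the mean and is idempotent", {
  tab <- compute_all(tree_T3())
  std <- standardize_scores(tab)
  expect_equal(std$ED, c(0.9, 0.9, 1.2))
  expect_true(attr(std, "standardised"))
  expect_equal(standardize_scores(std), std)
  for (m in metric_ids()) expect_equal(mean(std[[m]]), 1, tolerance = 1e-9)
  # a constant metric standardises to all ones
  fake <- tab
  fake$PE <- rep(2, 3)
  expect_equal(standardize_scores(fake)$PE, rep(1, 3))
  # zero-mean metric refused with a diagnostic
  fake$PE <- rep(0, 3)
  expect_error(standardize_scores(fake), "PE")
})

test_that("metric distance matrix has the documented geometry", {
  tab <- standardize_scores(compute_all(tree_T3()))
  raw <- metric_distance_matrix(tab, normalise = FALSE, scale = "mean")
  # FP/ED and ES have identical standardised vectors on this tree
  expect_equal(raw["ED", "ES"], 0)
  expect_equal(raw["ED", "PE"], sqrt(0.135), tolerance = 1e-12)
  expect_true(isSymmetric(raw))
  expect_equal(unname(diag(raw)), rep(0, nrow(raw)))

  set.seed(12)
  tab2 <- compute_all(simulate_bd_tree(50, 0.5, 0.25), standardise = TRUE)
  for (sc in c("sd", "mean")) {
    D <- metric_distance_matrix(tab2, scale = sc)
    off <- D[row(D) != col(D)]
    expect_equal(mean(off), 1, tolerance = 1e-9)
    expect_true(all(off >= 0))
  }
  # dispersion-equalised distances ignore positive affine maps:
  # VW and MVW differ by a factor 2 on bifurcating trees
  Dsd <- metric_distance_matrix(tab2, scale = "sd")
  expect_equal(Dsd["VW", "MVW"], 0, tolerance = 1e-9)
})

test_that("average-linkage clustering merges in the documented order", {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hierarchical_cluster(d)
  expect_equal(hc$height, c(1, 10))
  expect_equal(sort(cutree(hc, 2)[c("a", "b")]), c(a = 1, b = 1))
  # a zero-distance pair merges first
  tab <- compute_all(tree_cat4(), standardise = TRUE)
  D <- metric_distance_matrix(tab)
  hc2 <- hierarchical_cluster(D)
  first <- sort(hc2$labels[-hc2$merge[1, ]])
  expect_true(all(c("VW", "MVW") %in% first) || hc2$height[1] < 1e-9)
  # label permutation does not change heights
  perm <- sample(nrow(D))
  hc3 <- hierarchical_cluster(D[perm, perm])
  expect_equal(sort(hc3$height), sort(hc2$height), tolerance = 1e-12)
})

test_that("majority-rule consensus keeps clades above 50% with exact support", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  same <- majority_consensus(list(t1, t1, t1))
  expect_true(contains_clade(same, c("A", "B")))
  expect_true(all(same$node.label == 1))
  twothirds <- majority_consensus(list(t1, t1, t2))
  expect_true(contains_clade(twothirds, c("A", "B")))
  sup <- twothirds$node.label[twothirds$node.label < 1]
  expect_equal(unique(round(sup, 6)), round(2 / 3, 6))
  # conflicting resolutions at exactly 50% are excluded
  star <- majority_consensus(list(t1, t2))
  expect_equal(star$Nnode, 1L)
  expect_error(majority_consensus(list(t1, ape::read.tree(text = "((A,B),(C,E));"))),
               "mismatched")
})

test_that("consensus supports match an independent clade recount", {
  set.seed(31)
  dends <- lapply(1:25, function(i) {
    tab <- compute_all(simulate_bd_tree(30, 0.5, 0.25), standardise = TRUE)
    ape::as.phylo(hierarchical_cluster(metric_distance_matrix(tab)))
  })
  cons <- majority_consensus(dends)
  sets <- evoiso:::clade_tip_sets(cons)
  for (k in seq_along(sets)) {
    if (length(sets[[k]]) == length(cons$tip.label)) next  # root
    expect_equal(cons$node.label[k], clade_support(dends, sets[[k]]))
  }
})

test_that("variation captured behaves for both definitions", {
  set.seed(13)
  tabs <- lapply(1:5, function(i)
    compute_all(simulate_bd_tree(40, 0.5, 0.25), standardise = TRUE))
  # full set captures everything under both readings
  expect_equal(variation_captured(tabs, metric_ids(), method = "share"), 1)
  expect_equal(variation_captured(tabs, metric_ids(), method = "r2"), 1,
               tolerance = 1e-9)
  # r2 credits linear redundancy: VW present makes MVW fully captured
  one <- tabs[[1]]
  S <- evoiso:::score_covariance(one)
  r2_vw <- evoiso:::captured_from_cov(S, "VW")
  share_vw <- variation_captured(one, "VW", method = "share")
  expect_gt(r2_vw, share_vw)
  # r2 is monotone non-decreasing under subset inclusion
  subs <- list("APD", c("APD", "PE"), c("APD", "PE", "QE"),
               c("APD", "PE", "QE", "NWU"))
  caps <- vapply(subs, function(s)
    variation_captured(tabs, s, method = "r2"), 0)
  expect_true(all(diff(caps) >= -1e-12))
  # so is the share, trivially
  caps_s <- vapply(subs, function(s)
    variation_captured(tabs, s, method = "share"), 0)
  expect_true(all(diff(caps_s) >= -1e-12))
  # collinear subsets fall back to the pseudo-inverse without error
  expect_silent(variation_captured(tabs, c("VW", "MVW", "PE"),
                                   method = "r2"))
})

test_that("subset selection respects its modes", {
  set.seed(14)
  tabs <- lapply(1:4, function(i)
    compute_all(simulate_bd_tree(40, 0.5, 0.25), standardise = TRUE))
  # greedy never selects both members of a zero-distance pair
  sel <- select_dissimilar_subset(tabs, 5, mode = "greedy", method = "r2")
  expect_lt(sum(c("VW", "MVW") %in% sel), 2L)
  expect_equal(length(sel), 5L)
  expect_equal(length(unique(sel)), 5L)
  # k = 11 returns the full set
  expect_setequal(select_dissimilar_subset(tabs, 11, mode = "greedy"),
                  metric_ids())
  # one-per-group picks exactly one member per group, seeded
  groups <- list(c("PE", "ED"), c("APD", "NWW"), "QE")
  p1 <- select_dissimilar_subset(tabs, 3, mode = "one-per-group",
                                 groups = groups, seed = 2)
  p2 <- select_dissimilar_subset(tabs, 3, mode = "one-per-group",
                                 groups = groups, seed = 2)
  expect_identical(p1, p2)
  expect_true(p1[1] %in% groups[[1]] && p1[2] %in% groups[[2]])
  expect_error(select_dissimilar_subset(tabs, 2, mode = "one-per-group",
                                        groups = groups), "groups")
})

test_that("clade scaling profiles are consistent with full-tree scores", {
  set.seed(15)
  phy <- simulate_bd_tree(60, 0.5, 0.25)
  tip <- phy$tip.label[7]
  prof <- clade_scaling_profile(phy, tip, scale_by_max = FALSE)
  expect_equal(prof$clade_size[nrow(prof)], 60)
  full <- compute_all(phy)
  for (m in metric_ids()) {
    expect_equal(prof[[m]][nrow(prof)],
                 full[[m]][full$species == tip], tolerance = 1e-9)
  }
  # the pendant edge never changes across nested clades
  expect_lt(diff(range(prof$PE)), 1e-12)
  scaled <- clade_scaling_profile(phy, tip, scale_by_max = TRUE)
  expect_true(all(vapply(metric_ids(), function(m)
    max(scaled[[m]]) <= 1 + 1e-12, TRUE)))
})

test_that("asymptote slopes recover linear trends and constancy", {
  prof <- data.frame(clade_size = c(300, 600),
                     PE = c(1, 1), APD = c(1, 2))
  sl <- asymptote_slope(prof, c(250, 700))
  expect_equal(sl[["PE"]], 0)
  expect_equal(sl[["APD"]], 1 / 300)
  expect_error(asymptote_slope(prof, c(1000, 2000)), "fewer than 2")
})

test_that("APD stabilises with clade size once divided by tree length", {
  set.seed(16)
  phy <- simulate_bd_tree(250, 0.5, 0)
  # pick a tip with many nested clades
  depths <- 1 / vane_wright(phy)
  tip <- names(which.max(depths))
  prof <- clade_scaling_profile(phy, tip, scale_by_max = TRUE)
  n <- nrow(prof)
  half <- which.min(abs(prof$clade_size - prof$clade_size[n] / 2))
  d_apd <- abs(prof$APD[n] - prof$APD[half])
  d_apdpd <- abs(prof$APDPD[n] - prof$APDPD[half])
  expect_lt(d_apdpd, d_apd)
})
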