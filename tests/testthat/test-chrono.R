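test_that("mean-path-length dating: cherries, scaling and caterpillars", {
  # already ultrametric: pure rescaling
  tr <- ape::read.tree(text = "((A:2,B:2):3,(C:4,D:4):1);")
  um <- ultrametricize_mpl(tr, root_age = 100)
  depth <- ape::node.depth.edgelength(um)
  expect_equal(unname(depth[1:4]), rep(100, 4))
  expect_true(ape::is.ultrametric(um))

  # cherry (A:1, B:3): node raw age 2, both leaves end at the root age
  ch <- ape::read.tree(text = "((A:1,B:3):2,C:5);")
  um2 <- ultrametricize_mpl(ch, root_age = 100)
  expect_true(ape::is.ultrametric(um2))
  ages <- ape::branching.times(um2)
  expect_equal(max(ages), 100)
  # raw root age: mean path (1+2, 3+2, 5)/3 = 13/3; cherry raw age 2
  expect_equal(sort(unname(ages))[1], 2 * 100 / (13 / 3))

  # caterpillar with unit branches: ages strictly increase toward the root
  cat_tree <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  um3 <- ultrametricize_mpl(cat_tree, root_age = 100)
  expect_true(all(diff(sort(unname(ape::branching.times(um3)))) > 0))

  expect_error(ultrametricize_mpl(ape::read.tree(text = "(A:1,B:1,C:1);")),
               "unrooted")
})

test_that("dating is idempotent up to scale and lifts non-monotone nodes", {
  set.seed(19)
  tr <- ape::rtree(12)
  um <- ultrametricize_mpl(tr, root_age = 50)
  again <- ultrametricize_mpl(um, root_age = 50)
  expect_equal(ape::branching.times(again), ape::branching.times(um),
               tolerance = 1e-9)
  ages <- ape::branching.times(um)
  # child ages never exceed parent ages
  n_tip <- length(um$tip.label)
  for (e in seq_len(nrow(um$edge))) {
    if (um$edge[e, 2] > n_tip)
      expect_lte(ages[[as.character(um$edge[e, 2])]],
                 ages[[as.character(um$edge[e, 1])]] + 1e-9)
  }
})

test_that("pruning to a specimen keeps its copies plus outgroups and preserves ultrametry", {
  set.seed(23)
  tr <- ultrametricize_mpl(ape::rtree(20), root_age = 100)
  ids <- tr$tip.label
  rec <- timp_records(ids, "MKCV",
                      specimen = c(rep("focal", 10), rep("other", 10)),
                      clade = "Holothuroidea")
  sub <- prune_to_specimen(tr, rec, "focal", outgroup_ids = ids[19:20])
  expect_equal(length(sub$tip.label), 12)
  expect_true(ape::is.ultrametric(sub))
  # pruning to everything is the identity on the leaf set
  all_sub <- prune_to_specimen(tr, rec, c("focal", "other"))
  expect_setequal(all_sub$tip.label, ids)
  rec2 <- rec; rec2$specimen[1:8] <- "other"
  expect_error(prune_to_specimen(tr, rec2, "focal"), "fewer than 3")
})

test_that("LTT profiles read internode intervals off the node ages", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  p <- ltt_profile(t3)
  expect_equal(unname(p$g), c(1, 1))
  expect_equal(p$n, 3)
  expect_equal(p$total, 2 * 1 + 3 * 1)

  # simultaneous cherries give a zero g_3 interval
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  p4 <- ltt_profile(t4)
  expect_equal(unname(p4$g), c(1, 0, 1))
  expect_equal(sum(p4$g), p4$root_age)

  expect_error(ltt_profile(ape::read.tree(text = "((A:1,B:2):1,C:2);")),
               "not ultrametric")
})

test_that("gamma matches the closed form, the reference implementation, and is scale-free", {
  p <- ltt_profile(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  g <- gamma_stat(p)
  expect_equal(g$gamma, (2 - 2.5) / (5 * sqrt(1 / 12)), tolerance = 1e-12)
  expect_equal(g$p, 0.7290, tolerance = 1e-4)

  set.seed(29)
  for (i in 1:8) {
    tr <- yule_tree(sample(5:40, 1))
    mine <- gamma_stat(tr)
    expect_equal(mine$gamma, ape::gammaStat(tr), tolerance = 1e-9)
    # invariance under uniform rescaling (the arbitrary root age cancels)
    sc <- tr; sc$edge.length <- sc$edge.length * 37.5
    expect_equal(gamma_stat(sc)$gamma, mine$gamma, tolerance = 1e-9)
    expect_true(mine$p > 0 && mine$p <= 1)
  }
  # p decreases as |gamma| grows
  gam <- seq(0, 4, by = 0.5)
  ps <- 2 * (1 - pnorm(gam))
  expect_true(all(diff(ps) < 0))
})

test_that("balanced profiles give gamma exactly zero", {
  # choose g so that mean(T_2..T_{n-1}) equals T/2: n=3 with g2 = g3/ solves
  # 2 g2 = (2 g2 + 3 g3) / 2 => g3 = (2/3) g2
  tr <- ape::read.tree(text = "((A:0.6666666667,B:0.6666666667):1,C:1.6666666667);")
  expect_equal(gamma_stat(tr)$gamma, 0, tolerance = 1e-8)
})

test_that("Yule trees are reproducible and near-unbiased for gamma", {
  t1 <- yule_tree(12, seed = 31)
  t2 <- yule_tree(12, seed = 31)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  p <- ltt_profile(yule_tree(3, seed = 1))
  expect_true(all(p$g > 0))

  set.seed(37)
  gams <- vapply(1:200, function(i) gamma_stat(yule_tree(40))$gamma,
                 numeric(1))
  expect_lt(abs(mean(gams)), 0.15)
})

test_that("per-specimen diversification separates burst from steady histories", {
  set.seed(43)
  steady <- yule_tree(15)
  burst <- timpfam:::compress_node_ages(yule_tree(15), power = 4)
  expect_gt(gamma_stat(burst)$gamma, gamma_stat(steady)$gamma)

  # assembled tree: two specimens' clades plus 2 outgroups
  sA <- steady; sA$tip.label <- sprintf("A_T%02d", 1:15)
  sB <- burst; sB$tip.label <- sprintf("B_T%02d", 1:15)
  newick <- sprintf("((%s:10,%s:10):5,(og1:40,og2:40):5);",
                    sub(";$", "", ape::write.tree(sA)),
                    sub(";$", "", ape::write.tree(sB)))
  tr <- ultrametricize_mpl(ape::read.tree(text = newick), root_age = 100)
  rec <- timp_records(tr$tip.label, "MK",
                      specimen = c(rep("A", 15), rep("B", 15), "og", "og"),
                      clade = c(rep("Holothuroidea", 30), "outgroup", "outgroup"))
  div <- diversification_by_specimen(tr, rec, outgroup_ids = c("og1", "og2"),
                                     min_copies = 10)
  expect_setequal(div$specimen, c("A", "B"))
  expect_equal(div$n_tips, c(17, 17))
})
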