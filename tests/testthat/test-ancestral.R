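test_that("analytic ancestral-state cases: midpoint, fixed point, star tree", {
  # two-tip symmetric tree: root is the midpoint
  two <- parse_newick("(A:1,B:1);")
  rec <- estimate_ancestral_states(two, c(A = 0, B = 2))
  expect_equal(rec$states$state[!rec$states$is_tip], 1)

  # all tips equal: every node at the common value, all rates zero
  tr <- toy_tree()
  rec5 <- estimate_ancestral_states(tr, c(A = 5, B = 5, C = 5))
  expect_equal(rec5$states$state, rep(5, 5), tolerance = 1e-9)
  expect_equal(rec5$edges$rate, rep(0, 4), tolerance = 1e-9)
  expect_equal(rec5$edges$direction, rep(0, 4))

  # star tree: root equals the inverse-branch-length weighted mean
  star <- parse_newick("(A:1,B:2,C:4,D:8);")
  vals <- c(A = 3, B = -1, C = 6, D = 2)
  recs <- estimate_ancestral_states(star, vals)
  w <- 1 / c(1, 2, 4, 8)
  expect_equal(recs$states$state[5], sum(vals * w) / sum(w), tolerance = 1e-9)
})

test_that("tips are anchored exactly and estimates respect shift/scale", {
  set.seed(17)
  phy <- simulate_tree(20, root_age = 40, n_fossils = 3)$phy
  vals <- stats::setNames(rnorm(ape::Ntip(phy)), phy$tip.label)
  rec <- estimate_ancestral_states(phy, vals)
  expect_equal(rec$states$state[rec$states$is_tip],
               unname(vals[rec$states$label[rec$states$is_tip]]))
  expect_lt(rec$max_delta, rec$tol)

  # affine equivariance: states(a + b x) = a + b states(x); rates scale by |b|
  rec2 <- estimate_ancestral_states(phy, 3 - 2 * vals)
  expect_equal(rec2$states$state, 3 - 2 * rec$states$state, tolerance = 1e-8)
  expect_equal(rec2$edges$rate, 2 * rec$edges$rate, tolerance = 1e-8)
  expect_equal(rec2$edges$direction, -rec$edges$direction)

  expect_error(estimate_ancestral_states(phy, vals[-1]), "missing tip")
})

test_that("branch rates are |delta|/t and signed changes telescope", {
  # parent 1, child 3, t = 2 -> rate 1, direction +1
  two <- parse_newick("(A:2,B:2);")
  rec <- estimate_ancestral_states(two, c(A = 3, B = -1))
  # root = 1; A edge: |3-1|/2 = 1, +1; B edge: |-1-1|/2 = 1, -1
  eA <- rec$edges[rec$edges$child_label == "A", ]
  expect_equal(eA$rate, 1)
  expect_equal(eA$direction, 1)
  eB <- rec$edges[rec$edges$child_label == "B", ]
  expect_equal(eB$direction, -1)

  # telescoping: signed changes along each root-to-tip path sum to
  # tip value - root value
  set.seed(23)
  phy <- simulate_tree(15, root_age = 30, n_fossils = 2)$phy
  vals <- stats::setNames(rnorm(ape::Ntip(phy)), phy$tip.label)
  rec <- estimate_ancestral_states(phy, vals)
  states <- rec$states$state
  root <- ape::Ntip(phy) + 1L
  for (tip in seq_len(ape::Ntip(phy))) {
    path_nodes <- ape::nodepath(phy, root, tip)
    edges_on_path <- cbind(path_nodes[-length(path_nodes)], path_nodes[-1])
    idx <- match(paste(edges_on_path[, 1], edges_on_path[, 2]),
                 paste(rec$edges$parent, rec$edges$child))
    signed <- (states[rec$edges$child[idx]] - states[rec$edges$parent[idx]])
    expect_equal(sum(signed), states[tip] - states[root], tolerance = 1e-9)
  }
})

test_that("BM-GLS reconstruction matches an independent re-rooting oracle", {
  two <- parse_newick("(A:1,B:1);")
  bm <- bm_gls_reconstruction(two, c(A = 0, B = 2))
  expect_equal(bm$state[!bm$is_tip], 1)

  set.seed(29)
  phy <- simulate_tree(15, root_age = 30)$phy
  vals <- stats::setNames(rnorm(ape::Ntip(phy)), phy$tip.label)
  bm <- bm_gls_reconstruction(phy, vals)
  ref <- phytools::fastAnc(phy, vals)
  expect_equal(bm$state[!bm$is_tip], unname(ref[as.character(bm$node[!bm$is_tip])]),
               tolerance = 1e-6)
})

test_that("adaptive-peak and BM-GLS estimators agree on the harmonic system", {
  # the tip-clamped fixed point solves the same linear system as the BM
  # maximum-likelihood states, so the two routes must coincide
  set.seed(37)
  phy <- simulate_tree(12, root_age = 25, n_fossils = 2)$phy
  vals <- stats::setNames(rnorm(ape::Ntip(phy)), phy$tip.label)
  ie <- estimate_ancestral_states(phy, vals)
  bm <- bm_gls_reconstruction(phy, vals)
  expect_equal(ie$states$state, bm$state, tolerance = 1e-6)
})

test_that("BM simulation recovery: states correlate and a 10x branch stands out", {
  res <- rate_recovery_experiment(n_reps = 60, seed = 19)
  expect_gte(res$mean_state_cor, 0.8)
  expect_gte(res$detection_rate, 0.8)
})

test_that("BM-GLS node estimates track true simulated states", {
  phy <- simulate_tree(50, root_age = 47, seed = 42)$phy
  set.seed(43)
  sim <- simulate_traits(phy, sigma2 = 1)
  bm <- bm_gls_reconstruction(phy, sim$tip_values[, 1])
  est <- bm$state[!bm$is_tip]
  tru <- sim$node_states$trait1[!sim$node_states$is_tip]
  slope <- stats::coef(stats::lm(est ~ tru))[2]
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.1)
})
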