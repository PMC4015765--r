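test_that("phylogenetic mean: star-tree, explicit inversion, and constancy", {
  star <- parse_newick("(A:2,B:2,C:2,D:2);")
  X <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("v1", "v2")))
  C <- phylo_covariance(star, rownames(X))
  expect_equal(unname(phylogenetic_mean(X, C)), c(2.5, 25))

  # explicit 3x3 inversion oracle on a structured tree
  tr <- toy_tree()
  C3 <- phylo_covariance(tr, c("A", "B", "C"))
  x <- matrix(c(0, 0, 3), 3, 1, dimnames = list(c("A", "B", "C"), "v"))
  w <- rowSums(solve(C3))
  expect_equal(unname(phylogenetic_mean(x, C3)), sum(w * x) / sum(w))

  # exact interpolation of a constant
  xc <- matrix(7, 3, 1, dimnames = list(c("A", "B", "C"), "v"))
  expect_equal(unname(phylogenetic_mean(xc, C3)), 7)
})

test_that("pPCA on a star tree with equal depths matches ordinary PCA", {
  set.seed(31)
  n <- 12
  star <- ape::stree(n, "star")
  star$edge.length <- rep(5, n)
  star$tip.label <- paste0("t", 1:n)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(star$tip.label, paste0("v", 1:4)))
  pp <- phylo_pca(X, star)
  ord <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ord_share <- ord$sdev^2 / sum(ord$sdev^2) * 100
  expect_equal(pp$var_explained[1:4], ord_share, tolerance = 1e-8)
  for (j in 1:3) {
    expect_equal(abs(stats::cor(pp$scores[, j], ord$x[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("pPCA agrees with an independent BM phylogenetic PCA", {
  fix <- random_bone_fixture("hamate", n_tips = 10, seed = 41)
  pp <- phylo_pca(fix$ratios, fix$phy)
  ref <- phytools::phyl.pca(fix$phy, fix$ratios, method = "BM", mode = "cov")
  ref_share <- diag(ref$Eval) / sum(diag(ref$Eval)) * 100
  k <- length(pp$var_explained) - 1 # last eigenvalue is numerically zero-ish
  expect_equal(pp$var_explained[1:k], unname(ref_share)[1:k], tolerance = 1e-6)
  for (j in 1:2) {
    expect_equal(abs(stats::cor(pp$scores[, j],
                                ref$S[rownames(pp$scores), j])), 1,
                 tolerance = 1e-8)
    expect_equal(abs(stats::cor(pp$loadings[, j], ref$Evec[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("pPCA invariants: orthonormal loadings, GLS-centred scores, shares", {
  fix <- random_bone_fixture("lunate", n_tips = 14, seed = 51)
  pp <- phylo_pca(fix$ratios, fix$phy)
  G <- crossprod(pp$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(pp$var_explained >= 0))
  expect_equal(sum(pp$var_explained), 100, tolerance = 1e-6)
  # GLS centring: 1' C^-1 scores = 0
  Cinv <- solve(phylo_covariance(fix$phy, rownames(fix$ratios)))
  cen <- colSums(Cinv %*% pp$scores)
  expect_lt(max(abs(cen)), 1e-6)
  # sign convention: largest-|.| loading positive
  for (j in seq_len(ncol(pp$loadings))) {
    expect_gt(pp$loadings[which.max(abs(pp$loadings[, j])), j], 0)
  }
})

test_that("adding a constant shifts the mean but not loadings or eigenvalues", {
  fix <- random_bone_fixture("triquetrum", n_tips = 9, seed = 61)
  pp <- phylo_pca(fix$ratios, fix$phy)
  X2 <- fix$ratios
  X2[, 2] <- X2[, 2] + 5
  pp2 <- phylo_pca(X2, fix$phy)
  expect_equal(pp2$center[2], pp$center[2] + 5, tolerance = 1e-9)
  expect_equal(pp2$center[-2], pp$center[-2], tolerance = 1e-9)
  expect_equal(pp2$eig, pp$eig, tolerance = 1e-9)
  expect_equal(pp2$loadings, pp$loadings, tolerance = 1e-9)
})

test_that("tidy/glance/autoplot expose the result as tibbles and a plot", {
  fix <- random_bone_fixture("capitate", n_tips = 7, seed = 71)
  pp <- phylo_pca(fix$ratios, fix$phy, n_components = 2)
  sc <- tidy(pp, "scores")
  expect_tibble(sc)
  expect_named(sc, c("taxon", "PC1", "PC2"))
  ld <- tidy(pp, "loadings")
  expect_equal(nrow(ld), 6)
  ev <- tidy(pp, "eigenvalues")
  expect_equal(ev$cumulative[length(ev$cumulative)], 100, tolerance = 1e-6)
  gl <- glance(pp)
  expect_equal(gl$n_taxa, 7)
  expect_s3_class(autoplot(pp), "ggplot")
})

test_that("variance-equality F-test matches the F distribution", {
  # identical score sets -> F = 1, p = 1
  x <- c(rnorm(5), rnorm(5))
  x[6:10] <- x[1:5]
  ft <- variance_equality_test(x, rep(c("g1", "g2"), each = 5))
  expect_equal(ft$f, 1)
  expect_equal(ft$p_value, 1)

  # group variances 4 and 1 with n1 = n2 = 11 -> F = 4, p from F(10, 10)
  a <- scale(rnorm(11))[, 1] * 2 # sample variance exactly 4
  b <- scale(rnorm(11))[, 1] # sample variance exactly 1
  ft2 <- variance_equality_test(c(a, b), rep(c("a", "b"), each = 11))
  expect_equal(ft2$f, 4, tolerance = 1e-12)
  expect_equal(ft2$p_value, 2 * stats::pf(4, 10, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(ft2$df1, 10)
  expect_equal(ft2$df2, 10)

  # agreement with var.test (two-sided) on random unequal groups
  set.seed(81)
  for (rep in 1:5) {
    g1 <- rnorm(8, sd = runif(1, 0.5, 2))
    g2 <- rnorm(13, sd = runif(1, 0.5, 2))
    mine <- variance_equality_test(c(g1, g2), rep(c("x", "y"), c(8, 13)))
    ref <- stats::var.test(g1, g2)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_gte(mine$f, 1)
  }

  expect_error(variance_equality_test(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2")
  expect_error(variance_equality_test(1:6, rep(c("a", "b", "c"), 2)),
               "exactly 2")
})

test_that("F-test keeps nominal type-I error under equal variances", {
  cal <- ftest_calibration(n_reps = 800, n = 30, seed = 7)
  expect_lt(abs(cal$type1_rate - 0.05), 0.02)
})
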