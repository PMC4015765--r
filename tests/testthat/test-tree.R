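test_that("Newick parsing builds a valid dated tree and rejects bad input", {
  tr <- toy_tree()
  expect_equal(ape::Ntip(tr), 3)
  ages <- node_ages(tr)
  expect_equal(max(ages$age), 2) # root age = max root-to-tip path
  expect_equal(ages$age[ages$label %in% c("A", "B", "C")], c(0, 0, 0))

  expect_error(parse_newick("(A:1);"), "at least 2 tips")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "offset|malformed")
  expect_error(parse_newick("((A:1,B),C:2);"), "branch length")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("write/parse round-trips topology and branch lengths", {
  set.seed(5)
  for (rep in 1:5) {
    phy <- simulate_tree(24, root_age = 47)$phy
    back <- parse_newick(write_newick(phy))
    expect_equal(sort(back$tip.label), sort(phy$tip.label))
    d0 <- patristic_distances(phy)
    d1 <- patristic_distances(back)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("fossil grafting splits the stem branch and preserves other paths", {
  tr <- toy_tree()
  tr2 <- graft_fossil(tr, "F", c("A", "B"), stem_age = 1.5, tip_age = 0.5)
  # fossil branch length = stem_age - tip_age
  f_edge <- tr2$edge.length[tr2$edge[, 2] == match("F", tr2$tip.label)]
  expect_equal(f_edge, 1.0)
  # root -> A path unchanged
  ages <- node_ages(tr2)
  expect_equal(max(ages$age), 2)
  expect_equal(unname(patristic_distances(tr2)["A", "C"]), 4)
  # fossil tip terminates before the present
  expect_equal(ages$age[ages$label == "F"], 0.5)

  # boundary: stem age at the parent node is outside the open interval
  expect_error(graft_fossil(tr, "G", c("A", "B"), stem_age = 2, tip_age = 0.5),
               "outside")
  expect_error(graft_fossil(tr, "G", "A", stem_age = 1.5, tip_age = 0.5),
               "outside")
  expect_error(graft_fossil(tr2, "F", "C", stem_age = 1, tip_age = 0.2),
               "duplicate")
  expect_error(graft_fossil(tr, "G", "A", stem_age = 0.5, tip_age = 0.7),
               "tip_age")
})

test_that("graft-then-prune is the identity on patristic distances", {
  set.seed(9)
  for (rep in 1:4) {
    phy <- simulate_tree(12, root_age = 40)$phy
    d0 <- patristic_distances(phy)
    e <- sample(which(phy$edge[, 2] <= ape::Ntip(phy)), 1)
    ages <- node_ages(phy)
    child <- phy$edge[e, 2]
    lo <- ages$age[child]; hi <- ages$age[phy$edge[e, 1]]
    stem <- lo + 0.5 * (hi - lo)
    phy2 <- graft_fossil(phy, "foss", phy$tip.label[child], stem, stem / 2)
    phy3 <- prune_to_taxa(phy2, phy$tip.label)
    d1 <- patristic_distances(phy3)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("pruning conserves path lengths and rejects unknown taxa", {
  tr <- toy_tree()
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(unname(patristic_distances(pr)["A", "C"]), 4)
  expect_equal(ape::Nnode(pr), 1) # degree-2 node collapsed

  same <- prune_to_taxa(tr, tr$tip.label)
  expect_equal(patristic_distances(same), patristic_distances(tr))

  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
  expect_error(prune_to_taxa(tr, "A"), "at least 2")
})

test_that("phylogenetic covariance holds shared path lengths and is PSD", {
  tr <- toy_tree()
  C <- phylo_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  # star tree: no shared history off-diagonal
  star <- parse_newick("(A:3,B:3,C:3,D:3);")
  Cs <- phylo_covariance(star)
  expect_equal(unname(Cs), diag(3, 4))

  set.seed(13)
  phy <- simulate_tree(24, root_age = 47, n_fossils = 3)$phy
  C <- phylo_covariance(phy)
  expect_equal(C, t(C))
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_equal(unname(diag(C)), depths, tolerance = 1e-9)
})

test_that("fossil placements round-trip through YAML and graft in bulk", {
  placements <- tibble::tibble(
    fossil_name = c("f1", "f2"),
    attachment_lineage = list("A", c("A", "B")),
    stem_age_ma = c(0.5, 1.5),
    tip_age_ma = c(0.1, 0.6)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(2), function(i) list(
    fossil_name = placements$fossil_name[i],
    attachment_lineage = as.list(placements$attachment_lineage[[i]]),
    stem_age_ma = placements$stem_age_ma[i],
    tip_age_ma = placements$tip_age_ma[i]
  )), path)
  back <- read_fossil_placements(path)
  expect_equal(back$fossil_name, placements$fossil_name)
  expect_equal(back$stem_age_ma, placements$stem_age_ma)

  tr2 <- graft_fossils(toy_tree(), back)
  expect_equal(ape::Ntip(tr2), 5)
  expect_setequal(tr2$tip.label, c("A", "B", "C", "f1", "f2"))
})

test_that("polytomies resolve to a binary tree with zero-length branches", {
  poly <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_message(bin <- resolve_polytomies(poly), "polytomy")
  expect_true(ape::is.binary(bin))
  d0 <- patristic_distances(poly)
  expect_equal(patristic_distances(bin)[rownames(d0), colnames(d0)], d0)
})
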