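# shared fixtures built in code

toy_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

# two-specimen hamate table with exact values
toy_hamate_table <- function() {
  codes <- carpal_variables()$hamate
  tibble::tibble(
    specimen_id = rep(c("s1", "s2"), each = length(codes)),
    taxon = rep(c("A", "B"), each = length(codes)),
    bone = "hamate",
    variable = rep(codes, 2),
    value_mm = c(10, 4, 12, 5, 8, 6, 9, 11, 5, 13, 4, 9, 7, 10)
  )
}

# random trait matrix + tree for a given bone, deterministic under seed
random_bone_fixture <- function(bone = "hamate", n_tips = 8, seed = 11) {
  set.seed(seed)
  phy <- simulate_tree(n_tips, root_age = 30)$phy
  k <- length(carpal_variables()[[bone]])
  tr <- simulate_traits(phy, n_traits = k, sigma2 = 0.01)
  X <- exp(tr$tip_values)
  colnames(X) <- carpal_variables()[[bone]]
  list(phy = phy, ratios = X, sim = tr)
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

# write a small on-disk synthetic study (tree, measurements, placements)
# and return a run_pipeline() config pointing at it
write_study <- function(dir, seed = 5, drop_fossil_bone = NULL) {
  ds <- simulate_carpal_dataset(n_tips = 8, n_fossils = 2, n_range = c(2, 4),
                                cv_noise = 0.05, seed = seed)
  extant <- grep("^fossil_", ds$phy$tip.label, invert = TRUE, value = TRUE)
  write_newick(prune_to_taxa(ds$phy, extant), file.path(dir, "tree.nwk"))
  meas <- ds$measurements
  if (!is.null(drop_fossil_bone)) {
    meas <- meas[!(meas$taxon == "fossil_1" & meas$bone == drop_fossil_bone), ]
  }
  write_measurements(meas, file.path(dir, "meas.csv"))
  pl <- ds$placements
  yaml::write_yaml(lapply(seq_len(nrow(pl)), function(i) list(
    fossil_name = pl$fossil_name[i],
    attachment_lineage = as.list(pl$attachment_lineage[[i]]),
    stem_age_ma = pl$stem_age_ma[i],
    tip_age_ma = pl$tip_age_ma[i]
  )), file.path(dir, "placements.yaml"))
  list(
    tree = file.path(dir, "tree.nwk"),
    measurements = file.path(dir, "meas.csv"),
    placements = file.path(dir, "placements.yaml"),
    groups = list(cladeA = c("t1", "t2", "t3"), other = ".rest"),
    out_dir = file.path(dir, "out")
  )
}
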