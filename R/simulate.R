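#' Simulate a dated phylogeny with optional fossil tips
#'
#' Draws a random dated species tree from a birth-death process (the standard
#' generative model for clade-level phylogenies, giving realistic
#' branch-length variation), rescales it to the requested root age, and
#' grafts `n_fossils` fossil tips at random positions: each fossil's stem age
#' is drawn uniformly within a randomly chosen branch's age interval and its
#' last-occurrence age uniformly between 5% and 95% of the stem age (so
#' fossil tips always terminate before the present). Output is byte-identical
#' for a fixed seed.
#'
#' @param n_tips Number of extant tips.
#' @param root_age Root age in Myr (default 47, the depth of the haplorrhine
#'   radiation analysed here).
#' @param n_fossils Number of fossil tips to graft (default 0).
#' @param birth,death Speciation and extinction rates per lineage per Myr of
#'   the generating birth-death process (defaults 0.15 and 0.05, plausible
#'   for a primate-scale radiation; only relative branch lengths matter
#'   since the tree is rescaled to `root_age`).
#' @param seed Optional integer seed.
#' @return A list with `phy` (the tree, extant tips `t1..tn`, fossils
#'   `fossil_1..`) and `placements` (tibble in [read_fossil_placements()]
#'   format).
#' @export
simulate_tree <- function(n_tips, root_age = 47, n_fossils = 0,
                          birth = 0.15, death = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_tips >= 2, root_age > 0, n_fossils >= 0)
  phy <- ape::rphylo(n_tips, birth = birth, death = death)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy$edge.length <- phy$edge.length * root_age /
    max(ape::node.depth.edgelength(phy))

  placements <- tibble::tibble(
    fossil_name = character(), attachment_lineage = list(),
    stem_age_ma = numeric(), tip_age_ma = numeric()
  )
  for (i in seq_len(n_fossils)) {
    ages <- node_ages(phy)
    repeat {
      e <- sample.int(nrow(phy$edge), 1)
      child <- phy$edge[e, 2]
      parent <- phy$edge[e, 1]
      a_lo <- ages$age[child]
      a_hi <- ages$age[parent]
      if (a_hi - a_lo > 1e-6) break
    }
    stem <- stats::runif(1, a_lo + 0.05 * (a_hi - a_lo),
                         a_hi - 0.05 * (a_hi - a_lo))
    tip_age <- stats::runif(1, 0.05 * stem, 0.95 * stem)
    n_tip <- ape::Ntip(phy)
    lineage <- if (child <= n_tip) {
      phy$tip.label[child]
    } else {
      ape::extract.clade(phy, child)$tip.label
    }
    name <- paste0("fossil_", i)
    phy <- graft_fossil(phy, name, lineage, stem, tip_age)
    placements <- dplyr::bind_rows(placements, tibble::tibble(
      fossil_name = name, attachment_lineage = list(lineage),
      stem_age_ma = stem, tip_age_ma = tip_age
    ))
  }
  list(phy = phy, placements = placements)
}

#' Simulate trait evolution along a phylogeny
#'
#' Brownian motion with branch-specific rate multipliers, optionally with an
#' Ornstein-Uhlenbeck pull toward a branch-specific optimum (convergent
#' regimes). Along each branch of length t with multiplier m, the BM
#' increment is Normal(0, sigma2 * m * t); with `alpha > 0` the exact OU
#' transition toward the branch's `optimum` is used instead:
#' \deqn{x' = \theta + (x - \theta) e^{-\alpha t} +
#'   N(0,\; \sigma^2 m (1 - e^{-2\alpha t}) / (2\alpha))}
#' True states at every node are retained as ground truth, so estimator
#' recovery can be scored.
#'
#' @param phy A dated `phylo` object.
#' @param n_traits Number of traits simulated jointly.
#' @param sigma2 Base BM rate (trait^2 per Myr).
#' @param multipliers Per-edge rate multipliers (> 0), in tree edge order;
#'   default all 1.
#' @param alpha Per-edge OU pull strength (>= 0); default 0 (pure BM).
#'   Recycled if scalar.
#' @param optimum Per-edge optimum (recycled); only used where `alpha > 0`.
#' @param trait_cov Optional n_traits x n_traits covariance of increments
#'   (unit diagonal scaling recommended); default identity.
#' @param root_state Root value(s); scalar or length `n_traits`.
#' @param seed Optional integer seed.
#' @return A list: `tip_values` (matrix taxa x traits), `node_states`
#'   (tibble: `node`, `label`, `is_tip`, one column per trait), `multipliers`.
#' @export
simulate_traits <- function(phy, n_traits = 1, sigma2 = 1, multipliers = NULL,
                            alpha = 0, optimum = 0, trait_cov = NULL,
                            root_state = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_phylogeny(phy)
  n_edge <- nrow(phy$edge)
  if (is.null(multipliers)) multipliers <- rep(1, n_edge)
  stopifnot(length(multipliers) == n_edge, all(multipliers > 0))
  alpha <- rep_len(alpha, n_edge)
  optimum <- rep_len(optimum, n_edge)
  stopifnot(all(alpha >= 0), sigma2 >= 0)
  if (is.null(trait_cov)) trait_cov <- diag(n_traits)
  Lc <- chol(trait_cov)

  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  x <- matrix(NA_real_, n_all, n_traits)
  x[n_tip + 1L, ] <- rep_len(root_state, n_traits)

  # preorder: parents before children
  ord <- order(ape::node.depth.edgelength(phy)[phy$edge[, 2]])
  for (e in ord) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    t <- phy$edge.length[e]; m <- multipliers[e]
    z <- drop(stats::rnorm(n_traits) %*% Lc)
    if (alpha[e] > 0) {
      a <- alpha[e]
      sd2 <- sigma2 * m * (1 - exp(-2 * a * t)) / (2 * a)
      x[ch, ] <- optimum[e] + (x[p, ] - optimum[e]) * exp(-a * t) +
        z * sqrt(sd2)
    } else {
      x[ch, ] <- x[p, ] + z * sqrt(sigma2 * m * t)
    }
  }
  tip_values <- x[seq_len(n_tip), , drop = FALSE]
  rownames(tip_values) <- phy$tip.label
  colnames(tip_values) <- paste0("trait", seq_len(n_traits))
  ages <- node_ages(phy)
  node_states <- tibble::tibble(
    node = seq_len(n_all), label = ages$label, is_tip = ages$is_tip
  )
  for (j in seq_len(n_traits)) node_states[[paste0("trait", j)]] <- x[, j]
  list(tip_values = tip_values, node_states = node_states,
       multipliers = multipliers)
}

#' Simulate a specimen-level measurement table from species shape ratios
#'
#' Emulates museum-sample structure: each species' trait vector is first
#' normalized to unit geometric mean (shape ratios are identified only up to
#' a multiplicative constant once a per-specimen geometric mean is divided
#' out). Each specimen then receives a uniform size factor from `size_range`
#' (mm) and multiplicative log-normal noise with coefficient of variation
#' `cv_noise`; all values stay strictly positive, as the geometric mean
#' requires. With `cv_noise = 0` the size correction recovers the species
#' ratios exactly, whatever the size factors.
#'
#' @param species_values Matrix of positive species trait values (taxa in
#'   rows with rownames, variables in columns) or a tibble with a `taxon`
#'   column. Column names must be the variable codes of `bone`.
#' @param bone Bone identifier the variables belong to.
#' @param n_per_taxon Integer number of specimens per taxon; scalar or named
#'   vector per taxon.
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param size_range Length-2 numeric: range of the uniform size factor (mm).
#' @param seed Optional integer seed.
#' @return A long measurement tibble (`specimen_id`, `taxon`, `bone`,
#'   `variable`, `value_mm`) passing [validate_measurements()].
#' @export
simulate_specimens <- function(species_values, bone, n_per_taxon = 5,
                               cv_noise = 0.05, size_range = c(5, 15),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(species_values)) {
    species_values <- trait_matrix(species_values)
  }
  stopifnot(bone %in% carpal_bones(), all(species_values > 0),
            length(size_range) == 2L, cv_noise >= 0)
  codes <- carpal_variables()[[bone]]
  if (!setequal(colnames(species_values), codes)) {
    stop("column names must be the ", length(codes), " variable codes of '",
         bone, "'", call. = FALSE)
  }
  species_values <- species_values[, codes, drop = FALSE]
  # identify shape up to scale: unit geometric mean per taxon
  gm <- exp(rowMeans(log(species_values)))
  ratios <- species_values / gm
  taxa <- rownames(species_values)
  n_per <- if (length(n_per_taxon) == 1L) {
    stats::setNames(rep(n_per_taxon, length(taxa)), taxa)
  } else n_per_taxon[taxa]
  sdlog <- sqrt(log(1 + cv_noise^2))

  purrr::map_dfr(taxa, function(tx) {
    purrr::map_dfr(seq_len(n_per[[tx]]), function(s) {
      size <- stats::runif(1, size_range[1], size_range[2])
      noise <- if (cv_noise > 0) exp(stats::rnorm(length(codes), 0, sdlog)) else 1
      tibble::tibble(
        specimen_id = paste0(tx, "_s", s),
        taxon = tx,
        bone = bone,
        variable = codes,
        value_mm = as.vector(ratios[tx, ]) * size * noise
      )
    })
  })
}

#' Simulate a complete carpal-morphometrics study
#'
#' Convenience fixture builder covering every pipeline stage: a dated tree
#' with fossil tips, per-bone species shape ratios evolved by (geometric)
#' Brownian motion on the log scale, and specimen tables for all five carpal
#' bones. Defaults mirror the scale of a primate carpal study: 24 extant
#' taxa over a 47 Myr radiation plus fossil tips, the five-bone 38-variable
#' registry, and specimen counts drawn from the 2-146 range typical of
#' museum samples.
#'
#' @param n_tips Extant taxa (default 24).
#' @param root_age Root age in Myr (default 47).
#' @param n_fossils Fossil tips (default 8).
#' @param sigma2_log BM rate of log shape ratios per Myr (default 0.002,
#'   i.e. ~30% shape divergence over the tree depth).
#' @param cv_noise Within-species measurement CV (default 0.05).
#' @param n_range Range specimen counts are drawn from (default c(2, 146)).
#' @param seed Integer seed (default 1).
#' @return A list: `phy`, `placements`, `measurements` (all bones, long
#'   tibble), `true_states` (named list per bone: tibble of true log-ratio
#'   node states), `seed`.
#' @export
simulate_carpal_dataset <- function(n_tips = 24, root_age = 47, n_fossils = 8,
                                    sigma2_log = 0.002, cv_noise = 0.05,
                                    n_range = c(2, 146), seed = 1) {
  set.seed(seed)
  sim <- simulate_tree(n_tips, root_age, n_fossils)
  phy <- sim$phy
  n_per <- stats::setNames(
    sample(seq(n_range[1], n_range[2]), ape::Ntip(phy), replace = TRUE),
    phy$tip.label
  )
  # fossils are typically single specimens
  n_per[grepl("^fossil_", names(n_per))] <- 1L

  registry <- carpal_variables()
  measurements <- NULL
  true_states <- list()
  for (b in names(registry)) {
    k <- length(registry[[b]])
    tr <- simulate_traits(phy, n_traits = k, sigma2 = sigma2_log)
    ratios <- exp(tr$tip_values)
    colnames(ratios) <- registry[[b]]
    meas <- simulate_specimens(ratios, b, n_per_taxon = n_per,
                               cv_noise = cv_noise)
    measurements <- dplyr::bind_rows(measurements, meas)
    true_states[[b]] <- tr$node_states
  }
  list(phy = phy, placements = sim$placements, measurements = measurements,
       true_states = true_states, seed = seed)
}
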