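#' Parameter-recovery experiment for the ancestral-state estimator
#'
#' Simulates Brownian-motion trait evolution on a fixed birth-death tree and
#' scores how well the adaptive-peak estimator recovers the (known) internal
#' node states, plus how reliably a single rate-shifted branch stands out.
#' Two scenarios per replicate:
#'
#' * homogeneous rate: correlation between estimated and true internal
#'   states;
#' * one designated branch at `multiplier` times the base rate: whether that
#'   branch's estimated rate exceeds the tree-wide median rate.
#'
#' The designated branch is the terminal branch at the lower quartile of
#' terminal branch lengths — the "recently diverged autapomorphic lineage"
#' scenario (a hylobatid-hamate-style burst). Terminal branches are the
#' right place to probe detection power: the child state is anchored by the
#' observed tip, whereas an internal branch's two smoothed endpoints dilute
#' the signal, and per-branch rates scale as \eqn{\sqrt{\sigma^2 m / t}} so
#' very long branches yield low rates even when shifted.
#'
#' @param n_reps Number of simulation replicates (default 200).
#' @param n_tips Tips of the fixed tree (default 50).
#' @param sigma2 Base BM rate (default 1).
#' @param multiplier Rate multiplier on the designated branch (default 10).
#' @param seed Seed for the trait simulations (the tree itself is fixed
#'   internally so the experiment always runs on the same topology).
#' @return A list: `mean_state_cor` (mean correlation, homogeneous
#'   scenario), `detection_rate` (share of shifted replicates where the
#'   designated branch beats the median rate), `shift_edge_length`,
#'   `n_reps`, `n_tips`.
#' @export
rate_recovery_experiment <- function(n_reps = 200, n_tips = 50, sigma2 = 1,
                                     multiplier = 10, seed = 1) {
  phy <- simulate_tree(n_tips, root_age = 47, seed = 42)$phy
  n_tip <- ape::Ntip(phy)
  term <- which(phy$edge[, 2] <= n_tip)
  term_sorted <- term[order(phy$edge.length[term])]
  shift_edge <- term_sorted[max(1L, round(0.25 * length(term_sorted)))]
  mult <- rep(1, nrow(phy$edge))
  mult[shift_edge] <- multiplier

  set.seed(seed)
  cors <- numeric(n_reps)
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    bm <- simulate_traits(phy, sigma2 = sigma2)
    rec <- estimate_ancestral_states(phy, bm$tip_values[, 1])
    est <- rec$states$state[!rec$states$is_tip]
    tru <- bm$node_states$trait1[!bm$node_states$is_tip]
    cors[r] <- stats::cor(est, tru)

    bm2 <- simulate_traits(phy, sigma2 = sigma2, multipliers = mult)
    rec2 <- estimate_ancestral_states(phy, bm2$tip_values[, 1])
    hits[r] <- rec2$edges$rate[shift_edge] > stats::median(rec2$edges$rate)
  }
  list(
    mean_state_cor = mean(cors),
    detection_rate = mean(hits),
    shift_edge_length = phy$edge.length[shift_edge],
    n_reps = n_reps,
    n_tips = n_tips
  )
}

#' Type-I error calibration of the variance-equality F-test
#'
#' Simulates two equal-variance normal samples per replicate and records how
#' often the two-tailed F-test rejects at level `alpha`; a well-calibrated
#' test rejects at about the nominal rate.
#'
#' @param n_reps Number of replicates (default 2000).
#' @param n Per-group sample size (default 30).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A list: `type1_rate`, `n_reps`, `n`, `alpha`.
#' @export
ftest_calibration <- function(n_reps = 2000, n = 30, alpha = 0.05, seed = 1) {
  set.seed(seed)
  rejects <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    ft <- variance_equality_test(
      c(stats::rnorm(n), stats::rnorm(n)),
      rep(c("a", "b"), each = n)
    )
    rejects[r] <- ft$p_value < alpha
  }
  list(type1_rate = mean(rejects), n_reps = n_reps, n = n, alpha = alpha)
}
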