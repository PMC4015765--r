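#' Ancestral states and branch rates under an adaptive-peak scheme
#'
#' Estimates ancestral states for a univariate trait (typically one principal
#' component axis at a time) on a dated tree with extant and/or fossil tips,
#' using only the observed tip variation and phylogenetic relatedness — no a
#' priori evolutionary model parameters. Tips are anchored exactly at their
#' observed values; each internal node is driven to the inverse-branch-length
#' weighted mean of its neighbours (children, and parent for non-root nodes):
#' \deqn{x_k = \frac{\sum_c x_c/t_c + x_P/t_P}{\sum_c 1/t_c + 1/t_P}}
#' The fixed point is reached by Gauss-Seidel sweeps from a post-order
#' initialization (each node the inverse-branch-length weighted mean of its
#' children), stopping when the largest absolute change in a sweep falls
#' below `tol`. The iteration is a contraction for positive branch lengths,
#' so the result is deterministic. Short branches therefore bind a node
#' tightly to its neighbour — the adaptive-peak intuition that little time
#' allows little change — while Brownian-motion-like behaviour emerges on
#' trees with homogeneous branch lengths.
#'
#' Zero-length branches (from polytomy resolution) are given a ridge length
#' of `zero_ridge` Myr in the weights and flagged.
#'
#' @param phy A dated `phylo` object.
#' @param tip_values Named numeric vector covering every tip label, or a
#'   data frame with columns `taxon` and `value`.
#' @param tol Convergence tolerance on the max absolute per-sweep change
#'   (trait units). Default `1e-10`.
#' @param max_iter Maximum number of sweeps. Default `10000`.
#' @param zero_ridge Ridge length (Myr) substituted for zero-length branches.
#' @return An object of class `ancestral_recon`: list with `states` (tibble:
#'   `node`, `label`, `age`, `state`, `is_tip`), `edges` (tibble: `parent`,
#'   `child`, `parent_label`, `child_label`, `length`, `rate`, `direction`,
#'   `ridged`), `iterations`, `max_delta`, `tol`, and the tree.
#' @seealso [branch_rates()], [bm_gls_reconstruction()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' rec <- estimate_ancestral_states(tr, c(A = 0, B = 2, C = 1))
#' tidy(rec)
estimate_ancestral_states <- function(phy, tip_values, tol = 1e-10,
                                      max_iter = 10000, zero_ridge = 1e-6) {
  validate_phylogeny(phy)
  tip_values <- as_tip_values(tip_values)
  miss <- setdiff(phy$tip.label, names(tip_values))
  if (length(miss)) {
    stop("missing tip value(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  root <- n_tip + 1L

  edge <- phy$edge
  elen <- phy$edge.length
  ridged <- elen <= 0
  elen_w <- ifelse(ridged, zero_ridge, elen)

  # adjacency: for each node, its neighbour nodes and the 1/t weights
  nbr <- vector("list", n_all)
  wts <- vector("list", n_all)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c_ <- edge[e, 2]; w <- 1 / elen_w[e]
    nbr[[p]] <- c(nbr[[p]], c_); wts[[p]] <- c(wts[[p]], w)
    nbr[[c_]] <- c(nbr[[c_]], p); wts[[c_]] <- c(wts[[c_]], w)
  }

  x <- numeric(n_all)
  x[seq_len(n_tip)] <- tip_values[phy$tip.label]

  # post-order init: each internal node = inverse-length weighted child mean
  # deepest internal nodes first, so each node's children (tips or
  # already-initialized internals) have values
  depths <- ape::node.depth.edgelength(phy)
  po <- order(depths[(n_tip + 1L):n_all], decreasing = TRUE) + n_tip
  for (k in po) {
    sel <- edge[, 1] == k
    ch <- edge[sel, 2]
    w <- 1 / elen_w[sel]
    x[k] <- sum(x[ch] * w) / sum(w)
  }

  # for the root, drop the (nonexistent) parent term; others use all neighbours
  internal <- (n_tip + 1L):n_all
  iter <- 0L
  delta <- Inf
  while (delta >= tol && iter < max_iter) {
    delta <- 0
    for (k in internal) {
      w <- wts[[k]]
      new <- sum(x[nbr[[k]]] * w) / sum(w)
      d <- abs(new - x[k])
      if (d > delta) delta <- d
      x[k] <- new
    }
    iter <- iter + 1L
  }
  if (delta >= tol) {
    stop("ancestral-state iteration did not converge: final max delta ",
         format(delta), " after ", iter, " sweeps", call. = FALSE)
  }
  # exact tip anchoring (tips were never updated, but guard against drift)
  x[seq_len(n_tip)] <- tip_values[phy$tip.label]

  ages <- node_ages(phy)
  states <- tibble::tibble(
    node = seq_len(n_all),
    label = ages$label,
    age = ages$age,
    state = x,
    is_tip = ages$is_tip
  )
  edges <- tibble::tibble(
    parent = edge[, 1],
    child = edge[, 2],
    parent_label = vapply(edge[, 1], function(i) node_label(phy, i), character(1)),
    child_label = vapply(edge[, 2], function(i) node_label(phy, i), character(1)),
    length = elen,
    rate = abs(x[edge[, 2]] - x[edge[, 1]]) / elen_w,
    direction = sign(x[edge[, 2]] - x[edge[, 1]]),
    ridged = ridged
  )
  structure(
    list(states = states, edges = edges, iterations = iter, max_delta = delta,
         tol = tol, phy = phy),
    class = "ancestral_recon"
  )
}

as_tip_values <- function(tip_values) {
  if (is.data.frame(tip_values)) {
    stats::setNames(tip_values$value, tip_values$taxon)
  } else {
    if (is.null(names(tip_values))) stop("tip values must be named", call. = FALSE)
    tip_values
  }
}

#' Per-branch evolutionary rates and directions
#'
#' `rate = |state(child) - state(parent)| / branch length` (trait units per
#' Myr) and `direction = sign(state(child) - state(parent))`. The signed
#' per-branch changes telescope: summed along any root-to-tip path they equal
#' tip state minus root state exactly.
#'
#' @param recon An `ancestral_recon` object.
#' @return A tibble of per-branch rates (the `edges` element).
#' @export
branch_rates <- function(recon) {
  stopifnot(inherits(recon, "ancestral_recon"))
  recon$edges
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("Ancestral reconstruction:", sum(!x$states$is_tip), "internal nodes,",
      nrow(x$edges), "branches\n")
  cat("converged in", x$iterations, "sweeps (max delta",
      format(x$max_delta, digits = 3), "< tol", format(x$tol), ")\n")
  invisible(x)
}

#' Tidy an ancestral reconstruction
#' @param x An `ancestral_recon` object.
#' @param matrix `"states"` (per-node estimates) or `"rates"` (per-branch).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ancestral_recon
#' @export
tidy.ancestral_recon <- function(x, matrix = c("states", "rates"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "states") x$states else x$edges
}

#' One-row summary of an ancestral reconstruction
#' @param x An `ancestral_recon` object.
#' @param ... Unused.
#' @return A one-row tibble with node counts, convergence diagnostics, and
#'   the maximum branch rate.
#' @method glance ancestral_recon
#' @export
glance.ancestral_recon <- function(x, ...) {
  tibble::tibble(
    n_tips = sum(x$states$is_tip),
    n_nodes = sum(!x$states$is_tip),
    iterations = x$iterations,
    max_delta = x$max_delta,
    max_rate = max(x$edges$rate),
    median_rate = stats::median(x$edges$rate)
  )
}

#' Brownian-motion GLS ancestral reconstruction
#'
#' Validation baseline: each internal node's state is the GLS mean of the tip
#' values under the covariance implied by re-rooting the tree at that node,
#' i.e. \eqn{C_k[i,j] = (d(k,i) + d(k,j) - d(i,j))/2} with d the patristic
#' distance. This is the standard maximum-likelihood ancestral estimate
#' under Brownian motion, valid on non-ultrametric (fossil-bearing) trees.
#'
#' @inheritParams estimate_ancestral_states
#' @return A tibble with columns `node`, `label`, `age`, `state`, `is_tip`.
#' @export
bm_gls_reconstruction <- function(phy, tip_values) {
  validate_phylogeny(phy)
  tip_values <- as_tip_values(tip_values)
  miss <- setdiff(phy$tip.label, names(tip_values))
  if (length(miss)) {
    stop("missing tip value(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  D <- ape::dist.nodes(phy)
  x_tip <- tip_values[phy$tip.label]
  Dtt <- D[seq_len(n_tip), seq_len(n_tip)]
  states <- numeric(n_all)
  states[seq_len(n_tip)] <- x_tip
  for (k in (n_tip + 1L):n_all) {
    dk <- D[k, seq_len(n_tip)]
    Ck <- (outer(dk, dk, "+") - Dtt) / 2
    Ck <- (Ck + t(Ck)) / 2
    inv <- safe_inverse(Ck)
    w <- rowSums(inv)
    states[k] <- sum(w * x_tip) / sum(w)
  }
  ages <- node_ages(phy)
  tibble::tibble(
    node = seq_len(n_all),
    label = ages$label,
    age = ages$age,
    state = states,
    is_tip = ages$is_tip
  )
}
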