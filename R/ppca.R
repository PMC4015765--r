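#' GLS (phylogenetic) mean of a trait matrix
#'
#' The generalized least squares estimate of the root state for each
#' variable, \eqn{a = (1' C^{-1} 1)^{-1} 1' C^{-1} X}, where C is the
#' phylogenetic covariance matrix. On a star tree with equal depths C is
#' proportional to the identity and a reduces to the ordinary column mean.
#'
#' @param X Numeric matrix, taxa in rows (rownames) and variables in columns.
#' @param C Phylogenetic covariance matrix with matching taxon order.
#' @param ridge If C is numerically singular (e.g. zero-length
#'   polytomy-resolution branches), a diagonal ridge of
#'   `1e-8 * mean(diag(C))` is added once, with a message. Set
#'   `ridge = FALSE` to error instead.
#' @return Named numeric vector, one entry per variable.
#' @export
phylogenetic_mean <- function(X, C, ridge = TRUE) {
  X <- as.matrix(X)
  check_cov_match(X, C)
  Cinv <- safe_inverse(C, ridge)
  one <- rep(1, nrow(X))
  w <- as.vector(Cinv %*% one)
  a <- drop(crossprod(w, X)) / sum(w)
  stats::setNames(as.vector(a), colnames(X))
}

check_cov_match <- function(X, C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be square", call. = FALSE)
  if (nrow(X) != nrow(C)) stop("taxa of X and C differ in number", call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(C)) &&
      !identical(rownames(X), rownames(C))) {
    stop("taxon order of X and C must match", call. = FALSE)
  }
  invisible(TRUE)
}

safe_inverse <- function(C, ridge = TRUE) {
  inv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(inv) || kappa(C, exact = FALSE) > 1e12) {
    if (!isTRUE(ridge)) {
      stop("phylogenetic covariance is singular; jitter zero-length branches ",
           "or allow the ridge fallback", call. = FALSE)
    }
    message("near-singular phylogenetic covariance: adding 1e-8 * mean depth ridge")
    C <- C + diag(1e-8 * mean(diag(C)), nrow(C))
    inv <- solve(C)
  }
  inv
}

#' Phylogenetically weighted principal components analysis
#'
#' PCA of the evolutionary covariance matrix
#' \eqn{R = (X - 1a)' C^{-1} (X - 1a) / (n - 1)}, where a is the GLS
#' phylogenetic mean and C the phylogenetic covariance of the taxa. Loadings
#' are the eigenvectors of R in descending eigenvalue order; scores are the
#' GLS-centred data projected on the loadings
#' (\eqn{S = (X - 1a) L}); variance explained is the eigenvalue share in
#' percent. Species' shared ancestry is thereby down-weighted relative to
#' ordinary PCA, which treats species as independent draws.
#'
#' Each loading column is sign-flipped so that its entry of largest magnitude
#' is positive; all downstream statistics are invariant to this choice.
#'
#' @param traits A species trait table ([species_means()]) or a plain numeric
#'   matrix with taxon rownames.
#' @param phy A dated `phylo` object whose tips cover the taxa, or a
#'   precomputed covariance matrix.
#' @param n_components Number of components to retain (default
#'   `min(n_taxa - 1, n_variables)`).
#' @param mode `"cov"` (default) to decompose the evolutionary covariance of
#'   the (already dimensionless) variables, or `"cor"` for the correlation
#'   scale.
#' @param ridge Passed to [phylogenetic_mean()].
#' @return An object of class `phylo_pca`: a list with `center` (the GLS
#'   mean), `loadings`, `scores`, `eig`, `var_explained`, `taxa`,
#'   `variables`, `mode`.
#' @seealso [tidy.phylo_pca()], [glance.phylo_pca()], [autoplot.phylo_pca()]
#' @export
phylo_pca <- function(traits, phy, n_components = NULL, mode = c("cov", "cor"),
                      ridge = TRUE) {
  mode <- match.arg(mode)
  X <- if (is.matrix(traits)) traits else trait_matrix(traits)
  C <- if (inherits(phy, "phylo")) {
    missing_tips <- setdiff(rownames(X), phy$tip.label)
    if (length(missing_tips)) {
      stop("taxa not in tree: ", paste(missing_tips, collapse = ", "),
           call. = FALSE)
    }
    phylo_covariance(phy, rownames(X))
  } else {
    as.matrix(phy)[rownames(X), rownames(X)]
  }
  n <- nrow(X)
  p <- ncol(X)
  max_k <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- max_k
  if (n_components > max_k) {
    stop("n_components must be <= min(n_taxa - 1, n_variables) = ", max_k,
         call. = FALSE)
  }

  a <- phylogenetic_mean(X, C, ridge = ridge)
  Xc <- sweep(X, 2, a)
  Cinv <- safe_inverse(C, ridge)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  R <- (R + t(R)) / 2
  if (mode == "cor") {
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
  }
  es <- eigen(R, symmetric = TRUE)
  eig <- pmax(es$values, 0)
  L <- es$vectors
  # sign convention: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  k <- n_components
  L <- L[, seq_len(k), drop = FALSE]
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(k)))
  scores <- Xc %*% L
  structure(
    list(
      center = a,
      loadings = L,
      scores = scores,
      eig = eig,
      var_explained = eig / sum(eig) * 100,
      taxa = rownames(X),
      variables = colnames(X),
      mode = mode,
      C = C
    ),
    class = "phylo_pca"
  )
}

#' @export
print.phylo_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("Phylogenetically weighted PCA (", x$mode, " mode)\n", sep = "")
  cat(length(x$taxa), "taxa,", length(x$variables), "variables,", k,
      "components retained\n")
  cat("Variance explained (%):",
      paste0(sprintf("%.2f", x$var_explained[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a phylogenetic PCA
#'
#' @param x A `phylo_pca` object.
#' @param matrix Which quantity to return: `"scores"` (per-taxon component
#'   scores), `"loadings"`, or `"eigenvalues"` (with variance shares).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phylo_pca
#' @export
tidy.phylo_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tibble::as_tibble(x$scores, rownames = "taxon"),
    loadings = tibble::as_tibble(x$loadings, rownames = "variable"),
    eigenvalues = tibble::tibble(
      component = paste0("PC", seq_along(x$eig)),
      eigenvalue = x$eig,
      var_explained = x$var_explained,
      cumulative = cumsum(x$var_explained)
    )
  )
}

#' One-row summary of a phylogenetic PCA
#' @param x A `phylo_pca` object.
#' @param ... Unused.
#' @return A one-row tibble with taxon/variable counts and the variance
#'   explained by the first two components.
#' @method glance phylo_pca
#' @export
glance.phylo_pca <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_variables = length(x$variables),
    n_components = ncol(x$loadings),
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' Morphospace plot of a phylogenetic PCA
#'
#' @param object A `phylo_pca` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 taxon scores.
#' @method autoplot phylo_pca
#' @export
autoplot.phylo_pca <- function(object, ...) {
  df <- tidy(object, "scores")
  pct <- sprintf("%.1f%%", object$var_explained[1:2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$taxon), vjust = -0.6, size = 2.6) +
    ggplot2::labs(
      x = paste0("PC1 (", pct[1], ")"),
      y = paste0("PC2 (", pct[2], ")"),
      title = "Phylogenetically weighted morphospace"
    ) +
    ggplot2::theme_minimal()
}

#' F-test for equality of variance between two groups of scores
#'
#' Compares morphospace dispersion between two clades (tips plus, when
#' supplied, inferred ancestral nodes). The statistic is the ratio of the
#' larger to the smaller sample variance, with a two-tailed p-value from the
#' F distribution on (n_larger - 1, n_smaller - 1) degrees of freedom.
#'
#' @param scores A data frame with a numeric score column and a 2-level group
#'   column, or a numeric vector (then `groups` must be given).
#' @param groups Column name (string) when `scores` is a data frame, or a
#'   vector of group labels parallel to a numeric `scores` vector.
#' @param value Column name of the score column when `scores` is a data frame
#'   (default `"score"`).
#' @return A one-row tibble: `group_larger`, `group_smaller`, `n_larger`,
#'   `n_smaller`, `var_larger`, `var_smaller`, `f`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(score = c(rnorm(12, sd = 2), rnorm(12)),
#'                     clade = rep(c("hominoid", "other"), each = 12))
#' variance_equality_test(d, "clade")
variance_equality_test <- function(scores, groups, value = "score") {
  if (is.data.frame(scores)) {
    g <- scores[[groups]]
    x <- scores[[value]]
    if (is.null(x)) stop("no column '", value, "' in scores", call. = FALSE)
  } else {
    x <- scores
    g <- groups
  }
  g <- as.character(g)
  lv <- unique(g)
  if (length(lv) != 2L) stop("need exactly 2 groups, got ", length(lv), call. = FALSE)
  n <- table(factor(g, levels = lv))
  if (any(n < 2L)) {
    stop("group '", lv[which(n < 2)[1]], "' has fewer than 2 members", call. = FALSE)
  }
  v <- vapply(lv, function(l) stats::var(x[g == l]), numeric(1))
  i_big <- which.max(v)
  i_small <- 3L - i_big
  f <- unname(v[[i_big]] / v[[i_small]])
  df1 <- n[[i_big]] - 1L
  df2 <- n[[i_small]] - 1L
  p <- if (v[i_big] == v[i_small]) 1 else {
    min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  tibble::tibble(
    group_larger = lv[i_big], group_smaller = lv[i_small],
    n_larger = n[[i_big]], n_smaller = n[[i_small]],
    var_larger = v[[i_big]], var_smaller = v[[i_small]],
    f = f, df1 = df1, df2 = df2, p_value = p
  )
}
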