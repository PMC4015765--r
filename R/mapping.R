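#' Bivariate morphospace colours for nodes and tips
#'
#' Assigns each point a colour from a bivariate green-red gradient over its
#' (PC1, PC2) position: both axes are min-max normalized to [0, 1] and the
#' colour is the bilinear blend of four corner colours. The assignment is a
#' deterministic function of the normalized position, hence invariant to
#' affine rescaling of the scores; identical scores get identical colours.
#' A degenerate axis (all values equal) is fixed at 0.5 with a message.
#'
#' @param scores Data frame with numeric columns `PC1` and `PC2` (tips and
#'   ancestral nodes together), or a two-column numeric matrix.
#' @param corners Character vector of 4 hex colours, in the order
#'   c(low PC1 + low PC2, high PC1 + low PC2, low PC1 + high PC2,
#'   high PC1 + high PC2). Default: dark red, dark green, light red,
#'   light green.
#' @return The input as a tibble with added columns `u`, `v` (normalized
#'   position) and `colour` (hex).
#' @export
morphospace_colours <- function(scores,
                                corners = c("#8B1A1A", "#1A6B1A",
                                            "#F4A0A0", "#A0E8A0")) {
  if (is.matrix(scores)) {
    scores <- tibble::as_tibble(scores, rownames = "label")
  }
  stopifnot(all(c("PC1", "PC2") %in% names(scores)), length(corners) == 4L)
  if (nrow(scores) < 2L || nrow(unique(scores[, c("PC1", "PC2")])) < 2L) {
    stop("need at least 2 distinct score points", call. = FALSE)
  }
  norm01 <- function(x, axis) {
    r <- range(x)
    if (r[1] == r[2]) {
      message("degenerate ", axis, " axis (all scores equal): fixed at 0.5")
      return(rep(0.5, length(x)))
    }
    (x - r[1]) / (r[2] - r[1])
  }
  u <- norm01(scores$PC1, "PC1")
  v <- norm01(scores$PC2, "PC2")
  cc <- grDevices::col2rgb(corners) # 3 x 4
  w <- rbind((1 - u) * (1 - v), u * (1 - v), (1 - u) * v, u * v) # 4 x n
  rgbm <- cc %*% w # 3 x n
  out <- tibble::as_tibble(scores)
  out$u <- u
  out$v <- v
  out$colour <- grDevices::rgb(t(round(rgbm)), maxColorValue = 255)
  out
}

#' Branch colours from rates and directions
#'
#' Branches moving toward increasing scores (direction +1) use the green
#' family, decreasing (-1) the red family, and zero change the neutral
#' colour. Intensity grows monotonically with |rate|, normalized so the
#' maximal-rate branch has full intensity (the pure family colour); colours
#' are therefore invariant to rescaling all rates by a common factor. If all
#' rates are zero every branch is neutral, with a message.
#'
#' @param rates Non-negative numeric vector of per-branch rates, or the
#'   `edges` tibble from an [estimate_ancestral_states()] reconstruction.
#' @param directions Integer vector in \{-1, 0, 1\} (ignored when `rates` is
#'   an edges tibble, which carries its own).
#' @param family_pos,family_neg,neutral Hex colours for the increasing
#'   family, decreasing family, and zero-rate branches.
#' @return A tibble with columns `rate`, `direction`, `intensity`, `colour`.
#' @export
branch_colours <- function(rates, directions = NULL,
                           family_pos = "#1A6B1A", family_neg = "#8B1A1A",
                           neutral = "#BEBEBE") {
  if (is.data.frame(rates)) {
    directions <- rates$direction
    rates <- rates$rate
  }
  stopifnot(length(rates) == length(directions))
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!all(directions %in% c(-1, 0, 1))) {
    stop("directions must be in {-1, 0, 1}", call. = FALSE)
  }
  max_rate <- max(rates)
  if (max_rate == 0) {
    message("all branch rates are zero: neutral colour everywhere")
    intensity <- rep(0, length(rates))
  } else {
    intensity <- rates / max_rate
  }
  n_rgb <- grDevices::col2rgb(neutral)[, 1]
  fam <- vapply(directions, function(d) {
    if (d > 0) family_pos else if (d < 0) family_neg else neutral
  }, character(1))
  fam_rgb <- grDevices::col2rgb(fam) # 3 x n
  mix <- n_rgb + t(intensity * t(fam_rgb - n_rgb))
  tibble::tibble(
    rate = rates,
    direction = as.integer(directions),
    intensity = intensity,
    colour = grDevices::rgb(t(round(mix)), maxColorValue = 255)
  )
}

fmt_num <- function(x) sprintf("%.12g", x)

#' Export an annotated tree to NEXUS
#'
#' Writes the reconstruction onto the tree as BEAST-style square-bracket
#' metadata comments: every node carries `[&state=...,colour=...]` and every
#' branch length is preceded by the branch's `rate`. Internal nodes are
#' labelled `n<id>` so the annotations can be parsed back losslessly with
#' [parse_annotated_tree()].
#'
#' @param recon An `ancestral_recon` object.
#' @param node_colours Optional character vector of hex colours, one per node
#'   (tree node order), e.g. from [morphospace_colours()].
#' @param edge_colours Optional character vector of hex colours, one per edge
#'   (tree edge order), e.g. from [branch_colours()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_annotated_tree <- function(recon, path, node_colours = NULL,
                                  edge_colours = NULL) {
  stopifnot(inherits(recon, "ancestral_recon"))
  phy <- recon$phy
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  states <- recon$states$state
  if (!is.null(node_colours) && length(node_colours) != n_all) {
    stop("node_colours must have one colour per node (", n_all, ")", call. = FALSE)
  }
  edge_rate <- recon$edges$rate
  if (!is.null(edge_colours) && length(edge_colours) != nrow(phy$edge)) {
    stop("edge_colours must have one colour per edge", call. = FALSE)
  }

  node_name <- function(k) if (k <= n_tip) phy$tip.label[k] else paste0("n", k)
  node_meta <- function(k) {
    m <- paste0("state=", fmt_num(states[k]))
    if (!is.null(node_colours)) m <- paste0(m, ",colour=", node_colours[k])
    paste0("[&", m, "]")
  }
  edge_meta <- function(e) {
    m <- paste0("rate=", fmt_num(edge_rate[e]),
                ",direction=", recon$edges$direction[e])
    if (!is.null(edge_colours)) m <- paste0(m, ",colour=", edge_colours[e])
    paste0("[&", m, "]")
  }
  build <- function(k) {
    kids <- which(phy$edge[, 1] == k)
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(e) {
        paste0(build(phy$edge[e, 2]), edge_meta(e), ":",
               fmt_num(phy$edge.length[e]))
      }, character(1)), collapse = ","), ")")
    } else ""
    paste0(inner, node_name(k), node_meta(k))
  }
  root <- n_tip + 1L
  lines <- c(
    "#NEXUS",
    "BEGIN TREES;",
    paste0("TREE annotated = [&R] ", build(root), ";"),
    "END;"
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("could not write annotated tree to: ", path, call. = FALSE)
  invisible(path)
}

#' Parse an annotated NEXUS tree written by [export_annotated_tree()]
#'
#' @param path Path to the NEXUS file.
#' @return A list with `phy` (the tree), `nodes` (tibble: `label`, `state`,
#'   `colour`) and `edges` (tibble: `child_label`, `rate`, `direction`,
#'   `colour`).
#' @export
parse_annotated_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, regexpr("TREE[^=]*=\\s*(\\[&R\\])?\\s*[^;]+;", txt))
  if (!length(m)) stop("no TREE statement found in ", path, call. = FALSE)
  newick <- sub("^TREE[^=]*=\\s*(\\[&R\\]\\s*)?", "", m)

  # annotations attached to node names: <name>[&...]
  node_ann <- regmatches(newick,
    gregexpr("([A-Za-z0-9_.#-]+)\\[&[^]]*\\]", newick))[[1]]
  parse_kv <- function(s) {
    kv <- strsplit(sub("^.*\\[&", "", sub("\\]$", "", s)), ",")[[1]]
    parts <- strsplit(kv, "=")
    stats::setNames(vapply(parts, `[`, character(1), 2),
                    vapply(parts, `[`, character(1), 1))
  }
  nodes <- purrr::map_dfr(node_ann, function(s) {
    kv <- parse_kv(s)
    tibble::tibble(
      label = sub("\\[.*$", "", s),
      state = as.numeric(kv[["state"]]),
      colour = if ("colour" %in% names(kv)) kv[["colour"]] else NA_character_
    )
  })

  # branch annotations: ...)<name>[&node][&rate=...]:length — the edge
  # annotation is the [&...] block immediately before a ':'
  edge_ann <- regmatches(newick,
    gregexpr("([A-Za-z0-9_.#-]+)\\[&[^]]*\\]\\[&[^]]*\\]:", newick))[[1]]
  # exported form is <subtree><name>[&nodemeta]<edgemeta>:<len>; recover both
  edges <- purrr::map_dfr(edge_ann, function(s) {
    name <- sub("\\[.*$", "", s)
    blocks <- regmatches(s, gregexpr("\\[&[^]]*\\]", s))[[1]]
    kv <- parse_kv(blocks[2])
    tibble::tibble(
      child_label = name,
      rate = as.numeric(kv[["rate"]]),
      direction = as.integer(kv[["direction"]]),
      colour = if ("colour" %in% names(kv)) kv[["colour"]] else NA_character_
    )
  })

  plain <- gsub("\\[&[^]]*\\]", "", newick)
  phy <- ape::read.tree(text = plain)
  list(phy = phy, nodes = nodes, edges = edges)
}

#' Morphospace plot with tips and inferred ancestors
#'
#' Scatter of PC1-PC2 positions: full symbols for observed tips, open symbols
#' for inferred ancestral nodes, coloured by the bivariate morphospace
#' gradient.
#'
#' @param coloured Output of [morphospace_colours()]; must carry an `is_tip`
#'   logical column (joined from the reconstruction's node table).
#' @return A ggplot.
#' @export
plot_morphospace <- function(coloured) {
  stopifnot(all(c("PC1", "PC2", "colour", "is_tip") %in% names(coloured)))
  ggplot2::ggplot(coloured, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$is_tip),
      colour = coloured$colour, fill = coloured$colour, size = 2.5
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "tip (observed)", `FALSE` = "ancestor (inferred)"),
      name = NULL
    ) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Plot the tree with rate-coloured branches
#'
#' Base-graphics phylogram with branches coloured by rate family/intensity;
#' use inside an `svg()` or `pdf()` device for figure export.
#'
#' @param recon An `ancestral_recon` object.
#' @param edge_colours Character vector of hex colours, one per edge (e.g.
#'   `branch_colours(branch_rates(recon))$colour`).
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the reconstruction.
#' @export
plot_rate_tree <- function(recon, edge_colours, ...) {
  stopifnot(inherits(recon, "ancestral_recon"))
  ape::plot.phylo(recon$phy, edge.color = edge_colours, edge.width = 2, ...)
  invisible(recon)
}
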