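#' Parse a Newick string into a validated dated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream comparative methods rely on: a single root, at least two tips,
#' unique tip labels, and a branch length (in millions of years, Myr) on every
#' edge. Trees need not be ultrametric: fossil tips may terminate before the
#' present. Square-bracket comments are stripped before parsing.
#'
#' @param text A Newick string (with branch lengths).
#' @return An object of class `phylo`.
#' @seealso [write_newick()], [read_phylogeny()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text) # drop comments
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L) {
    stop("malformed Newick: no terminating ';' found (offset ", nchar(text), ")",
         call. = FALSE)
  }
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close) {
    # report offset of the first unmatched parenthesis
    depth <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
    off <- if (any(depth < 0)) which(depth < 0)[1] else nchar(text)
    stop("malformed Newick: unbalanced parentheses near character offset ", off,
         call. = FALSE)
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  validate_phylogeny(phy)
  phy
}

#' Read a dated phylogeny from a Newick file
#'
#' @param path Path to a Newick file.
#' @return A validated `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny to Newick
#'
#' @param phy A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(phy, path = NULL, digits = 12) {
  txt <- ape::write.tree(phy, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Validate the structural invariants of a dated phylogeny
#'
#' Checks: single root, >= 2 tips, unique tip labels, every edge has a
#' non-negative branch length. Zero-length edges are permitted (they arise
#' from polytomy resolution) but negative lengths or missing lengths are not.
#'
#' @param phy A `phylo` object.
#' @return `phy`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (ape::Ntip(phy) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(phy$edge.length)) {
    bad <- phy$edge[which(is.na(phy$edge.length))[1], 2]
    lab <- node_label(phy, bad)
    stop("missing branch length on the edge above node ", lab, call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  # note: a multifurcating root (star tree) still has a unique root node;
  # ape's is.rooted() binary-degree notion is not required here
  invisible(phy)
}

# human-readable label for a node index (tip label, node label, or "#<id>")
node_label <- function(phy, node) {
  n_tip <- ape::Ntip(phy)
  if (node <= n_tip) return(phy$tip.label[node])
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label[node - n_tip]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  paste0("#", node)
}

#' Node ages of a dated phylogeny
#'
#' Ages are measured backward from the youngest tip (present = 0), the
#' palaeontological convention: the root age is the maximum root-to-tip path
#' length and a node's age is root age minus its depth. Fossil tips have
#' positive age.
#'
#' @param phy A `phylo` object with branch lengths.
#' @return A tibble with columns `node` (integer index), `label`, `age` (Myr),
#'   and `is_tip`.
#' @export
node_ages <- function(phy) {
  validate_phylogeny(phy)
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths)
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  tibble::tibble(
    node = seq_len(n_node),
    label = vapply(seq_len(n_node), function(i) node_label(phy, i), character(1)),
    age = root_age - depths,
    is_tip = seq_len(n_node) <= n_tip
  )
}

#' Graft a dated fossil tip onto a phylogeny
#'
#' Splits the stem branch of `attachment_lineage` (a tip label, or a character
#' vector of tip labels naming a clade via its MRCA) at `stem_age` Myr before
#' present and hangs the fossil from the new node with branch length
#' `stem_age - tip_age`. All other path lengths are unchanged. `stem_age` must
#' lie strictly inside the age interval spanned by the attachment branch.
#'
#' @param phy A `phylo` object.
#' @param fossil_name Tip label for the fossil (must not already exist).
#' @param attachment_lineage Tip label or character vector of tip labels.
#' @param stem_age Divergence age of the fossil lineage (Myr before present).
#' @param tip_age Age of the fossil's last occurrence (Myr, `>= 0`,
#'   `< stem_age`).
#' @return A new `phylo` object with the fossil tip added.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr2 <- graft_fossil(tr, "F", c("A", "B"), stem_age = 1.5, tip_age = 0.5)
graft_fossil <- function(phy, fossil_name, attachment_lineage, stem_age, tip_age) {
  validate_phylogeny(phy)
  stopifnot(is.character(fossil_name), length(fossil_name) == 1L)
  if (fossil_name %in% phy$tip.label) {
    stop("duplicate fossil name: tip '", fossil_name, "' already in tree",
         call. = FALSE)
  }
  if (!is.numeric(stem_age) || !is.numeric(tip_age)) {
    stop("stem_age and tip_age must be numeric", call. = FALSE)
  }
  if (tip_age < 0) stop("tip_age must be >= 0", call. = FALSE)
  if (tip_age >= stem_age) stop("tip_age must be < stem_age", call. = FALSE)
  missing_taxa <- setdiff(attachment_lineage, phy$tip.label)
  if (length(missing_taxa)) {
    stop("attachment lineage taxa not in tree: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  node <- if (length(attachment_lineage) == 1L) {
    match(attachment_lineage, phy$tip.label)
  } else {
    ape::getMRCA(phy, attachment_lineage)
  }
  ages <- node_ages(phy)
  child_age <- ages$age[node]
  parent <- phy$edge[match(node, phy$edge[, 2]), 1]
  if (is.na(parent)) {
    stop("attachment lineage is the root; it has no stem branch", call. = FALSE)
  }
  parent_age <- ages$age[parent]
  if (stem_age <= child_age || stem_age >= parent_age) {
    stop(sprintf(
      "stem_age %.4g outside the attachment branch interval (%.4g, %.4g) Myr",
      stem_age, child_age, parent_age), call. = FALSE)
  }
  # direct edge surgery keeps all existing path lengths bit-exact:
  # parent --(parent_age - stem_age)--> new node --(stem_age - child_age)--> node
  #                                        \--(stem_age - tip_age)--> fossil
  n_tip <- ape::Ntip(phy)
  e_idx <- match(node, phy$edge[, 2])
  edge <- phy$edge
  # renumber: tips 1..n_tip+1 (fossil appended), internal nodes shift by 1,
  # the new internal node takes the last index
  shift <- function(v) ifelse(v > n_tip, v + 1L, v)
  edge <- cbind(shift(edge[, 1]), shift(edge[, 2]))
  storage.mode(edge) <- "integer"
  new_tip <- n_tip + 1L
  new_node <- n_tip + 1L + phy$Nnode + 1L
  old_child <- edge[e_idx, 2]
  edge[e_idx, 2] <- new_node
  edge <- rbind(edge,
                c(new_node, old_child),
                c(new_node, new_tip))
  elen <- c(phy$edge.length, stem_age - child_age, stem_age - tip_age)
  elen[e_idx] <- parent_age - stem_age
  out <- list(
    edge = edge,
    edge.length = elen,
    tip.label = c(phy$tip.label, fossil_name),
    Nnode = phy$Nnode + 1L
  )
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validate_phylogeny(out)
}

#' Read fossil placements from a YAML config
#'
#' The file is a YAML list of records with keys `fossil_name`,
#' `attachment_lineage` (scalar or list of tip labels), `stem_age_ma`,
#' `tip_age_ma`.
#'
#' @param path Path to the YAML file.
#' @return A tibble with columns `fossil_name`, `attachment_lineage`
#'   (list-column), `stem_age_ma`, `tip_age_ma`.
#' @export
read_fossil_placements <- function(path) {
  if (!file.exists(path)) stop("placement file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  need <- c("fossil_name", "attachment_lineage", "stem_age_ma", "tip_age_ma")
  purrr::walk(raw, function(rec) {
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop("placement record missing keys: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  })
  tibble::tibble(
    fossil_name = purrr::map_chr(raw, "fossil_name"),
    attachment_lineage = purrr::map(raw, function(r) as.character(unlist(r$attachment_lineage))),
    stem_age_ma = purrr::map_dbl(raw, "stem_age_ma"),
    tip_age_ma = purrr::map_dbl(raw, "tip_age_ma")
  )
}

#' Graft a table of fossil placements onto a phylogeny
#'
#' @param phy A `phylo` object.
#' @param placements A tibble as returned by [read_fossil_placements()].
#' @return The tree with all fossils grafted, in table order.
#' @export
graft_fossils <- function(phy, placements) {
  for (i in seq_len(nrow(placements))) {
    phy <- graft_fossil(
      phy,
      fossil_name = placements$fossil_name[i],
      attachment_lineage = placements$attachment_lineage[[i]],
      stem_age = placements$stem_age_ma[i],
      tip_age = placements$tip_age_ma[i]
    )
  }
  phy
}

#' Prune a phylogeny to a set of taxa
#'
#' Returns the induced subtree on `keep`: degree-2 internal nodes are
#' collapsed with branch lengths summed, so patristic distances among kept
#' tips are preserved.
#'
#' @param phy A `phylo` object.
#' @param keep Character vector of tip labels, length >= 2.
#' @return A `phylo` object.
#' @export
prune_to_taxa <- function(phy, keep) {
  validate_phylogeny(phy)
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  ape::keep.tip(phy, keep)
}

#' Resolve polytomies with zero-length branches
#'
#' Multifurcations are resolved in input order with zero-length branches so
#' that downstream GLS machinery sees a binary tree; a message reports how
#' many were resolved.
#'
#' @param phy A `phylo` object.
#' @return A binary `phylo` object.
#' @export
resolve_polytomies <- function(phy) {
  if (ape::is.binary(phy)) return(phy)
  n_before <- phy$Nnode
  out <- ape::multi2di(phy, random = FALSE)
  message("resolved ", out$Nnode - n_before,
          " polytomy node(s) with zero-length branches")
  out
}

#' Phylogenetic covariance matrix of a dated tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length (Myr) of taxa i and j;
#' the diagonal holds root-to-tip depths. The matrix is symmetric and
#' positive semi-definite, and is defined for non-ultrametric trees (fossil
#' tips simply have smaller diagonal entries).
#'
#' @param phy A `phylo` object.
#' @param taxa Ordered character vector of tip labels (default: all tips in
#'   tree order). The matrix rows/columns follow this order.
#' @return A numeric matrix with dimnames `taxa`.
#' @export
phylo_covariance <- function(phy, taxa = phy$tip.label) {
  validate_phylogeny(phy)
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  C <- ape::vcv.phylo(phy)
  C[taxa, taxa, drop = FALSE]
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips.
#'
#' @param phy A `phylo` object.
#' @return A symmetric matrix of distances (Myr) with tip-label dimnames.
#' @export
patristic_distances <- function(phy) {
  stats::cophenetic(phy)
}
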