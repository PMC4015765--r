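#' Assign tree nodes to two clade groups
#'
#' Tips are assigned by membership in the group tip sets; an internal node
#' (inferred ancestor) joins a group when every tip it subtends belongs to
#' that group — so crown and stem ancestors of a clade travel with the clade
#' — and otherwise falls in the complement group.
#'
#' @param phy A `phylo` object.
#' @param groups Named list of two character vectors of tip labels; one
#'   element may be the string `".rest"` meaning "all remaining tips".
#' @return A tibble: `node`, `label`, `is_tip`, `group`.
#' @export
assign_groups <- function(phy, groups) {
  stopifnot(is.list(groups), length(groups) == 2L, !is.null(names(groups)))
  gnames <- names(groups)
  tips <- phy$tip.label
  rest_idx <- which(vapply(groups, function(g) identical(g, ".rest"), logical(1)))
  if (length(rest_idx) == 1L) {
    groups[[rest_idx]] <- setdiff(tips, groups[[3L - rest_idx]])
  }
  unknown <- setdiff(unlist(groups), tips)
  if (length(unknown)) {
    stop("group taxa not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overlap <- intersect(groups[[1]], groups[[2]])
  if (length(overlap)) {
    stop("taxa in both groups: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(tips, unlist(groups))
  if (length(uncovered)) {
    stop("tips in no group: ", paste(uncovered, collapse = ", "),
         "; use '.rest' for a complement group", call. = FALSE)
  }
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  ages <- node_ages(phy)
  grp <- character(n_all)
  grp[seq_len(n_tip)] <- ifelse(tips %in% groups[[1]], gnames[1], gnames[2])
  for (k in (n_tip + 1L):n_all) {
    desc <- ape::extract.clade(phy, k)$tip.label
    grp[k] <- if (all(desc %in% groups[[1]])) {
      gnames[1]
    } else if (all(desc %in% groups[[2]])) {
      gnames[2]
    } else {
      # mixed ancestor: belongs to the backbone/complement group
      gnames[2]
    }
  }
  tibble::tibble(node = seq_len(n_all), label = ages$label,
                 is_tip = ages$is_tip, group = grp)
}

#' Read a pipeline run configuration
#'
#' @param path Path to a YAML config with keys `tree`, `measurements`,
#'   optional `placements`, `bones`, `groups` (named list of two tip sets,
#'   one may be `".rest"`), `n_components`, `pca_mode`, `log_ratios`,
#'   `ie_tol`, `ie_max_iter`, `out_dir`. Relative paths are resolved against
#'   the config file's directory.
#' @return A named list (class `carpal_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("tree", "measurements", "placements", "out_dir")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  structure(cfg, class = "carpal_config")
}

default_config <- function(cfg) {
  defaults <- list(bones = carpal_bones(), n_components = 2,
                   pca_mode = "cov", log_ratios = FALSE,
                   ie_tol = 1e-10, ie_max_iter = 10000)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  need <- c("tree", "measurements", "groups", "out_dir")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss)) {
    stop("config missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("tree", "measurements", "placements")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config path does not exist: ", cfg[[key]], call. = FALSE)
    }
  }
  cfg
}

write_tsv_q <- function(x, path) readr::write_tsv(x, path, progress = FALSE)

#' Run the full per-bone comparative analysis
#'
#' For each requested bone: restrict the fossil-grafted tree and the
#' measurement table to taxa with complete data, size-correct specimens by
#' their geometric mean, average to species shape ratios, run the
#' phylogenetically weighted PCA, estimate ancestral states and per-branch
#' rates on each retained component, run the clade variance-equality F-test
#' on tip + ancestor scores, and write colour tables and an annotated NEXUS
#' tree. All outputs are TSV/NEXUS/JSON under `out_dir/<bone>/`; identical
#' config and inputs give byte-identical outputs. Fossils lacking
#' measurements for a bone are pruned for that bone only (logged).
#'
#' On any stage failure the partially written output directory is removed
#' and the error reports the bone and stage.
#'
#' @param config A `carpal_config` (from [read_run_config()]) or a named
#'   list with the same keys.
#' @return Invisibly, the run report (also written as `run_report.json`):
#'   a list with the config hash, per-bone taxon/specimen counts, variance
#'   explained, and F-test results.
#' @export
run_pipeline <- function(config) {
  cfg <- default_config(config)
  stage <- "setup"
  out_dir <- cfg$out_dir
  created <- !dir.exists(out_dir)
  result <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "tree"
    phy0 <- read_phylogeny(cfg$tree)
    if (!ape::is.binary(phy0)) phy0 <- resolve_polytomies(phy0)
    if (!is.null(cfg$placements)) {
      placements <- read_fossil_placements(cfg$placements)
      phy0 <- graft_fossils(phy0, placements)
    }

    stage <- "measurements"
    meas <- load_measurements(cfg$measurements)

    # hash the analysis config only; the output location must not change
    # the scientific fingerprint of a run
    cfg_for_hash <- unclass(cfg)
    cfg_for_hash$out_dir <- NULL
    report <- list(config_hash = rlang::hash(cfg_for_hash), bones = list())
    ftests_all <- NULL

    for (b in cfg$bones) {
      if (!b %in% meas$bone) {
        message("bone '", b, "' absent from measurements; skipped")
        next
      }
      bone_dir <- file.path(out_dir, b)
      dir.create(bone_dir, showWarnings = FALSE)

      stage <- paste0(b, "/size_correct")
      corrected <- size_correct(meas, b, log_ratios = cfg$log_ratios)
      traits <- species_means(corrected)

      stage <- paste0(b, "/prune")
      shared <- intersect(traits$taxon, phy0$tip.label)
      off_tree <- setdiff(traits$taxon, phy0$tip.label)
      if (length(off_tree)) {
        message(b, ": taxa with data but no tree tip dropped: ",
                paste(off_tree, collapse = ", "))
      }
      no_data <- setdiff(phy0$tip.label, traits$taxon)
      if (length(no_data)) {
        message(b, ": tips without complete data pruned: ",
                paste(no_data, collapse = ", "))
      }
      if (length(shared) < 4L) {
        stop("fewer than 4 taxa with both data and tree tip", call. = FALSE)
      }
      phy <- prune_to_taxa(phy0, shared)
      traits <- traits[match(phy$tip.label, traits$taxon), ]
      attr(traits, "variables") <- carpal_variables()[[b]]
      write_tsv_q(traits, file.path(bone_dir, "trait_matrix.tsv"))

      stage <- paste0(b, "/ppca")
      k <- min(cfg$n_components, nrow(traits) - 1L,
               length(carpal_variables()[[b]]))
      pca <- phylo_pca(traits, phy, n_components = k, mode = cfg$pca_mode)
      write_tsv_q(tidy(pca, "loadings"), file.path(bone_dir, "loadings.tsv"))
      write_tsv_q(tidy(pca, "eigenvalues"),
                  file.path(bone_dir, "variance_explained.tsv"))

      stage <- paste0(b, "/ancestral")
      grp <- assign_groups(phy, cfg$groups)
      all_scores <- NULL
      rates_out <- NULL
      recon1 <- NULL
      for (j in seq_len(k)) {
        pc <- paste0("PC", j)
        rec <- estimate_ancestral_states(
          phy, stats::setNames(pca$scores[, j], rownames(pca$scores)),
          tol = cfg$ie_tol, max_iter = cfg$ie_max_iter
        )
        if (j == 1L) recon1 <- rec
        sc <- rec$states
        sc$component <- pc
        all_scores <- dplyr::bind_rows(all_scores, sc)
        rr <- rec$edges
        rr$component <- pc
        rates_out <- dplyr::bind_rows(rates_out, rr)
      }
      write_tsv_q(all_scores, file.path(bone_dir, "node_states.tsv"))
      write_tsv_q(rates_out, file.path(bone_dir, "branch_rates.tsv"))

      stage <- paste0(b, "/ftest")
      ft_bone <- NULL
      for (j in seq_len(k)) {
        pc <- paste0("PC", j)
        sc <- dplyr::filter(all_scores, .data$component == pc) |>
          dplyr::left_join(grp[, c("node", "group")], by = "node")
        ft <- variance_equality_test(sc, "group", value = "state")
        ft$bone <- b
        ft$component <- pc
        ft_bone <- dplyr::bind_rows(ft_bone, ft)
      }
      write_tsv_q(ft_bone, file.path(bone_dir, "ftests.tsv"))
      ftests_all <- dplyr::bind_rows(ftests_all, ft_bone)

      stage <- paste0(b, "/mapping")
      wide <- all_scores |>
        dplyr::select("node", "label", "is_tip", "component", "state") |>
        tidyr::pivot_wider(names_from = "component", values_from = "state")
      if (!"PC2" %in% names(wide)) wide$PC2 <- 0
      node_cols <- morphospace_colours(wide)
      write_tsv_q(node_cols, file.path(bone_dir, "node_colours.tsv"))
      br1 <- dplyr::filter(rates_out, .data$component == "PC1")
      edge_cols <- branch_colours(br1)
      write_tsv_q(dplyr::bind_cols(br1[, c("parent_label", "child_label")],
                                   edge_cols),
                  file.path(bone_dir, "branch_colours.tsv"))
      export_annotated_tree(recon1, file.path(bone_dir, "annotated_tree.nex"),
                            node_colours = node_cols$colour,
                            edge_colours = edge_cols$colour)

      report$bones[[b]] <- list(
        n_taxa = nrow(traits),
        n_specimens = dplyr::n_distinct(corrected$specimen_id),
        n_components = k,
        var_explained = unname(pca$var_explained[seq_len(k)]),
        ftests = ft_bone
      )
    }

    stage <- "report"
    if (!is.null(ftests_all)) {
      write_tsv_q(ftests_all, file.path(out_dir, "ftests_all.tsv"))
    }
    report_json <- list(
      config_hash = report$config_hash,
      bones = lapply(report$bones, function(bb) {
        bb$ftests <- as.list(bb$ftests)
        bb
      })
    )
    jsonlite::write_json(report_json, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report
  }, error = function(e) {
    if (created && dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
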