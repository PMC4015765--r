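#' Variable registries for the five carpal bones
#'
#' Named list mapping each bone to its linear-measurement variable codes
#' (7 hamate, 11 lunate, 7 triquetrum, 6 capitate, 7 scaphoid; 38 in total).
#' Codes follow the maximum length/height/breadth naming convention for the
#' bone body and its articular facets (e.g. `BHB` = maximum mediolateral
#' breadth of the hamate body).
#'
#' @return A named list of character vectors.
#' @export
#' @examples
#' lengths(carpal_variables())
carpal_variables <- function() {
  list(
    hamate     = c("LHB-H", "HHTF", "LHB", "LHTF", "HHB", "HHB-H", "BHB"),
    lunate     = c("BLRF", "HLRF", "BLCF", "BLB", "HLTF", "HLCF", "LLTF",
                   "HLB", "LLB", "HLSF", "LLSF"),
    triquetrum = c("HTHF", "BTHF", "BTB", "HTLF", "LTB", "LTLF", "HTB"),
    capitate   = c("BCN", "BCB", "BCPF", "LCB", "HCPF", "HCB"),
    scaphoid   = c("LSB", "HSB", "LSRF", "HSRF", "BSB", "HSLF", "LSLF")
  )
}

#' Names of the five carpal bones
#' @return Character vector of bone identifiers.
#' @export
carpal_bones <- function() names(carpal_variables())

#' Validate a specimen measurement table
#'
#' Enforces the structural invariants of the long-format measurement table:
#' required columns, known bones, variable codes drawn from each bone's
#' registry, strictly positive values (required by the geometric mean), and
#' no duplicated (specimen, bone, variable) cells. Rows with non-positive
#' values are dropped with a warning rather than failing the whole table,
#' since single bad cells are the common museum-data failure mode.
#'
#' @param data A data frame with columns `specimen_id`, `taxon`, `bone`,
#'   `variable`, `value_mm` (and optionally `session`).
#' @return A validated tibble.
#' @export
validate_measurements <- function(data) {
  need <- c("specimen_id", "taxon", "bone", "variable", "value_mm")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("measurement table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  registry <- carpal_variables()
  bad_bone <- setdiff(unique(data$bone), names(registry))
  if (length(bad_bone)) {
    stop("unknown bone(s): ", paste(bad_bone, collapse = ", "), call. = FALSE)
  }
  for (b in unique(data$bone)) {
    codes <- unique(data$variable[data$bone == b])
    bad <- setdiff(codes, registry[[b]])
    if (length(bad)) {
      stop("unknown variable code(s) for bone '", b, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  key_cols <- intersect(c("specimen_id", "bone", "variable", "session"), names(data))
  key <- do.call(paste, c(data[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), key_cols, drop = FALSE][1, ]
    stop("duplicate measurement for specimen '", dup$specimen_id,
         "', bone '", dup$bone, "', variable '", dup$variable, "'",
         call. = FALSE)
  }
  nonpos <- !is.finite(data$value_mm) | data$value_mm <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " row(s) with non-positive or missing values dropped",
            call. = FALSE)
    data <- data[!nonpos, , drop = FALSE]
  }
  data
}

#' Load a specimen measurement table from CSV/TSV
#'
#' @param path Path to a CSV or TSV file with columns `specimen_id`, `taxon`,
#'   `bone`, `variable`, `value_mm` (and optionally `session` for
#'   measurement-error studies). The delimiter is inferred from the file
#'   extension (`.tsv`/`.tab` = tab, otherwise comma).
#' @return A validated tibble (see [validate_measurements()]).
#' @export
load_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_measurements(data)
}

#' Write a measurement table to CSV
#' @param data A measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Geometric-mean size correction of specimen measurements
#'
#' For each specimen with the complete variable set for `bone`, the geometric
#' mean g of all its raw measurements for that bone is computed and each
#' measurement is divided by g, yielding dimensionless shape ratios whose
#' product is 1 (equivalently, whose geometric mean is 1). Specimens missing
#' any of the bone's variables are dropped with a warning. The correction is
#' exactly invariant to uniform scaling of a specimen's measurements, which
#' is what makes it usable when body mass is unknown.
#'
#' @param data A validated measurement tibble.
#' @param bone Bone identifier (one of [carpal_bones()]).
#' @param log_ratios If `TRUE`, return log(shape ratio) instead of the raw
#'   ratio. Default `FALSE`.
#' @return A tibble with columns `specimen_id`, `taxon`, `variable`, `value`
#'   (corrected, dimensionless) and `geomean_mm` (the specimen's size proxy).
#' @export
size_correct <- function(data, bone, log_ratios = FALSE) {
  stopifnot(length(bone) == 1L, bone %in% carpal_bones())
  codes <- carpal_variables()[[bone]]
  sub <- dplyr::filter(data, .data$bone == !!bone)
  if (!nrow(sub)) stop("no measurements for bone '", bone, "'", call. = FALSE)

  complete <- sub |>
    dplyr::distinct(.data$specimen_id, .data$variable) |>
    dplyr::count(.data$specimen_id) |>
    dplyr::filter(.data$n == length(codes))
  dropped <- setdiff(unique(sub$specimen_id), complete$specimen_id)
  if (length(dropped)) {
    warning("dropped ", length(dropped), " incomplete specimen(s) for bone '",
            bone, "': ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
    sub <- dplyr::filter(sub, .data$specimen_id %in% complete$specimen_id)
  }
  if (!nrow(sub)) stop("no complete specimens for bone '", bone, "'", call. = FALSE)

  out <- sub |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::mutate(geomean_mm = exp(mean(log(.data$value_mm)))) |>
    dplyr::ungroup() |>
    dplyr::mutate(value = .data$value_mm / .data$geomean_mm) |>
    dplyr::select("specimen_id", "taxon", "variable", "value", "geomean_mm")
  if (log_ratios) out$value <- log(out$value)
  out
}

#' Aggregate size-corrected specimens to a species trait matrix
#'
#' Each cell is the arithmetic mean of the corrected values across a taxon's
#' specimens; per-taxon specimen counts are recorded. Fossil taxa known from
#' a single specimen are handled identically (n = 1 mean).
#'
#' @param corrected Output of [size_correct()].
#' @return A tibble (one row per taxon) with an `n_specimens` column and one
#'   column per variable; attribute `"variables"` holds the variable order.
#' @export
species_means <- function(corrected) {
  wide <- corrected |>
    dplyr::group_by(.data$taxon, .data$variable) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  counts <- corrected |>
    dplyr::distinct(.data$taxon, .data$specimen_id) |>
    dplyr::count(.data$taxon, name = "n_specimens")
  out <- dplyr::left_join(counts, wide, by = "taxon")
  attr(out, "variables") <- setdiff(names(wide), "taxon")
  out
}

#' Extract the numeric matrix from a species trait table
#'
#' @param traits A tibble as returned by [species_means()].
#' @return A numeric matrix, taxa in rows (rownames) and variables in columns.
#' @export
trait_matrix <- function(traits) {
  vars <- attr(traits, "variables")
  if (is.null(vars)) vars <- setdiff(names(traits), c("taxon", "n_specimens"))
  m <- as.matrix(traits[, vars, drop = FALSE])
  rownames(m) <- traits$taxon
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    stop("missing trait cells for taxa: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Relative technical error of measurement across repeat sessions
#'
#' Quantifies intraobserver repeatability: the same specimens measured in
#' K >= 2 sessions. For each variable the relative TEM (%) is
#' \deqn{\sqrt{\sum_s \sum_k (x_{sk} - \bar x_s)^2 / (n (K-1))} / \bar x \times 100}
#' where s indexes specimens, k sessions, and \eqn{\bar x} is the grand mean.
#' For K = 2 this reduces to the classical \eqn{\sqrt{\sum d^2 / 2n}} form
#' based on within-specimen differences d.
#'
#' @param data A measurement tibble with a `session` column; every specimen
#'   and variable must appear in every session.
#' @return A tibble with columns `bone`, `variable`, `n_specimens`,
#'   `n_sessions`, `tem`, `tem_pct`.
#' @export
technical_error <- function(data) {
  if (!"session" %in% names(data)) {
    stop("measurement table needs a 'session' column", call. = FALSE)
  }
  data <- validate_measurements(data)
  sessions <- sort(unique(data$session))
  if (length(sessions) < 2L) stop("need >= 2 sessions", call. = FALSE)
  # every (specimen, bone, variable) must occur in every session
  cover <- data |>
    dplyr::count(.data$specimen_id, .data$bone, .data$variable) |>
    dplyr::filter(.data$n != length(sessions))
  if (nrow(cover)) {
    stop("mismatched specimen sets across sessions (e.g. specimen '",
         cover$specimen_id[1], "', variable '", cover$variable[1], "')",
         call. = FALSE)
  }
  K <- length(sessions)
  data |>
    dplyr::group_by(.data$bone, .data$variable) |>
    dplyr::summarise(
      n_specimens = dplyr::n_distinct(.data$specimen_id),
      n_sessions = K,
      tem = {
        dev2 <- stats::ave(.data$value_mm, .data$specimen_id,
                           FUN = function(v) (v - mean(v))^2)
        sqrt(sum(dev2) / (dplyr::n_distinct(.data$specimen_id) * (K - 1)))
      },
      tem_pct = .data$tem / mean(.data$value_mm) * 100,
      .groups = "drop"
    )
}
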