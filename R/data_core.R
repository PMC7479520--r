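# Core containers: the dataset (cells + clinical), the analysis configuration,
# and delimited-text readers/writers.
#
# On-disk contract:
#   cells CSV    - cell_id, region_id, patient_id, group, x, y, cell_type,
#                  one 0/1 column per marker named marker_<name>,
#                  optionally cn_label.
#   clinical CSV - patient_id, group, survival_time, event.

#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with the defaults of the
#' standard protocol for this analysis: 10-cell windows (centre cell included), k = 10 CNs,
#' pseudocount 1e-3 before logs, Tucker ranks (2,6,6), 5000 permutations for
#' communication edges, 10 training patients per group and 1000 repeated
#' hold-out (RHO) splits for classification, 200 RHO samples and 10 outer
#' repeats for the CN functional state alteration score, and a 100-cell
#' uniqueness mask for contact statistics.
#'
#' @param window_size Number of cells per spatial window, centre cell included.
#' @param n_cns Number of cellular neighborhoods (k for k-means).
#' @param artifact_cell_type Cell type marking imaging artifacts; the CN whose
#'   centroid loads most on it is removed. `NULL` disables removal.
#' @param artifact_cn Explicit CN id to remove instead (overrides the type rule).
#' @param excluded_cns CN ids excluded from frequency/tensor stages (e.g. the
#'   follicle CN, analysed separately).
#' @param pseudocount Added to frequencies before taking logs.
#' @param tucker_ranks Integer triple of Tucker ranks (patient, cell type, CN).
#' @param tucker_n_starts Random restarts for the Tucker decomposition.
#' @param n_permutations Permutations for the communication null.
#' @param rho_train_per_group Training patients per group in each RHO split.
#' @param rho_reps RHO repetitions for group classification.
#' @param alteration_rho_reps RHO samples per alteration-score estimate.
#' @param alteration_outer_reps Outer repeats of the alteration score.
#' @param min_unique_contact_cells Mask contact pairs with fewer unique
#'   interacting cells than this.
#' @param communication_edge_quantile Permutation quantile above which an
#'   observed canonical correlation becomes a communication edge.
#' @param mixing_cn_pair Integer pair of CN ids for the mixing-score stage.
#' @param kmeans_nstart,kmeans_iter_max Pinned k-means controls.
#' @param group_levels Optional explicit ordering of the two group levels;
#'   the first is the reference (coded 0). Default: lexicographic.
#' @param rng_seed Master seed; all stage randomness derives from it.
#' @return A list of class `cn_config`.
#' @export
cn_config <- function(window_size = 10L,
                      n_cns = 10L,
                      artifact_cell_type = NULL,
                      artifact_cn = NULL,
                      excluded_cns = integer(0),
                      pseudocount = 1e-3,
                      tucker_ranks = c(2L, 6L, 6L),
                      tucker_n_starts = 5L,
                      n_permutations = 5000L,
                      rho_train_per_group = 10L,
                      rho_reps = 1000L,
                      alteration_rho_reps = 200L,
                      alteration_outer_reps = 10L,
                      min_unique_contact_cells = 100L,
                      communication_edge_quantile = 0.90,
                      mixing_cn_pair = NULL,
                      kmeans_nstart = 5L,
                      kmeans_iter_max = 100L,
                      group_levels = NULL,
                      rng_seed = 1L) {
  stopifnot(window_size >= 2, pseudocount > 0,
            communication_edge_quantile > 0, communication_edge_quantile < 1,
            length(tucker_ranks) == 3)
  cfg <- list(window_size = as.integer(window_size),
              n_cns = as.integer(n_cns),
              artifact_cell_type = artifact_cell_type,
              artifact_cn = artifact_cn,
              excluded_cns = as.integer(excluded_cns),
              pseudocount = pseudocount,
              tucker_ranks = as.integer(tucker_ranks),
              tucker_n_starts = as.integer(tucker_n_starts),
              n_permutations = as.integer(n_permutations),
              rho_train_per_group = as.integer(rho_train_per_group),
              rho_reps = as.integer(rho_reps),
              alteration_rho_reps = as.integer(alteration_rho_reps),
              alteration_outer_reps = as.integer(alteration_outer_reps),
              min_unique_contact_cells = as.integer(min_unique_contact_cells),
              communication_edge_quantile = communication_edge_quantile,
              mixing_cn_pair = mixing_cn_pair,
              kmeans_nstart = as.integer(kmeans_nstart),
              kmeans_iter_max = as.integer(kmeans_iter_max),
              group_levels = group_levels,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "cn_config"
  cfg
}

#' Read an analysis configuration from a flat YAML file
#'
#' Keys are the arguments of [cn_config()]; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `cn_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(cn_config, vals)
}

marker_cols <- function(markers) {
  if (!length(markers)) return(character(0))
  paste0("marker_", markers)
}

#' Construct a validated dataset
#'
#' @param cells Data frame with columns `cell_id`, `region_id`, `patient_id`,
#'   `group`, `x`, `y`, `cell_type`, one 0/1 `marker_<name>` column per marker,
#'   and optionally `cn_label`.
#' @param clinical Data frame with columns `patient_id`, `group`,
#'   `survival_time`, `event`.
#' @param panel Ordered character vector of the declared cell types. Default:
#'   sorted unique types present.
#' @param markers Ordered character vector of marker names (without the
#'   `marker_` prefix). Default: inferred from the cell columns.
#' @return A list of class `cn_dataset` with elements `cells`, `clinical`,
#'   `panel`, `markers`.
#' @export
cn_dataset <- function(cells, clinical, panel = NULL, markers = NULL) {
  req <- c("cell_id", "region_id", "patient_id", "group", "x", "y", "cell_type")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cells table missing column(s): ", paste(miss, collapse = ", "))
  reqc <- c("patient_id", "group", "survival_time", "event")
  missc <- setdiff(reqc, names(clinical))
  if (length(missc)) stop("clinical table missing column(s): ", paste(missc, collapse = ", "))

  if (is.null(markers)) {
    markers <- sub("^marker_", "", grep("^marker_", names(cells), value = TRUE))
  }
  missm <- setdiff(marker_cols(markers), names(cells))
  if (length(missm)) stop("cells table missing marker column(s): ", paste(missm, collapse = ", "))
  if (is.null(panel)) panel <- sort(unique(as.character(cells$cell_type)))

  cells$cell_id <- as.character(cells$cell_id)
  cells$region_id <- as.character(cells$region_id)
  cells$patient_id <- as.character(cells$patient_id)
  cells$group <- as.character(cells$group)
  cells$cell_type <- as.character(cells$cell_type)
  clinical$patient_id <- as.character(clinical$patient_id)
  clinical$group <- as.character(clinical$group)
  if (!"cn_label" %in% names(cells)) cells$cn_label <- NA_integer_
  cells$cn_label <- as.integer(cells$cn_label)

  ds <- structure(list(cells = cells, clinical = clinical,
                       panel = panel, markers = markers),
                  class = "cn_dataset")
  validate_dataset(ds)
  ds
}

#' Validate dataset invariants
#'
#' Checks finite coordinates, panel membership, unique cell ids, 0/1 marker
#' flags, referential integrity of cells to clinical rows, that each region
#' belongs to exactly one patient, and non-negative survival times.
#'
#' @param ds A `cn_dataset`.
#' @return Invisibly `ds`; stops on any violation.
#' @export
validate_dataset <- function(ds) {
  cells <- ds$cells
  if (anyDuplicated(cells$cell_id))
    stop("integrity error: duplicate cell_id values")
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("integrity error: non-finite coordinates")
  unknown <- setdiff(unique(cells$cell_type), ds$panel)
  if (length(unknown))
    stop("unknown cell type(s) not in panel: ", paste(unknown, collapse = ", "))
  for (mc in marker_cols(ds$markers)) {
    v <- cells[[mc]]
    if (!all(v %in% c(0, 1)))
      stop("marker column ", mc, " must be 0/1")
  }
  if (anyDuplicated(ds$clinical$patient_id))
    stop("integrity error: duplicate patient_id in clinical table")
  orphan <- setdiff(unique(cells$patient_id), ds$clinical$patient_id)
  if (length(orphan))
    stop("integrity error: cells reference patient(s) absent from clinical: ",
         paste(orphan, collapse = ", "))
  rp <- unique(cells[, c("region_id", "patient_id")])
  if (anyDuplicated(rp$region_id))
    stop("integrity error: a region belongs to more than one patient")
  if (any(ds$clinical$survival_time < 0))
    stop("integrity error: negative survival_time")
  invisible(ds)
}

#' @export
print.cn_dataset <- function(x, ...) {
  cat("cn_dataset:", nrow(x$cells), "cells,",
      length(unique(x$cells$region_id)), "regions,",
      nrow(x$clinical), "patients,",
      length(x$panel), "cell types,",
      length(x$markers), "markers\n")
  lab <- sum(!is.na(x$cells$cn_label))
  if (lab > 0) cat("  cn_label assigned for", lab, "cells\n")
  invisible(x)
}

#' Read a dataset from delimited text files
#'
#' @param cell_table_path Path to the cells CSV.
#' @param clinical_table_path Path to the clinical CSV.
#' @param panel,markers Optional declared panel/markers (see [cn_dataset()]).
#' @return A validated `cn_dataset`.
#' @export
read_dataset <- function(cell_table_path, clinical_table_path,
                         panel = NULL, markers = NULL) {
  cells <- utils::read.csv(cell_table_path, stringsAsFactors = FALSE)
  clinical <- utils::read.csv(clinical_table_path, stringsAsFactors = FALSE)
  cn_dataset(cells, clinical, panel = panel, markers = markers)
}

#' Write a dataset to delimited text files
#'
#' @param ds A `cn_dataset`.
#' @param cell_table_path,clinical_table_path Output CSV paths.
#' @return Invisibly the two paths.
#' @export
write_dataset <- function(ds, cell_table_path, clinical_table_path) {
  utils::write.csv(ds$cells, cell_table_path, row.names = FALSE)
  utils::write.csv(ds$clinical, clinical_table_path, row.names = FALSE)
  invisible(c(cell_table_path, clinical_table_path))
}

#' Write an analysis result to disk
#'
#' Data frames and matrices are written as CSV; everything else as JSON
#' (round-trippable, full double precision).
#'
#' @param result A data frame, matrix, or list-like result object.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default chosen from the object.
#' @return Invisibly `path`.
#' @export
write_results <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (is.data.frame(result) || is.matrix(result)) "csv" else "json"
  }
  if (format == "csv") {
    if (is.matrix(result)) {
      df <- as.data.frame(result)
      df <- cbind(row = rownames(result) %||% seq_len(nrow(result)), df)
      utils::write.csv(df, path, row.names = FALSE)
    } else {
      utils::write.csv(result, path, row.names = FALSE)
    }
  } else if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else stop("unknown format: ", format)
  invisible(path)
}

# Encode the two-level group variable as 0/1. Reference level = first of
# group_levels (or lexicographic first).
group_indicator <- function(groups, group_levels = NULL) {
  lev <- group_levels %||% sort(unique(as.character(groups)))
  if (length(lev) != 2)
    stop("group variable must have exactly two levels, got: ",
         paste(lev, collapse = ", "))
  out <- as.integer(as.character(groups) == lev[2])
  attr(out, "levels") <- lev
  out
}
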