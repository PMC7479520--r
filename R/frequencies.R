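# Overall and CN-specific cell-type / marker-subset frequencies, marker
# proportion summaries, group t-tests, and PCA of abundances.
#
# A "subset" is a cell type optionally refined by required-positive markers
# (e.g. PD-1+ CD4+ T cells). The CN-specific frequency of a subset for a
# patient is the fraction of that patient's cells in the CN belonging to the
# subset (denominator: all cells of the patient in that CN, pooled over the
# patient's regions). The overall frequency uses all of the patient's cells
# in non-excluded CNs.

#' Declare a cell subset
#'
#' @param cell_type Panel cell type.
#' @param markers Character vector of markers required positive (may be empty).
#' @param name Display name; default derived from type and markers.
#' @return A list of class `cn_subset`.
#' @export
cn_subset <- function(cell_type, markers = character(0), name = NULL) {
  name <- name %||%
    if (length(markers)) paste0(paste0(markers, "+", collapse = ""), " ", cell_type)
    else cell_type
  structure(list(name = name, cell_type = cell_type, markers = markers),
            class = "cn_subset")
}

#' Default subset list: all plain panel types
#'
#' @param dataset A `cn_dataset`.
#' @param marker_types Optional character vector of cell types for which
#'   single-marker-positive refinements are added for every declared marker.
#' @return List of `cn_subset`.
#' @export
default_subsets <- function(dataset, marker_types = character(0)) {
  subs <- lapply(dataset$panel, cn_subset)
  for (ct in marker_types)
    for (m in dataset$markers)
      subs[[length(subs) + 1L]] <- cn_subset(ct, m)
  subs
}

subset_membership <- function(cells, subset, markers_declared) {
  bad <- setdiff(subset$markers, markers_declared)
  if (length(bad))
    stop("subset '", subset$name, "' references undeclared marker(s): ",
         paste(bad, collapse = ", "))
  sel <- cells$cell_type == subset$cell_type
  for (m in subset$markers) sel <- sel & cells[[marker_cols(m)]] == 1L
  sel
}

#' Compute overall and CN-specific subset frequencies
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @param subsets List of [cn_subset()]; default all plain panel types.
#' @param excluded_cns CN ids excluded from the overall denominator and from
#'   the CN-specific table (e.g. the follicle CN).
#' @return List of class `cn_frequencies`:
#'   `cn_specific` data frame (patient_id, cn, subset, freq; `NA` freq for
#'   zero-cell patient-CN combinations), `overall` data frame
#'   (patient_id, subset, freq), `occupancy` (patient x CN fraction of the
#'   patient's non-excluded cells in each CN), `subsets`, `subset_info`
#'   (name / cell_type / n_markers per subset), `cns`, `patients`.
#' @export
compute_frequencies <- function(dataset, subsets = default_subsets(dataset),
                                excluded_cns = integer(0)) {
  cells <- dataset$cells[!is.na(dataset$cells$cn_label), ]
  if (!nrow(cells)) stop("cn_label not assigned")
  cells <- cells[!(cells$cn_label %in% excluded_cns), ]
  if (!nrow(cells)) stop("all cells fall in excluded CNs")
  cns <- sort(unique(cells$cn_label))
  patients <- sort(unique(dataset$cells$patient_id))
  sub_names <- vapply(subsets, `[[`, character(1), "name")
  if (anyDuplicated(sub_names)) stop("duplicate subset names")

  pat <- factor(cells$patient_id, levels = patients)
  cnf <- factor(cells$cn_label, levels = cns)
  denom_cn <- table(pat, cnf)                     # cells per (patient, CN)
  denom_all <- rowSums(denom_cn)                  # non-excluded cells / patient

  cn_specific <- list(); overall <- list()
  for (s in seq_along(subsets)) {
    memb <- subset_membership(cells, subsets[[s]], dataset$markers)
    num_cn <- table(pat[memb], cnf[memb])
    # table() on a subset keeps factor levels, so dimensions align
    f_cn <- ifelse(denom_cn > 0, as.matrix(num_cn) / as.matrix(denom_cn), NA_real_)
    cn_specific[[s]] <- data.frame(
      patient_id = rep(patients, times = length(cns)),
      cn = rep(cns, each = length(patients)),
      subset = sub_names[s], freq = as.vector(f_cn),
      stringsAsFactors = FALSE)
    overall[[s]] <- data.frame(
      patient_id = patients, subset = sub_names[s],
      freq = ifelse(denom_all > 0, rowSums(as.matrix(num_cn)) / denom_all, NA_real_),
      stringsAsFactors = FALSE)
  }
  occupancy <- as.matrix(denom_cn) / as.numeric(denom_all)
  occupancy[denom_all == 0, ] <- NA_real_
  dimnames(occupancy) <- list(patients, paste0("CN", cns))
  subset_info <- data.frame(
    name = sub_names,
    cell_type = vapply(subsets, `[[`, character(1), "cell_type"),
    n_markers = vapply(subsets, function(s) length(s$markers), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(cn_specific = do.call(rbind, cn_specific),
                 overall = do.call(rbind, overall),
                 occupancy = occupancy,
                 subsets = sub_names, subset_info = subset_info,
                 cns = cns, patients = patients,
                 excluded_cns = as.integer(excluded_cns)),
            class = "cn_frequencies")
}

#' Wide frequency matrix
#'
#' @param freqs A `cn_frequencies`.
#' @param which `"overall"` (patients x subsets) or `"cn_specific"`
#'   (patients x subset:CN combinations).
#' @param subsets Optional subset names to keep.
#' @param cns Optional CN ids to keep (cn_specific only).
#' @return Numeric matrix with patient_id rownames; `NA` where undefined.
#' @export
frequency_matrix <- function(freqs, which = c("overall", "cn_specific"),
                             subsets = NULL, cns = NULL) {
  which <- match.arg(which)
  if (which == "overall") {
    df <- freqs$overall
    if (!is.null(subsets)) df <- df[df$subset %in% subsets, ]
    sn <- unique(df$subset)
    m <- matrix(NA_real_, length(freqs$patients), length(sn),
                dimnames = list(freqs$patients, sn))
    m[cbind(df$patient_id, df$subset)] <- df$freq
  } else {
    df <- freqs$cn_specific
    if (!is.null(subsets)) df <- df[df$subset %in% subsets, ]
    if (!is.null(cns)) df <- df[df$cn %in% cns, ]
    col <- paste0(df$subset, "@CN", df$cn)
    cn_order <- unique(col)
    m <- matrix(NA_real_, length(freqs$patients), length(cn_order),
                dimnames = list(freqs$patients, cn_order))
    m[cbind(df$patient_id, col)] <- df$freq
  }
  m
}

#' Marker-positivity proportions per CN
#'
#' For each listed cell subset and CN: (a) the fraction of subset cells
#' positive for at least one of the markers; (b) among marker-positive subset
#' cells, the fraction positive for each specific marker.
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @param markers Markers considered "functional" (default: all declared).
#' @param cell_types Cell types summarised (default: all panel types present).
#' @param per_patient If `TRUE`, proportions per patient; else pooled cells.
#' @return Data frame with columns `cn`, `cell_type` (and `patient_id` when
#'   per patient), `n_cells`, `prop_any_positive`, then `prop_<marker>`
#'   (share of each marker among marker-positive cells). `NA` for empty cells.
#' @export
marker_proportions <- function(dataset, markers = dataset$markers,
                               cell_types = NULL, per_patient = FALSE) {
  cells <- dataset$cells[!is.na(dataset$cells$cn_label), ]
  if (!nrow(cells)) stop("cn_label not assigned")
  cell_types <- cell_types %||% intersect(dataset$panel, unique(cells$cell_type))
  mcols <- marker_cols(markers)
  pos <- as.matrix(cells[, mcols, drop = FALSE]) == 1L
  any_pos <- rowSums(pos) > 0

  split_keys <- list(cn = cells$cn_label, cell_type = cells$cell_type)
  if (per_patient) split_keys$patient_id <- cells$patient_id
  keep <- cells$cell_type %in% cell_types
  grid <- unique(as.data.frame(split_keys, stringsAsFactors = FALSE)[keep, ])
  grid <- grid[order(grid$cn, grid$cell_type), , drop = FALSE]

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cells$cn_label == grid$cn[i] & cells$cell_type == grid$cell_type[i]
    if (per_patient) sel <- sel & cells$patient_id == grid$patient_id[i]
    n <- sum(sel)
    p_any <- if (n > 0) mean(any_pos[sel]) else NA_real_
    npos <- sum(any_pos[sel])
    p_each <- if (npos > 0) colMeans(pos[sel & any_pos, , drop = FALSE])
              else rep(NA_real_, length(markers))
    out <- data.frame(grid[i, , drop = FALSE], n_cells = n,
                      prop_any_positive = p_any, stringsAsFactors = FALSE)
    out[paste0("prop_", markers)] <- as.list(p_each)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t-tests of per-patient features between groups
#'
#' Student's t-test per feature, two-sided, with no multiplicity adjustment
#' by default (matching the figure-legend convention); Benjamini-Hochberg
#' available.
#'
#' @param values Patients x features numeric matrix (patient_id rownames).
#' @param groups Group labels named by patient_id (or aligned to rows).
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @param adjust `"none"` (default) or any `stats::p.adjust` method.
#' @return Data frame `feature`, `mean_ref`, `mean_alt`, `t`, `p`, `p_adj`.
#' @export
compare_group_frequencies <- function(values, groups, var_equal = TRUE,
                                      adjust = "none") {
  if (!is.null(names(groups)) && !is.null(rownames(values)))
    groups <- groups[rownames(values)]
  gi <- group_indicator(groups)
  lev <- attr(gi, "levels")
  res <- lapply(colnames(values) %||% seq_len(ncol(values)), function(f) {
    v <- values[, f]
    ok <- !is.na(v)
    a <- v[ok & gi == 0]; b <- v[ok & gi == 1]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(feature = f, mean_ref = mean(a), mean_alt = mean(b),
                        t = NA_real_, p = NA_real_))
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      warning("feature ", f, " has zero variance in both groups")
      tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1)
            else list(statistic = NA_real_, p.value = NA_real_)
    } else {
      t0 <- stats::t.test(b, a, var.equal = var_equal)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    data.frame(feature = f, mean_ref = mean(a), mean_alt = mean(b),
               t = tt$statistic, p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  attr(out, "group_levels") <- lev
  out
}

#' PCA of per-patient cell-type abundances
#'
#' Column-centred, unscaled principal components; constant features are
#' excluded with a warning.
#'
#' @param abundances Patients x features numeric matrix.
#' @param scale. Scale features to unit variance (default `FALSE`).
#' @return List `scores`, `loadings`, `explained_variance` (proportions),
#'   `dropped` (excluded constant features).
#' @export
pca_abundances <- function(abundances, scale. = FALSE) {
  stopifnot(nrow(abundances) >= 2, ncol(abundances) >= 2)
  v <- apply(abundances, 2, stats::var)
  dropped <- colnames(abundances)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning("constant feature(s) excluded: ", paste(dropped, collapse = ", "))
    abundances <- abundances[, !(colnames(abundances) %in% dropped), drop = FALSE]
  }
  pc <- stats::prcomp(abundances, center = TRUE, scale. = scale.)
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}
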