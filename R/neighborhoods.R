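# Cellular neighborhood identification: per-cell k-NN window compositions,
# k-means clustering of windows, artifact-CN removal, per-patient CN
# frequencies.
#
# A "window" is a cell plus its (window_size - 1) nearest neighbours by
# Euclidean distance within the same region; TMA cores are physically
# disjoint tissues, so windows never cross region boundaries. Distance ties
# are broken by input cell order (cell_id order within the region), so window
# construction is reproducible on gridded fixtures.

# Exact k nearest (including self) with stable (distance, order) tie-break.
# Uses a kd-tree with candidate slack, verified to cover the tie set.
knn_window_indices <- function(xy, k, tie_slack = 10L) {
  n <- nrow(xy)
  k <- min(k, n)
  kq <- min(n, k + tie_slack)
  nn <- RANN::nn2(xy, xy, k = kq)
  idx <- matrix(0L, n, k)
  d2 <- nn$nn.dists
  for (i in seq_len(n)) {
    o <- order(d2[i, ], nn$nn.idx[i, ])
    idx[i, ] <- nn$nn.idx[i, o[seq_len(k)]]
  }
  idx
}

#' Build per-cell window composition vectors
#'
#' For each cell, the window consists of the cell itself plus its
#' `window_size - 1` nearest neighbours (Euclidean, within region); the row is
#' the fraction of window cells of each panel type.
#'
#' @param dataset A `cn_dataset`.
#' @param window_size Window size including the centre cell (default 10).
#' @param on_small_region `"warn"` (exclude regions with fewer cells than
#'   `window_size`, with a warning) or `"error"`.
#' @return A list of class `cn_windows`: `composition` (cells x panel matrix,
#'   rows sum to 1, rownames = cell_id), `neighbors` (cells x window_size
#'   matrix of neighbour cell_ids, first column the cell itself),
#'   `window_size`.
#' @export
build_windows <- function(dataset, window_size = 10L,
                          on_small_region = c("warn", "error")) {
  on_small_region <- match.arg(on_small_region)
  cells <- dataset$cells
  panel <- dataset$panel
  comp_list <- list(); nb_list <- list(); keep_ids <- list()
  for (rid in unique(cells$region_id)) {
    sel <- which(cells$region_id == rid)
    if (length(sel) < window_size) {
      msg <- sprintf("region %s has %d < %d cells; excluded from windows",
                     rid, length(sel), window_size)
      if (on_small_region == "error") stop(msg)
      warning(msg)
      next
    }
    xy <- cbind(cells$x[sel], cells$y[sel])
    idx <- knn_window_indices(xy, window_size)
    types <- cells$cell_type[sel]
    tf <- factor(types, levels = panel)
    # composition: tabulate window member types per row
    comp <- matrix(0, length(sel), length(panel),
                   dimnames = list(cells$cell_id[sel], panel))
    code <- as.integer(tf)
    for (j in seq_len(window_size)) {
      cj <- code[idx[, j]]
      comp[cbind(seq_along(sel), cj)] <- comp[cbind(seq_along(sel), cj)] + 1
    }
    comp <- comp / window_size
    comp_list[[rid]] <- comp
    nb <- matrix(cells$cell_id[sel][idx], nrow(idx), window_size)
    rownames(nb) <- cells$cell_id[sel]
    nb_list[[rid]] <- nb
  }
  if (!length(comp_list)) stop("no region has enough cells for windows")
  composition <- do.call(rbind, comp_list)
  neighbors <- do.call(rbind, nb_list)
  # restore original cell order
  ord <- match(cells$cell_id[cells$cell_id %in% rownames(composition)],
               rownames(composition))
  structure(list(composition = composition[ord, , drop = FALSE],
                 neighbors = neighbors[ord, , drop = FALSE],
                 window_size = as.integer(window_size)),
            class = "cn_windows")
}

#' Cluster window compositions into cellular neighborhoods
#'
#' Batch k-means (multi-start Hartigan-Wong) on the window composition
#' matrix; every windowed cell is assigned the CN of its window. If the
#' matrix has fewer distinct rows than `n_cns`, the number of clusters is
#' reduced to the number of distinct rows with a warning (degenerate inputs
#' collapse to fewer CNs rather than erroring).
#'
#' @param windows A `cn_windows` from [build_windows()].
#' @param n_cns Number of CNs (k).
#' @param seed Integer seed; assignments are deterministic given it.
#' @param nstart,iter_max k-means controls (pinned for reproducibility).
#' @return A list of class `cn_model`: `n_cns`, `centroids` (k x panel),
#'   `assignments` (integer CN ids named by cell_id), `inertia`, `seed`.
#' @export
cluster_windows <- function(windows, n_cns = 10L, seed = 1L,
                            nstart = 5L, iter_max = 100L) {
  stopifnot(inherits(windows, "cn_windows"), n_cns >= 1)
  x <- windows$composition
  if (!nrow(x)) stop("empty window matrix")
  n_distinct <- nrow(unique(x))
  k <- n_cns
  if (n_distinct < k) {
    warning(sprintf("only %d distinct window rows; reducing n_cns from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  set.seed(stage_seed(seed, "cluster_windows"))
  if (k == 1L) {
    centroids <- matrix(colMeans(x), 1, ncol(x),
                        dimnames = list(NULL, colnames(x)))
    assignments <- stats::setNames(rep(1L, nrow(x)), rownames(x))
    inertia <- sum(scale(x, center = centroids[1, ], scale = FALSE)^2)
  } else {
    km <- tryCatch(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = iter_max),
      error = function(e) stop("window clustering failed (k = ", k, "): ",
                               conditionMessage(e)))
    centroids <- km$centers
    assignments <- stats::setNames(as.integer(km$cluster), rownames(x))
    inertia <- km$tot.withinss
  }
  structure(list(n_cns = k, centroids = centroids,
                 assignments = assignments, inertia = inertia,
                 seed = as.integer(seed)),
            class = "cn_model")
}

#' Assign CN labels to the dataset's cells
#'
#' @param dataset A `cn_dataset`.
#' @param model A `cn_model` from [cluster_windows()].
#' @return The dataset with `cn_label` filled for every windowed cell
#'   (`NA` for cells excluded from windowing).
#' @export
assign_neighborhoods <- function(dataset, model) {
  lab <- model$assignments[dataset$cells$cell_id]
  dataset$cells$cn_label <- as.integer(lab)
  dataset
}

#' Identify cellular neighborhoods end to end
#'
#' Convenience wrapper: windows, clustering and label assignment in one call.
#'
#' @inheritParams build_windows
#' @inheritParams cluster_windows
#' @return `list(dataset, model, windows)` with `cn_label` assigned.
#' @export
identify_neighborhoods <- function(dataset, window_size = 10L, n_cns = 10L,
                                   seed = 1L, nstart = 5L, iter_max = 100L) {
  windows <- build_windows(dataset, window_size)
  model <- cluster_windows(windows, n_cns, seed, nstart, iter_max)
  list(dataset = assign_neighborhoods(dataset, model),
       model = model, windows = windows)
}

#' Remove the artifact cellular neighborhood
#'
#' Drops the CN whose centroid has maximal weight on the declared artifact
#' cell type (or an explicitly configured CN id) and removes its cells from
#' the dataset, mirroring the removal of the imaging-artifact neighborhood
#' before downstream analysis.
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @param model The `cn_model` used for assignment.
#' @param artifact_cell_type Cell type marking imaging artifacts, or `NULL`.
#' @param artifact_cn Explicit CN id to remove (overrides the type rule).
#' @return `list(dataset, model, removed_cn, n_removed)`; a no-op with a
#'   warning when neither an artifact type in the panel nor a CN id is given.
#' @export
remove_artifact_cn <- function(dataset, model, artifact_cell_type = NULL,
                               artifact_cn = NULL) {
  if (is.null(artifact_cn)) {
    if (is.null(artifact_cell_type)) {
      warning("no artifact cell type or CN configured; nothing removed")
      return(list(dataset = dataset, model = model,
                  removed_cn = NA_integer_, n_removed = 0L))
    }
    if (!artifact_cell_type %in% colnames(model$centroids)) {
      warning("artifact type '", artifact_cell_type,
              "' not in panel; nothing removed")
      return(list(dataset = dataset, model = model,
                  removed_cn = NA_integer_, n_removed = 0L))
    }
    artifact_cn <- which.max(model$centroids[, artifact_cell_type])
  }
  if (!artifact_cn %in% seq_len(model$n_cns))
    stop("artifact_cn ", artifact_cn, " out of range 1..", model$n_cns)
  drop <- !is.na(dataset$cells$cn_label) & dataset$cells$cn_label == artifact_cn
  n_removed <- sum(drop)
  dataset$cells <- dataset$cells[!drop, , drop = FALSE]
  model$assignments <- model$assignments[dataset$cells$cell_id]
  cn_log(sprintf("removed artifact CN %d (%d cells)", artifact_cn, n_removed))
  list(dataset = dataset, model = model,
       removed_cn = as.integer(artifact_cn), n_removed = n_removed)
}

#' Per-patient CN frequencies (mean over cores)
#'
#' For each region, the fraction of its labelled cells in each CN; per
#' patient, the mean over that patient's regions.
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @return Matrix patients x CNs (rownames patient_id, colnames CN ids);
#'   rows sum to 1 when every region has all its cells labelled.
#' @export
cn_frequencies_by_patient <- function(dataset) {
  cells <- dataset$cells[!is.na(dataset$cells$cn_label), ]
  if (!nrow(cells)) stop("no labelled cells; run identify_neighborhoods first")
  cns <- sort(unique(cells$cn_label))
  tab <- table(cells$region_id, factor(cells$cn_label, levels = cns))
  frac <- tab / rowSums(tab)
  region_patient <- cells$patient_id[match(rownames(tab), cells$region_id)]
  patients <- unique(dataset$cells$patient_id)
  out <- matrix(NA_real_, length(patients), length(cns),
                dimnames = list(patients, paste0("CN", cns)))
  for (p in patients) {
    rows <- which(region_patient == p)
    if (!length(rows)) {
      warning("patient ", p, " has no labelled cells; excluded")
      next
    }
    out[p, ] <- colMeans(frac[rows, , drop = FALSE])
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}
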