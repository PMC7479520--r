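# Direct cell-cell contact statistics.
#
# Contacts are edges of the Delaunay triangulation of cell centroids within a
# region. For cell types i, j with Nij edges between them (homotypic edges
# counted once), Ni = sum_j Nij and Nt total edges:
#   likelihood ratio  lr_ij = Nij * Nt / (Ni * Nj)   (observed / expected)
#   relative frequency rf_ij = Nij / Ni              (row-normalised)
# Pairs with fewer than `min_unique` unique interacting cells are masked.

#' Delaunay contact graph of one region
#'
#' @param cells_in_region Data frame with `cell_id`, `x`, `y` for one region.
#' @return Data frame `from`, `to` (cell_ids) of undirected Delaunay edges;
#'   empty (with a warning) for fewer than 3 cells or degenerate geometry.
#' @export
delaunay_contacts <- function(cells_in_region) {
  n <- nrow(cells_in_region)
  empty <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  if (n < 3) {
    warning("fewer than 3 cells; empty contact graph")
    return(empty)
  }
  # exact collinearity has no triangulation (deldir would still return
  # tessellation neighbours); detect and return the empty graph
  if (qr(cbind(cells_in_region$x - mean(cells_in_region$x),
               cells_in_region$y - mean(cells_in_region$y)))$rank < 2) {
    warning("degenerate geometry (collinear cells?); empty contact graph")
    return(empty)
  }
  dd <- tryCatch(
    deldir::deldir(cells_in_region$x, cells_in_region$y),
    error = function(e) NULL)
  if (is.null(dd) || is.null(dd$delsgs) || !nrow(dd$delsgs)) {
    warning("degenerate geometry (collinear cells?); empty contact graph")
    return(empty)
  }
  e <- dd$delsgs[, c("ind1", "ind2")]
  data.frame(from = cells_in_region$cell_id[e$ind1],
             to = cells_in_region$cell_id[e$ind2],
             stringsAsFactors = FALSE)
}

#' Delaunay contact graph of a whole dataset
#'
#' @param dataset A `cn_dataset`.
#' @return Data frame `region_id`, `from`, `to` over all regions.
#' @export
contact_graph <- function(dataset) {
  cells <- dataset$cells
  out <- lapply(unique(cells$region_id), function(rid) {
    e <- delaunay_contacts(cells[cells$region_id == rid, ])
    if (!nrow(e)) return(NULL)
    cbind(region_id = rid, e)
  })
  do.call(rbind, out) %||%
    data.frame(region_id = character(0), from = character(0), to = character(0))
}

#' Contact statistics between cell types
#'
#' @param edges Edge data frame with `from`, `to` cell_ids.
#' @param type_labels Character vector of cell types named by cell_id,
#'   covering every edge endpoint.
#' @param panel Ordered cell-type panel (matrix dimension order).
#' @param min_unique Mask threshold on the number of unique interacting cells
#'   per pair (default 100).
#' @param convention `"once"` (Ni = sum_j Nij with homotypic edges counted
#'   once; the default, the literal reading of the printed margin formula) or
#'   `"degree"` (ordered-pair counting: the diagonal of Nij is doubled, Ni is
#'   the type's endpoint degree and Nt the number of ordered adjacent pairs).
#'   Only the degree convention makes the likelihood ratio calibrate to 1
#'   under random labelling; the "once" convention reproduces the printed
#'   worked formulas.
#' @return List of class `cn_contact_stats`: `nij`, `lr`, `rf`, `ni`, `nt`,
#'   `mask` (TRUE where the pair has `< min_unique` unique interacting cells).
#' @export
contact_stats <- function(edges, type_labels, panel,
                          min_unique = 100L,
                          convention = c("once", "degree")) {
  convention <- match.arg(convention)
  bad <- setdiff(unique(c(edges$from, edges$to)), names(type_labels))
  if (length(bad)) stop("unlabelled edge endpoint(s): ", bad[1], " ...")
  ti <- factor(type_labels[edges$from], levels = panel)
  tj <- factor(type_labels[edges$to], levels = panel)
  if (anyNA(ti) || anyNA(tj)) stop("edge endpoint with type outside the panel")

  t_ <- length(panel)
  nij <- matrix(0, t_, t_, dimnames = list(panel, panel))
  tab <- table(ti, tj)
  nij <- nij + unclass(tab)
  nij <- nij + t(unclass(tab))
  if (convention == "once") {
    diag(nij) <- diag(nij) / 2        # homotypic edges counted once
    nt <- sum(nij[upper.tri(nij, diag = TRUE)])
  } else {
    # ordered adjacent pairs: diagonal stays doubled, margins are degrees
    nt <- sum(nij)
  }
  ni <- rowSums(nij)

  denom <- outer(ni, ni)
  lr <- nij * nt / denom
  lr[denom == 0] <- NA_real_
  rf <- nij / ni                       # element (i, j) = Nij / Ni
  rf[ni == 0, ] <- NA_real_

  # unique interacting cells per unordered type pair
  mask <- matrix(TRUE, t_, t_, dimnames = list(panel, panel))
  key_i <- as.integer(ti); key_j <- as.integer(tj)
  for (a in seq_len(t_)) for (b in a:t_) {
    sel <- (key_i == a & key_j == b) | (key_i == b & key_j == a)
    ucells <- length(unique(c(edges$from[sel], edges$to[sel])))
    mask[a, b] <- mask[b, a] <- ucells < min_unique
  }
  structure(list(nij = nij, lr = lr, rf = rf, ni = ni, nt = nt, mask = mask,
                 convention = convention, min_unique = as.integer(min_unique)),
            class = "cn_contact_stats")
}

#' Log2 ratio of a contact metric between two groups
#'
#' @param stats_a,stats_b `cn_contact_stats` for the two groups (same panel).
#' @param metric `"lr"` or `"rf"`.
#' @return List `log2_ratio` (matrix, NA where a denominator is zero) and
#'   `mask` (union of the two masks).
#' @export
log2_group_ratio <- function(stats_a, stats_b, metric = c("lr", "rf")) {
  metric <- match.arg(metric)
  a <- stats_a[[metric]]; b <- stats_b[[metric]]
  if (!identical(dimnames(a), dimnames(b)))
    stop("contact statistics computed on different panels")
  ratio <- ifelse(!is.na(b) & b > 0 & !is.na(a) & a > 0, log2(a / b), NA_real_)
  list(log2_ratio = ratio, mask = stats_a$mask | stats_b$mask)
}

#' CN mixing score between two neighborhoods
#'
#' Per region: the fraction of CN-a cells with at least one CN-b cell among
#' their `window_size - 1` nearest neighbours, and vice versa; the two
#' directional fractions are averaged. Per patient: mean over regions (mean
#' of cores). A Delaunay-adjacency variant is available.
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @param cn_a,cn_b CN ids.
#' @param window_size Window size for the neighbour definition (default 10,
#'   as in CN identification).
#' @param method `"window"` (default) or `"delaunay"`.
#' @return Data frame `patient_id`, `score`, `frac_a_touch_b`,
#'   `frac_b_touch_a` (NA for patients with no cells in either CN).
#' @export
cn_mixing_score <- function(dataset, cn_a, cn_b, window_size = 10L,
                            method = c("window", "delaunay")) {
  method <- match.arg(method)
  cells <- dataset$cells
  if (all(is.na(cells$cn_label))) stop("cn_label not assigned")
  lab <- stats::setNames(cells$cn_label, cells$cell_id)

  region_scores <- lapply(unique(cells$region_id), function(rid) {
    rc <- cells[cells$region_id == rid, ]
    if (method == "window") {
      if (nrow(rc) < window_size) return(NULL)
      idx <- knn_window_indices(cbind(rc$x, rc$y), window_size)
      nb_lab <- matrix(rc$cn_label[idx[, -1, drop = FALSE]], nrow(idx))
      touches <- function(from, to) {
        sel <- which(!is.na(rc$cn_label) & rc$cn_label == from)
        if (!length(sel)) return(NA_real_)
        mean(apply(nb_lab[sel, , drop = FALSE], 1, function(v)
          any(!is.na(v) & v == to)))
      }
    } else {
      e <- delaunay_contacts(rc)
      if (!nrow(e)) return(NULL)
      adj <- rbind(e, data.frame(from = e$to, to = e$from))
      touches <- function(from, to) {
        ids <- rc$cell_id[!is.na(rc$cn_label) & rc$cn_label == from]
        if (!length(ids)) return(NA_real_)
        hit <- unique(adj$from[!is.na(lab[adj$to]) & lab[adj$to] == to])
        mean(ids %in% hit)
      }
    }
    data.frame(patient_id = rc$patient_id[1],
               a_to_b = touches(cn_a, cn_b), b_to_a = touches(cn_b, cn_a),
               stringsAsFactors = FALSE)
  })
  rs <- do.call(rbind, region_scores)
  patients <- unique(cells$patient_id)
  out <- data.frame(patient_id = patients,
                    score = NA_real_, frac_a_touch_b = NA_real_,
                    frac_b_touch_a = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(patients)) {
    sel <- rs$patient_id == patients[i]
    if (!any(sel)) next
    ab <- mean(rs$a_to_b[sel], na.rm = TRUE)
    ba <- mean(rs$b_to_a[sel], na.rm = TRUE)
    out$frac_a_touch_b[i] <- ab
    out$frac_b_touch_a[i] <- ba
    out$score[i] <- mean(c(ab, ba))
  }
  out
}
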