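# End-to-end pipeline: neighborhoods -> frequencies -> contacts -> tensor ->
# enrichment -> classification -> communication -> survival, deterministic
# given the configured seed. Each stage failure halts with the stage name.

run_stage <- function(name, expr, verbose = TRUE) {
  cn_log("stage: ", name, verbose = verbose)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full cellular-neighborhood coordination pipeline
#'
#' @param dataset A `cn_dataset`.
#' @param config A [cn_config()].
#' @param subsets Subset list for the frequency stage; default: all plain
#'   panel types plus single-marker refinements of `functional_types`.
#' @param functional_types Cell types given marker-positive refinements
#'   (default: the T-cell types present in the panel).
#' @param verbose Log stage progress.
#' @return A list of class `cn_results` with elements `model`, `dataset`
#'   (labelled, artifact CN removed), `cn_frequencies`, `frequencies`,
#'   `contacts`, `tensor`, `enrichment`, `classification`, `importance`,
#'   `communication`, `survival`, `config`. Stages that need two patient
#'   groups are `NULL` (with a warning) on single-group data.
#' @export
run_pipeline <- function(dataset, config = cn_config(), subsets = NULL,
                         functional_types = NULL, verbose = TRUE) {
  stopifnot(inherits(dataset, "cn_dataset"), inherits(config, "cn_config"))
  seed <- config$rng_seed
  groups <- stats::setNames(dataset$clinical$group, dataset$clinical$patient_id)
  two_groups <- length(unique(groups)) == 2

  nb <- run_stage("neighborhoods", {
    r <- identify_neighborhoods(dataset, config$window_size, config$n_cns,
                                seed = seed, nstart = config$kmeans_nstart,
                                iter_max = config$kmeans_iter_max)
    if (!is.null(config$artifact_cell_type) || !is.null(config$artifact_cn)) {
      rem <- remove_artifact_cn(r$dataset, r$model,
                                config$artifact_cell_type, config$artifact_cn)
      r$dataset <- rem$dataset; r$model <- rem$model
      r$removed_cn <- rem$removed_cn
    }
    r
  }, verbose)
  ds <- nb$dataset

  freqs <- run_stage("frequencies", {
    if (is.null(subsets)) {
      functional_types <- functional_types %||%
        intersect(c("CD4+ T cells", "CD8+ T cells", "Tregs"), ds$panel)
      subsets <- default_subsets(ds, marker_types = functional_types)
    }
    compute_frequencies(ds, subsets, excluded_cns = config$excluded_cns)
  }, verbose)
  cn_freq <- run_stage("cn_frequencies", cn_frequencies_by_patient(ds), verbose)

  contacts <- run_stage("contacts", {
    glev <- sort(unique(ds$cells$group))
    per_group <- lapply(glev, function(g) {
      sub <- ds$cells$group == g
      dsg <- ds; dsg$cells <- ds$cells[sub, , drop = FALSE]
      edges <- contact_graph(dsg)
      contact_stats(edges, stats::setNames(ds$cells$cell_type, ds$cells$cell_id),
                    ds$panel, min_unique = config$min_unique_contact_cells)
    })
    names(per_group) <- glev
    out <- list(stats = per_group)
    if (length(glev) == 2)
      out$log2_ratio <- log2_group_ratio(per_group[[1]], per_group[[2]])
    if (!is.null(config$mixing_cn_pair))
      out$mixing <- cn_mixing_score(ds, config$mixing_cn_pair[1],
                                    config$mixing_cn_pair[2],
                                    window_size = config$window_size)
    out
  }, verbose)

  tensor <- run_stage("tensor", {
    glev <- sort(unique(ds$cells$group))
    lapply(stats::setNames(glev, glev), function(g) {
      pats <- ds$clinical$patient_id[ds$clinical$group == g]
      tns <- build_tensor(ds, excluded_cns = config$excluded_cns,
                          patients = pats)
      ranks <- pmin(config$tucker_ranks, dim(tns$values))
      if (any(ranks < config$tucker_ranks))
        cn_log("tucker ranks clamped to tensor dimensions for group ", g,
               verbose = verbose)
      fit <- tucker_decompose(tns, ranks, n_starts = config$tucker_n_starts,
                              seed = stage_seed(seed, paste0("tucker:", g)))
      list(tensor = tns, fit = fit, modules = tissue_modules(fit))
    })
  }, verbose)

  enrichment <- classification <- importance <- NULL
  if (two_groups) {
    enrichment <- run_stage("enrichment",
      differential_enrichment(freqs, groups, pseudocount = config$pseudocount,
                              group_levels = config$group_levels), verbose)
    n_per_group <- table(groups)
    if (all(n_per_group > config$rho_train_per_group)) {
      classification <- run_stage("classification", {
        feats <- frequency_matrix(freqs, "cn_specific")
        classify_groups(feats, groups,
                        train_per_group = config$rho_train_per_group,
                        reps = config$rho_reps,
                        seed = seed, pseudocount = config$pseudocount,
                        group_levels = config$group_levels)
      }, verbose)
      importance <- feature_importance(classification)
    } else {
      warning("too few patients per group for classification; stage skipped")
    }
  } else {
    warning("single patient group: enrichment and classification skipped")
  }

  communication <- run_stage("communication", {
    marker_subs <- freqs$subset_info$name[freqs$subset_info$n_markers > 0]
    block_subs <- if (length(marker_subs) >= 2) marker_subs else freqs$subsets
    communication_graph(freqs, groups, subsets = block_subs,
                        n_perm = config$n_permutations,
                        edge_quantile = config$communication_edge_quantile,
                        pseudocount = config$pseudocount,
                        seed = stage_seed(seed, "communication"))
  }, verbose)

  surv <- run_stage("survival", {
    cn_spec <- frequency_matrix(freqs, "cn_specific")
    covars <- if (!is.null(importance)) {
      sel <- importance$feature[importance$selected]
      if (!length(sel)) sel <- importance$feature[1]
      sel
    } else colnames(cn_spec)[1]
    glev <- unique(ds$clinical$group)
    rows <- list(); splits <- list()
    for (g in glev) {
      cl <- ds$clinical[ds$clinical$group == g, ]
      for (cv in covars) {
        f <- stats::setNames(cn_spec[, cv], rownames(cn_spec))
        fit <- tryCatch(cox_cn_frequency(cl, f, config$pseudocount,
                                         covariate_name = cv),
                        error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, covariate = cv, coef = fit$coef, se = fit$se,
          hr = fit$hr, lrt_p = fit$lrt_p, ph_p = ph_diagnostic(fit),
          n = fit$n, n_events = fit$n_events, stringsAsFactors = FALSE)
        ks <- tryCatch(km_optimal_split(cl, log_pc(f[cl$patient_id],
                                                   config$pseudocount)),
                       error = function(e) NULL)
        if (!is.null(ks))
          splits[[paste(g, cv)]] <- data.frame(
            group = g, covariate = cv, split = ks$split,
            logrank_p = ks$logrank_p, stringsAsFactors = FALSE)
      }
    }
    list(cox = do.call(rbind, rows), splits = do.call(rbind, splits))
  }, verbose)

  structure(list(model = nb$model, dataset = ds, windows = NULL,
                 cn_frequencies = cn_freq, frequencies = freqs,
                 contacts = contacts, tensor = tensor,
                 enrichment = enrichment, classification = classification,
                 importance = importance, communication = communication,
                 survival = surv, config = config),
            class = "cn_results")
}

#' Write a pipeline results bundle to a directory
#'
#' Writes deterministic delimited-text and JSON files: labelled cells, CN
#' model centroids, frequency tables, contact matrices, tensor factors,
#' enrichment/classification/communication/survival tables.
#'
#' @param results A `cn_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly the vector of written paths.
#' @export
write_pipeline_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(obj, file, format = NULL) {
    p <- file.path(dir, file)
    write_results(obj, p, format)
    paths <<- c(paths, p)
  }
  w(results$dataset$cells, "cells_with_cn.csv")
  w(list(n_cns = results$model$n_cns,
         centroids = results$model$centroids,
         inertia = results$model$inertia, seed = results$model$seed),
    "model.json", "json")
  w(results$cn_frequencies, "cn_frequencies.csv")
  w(results$frequencies$cn_specific, "cn_specific.csv")
  w(results$frequencies$overall, "overall.csv")
  for (g in names(results$contacts$stats)) {
    st <- results$contacts$stats[[g]]
    w(st$nij, paste0("nij_", g, ".csv"))
    w(st$lr, paste0("lr_", g, ".csv"))
    w(st$rf, paste0("rf_", g, ".csv"))
  }
  if (!is.null(results$contacts$log2_ratio))
    w(results$contacts$log2_ratio$log2_ratio, "log2ratio_lr.csv")
  if (!is.null(results$contacts$mixing))
    w(results$contacts$mixing, "mixing.csv")
  for (g in names(results$tensor)) {
    fit <- results$tensor[[g]]$fit
    w(list(ranks = fit$ranks, core = fit$core,
           patient_factors = fit$patient_factors,
           ct_factors = fit$ct_factors, cn_factors = fit$cn_factors,
           loss = fit$loss, rel_loss = fit$rel_loss),
      paste0("tucker_", g, ".json"), "json")
  }
  if (!is.null(results$enrichment))
    w(as.data.frame(results$enrichment), "enrichment.csv")
  if (!is.null(results$classification)) {
    w(data.frame(rep = seq_along(results$classification$aucs),
                 auc = results$classification$aucs), "auc.csv")
    w(results$classification$roc, "roc.csv")
    w(results$importance, "importance.csv")
  }
  w(as.data.frame(results$communication), "communication.csv")
  if (!is.null(results$survival$cox)) w(results$survival$cox, "cox.csv")
  if (!is.null(results$survival$splits)) w(results$survival$splits, "km_splits.csv")
  invisible(paths)
}
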