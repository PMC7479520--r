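# Group classification by L1-penalised logistic regression with repeated
# hold-out (RHO), feature importance, and the CN functional state alteration
# score.
#
# Protocol: features x -> log(1e-3 + x), z-normalised across the whole
# dataset; each RHO repetition samples `train_per_group` patients per group,
# chooses the L1 strength by cross-validation on the training sample only,
# fits on the training sample, and scores the held-out patients; the AUC
# distribution over repetitions estimates prediction performance.

#' Transform frequency features for classification
#'
#' `log(pseudocount + x)` followed by z-normalisation across the dataset
#' (the stated protocol; note this uses all patients' scale, including later
#' test patients). Missing frequencies are treated as zero before the log.
#'
#' @param x Patients x features numeric matrix.
#' @param pseudocount Added before logs.
#' @param leak_free If `TRUE`, skip the global z-normalisation (the caller
#'   must standardise within training folds instead).
#' @return Transformed matrix.
#' @export
transform_features <- function(x, pseudocount = 1e-3, leak_free = FALSE) {
  x <- log_pc(x, pseudocount)
  if (leak_free) return(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  scale(x, center = TRUE, scale = sds)
}

# glmnet needs >= 2 columns; a zero column is inert (coefficient always 0).
pad_glmnet <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

# stratified fold ids for cv.glmnet
stratified_folds <- function(y, nfolds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    sel <- which(y == cl)
    id[sel] <- sample(rep_len(seq_len(nfolds), length(sel)))
  }
  id
}

rho_auc <- function(x, y, train_per_group, reps, nfolds = 5L,
                    keep_coefs = TRUE, roc_grid = NULL) {
  n <- nrow(x)
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  if (length(idx0) <= train_per_group || length(idx1) <= train_per_group)
    stop("need more than ", train_per_group, " patients per group")
  xp <- pad_glmnet(x)
  aucs <- numeric(reps)
  coefs <- if (keep_coefs) matrix(0, reps, ncol(x),
                                  dimnames = list(NULL, colnames(x))) else NULL
  tpr_sum <- if (!is.null(roc_grid)) numeric(length(roc_grid)) else NULL
  for (r in seq_len(reps)) {
    tr <- c(sample(idx0, train_per_group), sample(idx1, train_per_group))
    te <- setdiff(seq_len(n), tr)
    foldid <- stratified_folds(y[tr], nfolds)
    # small CV folds are intrinsic to the 10-per-group protocol; glmnet's
    # small-sample warning would fire on every repetition
    cv <- suppressWarnings(
      glmnet::cv.glmnet(xp[tr, , drop = FALSE], y[tr],
                        family = "binomial", alpha = 1,
                        foldid = foldid, nlambda = 50,
                        standardize = FALSE))
    pred <- stats::predict(cv, xp[te, , drop = FALSE], s = "lambda.min",
                           type = "response")[, 1]
    aucs[r] <- auc_rank(pred, y[te])
    if (keep_coefs) {
      cf <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
      coefs[r, ] <- cf[seq_len(ncol(x))]
    }
    if (!is.null(roc_grid)) {
      ord <- order(pred, decreasing = TRUE)
      yy <- y[te][ord]
      fpr <- cumsum(yy == 0) / max(sum(yy == 0), 1)
      tpr <- cumsum(yy == 1) / max(sum(yy == 1), 1)
      tpr_sum <- tpr_sum + stats::approx(c(0, fpr, 1), c(0, tpr, 1),
                                         xout = roc_grid, ties = "ordered",
                                         rule = 2)$y
    }
  }
  list(aucs = aucs, coefs = coefs,
       mean_tpr = if (!is.null(roc_grid)) tpr_sum / reps else NULL)
}

#' Classify patient groups by repeated hold-out L1 logistic regression
#'
#' @param features Patients x features frequency matrix (raw frequencies;
#'   transformed internally via [transform_features()]).
#' @param groups Group labels named by patient_id (or aligned to rows).
#' @param train_per_group Training patients sampled per group (default 10).
#' @param reps RHO repetitions (default 1000).
#' @param seed Integer seed (deterministic given it).
#' @param pseudocount,nfolds,leak_free Protocol controls.
#' @param group_levels Optional explicit group-level order.
#' @return List of class `cn_classifier_report`: `aucs` (per repetition),
#'   `mean_auc`, `roc` (data frame fpr/mean tpr), `coefs`
#'   (reps x features), `train_per_group`, `reps`, `group_levels`.
#' @export
classify_groups <- function(features, groups, train_per_group = 10L,
                            reps = 1000L, seed = 1L, pseudocount = 1e-3,
                            nfolds = 5L, leak_free = FALSE,
                            group_levels = NULL) {
  if (!is.null(names(groups)) && !is.null(rownames(features)))
    groups <- groups[rownames(features)]
  y <- group_indicator(groups, group_levels)
  x <- transform_features(features, pseudocount, leak_free)
  set.seed(stage_seed(seed, "classify"))
  grid <- seq(0, 1, by = 0.02)
  res <- rho_auc(x, y, train_per_group, reps, nfolds,
                 keep_coefs = TRUE, roc_grid = grid)
  structure(list(aucs = res$aucs, mean_auc = mean(res$aucs),
                 roc = data.frame(fpr = grid, tpr = res$mean_tpr),
                 coefs = res$coefs,
                 train_per_group = as.integer(train_per_group),
                 reps = as.integer(reps),
                 group_levels = attr(y, "levels")),
            class = "cn_classifier_report")
}

#' Feature importance from a classifier report
#'
#' Importance of a feature is the z-score of the absolute value of its
#' coefficient across RHO repetitions (mean / SD of |coefficient|); features
#' never selected score 0.
#'
#' @param report A `cn_classifier_report` with coefficients retained.
#' @param cutoff Features at/above this importance are flagged for downstream
#'   survival testing (default 0.3).
#' @return Data frame `feature`, `importance`, `mean_abs_coef`, `selected`
#'   (flag), sorted by decreasing importance.
#' @export
feature_importance <- function(report, cutoff = 0.3) {
  cf <- abs(report$coefs)
  if (is.null(cf)) stop("report has no retained coefficients")
  m <- colMeans(cf)
  s <- apply(cf, 2, stats::sd)
  imp <- ifelse(m == 0, 0, ifelse(s == 0, Inf, m / s))
  out <- data.frame(feature = colnames(cf), importance = imp,
                    mean_abs_coef = m, selected = imp >= cutoff,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' CN functional state alteration score for one subset
#'
#' Compares, over RHO samples, the AUC of a model using only the subset's
#' overall frequency with a model that adds its CN-specific frequencies in
#' all non-excluded CNs. The score is -log10 of the one-sided (Welch) t-test
#' p value that the CN-specific model has greater mean AUC. The whole
#' procedure is repeated `outer_reps` times to estimate its variability.
#'
#' @param freqs A `cn_frequencies` containing the subset.
#' @param subset_name Name of the subset (as in `freqs$subsets`).
#' @param groups Group labels named by patient_id.
#' @param rho_reps RHO samples per model per repeat (default 200).
#' @param outer_reps Outer repeats (default 10).
#' @param train_per_group,seed,pseudocount,nfolds Protocol controls.
#' @return List of class `cn_alteration`: `scores` (length `outer_reps`),
#'   `median_score`, `subset`.
#' @export
alteration_score <- function(freqs, subset_name, groups,
                             rho_reps = 200L, outer_reps = 10L,
                             train_per_group = 10L, seed = 1L,
                             pseudocount = 1e-3, nfolds = 5L) {
  stopifnot(inherits(freqs, "cn_frequencies"))
  if (!subset_name %in% freqs$subsets)
    stop("subset not in frequency tables: ", subset_name)
  overall <- frequency_matrix(freqs, "overall", subsets = subset_name)
  cn_spec <- frequency_matrix(freqs, "cn_specific", subsets = subset_name)
  if (!ncol(cn_spec))
    stop("subset ", subset_name, " absent from every CN")
  y <- group_indicator(groups[rownames(overall)])
  x1 <- transform_features(overall, pseudocount)
  x2 <- transform_features(cbind(overall, cn_spec), pseudocount)
  scores <- numeric(outer_reps)
  for (o in seq_len(outer_reps)) {
    set.seed(stage_seed(seed, paste0("alteration:", subset_name, ":", o)))
    a1 <- rho_auc(x1, y, train_per_group, rho_reps, nfolds,
                  keep_coefs = FALSE)$aucs
    a2 <- rho_auc(x2, y, train_per_group, rho_reps, nfolds,
                  keep_coefs = FALSE)$aucs
    p <- stats::t.test(a2, a1, alternative = "greater")$p.value
    scores[o] <- -log10(p)
  }
  structure(list(scores = scores, median_score = stats::median(scores),
                 subset = subset_name),
            class = "cn_alteration")
}
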