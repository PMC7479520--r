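# Inter-CN communication network by canonical correlation analysis with a
# permutation null.
#
# For each pair of CNs, the blocks are the patients' log CN-specific
# frequencies of a small set of functional subsets in each CN. The first
# canonical correlation measures coordinated variation; its significance is
# calibrated by permuting patient identity of one block. An edge joins CN
# pairs whose observed correlation exceeds the configured quantile of the
# permutation distribution.

#' First canonical correlation between two frequency blocks
#'
#' @param block_a,block_b Patients x features numeric matrices (same rows).
#' @return The first canonical correlation, or `NA` with a warning when there
#'   are too few complete patients (fewer than `max(ncol) + 2`).
#' @export
cca_pair <- function(block_a, block_b) {
  ok <- stats::complete.cases(block_a) & stats::complete.cases(block_b)
  a <- block_a[ok, , drop = FALSE]; b <- block_b[ok, , drop = FALSE]
  if (nrow(a) < max(ncol(a), ncol(b)) + 2) {
    warning("too few patients for CCA (", nrow(a), ")")
    return(NA_real_)
  }
  cc <- tryCatch(stats::cancor(a, b), error = function(e) NULL)
  if (is.null(cc) || !length(cc$cor)) return(NA_real_)
  cc$cor[1]
}

#' Permutation test of a canonical correlation
#'
#' Patient identity of the second block is permuted `n_perm` times; the p
#' value is the fraction of permuted first canonical correlations at or above
#' the observed one.
#'
#' @param block_a,block_b Patients x features matrices.
#' @param n_perm Number of permutations (default 5000; a warning is issued
#'   below 100).
#' @param seed Integer seed.
#' @return List `observed`, `p`, `n` (patients used), `perm` (the permuted
#'   correlations).
#' @export
permutation_test_cca <- function(block_a, block_b, n_perm = 5000L, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable p values")
  ok <- stats::complete.cases(block_a) & stats::complete.cases(block_b)
  a <- block_a[ok, , drop = FALSE]; b <- block_b[ok, , drop = FALSE]
  obs <- cca_pair(a, b)
  if (is.na(obs)) return(list(observed = NA_real_, p = NA_real_,
                              n = nrow(a), perm = numeric(0)))
  set.seed(stage_seed(seed, "cca_perm"))
  perm <- vapply(seq_len(n_perm), function(i) {
    cc <- tryCatch(stats::cancor(a, b[sample.int(nrow(b)), , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cc) || !length(cc$cor)) NA_real_ else cc$cor[1]
  }, numeric(1))
  perm <- perm[!is.na(perm)]
  list(observed = obs, p = mean(perm >= obs), n = nrow(a), perm = perm)
}

#' Build the inter-CN communication graph
#'
#' For each group and each pair of CNs, the blocks are the log
#' (pseudocounted) CN-specific frequencies of the given subsets; patients
#' with no cells in either CN are excluded pairwise. An edge is drawn when
#' the observed first canonical correlation exceeds the `edge_quantile`
#' quantile of its permutation distribution (equivalently p < 1 - quantile);
#' edges with p < 0.02 are tiered "strong", others "weak".
#'
#' @param freqs A `cn_frequencies` containing the subsets.
#' @param groups Group labels named by patient_id.
#' @param subsets Character vector of subset names forming each block
#'   (default: the four functional subsets used in the study protocol are the
#'   caller's responsibility; all subsets in `freqs` if `NULL`).
#' @param n_perm Permutations per pair (default 5000).
#' @param edge_quantile Edge rule quantile (default 0.90).
#' @param pseudocount Added before logs.
#' @param seed Integer seed.
#' @return Data frame of class `cn_communication`: `group`, `cn_a`, `cn_b`,
#'   `cancor`, `p`, `n`, `edge`, `tier`.
#' @export
communication_graph <- function(freqs, groups, subsets = NULL,
                                n_perm = 5000L, edge_quantile = 0.90,
                                pseudocount = 1e-3, seed = 1L) {
  stopifnot(inherits(freqs, "cn_frequencies"))
  subsets <- subsets %||% freqs$subsets
  glab <- groups[freqs$patients]
  rows <- list()
  for (g in sort(unique(glab))) {
    pats <- freqs$patients[glab == g]
    blocks <- lapply(freqs$cns, function(n) {
      m <- frequency_matrix(freqs, "cn_specific", subsets = subsets, cns = n)
      m[pats, , drop = FALSE]
    })
    names(blocks) <- as.character(freqs$cns)
    cn_ids <- freqs$cns
    for (i in seq_along(cn_ids)) for (j in seq_along(cn_ids)) {
      if (j <= i) next
      a_raw <- blocks[[i]]; b_raw <- blocks[[j]]
      # exclude patients lacking cells in either CN (all-NA block rows)
      ok <- stats::complete.cases(a_raw) & stats::complete.cases(b_raw)
      a <- log(pseudocount + a_raw[ok, , drop = FALSE])
      b <- log(pseudocount + b_raw[ok, , drop = FALSE])
      pt <- permutation_test_cca(a, b, n_perm = n_perm,
                                 seed = stage_seed(seed, paste0("pair:", g, ":",
                                                                i, ":", j)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cn_a = cn_ids[i], cn_b = cn_ids[j],
        cancor = pt$observed, p = pt$p, n = pt$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  alpha <- 1 - edge_quantile
  out$edge <- !is.na(out$p) & out$p < alpha
  out$tier <- ifelse(!out$edge, NA_character_,
                     ifelse(out$p < 0.02, "strong", "weak"))
  class(out) <- c("cn_communication", class(out))
  out
}

#' Pearson and Spearman correlation of two per-patient features
#'
#' @param x,y Numeric vectors (paired by patient).
#' @return Data frame `pearson`, `pearson_p`, `spearman`, `spearman_p`, `n`;
#'   `NA` with a warning for constant input.
#' @export
pairwise_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(data.frame(pearson = NA_real_, pearson_p = NA_real_,
                      spearman = NA_real_, spearman_p = NA_real_,
                      n = length(x)))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(pearson = unname(pe$estimate), pearson_p = pe$p.value,
             spearman = unname(sp$estimate), spearman_p = sp$p.value,
             n = length(x))
}
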