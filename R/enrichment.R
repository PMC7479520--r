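# CN-specific differential enrichment between patient groups.
#
# For CN n and subset c, the model is
#   Y_{n,c} = b0 + b1 * X + b3 * Y_c + e
# where Y_{n,c} is the log (pseudocounted) CN-specific frequency, Y_c the log
# overall frequency, and X the 0/1 group indicator. b1 measures enrichment of
# the subset in CN n in the second group level beyond what its overall
# abundance predicts. p values are unadjusted by default, as is conventional
# for this exploratory screen; BH adjustment is available.

#' Differential enrichment of subsets within CNs between groups
#'
#' @param freqs A `cn_frequencies` from [compute_frequencies()].
#' @param groups Group labels named by patient_id.
#' @param pseudocount Added before logs (default 1e-3).
#' @param missing `"pseudocount"` (patients without cells in the CN enter with
#'   frequency 0, i.e. Y = log(pseudocount); default) or `"drop"`.
#' @param min_per_group Minimum usable patients per group for a row (default 3).
#' @param adjust `"none"` (default) or a `stats::p.adjust` method.
#' @param group_levels Optional explicit group-level order (first = reference).
#' @return Data frame of class `cn_enrichment`: `cn`, `subset`, `beta0`,
#'   `beta1`, `beta3`, `p`, `p_adj`, `n`. Positive `beta1` = enriched in the
#'   second group level.
#' @export
differential_enrichment <- function(freqs, groups, pseudocount = 1e-3,
                                    missing = c("pseudocount", "drop"),
                                    min_per_group = 3L, adjust = "none",
                                    group_levels = NULL) {
  missing <- match.arg(missing)
  stopifnot(inherits(freqs, "cn_frequencies"))
  gi <- group_indicator(groups[freqs$patients], group_levels)
  lev <- attr(gi, "levels")
  overall <- frequency_matrix(freqs, "overall")

  rows <- list()
  for (s in freqs$subsets) {
    yc <- log_pc(overall[, s], pseudocount)
    for (n in freqs$cns) {
      df <- freqs$cn_specific
      v <- df$freq[df$subset == s & df$cn == n]
      names(v) <- df$patient_id[df$subset == s & df$cn == n]
      v <- v[freqs$patients]
      if (missing == "drop") {
        use <- !is.na(v)
      } else {
        use <- rep(TRUE, length(v))
      }
      y <- log_pc(v, pseudocount)
      x <- gi
      if (sum(use & x == 0) < min_per_group || sum(use & x == 1) < min_per_group)
        next
      dat <- data.frame(y = y[use], x = x[use], yc = yc[use])
      fit <- tryCatch(stats::lm(y ~ x + yc, data = dat), error = function(e) NULL)
      if (is.null(fit)) next
      cf <- summary(fit)$coefficients
      b1 <- if ("x" %in% rownames(cf)) cf["x", "Estimate"] else NA_real_
      p1 <- if ("x" %in% rownames(cf) && nrow(cf) >= 2) cf["x", "Pr(>|t|)"] else NA_real_
      b3 <- if ("yc" %in% rownames(cf)) cf["yc", "Estimate"] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cn = n, subset = s,
        beta0 = cf["(Intercept)", "Estimate"],
        beta1 = b1, beta3 = b3, p = p1, n = nrow(dat),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(cn = integer(0), subset = character(0), beta0 = numeric(0),
               beta1 = numeric(0), beta3 = numeric(0), p = numeric(0),
               n = integer(0))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  attr(out, "group_levels") <- lev
  class(out) <- c("cn_enrichment", class(out))
  out
}

#' Coefficient matrix with significance flags
#'
#' @param result A `cn_enrichment`.
#' @param alpha Significance level for flags (default 0.05, unadjusted p).
#' @param use_adjusted Flag on adjusted p values instead.
#' @return List `beta1` (CN x subset matrix) and `significant` (logical
#'   matrix; `TRUE` where p < alpha).
#' @export
enrichment_heatmap_table <- function(result, alpha = 0.05,
                                     use_adjusted = FALSE) {
  stopifnot(nrow(result) > 0)
  cns <- sort(unique(result$cn))
  subs <- unique(result$subset)
  b <- matrix(NA_real_, length(cns), length(subs),
              dimnames = list(paste0("CN", cns), subs))
  sig <- matrix(FALSE, length(cns), length(subs),
                dimnames = dimnames(b))
  p <- if (use_adjusted) result$p_adj else result$p
  idx <- cbind(match(result$cn, cns), match(result$subset, subs))
  b[idx] <- result$beta1
  sig[idx] <- !is.na(p) & p < alpha
  list(beta1 = b, significant = sig)
}
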