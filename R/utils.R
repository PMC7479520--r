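# Internal helpers: seeding, logging, small numerics.

#' Derive a deterministic stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its randomness from a named
#' substream derived from one master seed, so that inserting or reordering
#' stages does not silently reshuffle the randomness of the others.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. `"cluster"`, `"tucker:3"`).
#' @return An integer in `[1, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  s <- (abs(seed) %% m) * 48271 %% m
  out <- (s + h * 69621) %% m
  as.integer(out + 1L)
}

cn_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[cncoord] ", ...)
}

# Rank-based AUC (Mann-Whitney); labels logical/0-1, scores numeric.
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# log(pseudocount + x) with NA treated as zero frequency
log_pc <- function(x, pseudocount) {
  x[is.na(x)] <- 0
  log(pseudocount + x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
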