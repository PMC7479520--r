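# Joint patient x cell-type x CN composition tensor and its non-negative
# Tucker decomposition.
#
# The decomposition X ~ G x1 A x2 B x3 C (all factors and core non-negative)
# is fitted by multiplicative updates on the Frobenius loss (the Lee-Seung
# NMF updates generalised to the Tucker model), with multiple random starts
# and, in the elbow scan, warm starts nested from lower-rank solutions so
# that losses are non-increasing along any coordinate-wise rank increase.

unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}

# reconstruct from factors: G x1 A x2 B x3 C
tucker_reconstruct <- function(core, a, b, c_) {
  r <- dim(core)
  g1 <- matrix(core, r[1], r[2] * r[3])
  x1 <- a %*% g1 %*% t(kronecker(c_, b))
  array(x1, c(nrow(a), nrow(b), nrow(c_)))
}

# Multiplicative updates on the Frobenius loss; the iteration loop is
# compiled (src/ntd.cpp) and works with small mode products throughout.
ntd_fit_one <- function(x, ranks, init, max_iter = 2000, tol = 1e-9) {
  fit <- .ntd_mu(x, init$a, init$b, init$c, array(init$g, ranks),
                 as.integer(max_iter), tol)
  g <- array(fit$g, ranks)
  loss <- sqrt(sum((x - tucker_reconstruct(g, fit$a, fit$b, fit$c))^2))
  list(core = g, a = fit$a, b = fit$b, c = fit$c, loss = loss,
       rel_loss = loss / max(sqrt(sum(x^2)), 1e-12))
}

# HOSVD-style initialisation: magnitudes of the leading singular vectors of
# each mode unfolding, floored at a small positive value, with the core from
# the (non-negative) projection. Converges much faster than random starts.
hosvd_ntd_init <- function(x, ranks) {
  d <- dim(x)
  fac <- lapply(1:3, function(m) {
    u <- svd(unfold(x, m), nu = ranks[m])$u[, seq_len(ranks[m]), drop = FALSE]
    pmax(abs(u), 1e-3)
  })
  a <- fac[[1]]; b <- fac[[2]]; c_ <- fac[[3]]
  g1 <- crossprod(a, unfold(x, 1)) %*% kronecker(c_, b)
  g <- array(pmax(as.vector(g1), 1e-6), ranks)
  # scale core so the initial reconstruction has the right magnitude
  rec <- tucker_reconstruct(g, a, b, c_)
  s <- sum(x * rec) / max(sum(rec^2), 1e-12)
  list(a = a, b = b, c = c_, g = g * max(s, 1e-6))
}

random_ntd_init <- function(d, ranks, scale_to) {
  a <- matrix(stats::runif(d[1] * ranks[1], 0.1, 1), d[1], ranks[1])
  b <- matrix(stats::runif(d[2] * ranks[2], 0.1, 1), d[2], ranks[2])
  c_ <- matrix(stats::runif(d[3] * ranks[3], 0.1, 1), d[3], ranks[3])
  g <- array(stats::runif(prod(ranks), 0.1, 1), ranks)
  rec <- tucker_reconstruct(g, a, b, c_)
  s <- scale_to / max(mean(rec), 1e-12)
  g <- g * s
  list(a = a, b = b, c = c_, g = g)
}

#' Build the joint patient x cell type x CN composition tensor
#'
#' Default (joint) normalisation: entry (p, t, n) is the fraction of patient
#' p's non-excluded cells that are of type t and lie in CN n, so each patient
#' slice is a joint distribution over (type, CN) and its marginals are the
#' CN occupancy vector and the overall type frequencies. The within-CN
#' alternative normalises each (patient, CN) column to 1 instead.
#'
#' @param dataset A `cn_dataset` with `cn_label` assigned.
#' @param excluded_cns CN ids removed before normalisation (e.g. follicle CN).
#' @param normalization `"joint"` (default) or `"within_cn"`.
#' @param patients Optional patient subset (e.g. one group).
#' @return List of class `cn_tensor`: `values` (3-d array with dimnames),
#'   `normalization`.
#' @export
build_tensor <- function(dataset, excluded_cns = integer(0),
                         normalization = c("joint", "within_cn"),
                         patients = NULL) {
  normalization <- match.arg(normalization)
  cells <- dataset$cells[!is.na(dataset$cells$cn_label), ]
  if (!nrow(cells)) stop("cn_label not assigned")
  cells <- cells[!(cells$cn_label %in% excluded_cns), ]
  if (!is.null(patients)) cells <- cells[cells$patient_id %in% patients, ]
  if (!nrow(cells)) stop("empty tensor: no cells left after exclusions")
  pats <- sort(unique(cells$patient_id))
  cns <- sort(unique(cells$cn_label))
  cnt <- table(factor(cells$patient_id, levels = pats),
               factor(cells$cell_type, levels = dataset$panel),
               factor(cells$cn_label, levels = cns))
  x <- array(as.numeric(cnt), dim(cnt),
             dimnames = list(pats, dataset$panel, paste0("CN", cns)))
  if (normalization == "joint") {
    tot <- apply(x, 1, sum)
    drop <- tot == 0
    if (any(drop)) {
      warning("patient(s) with zero non-excluded cells dropped: ",
              paste(pats[drop], collapse = ", "))
      x <- x[!drop, , , drop = FALSE]; tot <- tot[!drop]
    }
    x <- sweep(x, 1, tot, "/")
  } else {
    tot <- apply(x, c(1, 3), sum)
    for (n in seq_len(dim(x)[3]))
      x[, , n] <- x[, , n] / ifelse(tot[, n] > 0, tot[, n], NA_real_)
    x[is.na(x)] <- 0
  }
  structure(list(values = x, normalization = normalization,
                 excluded_cns = as.integer(excluded_cns)),
            class = "cn_tensor")
}

#' Non-negative Tucker decomposition
#'
#' Best-loss solution across `n_starts` random initialisations of the
#' multiplicative-update algorithm; deterministic given `seed`. Factor
#' columns are normalised to unit maximum with the scale absorbed into the
#' core, so factors are comparable across runs.
#'
#' @param tensor A `cn_tensor` or a 3-d array.
#' @param ranks Integer triple (patient, cell type, CN module ranks).
#' @param n_starts Random restarts.
#' @param seed Integer seed.
#' @param max_iter,tol Iteration controls.
#' @param extra_inits Optional list of initialisations to include alongside
#'   the random starts (used by [elbow_scan()] for warm-start nesting).
#' @return List of class `cn_tucker`: `core` (r1 x r2 x r3),
#'   `patient_factors`, `ct_factors`, `cn_factors`, `loss` (Frobenius),
#'   `rel_loss`, `n_starts`, `ranks`.
#' @export
tucker_decompose <- function(tensor, ranks = c(2L, 6L, 6L), n_starts = 5L,
                             seed = 1L, max_iter = 20000, tol = 1e-9,
                             extra_inits = NULL) {
  x <- if (inherits(tensor, "cn_tensor")) tensor$values else tensor
  stopifnot(length(dim(x)) == 3)
  if (any(x < 0)) stop("tensor must be non-negative")
  d <- dim(x)
  modes <- c("patient", "cell type", "CN")
  for (m in 1:3) if (ranks[m] > d[m])
    stop("rank ", ranks[m], " exceeds ", modes[m], " dimension ", d[m])
  best <- NULL
  inits <- extra_inits %||% list()
  inits[[length(inits) + 1L]] <- hosvd_ntd_init(x, ranks)
  for (s in seq_len(max(n_starts - 1L, 0L))) {
    set.seed(stage_seed(seed, paste0("tucker:", s)))
    inits[[length(inits) + 1L]] <- random_ntd_init(d, ranks, mean(x))
  }
  for (init in inits) {
    fit <- ntd_fit_one(x, ranks, init, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  # unit-max column normalisation, scale absorbed into the core
  norm_mode <- function(f, g, mode) {
    s <- apply(f, 2, max)
    s[s <= 0] <- 1
    f <- sweep(f, 2, s, "/")
    g <- sweep(g, mode, s, "*")
    list(f = f, g = g)
  }
  g <- best$core
  n1 <- norm_mode(best$a, g, 1); g <- n1$g
  n2 <- norm_mode(best$b, g, 2); g <- n2$g
  n3 <- norm_mode(best$c, g, 3); g <- n3$g
  dn <- dimnames(x)
  if (!is.null(dn)) {
    rownames(n1$f) <- dn[[1]]; rownames(n2$f) <- dn[[2]]; rownames(n3$f) <- dn[[3]]
  }
  structure(list(core = g, patient_factors = n1$f, ct_factors = n2$f,
                 cn_factors = n3$f, loss = best$loss,
                 rel_loss = best$rel_loss, n_starts = length(inits),
                 ranks = as.integer(ranks)),
            class = "cn_tucker")
}

#' Reconstruct the tensor approximated by a Tucker fit
#'
#' @param fit A `cn_tucker`.
#' @return 3-d array of the same shape as the decomposed tensor.
#' @export
tucker_fitted <- function(fit) {
  tucker_reconstruct(fit$core, fit$patient_factors, fit$ct_factors,
                     fit$cn_factors)
}

# pad a lower-rank fit to higher ranks with small positive noise
pad_init <- function(fit, ranks, scale = 1e-2) {
  grow <- function(m, r) {
    if (ncol(m) >= r) return(m[, seq_len(r), drop = FALSE])
    cbind(m, matrix(stats::runif(nrow(m) * (r - ncol(m)), 0, scale),
                    nrow(m), r - ncol(m)))
  }
  g_old <- fit$core
  g <- array(stats::runif(prod(ranks), 0, scale * max(g_old)), ranks)
  r0 <- dim(g_old)
  g[seq_len(r0[1]), seq_len(r0[2]), seq_len(r0[3])] <- g_old
  list(a = grow(fit$patient_factors, ranks[1]),
       b = grow(fit$ct_factors, ranks[2]),
       c = grow(fit$cn_factors, ranks[3]),
       g = g)
}

#' Rank elbow scan for the Tucker decomposition
#'
#' Fits every rank combination in the grid, warm-starting each fit from the
#' already-fitted coordinate predecessors (padded with small noise) alongside
#' the random starts, which makes losses non-increasing along any
#' coordinate-wise rank increase.
#'
#' @param tensor A `cn_tensor` or 3-d array.
#' @param rank_grid Data frame or matrix with columns r1, r2, r3.
#' @param n_starts,seed,max_iter,tol Passed to [tucker_decompose()].
#' @return Data frame `r1`, `r2`, `r3`, `loss`, `rel_loss`.
#' @export
elbow_scan <- function(tensor, rank_grid, n_starts = 3L, seed = 1L,
                       max_iter = 20000, tol = 1e-9) {
  x <- if (inherits(tensor, "cn_tensor")) tensor$values else tensor
  grid <- as.data.frame(rank_grid)
  if (!nrow(grid) || ncol(grid) < 3) stop("empty or malformed rank grid")
  names(grid)[1:3] <- c("r1", "r2", "r3")
  grid <- grid[order(grid$r1 + grid$r2 + grid$r3, grid$r1, grid$r2, grid$r3), ]
  fits <- list()
  key <- function(r) paste(r, collapse = "x")
  losses <- numeric(nrow(grid)); rel <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- as.integer(grid[i, 1:3])
    warm <- list()
    for (m in 1:3) {
      rp <- r; rp[m] <- rp[m] - 1L
      prev <- fits[[key(rp)]]
      if (!is.null(prev)) {
        set.seed(stage_seed(seed, paste0("pad:", key(r), ":", m)))
        warm[[length(warm) + 1L]] <- pad_init(prev, r)
      }
    }
    fit <- tucker_decompose(x, r, n_starts = n_starts, seed = seed,
                            max_iter = max_iter, tol = tol,
                            extra_inits = warm)
    fits[[key(r)]] <- fit
    losses[i] <- fit$loss; rel[i] <- fit$rel_loss
  }
  cbind(grid, loss = losses, rel_loss = rel)
}

#' Tissue modules: core slices as CN-module x CT-module bipartite graphs
#'
#' Each patient-mode component of the Tucker fit is a tissue module; its core
#' slice gives the coupling weights between CN modules and CT modules. Edges
#' below the threshold are flagged inactive (not dropped).
#'
#' @param fit A `cn_tucker`.
#' @param edge_threshold Absolute weight threshold; default 20% of the
#'   maximum core weight. Values outside `[0, max]` are clamped with warning.
#' @return List (one element per tissue module) of data frames
#'   `cn_module`, `ct_module`, `weight`, `active`.
#' @export
tissue_modules <- function(fit, edge_threshold = NULL) {
  g <- fit$core
  wmax <- max(g)
  thr <- edge_threshold %||% (0.2 * wmax)
  if (thr < 0 || thr > wmax) {
    warning("edge_threshold outside [0, max core weight]; clamped")
    thr <- min(max(thr, 0), wmax)
  }
  lapply(seq_len(dim(g)[1]), function(q) {
    slice <- g[q, , ]                       # CT modules x CN modules
    df <- expand.grid(ct_module = seq_len(nrow(slice)),
                      cn_module = seq_len(ncol(slice)))
    df$weight <- slice[cbind(df$ct_module, df$cn_module)]
    df$active <- df$weight >= thr
    df[, c("cn_module", "ct_module", "weight", "active")]
  })
}
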