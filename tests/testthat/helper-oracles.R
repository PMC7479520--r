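# Independent brute-force oracles and small fixture builders.

# k nearest (including self) by full distance sort; ties by (distance, index).
brute_knn <- function(xy, k) {
  n <- nrow(xy)
  t(vapply(seq_len(n), function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    order(d2, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# Delaunay edges by the empty-circumcircle test over all triangles.
# Returns a 2-column matrix of index pairs (i < j). Co-circular point sets
# yield edges of every empty-circle triangle (a superset of any particular
# triangulation's diagonal choice).
brute_delaunay <- function(xy) {
  n <- nrow(xy)
  edges <- matrix(integer(0), 0, 2)
  tol <- 1e-9
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- xy[i, 1]; ay <- xy[i, 2]
    bx <- xy[j, 1]; by <- xy[j, 2]
    cx <- xy[k, 1]; cy <- xy[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (xy[, 1] - ux)^2 + (xy[, 2] - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 - tol * max(r2, 1))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Minimal valid dataset from coordinate/type vectors (single patient/region
# unless given).
toy_dataset <- function(x, y, types,
                        region = "r1", patient = "p1", group = "G1",
                        markers = character(0), panel = NULL,
                        survival_time = 10, event = 1L) {
  n <- length(x)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      region_id = rep_len(region, n),
                      patient_id = rep_len(patient, n),
                      group = rep_len(group, n),
                      x = x, y = y, cell_type = types,
                      stringsAsFactors = FALSE)
  for (m in markers) cells[[paste0("marker_", m)]] <- 0L
  pats <- unique(cells$patient_id)
  grp <- cells$group[match(pats, cells$patient_id)]
  clinical <- data.frame(patient_id = pats, group = grp,
                         survival_time = rep_len(survival_time, length(pats)),
                         event = rep_len(event, length(pats)),
                         stringsAsFactors = FALSE)
  cn_dataset(cells, clinical, panel = panel, markers = markers)
}

# Frequency tables generated exactly from the enrichment linear model in log
# space: Y_c ~ N(mu, sd_c); Y_{n,c} = b0 + b1*X + b3*Y_c + N(0, sd_e).
# OLS inference is exact under this generator, so it calibrates type-I tests.
sim_freq_tables_lm <- function(n_ref = 18, n_alt = 17, n_cns = 3,
                               b0 = -0.5, b1 = 0, b3 = 0.8,
                               mu = log(0.05), sd_c = 0.4, sd_e = 0.3,
                               shift_cn = 1) {
  pc <- 1e-3
  patients <- sprintf("P%02d", seq_len(n_ref + n_alt))
  groups <- stats::setNames(rep(c("A", "B"), c(n_ref, n_alt)), patients)
  xg <- as.integer(groups == "B")
  yc <- stats::rnorm(length(patients), mu, sd_c)
  cn_specific <- do.call(rbind, lapply(seq_len(n_cns), function(n) {
    b1n <- if (n == shift_cn) b1 else 0
    y <- b0 + b1n * xg + b3 * yc + stats::rnorm(length(patients), 0, sd_e)
    data.frame(patient_id = patients, cn = n, subset = "S1",
               freq = pmax(exp(y) - pc, 0), stringsAsFactors = FALSE)
  }))
  overall <- data.frame(patient_id = patients, subset = "S1",
                        freq = pmax(exp(yc) - pc, 0), stringsAsFactors = FALSE)
  occ <- matrix(1 / n_cns, length(patients), n_cns,
                dimnames = list(patients, paste0("CN", seq_len(n_cns))))
  freqs <- structure(list(cn_specific = cn_specific, overall = overall,
                          occupancy = occ, subsets = "S1",
                          cns = seq_len(n_cns), patients = patients,
                          excluded_cns = integer(0)),
                     class = "cn_frequencies")
  list(freqs = freqs, groups = groups)
}

# Per-patient frequency tables drawn directly (no spatial simulation):
# lognormal-noise CN-specific frequencies for calibration/power studies of
# the modelling stages.
sim_freq_tables <- function(n_ref = 18, n_alt = 17, n_cns = 5, n_subsets = 4,
                            base = 0.05, noise_sd = 0.3,
                            shift = NULL) {
  patients <- sprintf("P%02d", seq_len(n_ref + n_alt))
  groups <- stats::setNames(rep(c("A", "B"), c(n_ref, n_alt)), patients)
  subs <- paste0("S", seq_len(n_subsets))
  cns <- seq_len(n_cns)
  pat_scale <- exp(stats::rnorm(length(patients), 0, noise_sd))  # shared Y_c driver
  cn_specific <- expand.grid(patient_id = patients, cn = cns, subset = subs,
                             stringsAsFactors = FALSE)
  f <- base * pat_scale[match(cn_specific$patient_id, patients)] *
    exp(stats::rnorm(nrow(cn_specific), 0, noise_sd))
  if (!is.null(shift)) {
    hit <- cn_specific$cn == shift$cn & cn_specific$subset == shift$subset &
      groups[cn_specific$patient_id] == "B"
    f[hit] <- f[hit] * shift$fold
  }
  cn_specific$freq <- pmin(f, 1)
  occ <- matrix(1 / n_cns, length(patients), n_cns,
                dimnames = list(patients, paste0("CN", cns)))
  overall <- do.call(rbind, lapply(subs, function(s) {
    m <- cn_specific[cn_specific$subset == s, ]
    agg <- tapply(m$freq, m$patient_id, mean)
    data.frame(patient_id = names(agg), subset = s, freq = as.numeric(agg),
               stringsAsFactors = FALSE)
  }))
  freqs <- structure(list(cn_specific = cn_specific, overall = overall,
                          occupancy = occ, subsets = subs, cns = cns,
                          patients = patients, excluded_cns = integer(0)),
                     class = "cn_frequencies")
  list(freqs = freqs, groups = groups)
}
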