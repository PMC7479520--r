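# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# two-group cohort of TMA cores (regions), each core a disc in which planted
# cellular neighborhoods are contiguous Voronoi zones of random seed points;
# cell types drawn from CN-characteristic mixtures; binary functional-marker
# flags with (group, CN, cell type)-specific positivity rates; patient-level
# CN abundance variation with an optional latent coupling between two CNs;
# and survival times whose log-hazard depends on one CN-specific frequency.

default_panel <- function() {
  c("tumor cells", "tumor/immune mix", "CD4+ T cells", "CD8+ T cells",
    "Tregs", "CD4+CD45RO+ T cells", "B cells", "plasma cells",
    "CD68+ macrophages", "CD68+CD163+ macrophages", "CD11b+ monocytes",
    "CD11c+ DCs", "granulocytes", "NK cells", "mast cells",
    "smooth muscle", "stroma", "vasculature", "lymphatics", "nerves",
    "adipocytes", "CD3+ other T cells", "gd T cells", "CD4+CD69+ T cells",
    "plasmacytoid DCs", "CD163+ macrophages", "undefined", "dirt")
}

default_marker_effects <- function() {
  data.frame(
    group = c("DII", "DII", "DII", "CLR"),
    cn = c(9L, 9L, 4L, 1L),
    cell_type = c("CD4+ T cells", "CD4+ T cells", "Tregs", "CD8+ T cells"),
    marker = c("PD1", "ICOS", "Ki67", "Ki67"),
    rate = c(0.45, 0.35, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults mirror the cohort shape of the motivating study: 35 patients
#' (17 CLR, 18 DII), 4 TMA cores per patient (140 regions), ~2000 cells per
#' core, a 28-type panel, 9 planted CNs, three functional markers
#' (PD-1, Ki-67, ICOS) with group- and CN-specific positivity rates, a latent
#' coupling between two CN abundances, and survival whose log-hazard is
#' linear in the log CN-specific frequency of PD-1+ CD4+ T cells in CN 9.
#'
#' @param groups Two group labels; the first is the reference level.
#' @param n_patients Integer pair: patients per group.
#' @param regions_per_patient Cores per patient.
#' @param cells_per_region Expected cells per core.
#' @param panel Cell-type panel.
#' @param markers Marker names (CSV columns get a `marker_` prefix).
#' @param n_cns Number of planted CNs.
#' @param cn_mixtures Optional `n_cns x length(panel)` row-stochastic matrix;
#'   by default each CN gets three dominant types holding `dominance` of the
#'   mass, assigned disjointly while the panel allows.
#' @param dominance Probability mass on a CN's dominant types.
#' @param region_radius Core radius (same length unit as coordinates).
#' @param seeds_per_cn Average Voronoi zone seeds per CN per region.
#' @param cn_weight_sd SD of patient-level log CN weights (abundance spread).
#' @param coupling `list(cn_a, cn_b, strength, marker_strength)`: a patient
#'   latent factor shifts both the abundances of the two CNs (by `strength`
#'   on the log-weight scale) and, when `marker_strength > 0`, the marker
#'   positivity rates of cells inside them (on the logit scale), planting
#'   correlated CN-specific functional frequencies across patients. `NULL`
#'   disables coupling.
#' @param marker_base_rates Named baseline positivity per marker.
#' @param marker_effects Data frame (group, cn, cell_type, marker, rate) of
#'   positivity-rate overrides; `NULL` for none, default plants group-specific
#'   functional enrichment.
#' @param include_artifact If `TRUE`, adds an extra planted zone (CN id
#'   `n_cns + 1`) populated almost purely by an `"imaging artifacts"` type.
#' @param survival `list(cn, cell_type, marker, b, baseline_hazard,
#'   group_loghr, admin_horizon, dropout_rate, pseudocount)` or `NULL`.
#'   `b` is the log-hazard coefficient on the centred
#'   `log(pseudocount + CN-specific frequency)` of the designated subset.
#' @return A list of class `cn_sim_config`.
#' @export
sim_config <- function(groups = c("CLR", "DII"),
                       n_patients = c(17L, 18L),
                       regions_per_patient = 4L,
                       cells_per_region = 2000L,
                       panel = default_panel(),
                       markers = c("PD1", "Ki67", "ICOS"),
                       n_cns = 9L,
                       cn_mixtures = NULL,
                       dominance = 0.75,
                       region_radius = 350,
                       seeds_per_cn = 2L,
                       cn_weight_sd = 0.35,
                       coupling = list(cn_a = 1L, cn_b = 4L, strength = 0.6,
                                       marker_strength = 1.0),
                       marker_base_rates = c(PD1 = 0.08, Ki67 = 0.12, ICOS = 0.08),
                       marker_effects = default_marker_effects(),
                       include_artifact = FALSE,
                       survival = list(cn = 9L, cell_type = "CD4+ T cells",
                                       marker = "PD1", b = -1.2,
                                       baseline_hazard = 0.015,
                                       group_loghr = 0.9,
                                       admin_horizon = 120,
                                       dropout_rate = 0.004,
                                       pseudocount = 1e-3)) {
  stopifnot(length(groups) == 2, length(n_patients) == 2,
            cells_per_region >= 1, n_cns >= 1,
            dominance > 0, dominance <= 1)
  if (!is.null(cn_mixtures)) {
    if (!is.matrix(cn_mixtures) || nrow(cn_mixtures) != n_cns ||
        ncol(cn_mixtures) != length(panel))
      stop("cn_mixtures must be a ", n_cns, " x ", length(panel), " matrix")
    if (any(abs(rowSums(cn_mixtures) - 1) > 1e-12))
      stop("cn_mixtures rows must sum to 1")
    if (any(cn_mixtures < 0)) stop("cn_mixtures must be non-negative")
  }
  missing_m <- setdiff(markers, names(marker_base_rates))
  if (length(missing_m))
    stop("marker_base_rates missing marker(s): ", paste(missing_m, collapse = ", "))
  cfg <- as.list(environment())
  class(cfg) <- "cn_sim_config"
  cfg
}

# Deterministic CN-characteristic mixtures: disjoint dominant triples plus a
# flat background over the remaining panel. Functional T-cell types (CD4+,
# CD8+, Tregs), when present, keep a floor share in every CN: lymphocytes
# infiltrate all neighborhoods in tissue, and the floor gives marker-positive
# subset frequencies measurable support everywhere.
make_mixtures <- function(n_cns, panel, dominance,
                          floor_types = c("CD4+ T cells", "CD8+ T cells",
                                          "Tregs"),
                          floor_share = 0.05) {
  t_ <- length(panel)
  mix <- matrix((1 - dominance) / max(t_ - 3, 1), n_cns, t_,
                dimnames = list(paste0("CN", seq_len(n_cns)), panel))
  if (t_ <= 3) {
    mix[] <- 0
    for (k in seq_len(n_cns)) mix[k, ] <- 1 / t_
    return(mix)
  }
  for (k in seq_len(n_cns)) {
    dom <- ((k - 1) * 3 + 0:2) %% t_ + 1
    mix[k, dom] <- dominance / 3
    mix[k, -dom] <- (1 - dominance) / (t_ - 3)
  }
  ft <- match(intersect(floor_types, panel), panel)
  if (length(ft)) {
    for (k in seq_len(n_cns)) {
      low <- ft[mix[k, ft] < floor_share]
      mix[k, low] <- floor_share
    }
  }
  mix / rowSums(mix)
}

marker_rate_lookup <- function(cfg) {
  eff <- cfg$marker_effects
  function(group, cn, cell_type, marker) {
    r <- unname(cfg$marker_base_rates[marker])
    if (!is.null(eff) && nrow(eff)) {
      hit <- eff$group == group & eff$cn == cn &
        eff$cell_type == cell_type & eff$marker == marker
      if (any(hit)) r <- eff$rate[which(hit)[1]]
    }
    r
  }
}

#' Simulate a spatial cohort with planted cellular neighborhoods
#'
#' Cells are placed uniformly within a disc per region; planted CN zones are
#' the Voronoi cells of random zone seeds whose CN identities are drawn from
#' patient-specific CN weights (log-normal spread, optional latent coupling
#' between two CNs). Cell types are drawn from the zone's mixture, marker
#' flags are independent Bernoulli draws at (group, CN, type, marker)-specific
#' rates, and survival times follow an exponential proportional-hazards model
#' on the designated log CN-specific subset frequency with administrative
#' plus exponential-dropout censoring.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return `list(dataset, truth)` where `dataset` is a [cn_dataset()] and
#'   `truth` (class `cn_sim_truth`) records the planted zones, per-cell CN
#'   ids, mixtures, patient CN weights and the survival covariate.
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cn_sim_config"))
  set.seed(stage_seed(seed, "simulate"))

  panel <- cfg$panel
  n_cns <- cfg$n_cns
  if (cfg$include_artifact && !("imaging artifacts" %in% panel))
    panel <- c(panel, "imaging artifacts")
  mix <- cfg$cn_mixtures %||% make_mixtures(cfg$n_cns, cfg$panel, cfg$dominance)
  if (cfg$include_artifact) {
    # extra planted zone: almost pure artifact type
    n_cns <- n_cns + 1L
    m2 <- matrix(0, n_cns, length(panel), dimnames = list(NULL, panel))
    m2[seq_len(nrow(mix)), colnames(mix)] <- mix
    art <- rep(0.02 / (length(panel) - 1), length(panel))
    art[match("imaging artifacts", panel)] <- 0.98
    m2[n_cns, ] <- art
    mix <- m2
  }

  groups <- rep(cfg$groups, cfg$n_patients)
  n_pat <- sum(cfg$n_patients)
  patient_ids <- sprintf("P%02d", seq_len(n_pat))

  # patient-level CN weights with optional latent coupling
  lw <- matrix(stats::rnorm(n_pat * n_cns, 0, cfg$cn_weight_sd), n_pat, n_cns)
  z <- rep(0, n_pat)
  coupled_cns <- integer(0)
  marker_strength <- 0
  if (!is.null(cfg$coupling) && n_cns >= max(cfg$coupling$cn_a, cfg$coupling$cn_b)) {
    z <- stats::rnorm(n_pat)
    lw[, cfg$coupling$cn_a] <- lw[, cfg$coupling$cn_a] + cfg$coupling$strength * z
    lw[, cfg$coupling$cn_b] <- lw[, cfg$coupling$cn_b] + cfg$coupling$strength * z
    coupled_cns <- c(cfg$coupling$cn_a, cfg$coupling$cn_b)
    marker_strength <- cfg$coupling$marker_strength %||% 0
  }
  w <- exp(lw)
  w <- w / rowSums(w)
  rownames(w) <- patient_ids

  n_seeds <- max(n_cns * cfg$seeds_per_cn, n_cns)
  rate_of <- marker_rate_lookup(cfg)
  R <- cfg$region_radius

  cells_list <- list()
  zones_list <- list()
  cn_truth <- list()
  idx <- 0L
  for (p in seq_len(n_pat)) {
    for (r in seq_len(cfg$regions_per_patient)) {
      region_id <- sprintf("%s_r%d", patient_ids[p], r)
      # zone seeds: CN identity ~ patient weights, positions uniform in disc
      seed_cn <- if (n_cns == 1L) rep(1L, n_seeds) else
        as.integer(sample.int(n_cns, n_seeds, replace = TRUE, prob = w[p, ]))
      th <- stats::runif(n_seeds, 0, 2 * pi)
      rr <- R * sqrt(stats::runif(n_seeds))
      zx <- rr * cos(th); zy <- rr * sin(th)

      n_c <- cfg$cells_per_region
      th <- stats::runif(n_c, 0, 2 * pi)
      rr <- R * sqrt(stats::runif(n_c))
      x <- rr * cos(th); y <- rr * sin(th)
      zone <- RANN::nn2(cbind(zx, zy), cbind(x, y), k = 1)$nn.idx[, 1]
      cn <- seed_cn[zone]
      type <- character(n_c)
      for (k in unique(cn)) {
        sel <- cn == k
        type[sel] <- sample(panel, sum(sel), replace = TRUE, prob = mix[k, ])
      }

      flags <- matrix(0L, n_c, length(cfg$markers),
                      dimnames = list(NULL, marker_cols(cfg$markers)))
      for (m in cfg$markers) {
        # vectorized over the distinct (cn, type) combos present
        key <- paste(cn, type, sep = "\r")
        for (k in unique(key)) {
          sel <- key == k
          rate <- rate_of(groups[p], cn[sel][1], type[sel][1], m)
          if (marker_strength > 0 && cn[sel][1] %in% coupled_cns)
            rate <- stats::plogis(stats::qlogis(min(max(rate, 1e-6), 1 - 1e-6)) +
                                    marker_strength * z[p])
          flags[sel, marker_cols(m)] <- stats::rbinom(sum(sel), 1L, rate)
        }
      }

      cells_list[[length(cells_list) + 1L]] <- data.frame(
        cell_id = sprintf("c%07d", idx + seq_len(n_c)),
        region_id = region_id, patient_id = patient_ids[p],
        group = groups[p], x = x, y = y, cell_type = type,
        flags, stringsAsFactors = FALSE, check.names = FALSE)
      zones_list[[length(zones_list) + 1L]] <- data.frame(
        region_id = region_id, seed_x = zx, seed_y = zy, cn = seed_cn,
        stringsAsFactors = FALSE)
      cn_truth[[length(cn_truth) + 1L]] <-
        stats::setNames(cn, sprintf("c%07d", idx + seq_len(n_c)))
      idx <- idx + n_c
    }
  }
  cells <- do.call(rbind, cells_list)
  zones <- do.call(rbind, zones_list)
  cell_cn <- do.call(c, cn_truth)

  # survival: covariate is the centred log CN-specific subset frequency
  sv <- cfg$survival
  if (!is.null(sv)) {
    f <- vapply(patient_ids, function(pid) {
      sel <- cells$patient_id == pid & cell_cn[cells$cell_id] == sv$cn
      if (!any(sel)) return(NA_real_)
      sub <- cells$cell_type[sel] == sv$cell_type &
        cells[[marker_cols(sv$marker)]][sel] == 1L
      mean(sub)
    }, numeric(1))
    xcov <- log(sv$pseudocount + ifelse(is.na(f), 0, f))
    xcov <- xcov - mean(xcov)
    rate <- sv$baseline_hazard *
      exp(sv$b * xcov + sv$group_loghr * (groups == cfg$groups[2]))
    t_event <- stats::rexp(n_pat, rate)
    t_cens <- pmin(sv$admin_horizon, stats::rexp(n_pat, sv$dropout_rate))
    clinical <- data.frame(patient_id = patient_ids, group = groups,
                           survival_time = pmin(t_event, t_cens),
                           event = as.integer(t_event <= t_cens),
                           stringsAsFactors = FALSE)
  } else {
    f <- rep(NA_real_, n_pat); xcov <- rep(0, n_pat)
    clinical <- data.frame(patient_id = patient_ids, group = groups,
                           survival_time = stats::rexp(n_pat, 0.01),
                           event = 1L, stringsAsFactors = FALSE)
  }

  ds <- cn_dataset(cells, clinical, panel = panel, markers = cfg$markers)
  truth <- structure(list(mixtures = mix, zones = zones, cell_cn = cell_cn,
                          patient_weights = w, coupling_latent = z,
                          survival_covariate = xcov,
                          survival_frequency = f, config = cfg, seed = seed),
                     class = "cn_sim_truth")
  list(dataset = ds, truth = truth)
}

#' Planted CN label of every cell
#'
#' Recomputes zone membership (nearest planted zone seed within the cell's
#' region) from the simulation truth; equals the labels used at generation
#' time by construction.
#'
#' @param truth A `cn_sim_truth`.
#' @param cells Cell table of the matching dataset.
#' @return Integer vector of planted CN ids, named by `cell_id`.
#' @export
planted_cn_labels <- function(truth, cells) {
  stopifnot(inherits(truth, "cn_sim_truth"))
  out <- integer(nrow(cells))
  for (rid in unique(cells$region_id)) {
    z <- truth$zones[truth$zones$region_id == rid, ]
    if (!nrow(z)) stop("internal error: region ", rid, " has no planted zones")
    sel <- cells$region_id == rid
    idx <- RANN::nn2(cbind(z$seed_x, z$seed_y),
                     cbind(cells$x[sel], cells$y[sel]), k = 1)$nn.idx[, 1]
    out[sel] <- z$cn[idx]
  }
  stats::setNames(out, cells$cell_id)
}
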