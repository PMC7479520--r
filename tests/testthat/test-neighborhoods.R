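test_that("window composition on hand-worked fixtures", {
  # 3 collinear cells, window 3: every window holds all three cells
  ds <- toy_dataset(x = c(0, 1, 2), y = c(0, 0, 0), types = c("A", "B", "C"))
  w <- build_windows(ds, window_size = 3)
  expect_equal(unname(w$composition),
               matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # homogeneous region: every row is the indicator of the single type
  ds2 <- toy_dataset(x = runif(50), y = runif(50), types = rep("A", 50))
  w2 <- build_windows(ds2, window_size = 10)
  expect_true(all(w2$composition[, "A"] == 1))
  expect_true(all(rowSums(w2$composition) == 1))
})

test_that("k-NN windows equal the brute-force all-pairs oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 600
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    ds <- toy_dataset(x = x, y = y,
                      types = sample(c("A", "B", "C"), n, replace = TRUE))
    w <- build_windows(ds, window_size = 10)
    oracle <- brute_knn(cbind(x, y), 10)
    ids <- matrix(ds$cells$cell_id[oracle], n, 10)
    expect_identical(unname(w$neighbors), ids,
                     info = paste("fixture seed", seed))
  }
})

test_that("windows never cross region boundaries and rows sum to one", {
  set.seed(4)
  ds <- toy_dataset(x = runif(80), y = runif(80),
                    types = sample(c("A", "B"), 80, TRUE),
                    region = rep(c("r1", "r2"), each = 40),
                    patient = rep(c("p1", "p2"), each = 40),
                    group = rep(c("g", "g"), each = 40))
  w <- build_windows(ds, window_size = 5)
  reg <- setNames(ds$cells$region_id, ds$cells$cell_id)
  for (i in seq_len(nrow(w$neighbors)))
    expect_true(all(reg[w$neighbors[i, ]] == reg[rownames(w$neighbors)[i]]))
  expect_equal(unname(rowSums(w$composition)), rep(1, 80), tolerance = 1e-9)
})

test_that("small regions are excluded with a warning (or error on request)", {
  ds <- toy_dataset(x = c(0, 1, 2, 0, 1), y = c(0, 0, 0, 1, 1),
                    types = rep("A", 5),
                    region = c("big", "big", "big", "big", "tiny"),
                    patient = "p1", group = "g")
  expect_warning(w <- build_windows(ds, window_size = 4), "tiny")
  expect_equal(nrow(w$composition), 4)
  expect_error(build_windows(ds, window_size = 4, on_small_region = "error"),
               "tiny")
})

test_that("clustering separates two window archetypes perfectly and is deterministic", {
  set.seed(2)
  # windows drawn from two orthogonal compositions
  n <- 200
  truth <- rep(1:2, each = n / 2)
  comp <- rbind(matrix(rep(c(0.9, 0.1, 0, 0), n / 2), ncol = 4, byrow = TRUE),
                matrix(rep(c(0, 0, 0.2, 0.8), n / 2), ncol = 4, byrow = TRUE))
  comp <- comp + matrix(runif(n * 4, 0, 0.02), n, 4)
  comp <- comp / rowSums(comp)
  rownames(comp) <- sprintf("c%03d", 1:n)
  colnames(comp) <- c("A", "B", "C", "D")
  w <- structure(list(composition = comp, neighbors = NULL, window_size = 10L),
                 class = "cn_windows")
  m1 <- cluster_windows(w, n_cns = 2, seed = 5)
  expect_equal(mclust::adjustedRandIndex(m1$assignments, truth), 1.0)
  m2 <- cluster_windows(w, n_cns = 2, seed = 5)
  expect_identical(m1$assignments, m2$assignments)
})

test_that("degenerate clustering input collapses to fewer clusters with warning", {
  comp <- matrix(0.5, 20, 2, dimnames = list(sprintf("c%02d", 1:20), c("A", "B")))
  w <- structure(list(composition = comp, neighbors = NULL, window_size = 3L),
                 class = "cn_windows")
  expect_warning(m <- cluster_windows(w, n_cns = 2, seed = 1), "distinct")
  expect_equal(m$n_cns, 1L)
  expect_true(all(m$assignments == 1L))
})

test_that("artifact CN removal drops the planted artifact zone", {
  sim <- simulate_dataset(
    sim_config(n_patients = c(2L, 2L), regions_per_patient = 2L,
               cells_per_region = 800L, n_cns = 3L,
               panel = default_panel()[1:9], include_artifact = TRUE,
               survival = NULL),
    seed = 13)
  r <- identify_neighborhoods(sim$dataset, window_size = 10, n_cns = 4, seed = 2)
  planted <- sim$truth$cell_cn[r$dataset$cells$cell_id]
  n_artifact <- sum(planted == 4L)  # artifact zone has id n_cns + 1
  rem <- remove_artifact_cn(r$dataset, r$model,
                            artifact_cell_type = "imaging artifacts")
  # removal should take out approximately the artifact zone's cells
  expect_lt(abs(rem$n_removed - n_artifact) / n_artifact, 0.2)
  expect_equal(nrow(rem$dataset$cells), nrow(r$dataset$cells) - rem$n_removed)
  # no-op cases
  expect_warning(r2 <- remove_artifact_cn(r$dataset, r$model), "nothing removed")
  expect_equal(r2$n_removed, 0L)
  expect_warning(remove_artifact_cn(r$dataset, r$model,
                                    artifact_cell_type = "not a type"),
                 "not in panel")
  expect_error(remove_artifact_cn(r$dataset, r$model, artifact_cn = 99L),
               "out of range")
})

test_that("per-patient CN frequencies average regions (mean of cores)", {
  # two regions with CN-1 fractions 0.2 and 0.4 -> patient value 0.3
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:15),
    region_id = rep(c("r1", "r2"), c(5, 10)),
    patient_id = "p1", group = "g",
    x = seq_len(15), y = 0, cell_type = "A",
    cn_label = c(rep(1L, 1), rep(2L, 4),        # r1: 0.2 in CN1
                 rep(1L, 4), rep(2L, 6)),        # r2: 0.4 in CN1
    stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = "p1", group = "g",
                         survival_time = 1, event = 1L)
  ds <- cn_dataset(cells, clinical)
  f <- cn_frequencies_by_patient(ds)
  expect_equal(unname(f["p1", "CN1"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(rowSums(f)), 1, tolerance = 1e-9)
})

test_that("CN recovery on well-separated planted neighborhoods", {
  sim <- simulate_dataset(
    sim_config(n_patients = c(2L, 2L), regions_per_patient = 2L,
               cells_per_region = 1200L, n_cns = 4L,
               panel = default_panel()[1:12], dominance = 0.85,
               survival = NULL),
    seed = 17)
  r <- identify_neighborhoods(sim$dataset, window_size = 10, n_cns = 4, seed = 8)
  ari <- mclust::adjustedRandIndex(r$dataset$cells$cn_label,
                                   sim$truth$cell_cn[r$dataset$cells$cell_id])
  expect_gt(ari, 0.8)
})
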