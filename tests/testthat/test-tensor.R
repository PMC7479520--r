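# planted non-negative Tucker tensor with optional noise
planted_tucker <- function(dims, ranks, seed = 1, noise = 0) {
  set.seed(seed)
  a <- matrix(runif(dims[1] * ranks[1]), dims[1])
  b <- matrix(runif(dims[2] * ranks[2]), dims[2])
  c_ <- matrix(runif(dims[3] * ranks[3]), dims[3])
  g <- array(runif(prod(ranks)), ranks)
  x <- cncoord:::tucker_reconstruct(g, a, b, c_)
  if (noise > 0) x <- x + array(abs(rnorm(prod(dims), 0, noise * mean(x))), dims)
  x
}

tensor_fixture <- function(seed = 9) {
  set.seed(seed)
  n <- 600
  pats <- sprintf("p%d", 1:4)
  cells <- data.frame(
    cell_id = sprintf("c%04d", 1:n),
    region_id = paste0(rep(pats, each = n / 4), "_r1"),
    patient_id = rep(pats, each = n / 4),
    group = rep(c("g1", "g2"), each = n / 2),
    x = runif(n), y = runif(n),
    cell_type = sample(c("A", "B", "C"), n, TRUE),
    cn_label = sample(1:3, n, TRUE), stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = pats,
                         group = rep(c("g1", "g2"), each = 2),
                         survival_time = 1, event = 1L)
  cn_dataset(cells, clinical)
}

test_that("joint tensor marginals equal CN occupancy and overall type frequencies", {
  ds <- tensor_fixture()
  tns <- build_tensor(ds)
  x <- tns$values
  expect_equal(unname(apply(x, 1, sum)), rep(1, dim(x)[1]), tolerance = 1e-12)
  fr <- compute_frequencies(ds)
  occ <- apply(x, c(1, 3), sum)
  expect_equal(unname(occ), unname(fr$occupancy[rownames(x), ]),
               tolerance = 1e-12)
  types <- apply(x, c(1, 2), sum)
  ov <- frequency_matrix(fr, "overall")[rownames(x), colnames(types)]
  expect_equal(unname(types), unname(ov), tolerance = 1e-12)
})

test_that("excluding a CN renormalises the remaining joint entries", {
  ds <- tensor_fixture()
  full <- build_tensor(ds)$values
  excl <- build_tensor(ds, excluded_cns = 3L)$values
  # per patient: remaining mass rescaled by 1 / (1 - share of CN 3)
  for (p in rownames(excl)) {
    share <- sum(full[p, , "CN3"])
    expect_equal(excl[p, , c("CN1", "CN2")],
                 full[p, , c("CN1", "CN2")] / (1 - share), tolerance = 1e-12)
  }
  expect_error(build_tensor(ds, excluded_cns = 1:3), "empty tensor")
})

test_that("single-entry degenerate tensor decomposes exactly", {
  cells <- data.frame(cell_id = c("a", "b"), region_id = "r1",
                      patient_id = "p1", group = "g", x = c(0, 1), y = 0,
                      cell_type = "A", cn_label = 1L, stringsAsFactors = FALSE)
  clin <- data.frame(patient_id = "p1", group = "g", survival_time = 1, event = 1L)
  ds <- cn_dataset(cells, clin)
  tns <- build_tensor(ds)
  expect_equal(sum(tns$values), 1)
  expect_equal(max(tns$values), 1)
})

test_that("exact rank-(1,1,1) tensor is recovered to numerical precision", {
  x <- planted_tucker(c(6, 5, 4), c(1, 1, 1), seed = 2)
  fit <- tucker_decompose(x, ranks = c(1, 1, 1), n_starts = 3, seed = 1,
                          max_iter = 2000, tol = 1e-14)
  expect_lte(fit$rel_loss, 1e-6)
})

test_that("planted (2,3,3) tensor with 1% noise is recovered within 5% relative error", {
  x <- planted_tucker(c(15, 10, 8), c(2, 3, 3), seed = 4, noise = 0.01)
  fit <- tucker_decompose(x, ranks = c(2, 3, 3), n_starts = 5, seed = 1)
  expect_lte(fit$rel_loss, 0.05)
  # determinism
  fit2 <- tucker_decompose(x, ranks = c(2, 3, 3), n_starts = 5, seed = 1)
  expect_identical(fit$loss, fit2$loss)
  expect_identical(fit$core, fit2$core)
  # rank exceeding a dimension errors with the mode named
  expect_error(tucker_decompose(x, ranks = c(20, 3, 3)), "patient")
})

test_that("factors and core are non-negative and reconstruction matches the loss", {
  x <- planted_tucker(c(8, 7, 6), c(2, 2, 2), seed = 6, noise = 0.05)
  fit <- tucker_decompose(x, ranks = c(2, 2, 2), n_starts = 3, seed = 3)
  expect_true(all(fit$core >= 0))
  expect_true(all(fit$patient_factors >= 0))
  expect_true(all(fit$ct_factors >= 0))
  expect_true(all(fit$cn_factors >= 0))
  rec <- tucker_fitted(fit)
  expect_equal(sqrt(sum((x - rec)^2)), fit$loss, tolerance = 1e-8)
  # unit-max column normalisation of non-dead factor columns
  expect_true(all(abs(apply(fit$patient_factors, 2, max) - 1) < 1e-9))
})

test_that("multi-start loss is stable across seeds on the planted tensor", {
  x <- planted_tucker(c(12, 9, 7), c(2, 3, 3), seed = 8, noise = 0.01)
  losses <- vapply(1:6, function(s)
    tucker_decompose(x, ranks = c(2, 3, 3), n_starts = 3, seed = s)$loss, numeric(1))
  expect_lt(sd(losses) / mean(losses), 0.05)
})

test_that("elbow scan losses are non-increasing in every mode and drop at the planted rank", {
  x <- planted_tucker(c(12, 10, 8), c(2, 3, 3), seed = 10, noise = 0.005)
  grid <- expand.grid(r1 = 1:3, r2 = 2:4, r3 = 2:4)
  sc <- elbow_scan(x, grid, n_starts = 2, seed = 2)
  # monotone non-increase along each coordinate
  for (i in seq_len(nrow(sc))) for (m in 1:3) {
    r <- as.integer(sc[i, 1:3]); r[m] <- r[m] + 1L
    j <- which(sc$r1 == r[1] & sc$r2 == r[2] & sc$r3 == r[3])
    if (length(j))
      expect_lte(sc$loss[j], sc$loss[i] + 1e-6 * max(sc$loss[i], 1))
  }
  # loss at the planted rank is near zero and far below the rank just under it
  at <- sc$loss[sc$r1 == 2 & sc$r2 == 3 & sc$r3 == 3]
  under <- sc$loss[sc$r1 == 1 & sc$r2 == 3 & sc$r3 == 3]
  expect_lt(at, 0.2 * under)
  # full ranks reproduce the tensor (done on a small exact tensor)
  x0 <- planted_tucker(c(4, 3, 3), c(2, 2, 2), seed = 3)
  sc0 <- elbow_scan(x0, data.frame(r1 = 4, r2 = 3, r3 = 3), n_starts = 2,
                    seed = 1, max_iter = 3000, tol = 1e-14)
  expect_lt(sc0$rel_loss, 1e-3)
})

test_that("tissue modules expose core slices as bipartite edge tables", {
  g <- array(0, c(2, 3, 3))
  g[1, 2, 3] <- 5
  fit <- structure(list(core = g,
                        patient_factors = matrix(1, 4, 2),
                        ct_factors = matrix(1, 5, 3),
                        cn_factors = matrix(1, 6, 3),
                        ranks = c(2L, 3L, 3L)), class = "cn_tucker")
  tm <- tissue_modules(fit)
  expect_length(tm, 2)
  active <- tm[[1]][tm[[1]]$active, ]
  expect_equal(nrow(active), 1)
  expect_equal(active$ct_module, 2)
  expect_equal(active$cn_module, 3)
  expect_equal(sum(tm[[2]]$active), 0)
  # threshold 0 activates every edge
  tm0 <- tissue_modules(fit, edge_threshold = 0)
  expect_true(all(tm0[[1]]$active))
  expect_warning(tissue_modules(fit, edge_threshold = 99), "clamped")
})

test_that("planted two-community structure is recovered in the factors", {
  # two disjoint CN/CT communities across patients
  set.seed(12)
  n_pat <- 12
  a <- matrix(0, n_pat, 2); a[1:6, 1] <- runif(6, 0.5, 1); a[7:12, 2] <- runif(6, 0.5, 1)
  b <- matrix(0, 8, 2); b[1:4, 1] <- runif(4, 0.5, 1); b[5:8, 2] <- runif(4, 0.5, 1)
  c_ <- matrix(0, 6, 2); c_[1:3, 1] <- runif(3, 0.5, 1); c_[4:6, 2] <- runif(3, 0.5, 1)
  g <- array(0, c(2, 2, 2)); g[1, 1, 1] <- 1; g[2, 2, 2] <- 1
  x <- cncoord:::tucker_reconstruct(g, a, b, c_) +
    array(runif(n_pat * 8 * 6, 0, 1e-3), c(n_pat, 8, 6))
  fit <- tucker_decompose(x, ranks = c(2, 2, 2), n_starts = 6, seed = 5)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  # best assignment (2 components: identity or swap) of CT factors to truth
  match_score <- function(f, truth) {
    s_id <- mean(c(cosine(f[, 1], truth[, 1]), cosine(f[, 2], truth[, 2])))
    s_sw <- mean(c(cosine(f[, 1], truth[, 2]), cosine(f[, 2], truth[, 1])))
    max(s_id, s_sw)
  }
  expect_gte(match_score(fit$ct_factors, b), 0.9)
  expect_gte(match_score(fit$cn_factors, c_), 0.9)
})
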