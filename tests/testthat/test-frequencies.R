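# dataset with assigned cn labels and marker flags for frequency tests
freq_fixture <- function(seed = 5, n = 400, n_pat = 4) {
  set.seed(seed)
  pats <- sprintf("p%d", seq_len(n_pat))
  cells <- data.frame(
    cell_id = sprintf("c%04d", 1:n),
    region_id = paste0(rep(pats, each = n / n_pat), "_r1"),
    patient_id = rep(pats, each = n / n_pat),
    group = rep(c("g1", "g2"), each = n / 2),
    x = runif(n), y = runif(n),
    cell_type = sample(c("A", "B", "C"), n, TRUE),
    marker_M = rbinom(n, 1, 0.4),
    marker_K = rbinom(n, 1, 0.2),
    cn_label = sample(1:3, n, TRUE),
    stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = pats,
                         group = rep(c("g1", "g2"), each = n_pat / 2),
                         survival_time = 1, event = 1L)
  cn_dataset(cells, clinical)
}

test_that("CN-specific frequencies on a hand-counted fixture", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:10), region_id = "r1", patient_id = "p1",
    group = "g", x = 1:10, y = 0,
    cell_type = c(rep("A", 4), rep("B", 6)),
    cn_label = rep(1L, 10), stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = "p1", group = "g",
                         survival_time = 1, event = 1L)
  ds <- cn_dataset(cells, clinical)
  fr <- compute_frequencies(ds)
  v <- fr$cn_specific
  expect_equal(v$freq[v$subset == "A" & v$cn == 1], 0.4)
  expect_equal(fr$overall$freq[fr$overall$subset == "A"], 0.4)
})

test_that("overall frequency is the occupancy-weighted sum of CN-specific frequencies", {
  ds <- freq_fixture()
  fr <- compute_frequencies(ds)
  for (s in fr$subsets) {
    cn_mat <- frequency_matrix(fr, "cn_specific", subsets = s)
    cn_mat[is.na(cn_mat)] <- 0
    recon <- rowSums(cn_mat * fr$occupancy)
    ov <- frequency_matrix(fr, "overall", subsets = s)[, 1]
    expect_equal(recon, ov, tolerance = 1e-12)
  }
})

test_that("plain-type CN-specific frequencies close to 1 and subsets are monotone", {
  ds <- freq_fixture()
  fr <- compute_frequencies(ds, subsets = c(default_subsets(ds),
                                            list(cn_subset("A", "M"),
                                                 cn_subset("A", c("M", "K")))))
  plain <- fr$cn_specific[fr$cn_specific$subset %in% c("A", "B", "C"), ]
  sums <- tapply(plain$freq, list(plain$patient_id, plain$cn), sum)
  expect_true(all(abs(sums - 1) < 1e-12, na.rm = TRUE))
  wide <- frequency_matrix(fr, "cn_specific")
  for (cn in fr$cns) {
    a <- wide[, paste0("A@CN", cn)]
    am <- wide[, paste0("M+ A@CN", cn)]
    amk <- wide[, paste0("M+K+ A@CN", cn)]
    expect_true(all(am <= a & amk <= am, na.rm = TRUE))
  }
})

test_that("marker-refined subset equals parent type when all parents are positive", {
  ds <- freq_fixture()
  ds$cells$marker_M[ds$cells$cell_type == "A"] <- 1L
  fr <- compute_frequencies(ds, subsets = list(cn_subset("A"), cn_subset("A", "M")))
  a <- frequency_matrix(fr, "cn_specific", subsets = "A")
  am <- frequency_matrix(fr, "cn_specific", subsets = "M+ A")
  expect_equal(unname(am), unname(a), tolerance = 1e-12)
  expect_error(compute_frequencies(ds, subsets = list(cn_subset("A", "ghost"))),
               "undeclared marker")
})

test_that("zero-cell patient-CN combinations are missing, not zero", {
  ds <- freq_fixture()
  ds$cells <- ds$cells[!(ds$cells$patient_id == "p1" & ds$cells$cn_label == 2L), ]
  fr <- compute_frequencies(ds)
  v <- fr$cn_specific
  expect_true(all(is.na(v$freq[v$patient_id == "p1" & v$cn == 2])))
})

test_that("marker proportions match hand computation and the independence closed form", {
  ds <- freq_fixture()
  mp <- marker_proportions(ds, markers = c("M", "K"))
  row <- mp[mp$cn == 1 & mp$cell_type == "A", ]
  sel <- ds$cells$cn_label == 1 & ds$cells$cell_type == "A"
  pos <- ds$cells$marker_M[sel] == 1 | ds$cells$marker_K[sel] == 1
  expect_equal(row$prop_any_positive, mean(pos))
  expect_equal(row$prop_M, mean(ds$cells$marker_M[sel][pos] == 1))
  # independence closed form: P(any) = 1 - (1-p1)(1-p2)(1-p3)
  set.seed(7)
  n <- 4000
  cells <- data.frame(
    cell_id = sprintf("c%05d", 1:n), region_id = "r1", patient_id = "p1",
    group = "g", x = runif(n), y = runif(n), cell_type = "T",
    marker_a = rbinom(n, 1, 0.2), marker_b = rbinom(n, 1, 0.3),
    marker_c = rbinom(n, 1, 0.4), cn_label = 1L, stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = "p1", group = "g",
                         survival_time = 1, event = 1L)
  ds2 <- cn_dataset(cells, clinical)
  mp2 <- marker_proportions(ds2)
  expect_lt(abs(mp2$prop_any_positive - (1 - 0.8 * 0.7 * 0.6)), 0.03)
})

test_that("group comparison t-tests: identity, calibration and power", {
  # identical groups: t = 0, p = 1
  v <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), ncol = 2,
              dimnames = list(sprintf("p%d", 1:6), c("f1", "f2")))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(v))
  r <- compare_group_frequencies(v, g)
  expect_equal(r$t, c(0, 0))
  expect_equal(r$p, c(1, 1))
  # power: N(0,1) vs N(2,1) at n = 18/17 rejects essentially always
  set.seed(11)
  rej <- replicate(200, {
    x <- matrix(c(rnorm(18), rnorm(17, 2)), ncol = 1)
    rownames(x) <- sprintf("p%02d", 1:35)
    gg <- setNames(rep(c("a", "b"), c(18, 17)), rownames(x))
    compare_group_frequencies(x, gg)$p < 0.05
  })
  expect_gte(mean(rej), 0.99)
  # calibration under the null
  rej0 <- replicate(600, {
    x <- matrix(rnorm(35), ncol = 1)
    rownames(x) <- sprintf("p%02d", 1:35)
    gg <- setNames(rep(c("a", "b"), c(18, 17)), rownames(x))
    compare_group_frequencies(x, gg)$p < 0.05
  })
  expect_lt(abs(mean(rej0) - 0.05), 0.025)
})

test_that("PCA of abundances: identities and degenerate features", {
  set.seed(3)
  base <- rnorm(10)
  m <- cbind(f1 = base, f2 = 2 * base + 1, f3 = rep(0.5, 10))
  rownames(m) <- sprintf("p%d", 1:10)
  expect_warning(pc <- pca_abundances(m), "constant")
  expect_equal(pc$dropped, "f3")
  expect_gt(pc$explained_variance[1], 1 - 1e-12)
  expect_equal(unname(colMeans(pc$scores)), rep(0, ncol(pc$scores)),
               tolerance = 1e-12)
  # completeness: scores %*% t(loadings) reconstructs the centred input
  m2 <- matrix(rnorm(40), 8, 5)
  pc2 <- pca_abundances(m2)
  expect_equal(pc2$scores %*% t(pc2$loadings),
               scale(m2, center = TRUE, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(pc2$loadings), diag(ncol(pc2$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
})
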