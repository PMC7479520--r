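test_that("Delaunay edges on hand geometries", {
  # triangle: 3 edges
  tri <- data.frame(cell_id = c("a", "b", "c"), x = c(0, 1, 0.5), y = c(0, 0, 1))
  expect_equal(nrow(delaunay_contacts(tri)), 3)
  # unit square: 4 sides + 1 diagonal (either diagonal acceptable)
  sq <- data.frame(cell_id = c("a", "b", "c", "d"),
                   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  e <- delaunay_contacts(sq)
  expect_equal(nrow(e), 5)
  keys <- edge_key(e$from, e$to)
  sides <- c(edge_key("a", "b"), edge_key("b", "c"),
             edge_key("c", "d"), edge_key("d", "a"))
  expect_true(all(sides %in% keys))
  expect_true(edge_key("a", "c") %in% keys || edge_key("b", "d") %in% keys)
  # degenerate inputs: too few or collinear cells
  expect_warning(e2 <- delaunay_contacts(tri[1:2, ]), "fewer than 3")
  expect_equal(nrow(e2), 0)
  col <- data.frame(cell_id = c("a", "b", "c"), x = 0:2, y = 0:2)
  expect_warning(e3 <- delaunay_contacts(col), "degenerate")
  expect_equal(nrow(e3), 0)
})

test_that("Delaunay edges match the empty-circumcircle brute force", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 50
    df <- data.frame(cell_id = sprintf("p%02d", 1:n),
                     x = runif(n), y = runif(n))
    e <- delaunay_contacts(df)
    idx_from <- match(e$from, df$cell_id)
    idx_to <- match(e$to, df$cell_id)
    got <- sort(edge_key(idx_from, idx_to))
    want <- brute_delaunay(cbind(df$x, df$y))
    expect_identical(got, sort(edge_key(want[, 1], want[, 2])),
                     info = paste("fixture seed", seed))
  }
})

test_that("contact statistics reproduce the worked 4-edge example", {
  edges <- data.frame(from = c("A1", "A1", "A2", "B1"),
                      to = c("A2", "B1", "B2", "B2"),
                      stringsAsFactors = FALSE)
  types <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  st <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 1)
  expect_equal(st$nij["A", "A"], 1)
  expect_equal(st$nij["A", "B"], 2)
  expect_equal(st$nt, 4)
  expect_equal(unname(st$ni["A"]), 3)
  expect_equal(st$lr["A", "B"], 8 / 9, tolerance = 1e-12)
  expect_equal(st$lr["A", "A"], 4 / 9, tolerance = 1e-12)
  expect_equal(st$rf["A", "B"], 2 / 3, tolerance = 1e-12)
  # symmetry of counts, asymmetry of rf
  expect_identical(st$nij, t(st$nij))
  # degree convention counts homotypic edges twice in the margin
  st2 <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 1,
                       convention = "degree")
  expect_equal(unname(st2$ni["A"]), 4)
})

test_that("pairs below the unique-interacting-cells threshold are masked", {
  edges <- data.frame(from = c("A1", "A2"), to = c("B1", "B1"))
  types <- c(A1 = "A", A2 = "A", B1 = "B")
  st <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 4)
  expect_true(st$mask["A", "B"])   # only 3 unique interacting cells
  st2 <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 3)
  expect_false(st2$mask["A", "B"])
})

test_that("log2 group ratio: identical groups give zeros; masks union", {
  edges <- data.frame(from = c("A1", "A1", "A2", "B1"),
                      to = c("A2", "B1", "B2", "B2"))
  types <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  st <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 1)
  r <- log2_group_ratio(st, st)
  expect_true(all(r$log2_ratio == 0, na.rm = TRUE))
  stm <- contact_stats(edges, types, panel = c("A", "B"), min_unique = 100)
  r2 <- log2_group_ratio(st, stm)
  expect_true(all(r2$mask))
})

test_that("likelihood ratios approach 1 under complete spatial randomness", {
  set.seed(31)
  devs <- replicate(5, {
    n <- 3000
    ds <- toy_dataset(x = runif(n), y = runif(n),
                      types = sample(c("A", "B", "C"), n, TRUE,
                                     prob = c(0.5, 0.3, 0.2)))
    st <- contact_stats(contact_graph(ds),
                        setNames(ds$cells$cell_type, ds$cells$cell_id),
                        ds$panel, min_unique = 1, convention = "degree")
    mean(abs(st$lr - 1))
  })
  expect_lt(mean(devs), 0.1)
})

test_that("CN mixing score on hand-worked configurations", {
  # far-apart CN blocks: score ~ 0
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    region_id = "r1", patient_id = "p1", group = "g",
    x = c(seq(0, 0.9, 0.1), seq(100, 100.9, 0.1)),
    y = 0, cell_type = "A",
    cn_label = rep(c(1L, 2L), each = 10), stringsAsFactors = FALSE)
  clin <- data.frame(patient_id = "p1", group = "g", survival_time = 1, event = 1L)
  ds <- cn_dataset(cells, clin)
  s <- cn_mixing_score(ds, 1, 2, window_size = 4)
  expect_equal(s$score, 0)
  # alternating line of CNs: every cell has a cross-CN neighbour
  cells2 <- cells
  cells2$x <- seq(0, 1.9, 0.1)
  cells2$cn_label <- rep(c(1L, 2L), 10)
  ds2 <- cn_dataset(cells2, clin)
  s2 <- cn_mixing_score(ds2, 1, 2, window_size = 4)
  expect_equal(s2$score, 1)
  # asymmetric contact: fractions 1/2 and 1/1 average to 0.75
  cells3 <- data.frame(
    cell_id = c("a", "b", "c"), region_id = "r1", patient_id = "p1",
    group = "g", x = c(0, 3, -0.5), y = c(0, 0, 0),
    cell_type = "A", cn_label = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  ds3 <- cn_dataset(cells3, clin)
  s3 <- cn_mixing_score(ds3, 1, 2, window_size = 2)
  expect_equal(s3$frac_a_touch_b, 0.5)
  expect_equal(s3$frac_b_touch_a, 1.0)
  expect_equal(s3$score, 0.75)
  # symmetry in the pair
  s3r <- cn_mixing_score(ds3, 2, 1, window_size = 2)
  expect_equal(s3r$score, s3$score)
})
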