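three_control_reference <- function() {
  # one shared edge (n01-n02) with gFA 0.4 / 0.5 / 0.6 across three controls,
  # plus an edge only control 1 possesses, plus an edge nobody possesses
  g <- function(w12, extra = NA) {
    m <- matrix(NA_real_, 4, 4)
    m[1, 2] <- w12
    m[3, 4] <- 0.5          # shared by all three (constant -> sd 0)
    if (!is.na(extra)) m[1, 3] <- extra
    m
  }
  list(toy_connectome(g(0.4, extra = 0.3)), toy_connectome(g(0.5)),
       toy_connectome(g(0.6)))
}

test_that("reference mean/SD/count match hand arithmetic", {
  ref <- build_reference(three_control_reference())
  expect_identical(ref$count["n01", "n02"], 3L)
  expect_equal(ref$mean["n01", "n02"], 0.5)
  expect_equal(ref$sd["n01", "n02"], 0.1)
  # edge absent in all controls: count 0, undefined moments
  expect_identical(ref$count["n02", "n04"], 0L)
  expect_true(is.na(ref$mean["n02", "n04"]))
  # edge in one control: count 1, moments undefined (need >= 2)
  expect_identical(ref$count["n01", "n03"], 1L)
  expect_true(is.na(ref$sd["n01", "n03"]))
})

test_that("presence counts equal a brute-force recount on a random cohort", {
  cfg <- generator_config(n_nodes = 30, n_controls = 10, n_patients = 1,
                          edge_dropout = 0.3, seed = 21)
  controls <- generate_controls(cfg, sparenet:::make_scaffold(cfg))
  ref <- build_reference(controls)
  n <- 30
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cnt <- sum(vapply(controls, function(ct) ct$streamline[i, j] > 0,
                      logical(1)))
    expect_equal(unname(ref$count[i, j]), cnt)
  }
})

test_that("mismatched node sets are rejected with the offending labels", {
  a <- toy_connectome(matrix(c(NA, 0.5, 0.5, NA), 2, 2))
  nodes_b <- toy_nodes(2); nodes_b$label <- c("n01", "other")
  b <- toy_connectome(matrix(c(NA, 0.5, 0.5, NA), 2, 2), nodes_b)
  expect_error(build_reference(list(a, b)), "other")
  expect_error(build_reference(list(a)), "at least 2")
})

test_that("z-scores follow (w - mean) / sd and the validity rules", {
  ref <- build_reference(three_control_reference())
  g <- matrix(NA_real_, 4, 4)
  g[1, 2] <- 0.8        # z = (0.8 - 0.5)/0.1 = 3
  g[3, 4] <- 0.7        # control sd 0 -> invalid
  patient <- toy_connectome(g)
  zn <- z_score_network(patient, ref, min_controls = 2)
  expect_equal(zn$z["n01", "n02"], 3.0)
  expect_false(zn$valid["n03", "n04"])    # zero-variance reference
  expect_false(zn$valid["n01", "n03"])    # patient lacks the edge
  # w = mean -> z = 0
  g[1, 2] <- 0.5
  zn0 <- z_score_network(toy_connectome(g), ref, min_controls = 2)
  expect_equal(zn0$z["n01", "n02"], 0)
  expect_error(z_score_network(patient, ref, min_controls = 10),
               "min_controls")
})

test_that("edges below the control-presence filter are excluded", {
  # edge n01-n02 present in 9 of 29 controls, n01-n03 in 10 of 29
  controls <- lapply(1:29, function(i) {
    m <- matrix(NA_real_, 4, 4)
    if (i <= 9) m[1, 2] <- 0.4 + i / 100
    if (i <= 10) m[1, 3] <- 0.5 + i / 100
    m[2, 4] <- 0.4 + i / 50
    toy_connectome(m)
  })
  ref <- build_reference(controls)
  g <- matrix(NA_real_, 4, 4); g[1, 2] <- 0.5; g[1, 3] <- 0.55; g[2, 4] <- 0.6
  zn <- z_score_network(toy_connectome(g), ref, min_controls = 10)
  expect_false(zn$valid["n01", "n02"])   # 9 < 10 controls
  expect_true(zn$valid["n01", "n03"])    # exactly 10 controls
  expect_true(zn$valid["n02", "n04"])
  # valid mask shrinks monotonically as the filter tightens
  v10 <- sum(zn$valid)
  v11 <- sum(z_score_network(toy_connectome(g), ref, min_controls = 11)$valid)
  v29 <- sum(z_score_network(toy_connectome(g), ref, min_controls = 29)$valid)
  expect_true(v29 <= v11 && v11 <= v10)
})

test_that("a held-out control z-scores to approximately standard normal edges", {
  cfg <- generator_config(n_nodes = 60, n_controls = 25, n_patients = 1,
                          seed = 31)
  controls <- generate_controls(cfg, sparenet:::make_scaffold(cfg))
  ref <- build_reference(controls[-1])
  zn <- z_score_network(controls[[1]], ref, min_controls = 10)
  zv <- zn$z[zn$valid & upper.tri(zn$valid)]
  expect_gt(length(zv), 500)
  expect_lt(abs(mean(zv)), 0.12)
  expect_lt(abs(sd(zv) - 1), 0.15)
})

test_that("z-scoring is equivariant under a node permutation", {
  cfg <- generator_config(n_nodes = 20, n_controls = 8, n_patients = 1,
                          seed = 41)
  scaffold <- sparenet:::make_scaffold(cfg)
  controls <- generate_controls(cfg, scaffold)
  patient <- generate_patient(cfg, scaffold, scaffold$nodes$label[1], "left",
                              seed = 5)$connectome
  set.seed(6)
  perm <- sample(20)
  permute <- function(conn) {
    connectome(conn$gfa[perm, perm], conn$streamline[perm, perm],
               conn$nodes[perm, ])
  }
  zn <- z_score_network(patient, build_reference(controls), min_controls = 5)
  znp <- z_score_network(permute(patient),
                         build_reference(lapply(controls, permute)),
                         min_controls = 5)
  expect_equal(znp$z, zn$z[perm, perm])
  expect_identical(unname(znp$degree), unname(zn$degree[perm]))
})
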