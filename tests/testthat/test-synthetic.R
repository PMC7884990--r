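test_that("the same seed reproduces the cohort exactly", {
  cfg <- small_cohort_config(seed = 3, n_patients = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$controls, b$controls)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(lapply(a$patients, `[[`, "truth"),
                   lapply(b$patients, `[[`, "truth"))
})

test_that("zero dropout gives every control every scaffold edge", {
  cfg <- generator_config(n_nodes = 24, n_controls = 4, n_patients = 1,
                          edge_dropout = 0, seed = 2)
  scaffold <- sparenet:::make_scaffold(cfg)
  controls <- generate_controls(cfg, scaffold)
  for (ct in controls)
    expect_identical(unname(ct$streamline > 0), unname(scaffold$present))
})

test_that("edge presence counts follow the binomial expectation", {
  cfg <- generator_config(n_nodes = 40, n_controls = 29, n_patients = 1,
                          edge_dropout = 0.2, seed = 6)
  scaffold <- sparenet:::make_scaffold(cfg)
  controls <- generate_controls(cfg, scaffold)
  counts <- Reduce(`+`, lapply(controls, function(ct) ct$streamline > 0))
  obs <- counts[upper.tri(counts) & scaffold$present]
  expected <- 29 * 0.8
  # mean over ~600 iid Binomial(29, .8) draws; 4 SE band
  se <- sqrt(29 * 0.8 * 0.2 / length(obs))
  expect_lt(abs(mean(obs) - expected), 4 * se)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(edge_dropout = 1.4), "edge_dropout")
  expect_error(generator_config(n_controls = 1), "n_controls")
  expect_error(generator_config(gfa_mean_range = c(0.7, 0.3)), "gfa_mean_range")
  expect_error(generator_config(outcome_cutpoints = c(1, 1, 2, 3)),
               "outcome_cutpoints")
})

test_that("planting outside the parcellation is rejected", {
  cfg <- small_cohort_config()
  scaffold <- sparenet:::make_scaffold(cfg)
  expect_error(generate_patient(cfg, scaffold, c(scaffold$nodes$label[1], "nope"), "left"),
               "nope")
})

test_that("planted edges are incident to planted nodes and all get shifted", {
  cfg <- small_cohort_config(seed = 9)
  scaffold <- sparenet:::make_scaffold(cfg)
  planted <- scaffold$nodes$label[c(3, 9, 21)]
  p <- generate_patient(cfg, scaffold, planted, "left", seed = 1)
  pe <- p$truth$planted_edges
  expect_true(all(pe$node_a %in% planted | pe$node_b %in% planted))
  # every present edge incident to a planted node is recorded as planted
  pres <- p$connectome$streamline > 0
  lab <- p$connectome$nodes$label
  idx <- which(pres & upper.tri(pres), arr.ind = TRUE)
  inc <- lab[idx[, 1]] %in% planted | lab[idx[, 2]] %in% planted
  expect_equal(sum(inc), nrow(pe))
})

test_that("planting entirely inside the resection leaves zero true spared load", {
  cfg <- small_cohort_config(seed = 4)
  scaffold <- sparenet:::make_scaffold(cfg)
  inside <- scaffold$nodes$label[scaffold$nodes$area == cfg$resection_area &
                                   scaffold$nodes$hemisphere == "left"]
  p <- generate_patient(cfg, scaffold, inside, "left", seed = 2)
  expect_identical(p$truth$true_spared_load, 0L)
})

test_that("a null patient (no planted effect) matches the control model", {
  cfg <- generator_config(n_nodes = 40, n_controls = 20, n_patients = 1,
                          planted_effect = 0, seed = 8)
  scaffold <- sparenet:::make_scaffold(cfg)
  controls <- generate_controls(cfg, scaffold)
  ref <- build_reference(controls)
  p <- generate_patient(cfg, scaffold, scaffold$nodes$label[1:2], "left",
                        seed = 3)
  zn <- z_score_network(p$connectome, ref, min_controls = 10)
  zv <- zn$z[zn$valid & upper.tri(zn$valid)]
  # t-like null: near-zero mean, SD near 1 allowing estimation inflation
  expect_lt(abs(mean(zv)), 0.1)
  expect_gt(sd(zv), 0.85)
  expect_lt(sd(zv), 1.25)
})

make_truths <- function(loads)
  lapply(loads, function(l) list(true_spared_load = l))

fake_clinical <- function(n)
  data.frame(patient = sprintf("p%03d", seq_len(n)),
             age_surgery = rep(30, n), n_AEDs = rep(2.5, n))

test_that("an extreme outcome slope dichotomizes patients by spared load", {
  cfg <- generator_config(outcome_coefs = c(intercept = -5, spared_load = 1e3,
                                            age_surgery = 0, n_AEDs = 0),
                          seed = 1)
  out <- assign_outcomes(make_truths(c(0, 0, 3, 5, 1)), fake_clinical(5), cfg)
  expect_true(all(out$ilae_year1[c(3, 4, 5)] == 5))
  expect_true(all(out$ilae_year1[c(1, 2)] == 1))
})

test_that("with zero slopes, class frequencies match the intercept-only expectation", {
  b0 <- 1.0
  cfg <- generator_config(outcome_coefs = c(intercept = b0, spared_load = 0,
                                            age_surgery = 0, n_AEDs = 0),
                          seed = 7)
  n <- 4000
  out <- assign_outcomes(make_truths(rep(2, n)), fake_clinical(n), cfg,
                         seed = 99)
  # closed form: P(class <= k) = plogis(c_k - b0)
  expected_ile1 <- plogis(cfg$outcome_cutpoints[1] - b0)
  obs <- mean(out$ilae_year1 == 1)
  se <- sqrt(expected_ile1 * (1 - expected_ile1) / n)
  expect_lt(abs(obs - expected_ile1), 4 * se)
  expected_le2 <- plogis(cfg$outcome_cutpoints[2] - b0)
  obs2 <- mean(out$ilae_year1 <= 2)
  expect_lt(abs(obs2 - expected_le2), 4 * sqrt(expected_le2 * (1 - expected_le2) / n))
})

test_that("relapse labels exist only for patients at ILAE 1-2 at year 1", {
  coh <- simulate_cohort(small_cohort_config(seed = 11, n_patients = 30))
  out <- coh$outcomes
  bad <- out$ilae_year1 >= 3
  for (y in 2:5)
    expect_true(all(is.na(out[[paste0("relapse_year", y)]][bad])))
  # relapse, once observed, persists in later years
  for (i in which(!bad)) {
    rl <- unlist(out[i, paste0("relapse_year", 2:5)])
    seen <- which(!is.na(rl) & rl)
    if (length(seen)) expect_true(all(rl[seq(min(seen), length(rl))] %in% TRUE))
  }
})
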