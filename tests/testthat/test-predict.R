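test_that("classification metrics match their definitions and the pairwise oracle", {
  m <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  tied <- classification_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$auc, 0.5)
  set.seed(21)
  prob <- runif(6); lab <- c(1, 0, 1, 0, 0, 1)
  expect_equal(classification_metrics(prob, lab)$auc, brute_auc(prob, lab))
  expect_error(classification_metrics(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("sensitivity is the recall of the not-seizure-free class", {
  prob <- c(0.9, 0.4, 0.6, 0.1)   # positives: 1 of 2 above 0.5
  lab <- c(1, 1, 0, 0)
  m <- classification_metrics(prob, lab)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.5)
})

test_that("a perfectly separating feature dominates the trained fold model", {
  set.seed(22)
  n <- 24
  lab <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(signal = lab * 4 + rnorm(n, sd = 0.1),
             noise1 = rnorm(n), noise2 = rnorm(n))
  fm <- fold_train(x, lab, predict_config(c_grid = 1), seed = 1)
  expect_equal(unname(which.max(fm$importances)), 1L)
  expect_equal(max(fm$importances), 1)          # normalized to [0,1]
  prob <- predict_prob(fm, x)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_equal(as.integer(prob >= 0.5), lab)    # training accuracy 1
  expect_error(fold_train(x, rep(1L, n), predict_config(c_grid = 1)),
               "both classes")
})

test_that("Platt calibration is monotone in the decision value", {
  set.seed(23)
  dec <- rnorm(30)
  lab <- as.integer(dec + rnorm(30, sd = 0.5) > 0)
  ab <- sparenet:::platt_fit(dec, lab)
  p <- sparenet:::platt_predict(ab, sort(dec))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p < 1))
})

# small end-to-end cohort shared by the sweep tests below
sweep_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    coh <- simulate_cohort(small_cohort_config(seed = 19, n_patients = 18))
    ref <- build_reference(coh$controls)
    znets <- lapply(coh$patients, function(p)
      z_score_network(p$connectome, ref, min_controls = 5))
    spared <- lapply(seq_along(znets), function(i)
      apply_resection(znets[[i]], coh$patients[[i]]$resection))
    grid <- threshold_grid()
    cache <<- list(
      coh = coh,
      ft = feature_table(coh$clinical, coh$outcomes),
      pre = lapply(znets, load_grid, grid = grid),
      sp = lapply(spared, load_grid, grid = grid))
    cache
  }
})

test_that("the sweep runs 15 steps down to a single feature, deterministically", {
  fx <- sweep_fixture()
  cfgp <- predict_config(c_grid = c(0.1, 1), inner_folds = 3, seed = 7)
  sw <- nested_loo_sweep(fx$ft, fx$pre, fx$sp, cfgp)
  expect_identical(nrow(sw$metrics), 15L)
  expect_identical(sw$metrics$n_features, 15:1)
  expect_length(sw$final_feature, 1)
  expect_identical(length(sw$eliminated), 14L)
  expect_true(all(sw$metrics$auc >= 0 & sw$metrics$auc <= 1))
  probs <- sw$probabilities
  expect_true(all(probs >= 0 & probs <= 1))
  # ILAE 2 patients are scored even though they never enter training
  expect_true(all(is.finite(probs[fx$ft$ilae == 2, ])))
  # bit-identical rerun under the same config
  sw2 <- nested_loo_sweep(fx$ft, fx$pre, fx$sp, cfgp)
  expect_identical(sw$metrics, sw2$metrics)
  expect_identical(sw$probabilities, sw2$probabilities)
})

test_that("held-out patients are excluded from their own fold's training", {
  fx <- sweep_fixture()
  labeled <- which(!is.na(fx$ft$label))
  for (f in seq_along(labeled))
    expect_false(labeled[f] %in% setdiff(labeled, labeled[f]))
  # single-feature degenerate input still sweeps from the available count
  ft1 <- fx$ft
  ft1$clinical <- ft1$clinical[, 1:3]
  sw <- nested_loo_sweep(ft1, fx$pre, fx$sp,
                         predict_config(c_grid = 1, seed = 3))
  expect_identical(nrow(sw$metrics), 5L)       # 3 clinical + 2 loads
})

test_that("relapse association recovers trivial orderings", {
  set.seed(25)
  ilae <- c(1, 1, 1, 2, 2, 3, 4, 5)
  prob <- ilae / 10                      # strictly ordered by class
  relapse <- matrix(NA, 8, 4,
                    dimnames = list(NULL, paste0("relapse_year", 2:5)))
  relapse[1:5, 4] <- c(FALSE, FALSE, TRUE, TRUE, FALSE)
  relapse[1:5, 2] <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  res <- suppressWarnings(
    relapse_association(prob, relapse, ilae, n_perm = 199, n_resamples = 200,
                        seed = 31))
  expect_equal(res$spearman$statistic, 1)
  yr5 <- res$by_year[res$by_year$year == 5, ]
  expect_equal(yr5$n_relapse, 2)
  # identical distributions: one-tailed p >= 0.5
  same <- suppressWarnings(
    relapse_association(rep(c(0.2, 0.4), 4), relapse, rep(c(1, 2), 4),
                        n_perm = 199, n_resamples = 200, seed = 32))
  expect_true(all(same$by_year$p >= 0.5))
  # years with fewer than 2 patients in a group are skipped with a warning
  w <- testthat::capture_warnings(
    relapse_association(prob, relapse, ilae, n_perm = 99, n_resamples = 200,
                        seed = 33))
  expect_true(any(grepl("skipped", w)))
})
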