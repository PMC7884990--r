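#' Names of the 13 clinical covariates used as classifier features
#' @return character vector of length 13.
#' @export
clinical_features <- function() {
  c("age_onset", "age_surgery", "duration", "n_AEDs", "sex", "side", "HS",
    "MRI_abnormal", "GTCS_history", "febrile_seizures",
    "psychiatric_comorbidity", "family_history", "handedness")
}

#' Assemble the per-patient feature table
#'
#' Combines the 13 clinical covariates with the two network features
#' (presurgery and spared abnormality load; appended later, per training
#' fold) and the outcome labels. ILAE 2 patients keep their features and
#' ILAE class but carry no training label.
#'
#' @param clinical clinical covariate table (one row per patient).
#' @param outcomes outcome table from [assign_outcomes()] (or real data with
#'   the same columns).
#' @return list with `clinical` feature matrix, `ilae` class vector, `label`
#'   (1 = not seizure-free, 0 = seizure-free, NA = ILAE 2), relapse columns,
#'   and patient ids.
#' @export
feature_table <- function(clinical, outcomes) {
  stopifnot(identical(clinical$patient, outcomes$patient))
  feats <- as.matrix(clinical[, clinical_features()])
  rownames(feats) <- clinical$patient
  label <- ifelse(outcomes$label == "not_seizure_free", 1L,
                  ifelse(outcomes$label == "seizure_free", 0L, NA_integer_))
  relapse <- as.matrix(outcomes[, paste0("relapse_year", 2:5)])
  list(clinical = feats, ilae = outcomes$ilae_year1, label = label,
       relapse = relapse, patient = clinical$patient)
}

# Platt sigmoid calibration: fit P(y=1|f) = 1/(1+exp(A f + B)) on training
# decision values by Newton steps on the cross-entropy, with Platt's smoothed
# targets to keep A finite on separable folds.
platt_fit <- function(decision, label) {
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  t1 <- (n1 + 1) / (n1 + 2); t0 <- 1 / (n0 + 2)
  t <- ifelse(label == 1, t1, t0)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  for (it in 1:100) {
    fApB <- decision * A + B
    p <- 1 / (1 + exp(fApB))          # predicted P(y=1)
    d1 <- t - p                        # gradient pieces (Platt 1999 signs)
    g1 <- sum(decision * d1); g2 <- sum(d1)
    h <- p * (1 - p)
    h11 <- sum(decision^2 * h) + 1e-12
    h22 <- sum(h) + 1e-12
    h21 <- sum(decision * h)
    det <- h11 * h22 - h21^2
    if (abs(det) < 1e-12) break
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    A <- A + dA; B <- B + dB
    if (max(abs(dA), abs(dB)) < 1e-10) break
  }
  c(A = A, B = B)
}

platt_predict <- function(ab, decision) 1 / (1 + exp(decision * ab["A"] + ab["B"]))

# stratified k-fold assignment, seeded
stratified_folds <- function(label, k, seed) {
  with_seed(seed, {
    fold <- integer(length(label))
    for (cl in unique(label)) {
      idx <- sample(which(label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# fit a linear max-margin classifier; returns weights, intercept and a
# decision function oriented so positive values favor class 1
linear_svm_fit <- function(xs, label, cost, class_weights) {
  yf <- factor(label, levels = c(0, 1))
  model <- e1071::svm(xs, yf, kernel = "linear", cost = cost, scale = FALSE,
                      class.weights = class_weights)
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  # libsvm orients the decision value towards the first class seen in the
  # data; flip so that larger decision values always mean class "1"
  flip <- if (model$labels[1] == 2) 1 else -1
  list(w = flip * w, b = flip * b,
       decision = function(newx) flip * drop(newx %*% w + b))
}

#' Train one outer-fold model
#'
#' On the training patients only: selects the most discriminatory
#' `(tau_z, tau_p)` pair per network kind via [select_threshold_pair()],
#' standardizes features with training-fold statistics, tunes the SVM
#' regularization parameter `C` on an inner stratified cross-validation by
#' validation AUC, fits the linear max-margin classifier (inverse
#' class-frequency weights by default), and fits a Platt sigmoid on the
#' training decision values.
#'
#' @param features numeric feature matrix (training patients x features;
#'   clinical columns plus `presurgery_load` / `spared_load` when present).
#' @param label binary training labels (both classes required).
#' @param config list of options; see [predict_config()].
#' @param seed seed for the inner fold assignment.
#' @return A `fold_model` with scaling, weights `w`, intercept, chosen `C`,
#'   calibration parameters and normalized importances.
#' @export
fold_train <- function(features, label, config = predict_config(),
                       seed = config$seed) {
  if (length(unique(label)) < 2)
    stop("training fold must contain both classes", call. = FALSE)
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(features, mu, sdv)
  cw <- if (config$class_weights) {
    tab <- table(factor(label, c(0, 1)))
    w <- sum(tab) / (2 * tab)
    stats::setNames(as.numeric(w), names(tab))
  } else c("0" = 1, "1" = 1)

  c_grid <- config$c_grid
  if (length(c_grid) > 1) {
    k <- min(config$inner_folds, min(table(label)))
    k <- max(k, 2)
    fold <- stratified_folds(label, k, seed)
    inner_auc <- vapply(c_grid, function(cc) {
      aucs <- vapply(seq_len(k), function(f) {
        tr <- fold != f; va <- !tr
        if (length(unique(label[tr])) < 2 || length(unique(label[va])) < 2)
          return(NA_real_)
        m <- linear_svm_fit(xs[tr, , drop = FALSE], label[tr], cc, cw)
        auc_rank(m$decision(xs[va, , drop = FALSE]), label[va])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best_c <- c_grid[which.max(inner_auc)]   # ties -> smallest C
  } else best_c <- c_grid

  m <- linear_svm_fit(xs, label, best_c, cw)
  dec_train <- m$decision(xs)
  ab <- platt_fit(dec_train, label)
  imp <- abs(m$w)
  if (max(imp) > 0) imp <- imp / max(imp)
  structure(list(center = mu, scale = sdv, w = m$w, b = m$b, C = best_c,
                 calibration = ab, importances = imp,
                 features = colnames(features)),
            class = "fold_model")
}

#' Predict calibrated probability of a not-seizure-free outcome
#' @param model a `fold_model` from [fold_train()].
#' @param newx feature matrix on the original scale (columns as trained).
#' @return probability vector in `[0, 1]`.
#' @export
predict_prob <- function(model, newx) {
  newx <- newx[, model$features, drop = FALSE]
  dec <- drop(scale(newx, model$center, model$scale) %*% model$w + model$b)
  unname(platt_predict(model$calibration, dec))
}

#' Options for the outcome-prediction sweep
#'
#' @param c_grid candidate SVM regularization parameters (default 13
#'   log-spaced points from 1e-3 to 1e3).
#' @param inner_folds inner stratified CV folds for tuning C (default 5).
#' @param class_weights use inverse class-frequency weights (default TRUE).
#' @param threshold_direction abnormal-link direction switch passed to the
#'   load-grid computation.
#' @param seed base seed; every stochastic step derives from it.
#' @return named list of options.
#' @export
predict_config <- function(c_grid = 10^seq(-3, 3, length.out = 13),
                           inner_folds = 5, class_weights = TRUE,
                           threshold_direction = "abs", seed = 1L) {
  list(c_grid = c_grid, inner_folds = inner_folds,
       class_weights = class_weights,
       threshold_direction = threshold_direction, seed = as.integer(seed))
}

#' Nested leave-one-out outcome prediction with recursive feature elimination
#'
#' Outer leave-one-out over the labeled patients (ILAE 1 and ILAE 3-5 only;
#' ILAE 2 patients are excluded from training and the outer loop but are
#' scored by averaging all outer-fold models' probabilities). Within each
#' outer fold the abnormality thresholds are re-selected, features re-scaled,
#' and C re-tuned on the training patients alone, so the held-out patient
#' never influences its own model. The sweep starts with all features and
#' repeatedly drops the feature with the smallest mean importance (mean |w|
#' across outer folds, ties broken by feature index) until one remains.
#'
#' @param ft feature table from [feature_table()].
#' @param pre_grids,spared_grids per-patient abnormality-load grids
#'   ([load_grid()]) for the presurgery and spared networks.
#' @param config a [predict_config()].
#' @param grid the [threshold_grid()] the load grids were computed on.
#' @return A `prediction_sweep`: per-step metrics (`auc`, `accuracy`,
#'   `sensitivity`, `specificity`), per-step per-patient probabilities
#'   (labeled and ILAE 2 patients), mean importance matrix, the elimination
#'   order, and per-step selected thresholds.
#' @export
nested_loo_sweep <- function(ft, pre_grids, spared_grids,
                             config = predict_config(),
                             grid = threshold_grid()) {
  labeled <- which(!is.na(ft$label))
  if (length(unique(ft$label[labeled])) < 2 || length(labeled) < 4)
    stop("need at least 2 labeled patients per class", call. = FALSE)
  ilae2 <- which(is.na(ft$label))
  np <- length(ft$patient)
  all_features <- c(colnames(ft$clinical), "presurgery_load", "spared_load")
  active <- all_features
  n_steps <- length(active)
  metrics <- data.frame(step = seq_len(n_steps), n_features = NA_integer_,
                        auc = NA_real_, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_)
  prob_mat <- matrix(NA_real_, np, n_steps,
                     dimnames = list(ft$patient, NULL))
  imp_mat <- matrix(NA_real_, length(all_features), n_steps,
                    dimnames = list(all_features, NULL))
  eliminated <- character(0)

  # Threshold selection depends only on the training patients, not on the
  # active feature subset, so compute it once per outer fold.
  fold_cache <- lapply(seq_along(labeled), function(f) {
    test_i <- labeled[f]
    train_i <- setdiff(labeled, test_i)
    stopifnot(!test_i %in% train_i)          # leakage guard
    lab_tr <- ft$label[train_i]
    sel_pre <- select_threshold_pair(pre_grids[train_i], lab_tr, grid)
    sel_sp <- select_threshold_pair(spared_grids[train_i], lab_tr, grid)
    feat_all <- cbind(
      ft$clinical,
      presurgery_load = vapply(pre_grids, function(g)
        as.numeric(g[sel_pre$i, sel_pre$j]), numeric(1)),
      spared_load = vapply(spared_grids, function(g)
        as.numeric(g[sel_sp$i, sel_sp$j]), numeric(1)))
    list(test_i = test_i, train_i = train_i, lab_tr = lab_tr,
         features = feat_all,
         thresholds = c(pre_tz = sel_pre$tau_z, pre_tp = sel_pre$tau_p,
                        sp_tz = sel_sp$tau_z, sp_tp = sel_sp$tau_p))
  })
  thresholds <- t(vapply(fold_cache, `[[`, numeric(4), "thresholds"))

  for (step in seq_len(n_steps)) {
    nf <- length(active)
    probs <- rep(NA_real_, length(labeled))
    imp_step <- matrix(0, nf, length(labeled), dimnames = list(active, NULL))
    prob_ilae2 <- matrix(0, length(ilae2), length(labeled))
    for (f in seq_along(labeled)) {
      fc <- fold_cache[[f]]
      feat_all <- fc$features
      fm <- fold_train(feat_all[fc$train_i, active, drop = FALSE], fc$lab_tr,
                       config, seed = derive_seed(config$seed,
                                                  step * 1000 + f))
      probs[f] <- predict_prob(fm, feat_all[fc$test_i, , drop = FALSE])
      imp_step[, f] <- fm$importances
      if (length(ilae2))
        prob_ilae2[, f] <- predict_prob(fm, feat_all[ilae2, , drop = FALSE])
    }
    lab <- ft$label[labeled]
    cm <- classification_metrics(probs, lab)
    metrics[step, ] <- list(step, nf, cm$auc, cm$accuracy, cm$sensitivity,
                            cm$specificity)
    prob_mat[labeled, step] <- probs
    if (length(ilae2)) prob_mat[ilae2, step] <- rowMeans(prob_ilae2)
    mean_imp <- rowMeans(imp_step)
    if (max(mean_imp) > 0) mean_imp <- mean_imp / max(mean_imp)
    imp_mat[active, step] <- mean_imp
    if (nf > 1) {
      drop_idx <- which(mean_imp == min(mean_imp))[1]  # ties: lowest index
      eliminated <- c(eliminated, active[drop_idx])
      active <- active[-drop_idx]
    }
  }
  structure(list(metrics = metrics, probabilities = prob_mat,
                 importances = imp_mat, eliminated = eliminated,
                 final_feature = active, thresholds = thresholds,
                 labeled = labeled, ilae2 = ilae2, config = config),
            class = "prediction_sweep")
}

#' @export
print.prediction_sweep <- function(x, ...) {
  cat(sprintf("nested LOO sweep: %d steps, mean AUC %.3f (best %.3f at %d features)\n",
              nrow(x$metrics), mean(x$metrics$auc),
              max(x$metrics$auc),
              x$metrics$n_features[which.max(x$metrics$auc)]))
  invisible(x)
}

#' Classification metrics for probabilistic predictions
#'
#' AUC is rank-based (tied scores contribute 1/2); sensitivity is the recall
#' of the not-seizure-free (positive) class, specificity the recall of the
#' seizure-free class, at the given probability threshold.
#'
#' @param prob probabilities of the positive class.
#' @param label binary labels (both classes required).
#' @param threshold classification cut-off (default 0.5).
#' @return list with `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(prob, label, threshold = 0.5) {
  label <- as.integer(label)
  if (length(unique(label)) < 2)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  pred <- as.integer(prob >= threshold)
  list(auc = auc_rank(prob, label),
       accuracy = mean(pred == label),
       sensitivity = mean(pred[label == 1] == 1),
       specificity = mean(pred[label == 0] == 0))
}

#' Association of predicted relapse likelihood with outcomes and relapse
#'
#' Correlates the predicted probabilities with the ILAE class at year 1
#' (Spearman, plus a robust-slope permutation test of the trend), and for
#' each follow-up year compares relapse vs no-relapse patients (ILAE 1-2 at
#' year 1 only) by one-tailed exact rank-sum (relapse > no relapse) with
#' Cohen's d and BCa confidence intervals on the group medians.
#'
#' @param prob per-patient probabilities (typically from the spared-load-only
#'   sweep step).
#' @param relapse logical matrix patients x years (`relapse_year2` ..
#'   `relapse_year5`; NA = censored or not applicable).
#' @param ilae ILAE class 1-5 at year 1 per patient.
#' @param n_perm permutations for the slope test.
#' @param n_resamples bootstrap resamples for the median CIs.
#' @param seed RNG seed.
#' @return list with `spearman` (`stat_result`), `slope_perm`
#'   (`stat_result`), and `by_year`, a data.frame of yearly rank-sum results;
#'   years with fewer than 2 patients in either group are skipped with a
#'   warning.
#' @export
relapse_association <- function(prob, relapse, ilae, n_perm = 1000,
                                n_resamples = 10000, seed = NULL) {
  stopifnot(length(prob) == length(ilae), nrow(relapse) == length(prob))
  sp <- spearman_rho(prob, as.numeric(ilae))
  slope <- permutation_slope_test(as.numeric(ilae), prob, n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL
                                         else derive_seed(seed, 11))
  eligible <- ilae <= 2
  rows <- list()
  for (y in 2:5) {
    rl <- relapse[, paste0("relapse_year", y)]
    rel <- eligible & !is.na(rl) & rl
    norel <- eligible & !is.na(rl) & !rl
    if (sum(rel) < 2 || sum(norel) < 2) {
      warning(sprintf("year %d skipped: fewer than 2 patients in a group", y))
      next
    }
    rs <- ranksum_exact(prob[rel], prob[norel], alternative = "greater")
    d <- cohen_d(prob[rel], prob[norel])
    ci_rel <- bootstrap_ci_bca(prob[rel], stats::median, n_resamples,
                               seed = if (is.null(seed)) NULL
                                      else derive_seed(seed, 20 + y))
    ci_norel <- bootstrap_ci_bca(prob[norel], stats::median, n_resamples,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed, 30 + y))
    rows[[length(rows) + 1]] <- data.frame(
      year = y, n_relapse = sum(rel), n_norelapse = sum(norel),
      median_relapse = stats::median(prob[rel]),
      median_norelapse = stats::median(prob[norel]),
      median_relapse_lo = ci_rel[1], median_relapse_hi = ci_rel[2],
      median_norelapse_lo = ci_norel[1], median_norelapse_hi = ci_norel[2],
      p = rs$p, d = d)
  }
  list(spearman = sp, slope_perm = slope,
       by_year = if (length(rows)) do.call(rbind, rows) else
         data.frame())
}
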