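#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the study design the pipeline was built for: a
#' normative control cohort, a patient cohort with abnormal subnetworks
#' planted around a small set of nodes concentrated in the ipsilateral
#' temporal lobe, a temporal-lobe resection per patient, thirteen clinical
#' covariates, and seizure outcome / relapse labels driven by the abnormality
#' that the resection fails to remove.
#'
#' All randomness is governed by `seed`; the same seed reproduces the cohort
#' exactly.
#'
#' @param n_nodes number of parcellation nodes (default 114; 82 mimics a
#'   coarser atlas).
#' @param n_controls,n_patients cohort sizes (defaults 29 and 51).
#' @param scaffold_density fraction of node pairs carrying a shared-scaffold
#'   edge. The default (0.96) is deliberately dense: node degrees must be
#'   large relative to the planted set for node-level recovery to be
#'   identifiable at the percentage threshold (see the methods vignette).
#' @param edge_dropout per-subject probability that an existing scaffold edge
#'   is absent from that subject's network.
#' @param gfa_mean_range,gfa_sd_range intervals from which each edge's
#'   population gFA mean and SD are drawn (gFA lives in (0,1)).
#' @param planted_nodes_per_patient number of abnormal nodes planted per
#'   patient (default 8).
#' @param planted_effect shift of the gFA mean on every edge incident to a
#'   planted node, in units of that edge's population SD (default 4).
#' @param planted_sign -1 (default) shifts planted edges downwards (reduced
#'   anisotropy, as in epilepsy), +1 upwards.
#' @param plant_temporal_weight sampling weight of ipsilateral temporal nodes
#'   when drawing planted nodes (non-temporal nodes have weight 1); controls
#'   how much of the planted abnormality the resection removes.
#' @param resection_area area label whose ipsilateral nodes are resected
#'   (default "temporal", an anterior temporal lobe resection).
#' @param passthrough_fraction fraction of non-incident edges additionally
#'   marked surgery-affected (streamlines passing through the cavity).
#' @param outcome_coefs named numeric: `intercept`, `spared_load`,
#'   `age_surgery`, `n_AEDs` -- linear predictor of the ordinal outcome model
#'   (age and AED count enter standardized).
#' @param outcome_cutpoints four increasing cut-points mapping the latent
#'   outcome score to ILAE classes 1-5.
#' @param relapse_coefs named numeric: `intercept`, `spared_load` -- yearly
#'   relapse hazard (logistic) for patients at ILAE 1-2 at year 1.
#' @param followup_probs probabilities that a patient's follow-up ends at
#'   years 2, 3, 4, 5.
#' @param seed integer seed fully determining the cohort.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_nodes = 114,
                             n_controls = 29,
                             n_patients = 51,
                             scaffold_density = 0.96,
                             edge_dropout = 0.04,
                             gfa_mean_range = c(0.35, 0.65),
                             gfa_sd_range = c(0.02, 0.05),
                             planted_nodes_per_patient = 8,
                             planted_effect = 4,
                             planted_sign = -1,
                             plant_temporal_weight = 12,
                             resection_area = "temporal",
                             passthrough_fraction = 0.05,
                             outcome_coefs = c(intercept = -4.0,
                                               spared_load = 1.5,
                                               age_surgery = 0.25,
                                               n_AEDs = 0.25),
                             outcome_cutpoints = c(1.2, 2.6, 4.2, 5.4),
                             relapse_coefs = c(intercept = -3.2,
                                               spared_load = 0.5),
                             followup_probs = c(0.12, 0.16, 0.12, 0.60),
                             seed = 1L) {
  chk_int <- function(x, field, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
        x != round(x)) stop_field(field, sprintf("must be an integer >= %s", min))
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop_field(field, "must be a probability in [0,1]")
  }
  chk_int(n_nodes, "n_nodes", 12); chk_int(n_controls, "n_controls", 2)
  chk_int(n_patients, "n_patients", 1)
  chk_prob(scaffold_density, "scaffold_density")
  chk_prob(edge_dropout, "edge_dropout")
  chk_prob(passthrough_fraction, "passthrough_fraction")
  rng_ok <- function(r, field) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0 ||
        r[2] >= 1) stop_field(field, "must be an interval inside (0,1)")
  }
  rng_ok(gfa_mean_range, "gfa_mean_range"); rng_ok(gfa_sd_range, "gfa_sd_range")
  chk_int(planted_nodes_per_patient, "planted_nodes_per_patient", 0)
  if (!is.numeric(planted_effect) || planted_effect < 0)
    stop_field("planted_effect", "must be a nonnegative number (sigma units)")
  if (!planted_sign %in% c(-1, 1))
    stop_field("planted_sign", "must be -1 or +1")
  if (plant_temporal_weight < 1)
    stop_field("plant_temporal_weight", "must be >= 1")
  areas <- c("temporal", "subcortical", "parietal", "occipital", "frontal",
             "cingulate")
  if (!resection_area %in% areas)
    stop_field("resection_area", paste("must be one of", paste(areas, collapse = ", ")))
  need <- function(x, nm, field) {
    if (!all(nm %in% names(x))) stop_field(field, paste("needs names", paste(nm, collapse = ", ")))
  }
  need(outcome_coefs, c("intercept", "spared_load", "age_surgery", "n_AEDs"),
       "outcome_coefs")
  need(relapse_coefs, c("intercept", "spared_load"), "relapse_coefs")
  if (length(outcome_cutpoints) != 4 || is.unsorted(outcome_cutpoints, strictly = TRUE))
    stop_field("outcome_cutpoints", "must be 4 strictly increasing values")
  if (length(followup_probs) != 4 || any(followup_probs < 0) ||
      abs(sum(followup_probs) - 1) > 1e-8)
    stop_field("followup_probs", "must be 4 probabilities summing to 1")
  chk_int(seed, "seed", 0)
  structure(list(
    n_nodes = as.integer(n_nodes), n_controls = as.integer(n_controls),
    n_patients = as.integer(n_patients),
    scaffold_density = scaffold_density, edge_dropout = edge_dropout,
    gfa_mean_range = gfa_mean_range, gfa_sd_range = gfa_sd_range,
    planted_nodes_per_patient = as.integer(planted_nodes_per_patient),
    planted_effect = planted_effect, planted_sign = planted_sign,
    plant_temporal_weight = plant_temporal_weight,
    resection_area = resection_area,
    passthrough_fraction = passthrough_fraction,
    outcome_coefs = outcome_coefs, outcome_cutpoints = outcome_cutpoints,
    relapse_coefs = relapse_coefs, followup_probs = followup_probs,
    seed = as.integer(seed)), class = "generator_config")
}

# Node metadata for a synthetic parcellation: two hemispheres, six areas with
# proportions loosely following a 114-region cortical+subcortical atlas
# (per hemisphere: temporal 16, frontal 15, subcortical 9, parietal 8,
# occipital 6, cingulate 3, scaled to n_nodes).
make_nodes <- function(n_nodes) {
  base <- c(temporal = 16, frontal = 15, subcortical = 9, parietal = 8,
            occipital = 6, cingulate = 3)
  per_hemi <- c(floor(n_nodes / 2), ceiling(n_nodes / 2))
  out <- lapply(seq_along(per_hemi), function(h) {
    n_h <- per_hemi[h]
    raw <- base / sum(base) * n_h
    cnt <- floor(raw)
    rem <- n_h - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    cnt <- pmax(cnt, 1L)
    while (sum(cnt) > n_h) { i <- which.max(cnt); cnt[i] <- cnt[i] - 1L }
    hemi <- c("left", "right")[h]
    area <- rep(names(cnt), cnt)
    data.frame(
      label = sprintf("%s_%s_%02d", substr(hemi, 1, 1), area,
                      unlist(lapply(cnt, seq_len))),
      hemisphere = hemi, area = area, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Shared population scaffold: which node pairs can carry an edge, and each
# edge's population gFA mean/SD and streamline log-normal location.
make_scaffold <- function(cfg) {
  nodes <- make_nodes(cfg$n_nodes)
  n <- cfg$n_nodes
  with_seed(derive_seed(cfg$seed, 1), {
    ut <- upper.tri(matrix(0, n, n))
    present <- matrix(FALSE, n, n)
    present[ut] <- stats::runif(sum(ut)) < cfg$scaffold_density
    present <- present | t(present)
    mu <- sig <- slog <- matrix(NA_real_, n, n)
    m <- stats::runif(sum(ut), cfg$gfa_mean_range[1], cfg$gfa_mean_range[2])
    s <- stats::runif(sum(ut), cfg$gfa_sd_range[1], cfg$gfa_sd_range[2])
    l <- stats::rnorm(sum(ut), 3, 0.8)
    mu[ut] <- m; sig[ut] <- s; slog[ut] <- l
    mu[lower.tri(mu)] <- t(mu)[lower.tri(mu)]
    sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
    slog[lower.tri(slog)] <- t(slog)[lower.tri(slog)]
    mu[!present] <- sig[!present] <- slog[!present] <- NA_real_
    lab <- nodes$label
    dimnames(present) <- dimnames(mu) <- dimnames(sig) <- dimnames(slog) <-
      list(lab, lab)
    list(nodes = nodes, present = present, mu = mu, sigma = sig,
         streamline_meanlog = slog)
  })
}

# Normal truncated to (0,1), sampled by inverse CDF (exact, vectorized).
rtrunc01 <- function(mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(length(mean), lo, hi), mean, sd)
}

# Draw one subject from the scaffold model; mean_shift is an optional matrix
# added to the population gFA means (used to plant abnormalities).
draw_subject <- function(cfg, scaffold, mean_shift = NULL) {
  n <- cfg$n_nodes
  ut <- upper.tri(matrix(0, n, n)) & scaffold$present
  keep <- ut & matrix(stats::runif(n * n) >= cfg$edge_dropout, n, n)
  mu <- scaffold$mu
  if (!is.null(mean_shift)) mu <- mu + mean_shift
  gfa <- matrix(NA_real_, n, n)
  gfa[keep] <- rtrunc01(mu[keep], scaffold$sigma[keep])
  sc <- matrix(0L, n, n)
  sc[keep] <- as.integer(round(exp(stats::rnorm(sum(keep),
                                                scaffold$streamline_meanlog[keep],
                                                0.4)))) + 1L
  gfa[lower.tri(gfa)] <- t(gfa)[lower.tri(gfa)]
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  connectome(gfa, sc, scaffold$nodes)
}

#' Generate the control cohort
#'
#' Draws `cfg$n_controls` subjects from the shared scaffold model: each
#' scaffold edge is present in a subject with probability
#' `1 - edge_dropout`, and present edges carry gFA weights drawn from the
#' edge's population normal distribution truncated to (0,1).
#'
#' @param cfg a [generator_config()].
#' @param scaffold shared scaffold as built internally by [simulate_cohort()];
#'   if `NULL`, one is derived from `cfg`.
#' @return list of [connectome()] objects.
#' @export
generate_controls <- function(cfg, scaffold = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(scaffold)) scaffold <- make_scaffold(cfg)
  with_seed(derive_seed(cfg$seed, 2),
            lapply(seq_len(cfg$n_controls), function(i) draw_subject(cfg, scaffold)))
}

#' Generate one synthetic patient with planted abnormalities
#'
#' The patient is drawn from the control generative model, except that every
#' scaffold edge incident to a planted node has its population gFA mean
#' shifted by `planted_sign * planted_effect` SDs. The resection removes all
#' edges incident to ipsilateral `resection_area` nodes plus a
#' `passthrough_fraction` random sample of the remaining present edges.
#'
#' @param cfg a [generator_config()].
#' @param scaffold shared scaffold (see [generate_controls()]).
#' @param planted_nodes character vector of node labels to plant.
#' @param surgery_side `"left"` or `"right"`.
#' @param seed seed for this patient's draw.
#' @return list with elements `connectome`, `resection` (a
#'   [resection_effect()]), and `truth` (planted sets plus the true spared
#'   abnormality load).
#' @export
generate_patient <- function(cfg, scaffold, planted_nodes,
                             surgery_side = "left", seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  lab <- scaffold$nodes$label
  bad <- setdiff(planted_nodes, lab)
  if (length(bad))
    stop(sprintf("planted node(s) outside parcellation: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!surgery_side %in% c("left", "right"))
    stop("surgery_side must be 'left' or 'right'", call. = FALSE)
  n <- cfg$n_nodes
  shift_mag <- cfg$planted_sign * cfg$planted_effect * scaffold$sigma
  idx <- lab %in% planted_nodes
  shift <- matrix(0, n, n)
  shift[idx, ] <- shift_mag[idx, ]
  shift[, idx] <- shift_mag[, idx]   # symmetric; incident edges shifted once
  shift[is.na(shift)] <- 0

  with_seed(seed, {
    conn <- draw_subject(cfg, scaffold, mean_shift = shift)
    present <- conn$streamline > 0
    resected_nodes <- lab[scaffold$nodes$area == cfg$resection_area &
                            scaffold$nodes$hemisphere == surgery_side]
    inc <- lab %in% resected_nodes
    aff_mask <- present & (matrix(inc, n, n) | matrix(inc, n, n, byrow = TRUE))
    other <- which(present & upper.tri(present) & !aff_mask)
    n_pass <- round(cfg$passthrough_fraction * length(other))
    if (n_pass > 0) {
      pick <- sample(other, n_pass)
      aff_mask[pick] <- TRUE
      aff_mask[cbind(col(aff_mask)[pick], row(aff_mask)[pick])] <- TRUE
    }
    aff_idx <- which(aff_mask & upper.tri(aff_mask), arr.ind = TRUE)
    affected <- data.frame(node_a = lab[aff_idx[, 1]], node_b = lab[aff_idx[, 2]],
                           stringsAsFactors = FALSE)
    effect <- resection_effect(affected, side = surgery_side, labels = lab)

    planted_mask <- present & (matrix(idx, n, n) | matrix(idx, n, n, byrow = TRUE))
    pl_idx <- which(planted_mask & upper.tri(planted_mask), arr.ind = TRUE)
    planted_edges <- data.frame(node_a = lab[pl_idx[, 1]],
                                node_b = lab[pl_idx[, 2]],
                                stringsAsFactors = FALSE)
    # True spared abnormality load: planted nodes for which at least 10% of
    # their present edges survive the resection as (truly) abnormal links.
    surviving <- planted_mask & !aff_mask
    deg <- rowSums(present)
    frac <- ifelse(deg > 0, rowSums(surviving) / deg, 0)
    true_spared <- lab[idx & frac >= 0.10]
    truth <- list(planted_nodes = planted_nodes,
                  planted_edges = planted_edges,
                  true_spared_nodes = true_spared,
                  true_spared_load = length(true_spared),
                  surgery_side = surgery_side)
    list(connectome = conn, resection = effect, truth = truth)
  })
}

#' Assign ILAE outcomes and yearly relapse labels from ground truth
#'
#' Ordinal-latent outcome model: the latent score is the linear predictor
#' (intercept + slopes on true spared load and standardized age at surgery /
#' AED count) plus standard-logistic noise; fixed cut-points map it to ILAE
#' classes 1-5. For patients at ILAE 1-2 at year 1, a yearly relapse hazard
#' `plogis(intercept + slope * spared load)` generates the first relapse year
#' over years 2-5, truncated by each patient's follow-up duration.
#'
#' @param truths list of per-patient ground-truth lists (see
#'   [generate_patient()]).
#' @param clinical clinical covariate table with one row per patient.
#' @param cfg a [generator_config()].
#' @param seed seed (defaults to a stream derived from `cfg$seed`).
#' @return data.frame: `patient`, `ilae_year1`, `label`
#'   (`seizure_free` / `not_seizure_free` / `ilae2`), `followup_years`,
#'   `relapse_year2` .. `relapse_year5` (logical, `NA` once censored), and the
#'   latent score.
#' @export
assign_outcomes <- function(truths, clinical, cfg,
                            seed = derive_seed(cfg$seed, 4)) {
  stopifnot(inherits(cfg, "generator_config"))
  np <- length(truths)
  if (nrow(clinical) != np)
    stop("one clinical row per patient is required", call. = FALSE)
  load <- vapply(truths, function(t) t$true_spared_load, numeric(1))
  oc <- cfg$outcome_coefs
  eta <- oc[["intercept"]] + oc[["spared_load"]] * load +
    oc[["age_surgery"]] * (clinical$age_surgery - 30) / 10 +
    oc[["n_AEDs"]] * (clinical$n_AEDs - 2.5)
  with_seed(seed, {
    latent <- eta + stats::rlogis(np)
    ilae <- findInterval(latent, cfg$outcome_cutpoints) + 1L
    followup <- sample(2:5, np, replace = TRUE, prob = cfg$followup_probs)
    rc <- cfg$relapse_coefs
    hazard <- stats::plogis(rc[["intercept"]] + rc[["spared_load"]] * load)
    relapse <- matrix(NA, np, 4, dimnames = list(NULL, paste0("relapse_year", 2:5)))
    for (i in seq_len(np)) {
      if (ilae[i] > 2) next              # relapse defined only for ILAE 1-2
      first <- Inf
      for (y in 2:5) if (stats::runif(1) < hazard[i]) { first <- y; break }
      for (y in 2:5) {
        if (y > followup[i] && first > followup[i]) break  # censored
        relapse[i, y - 1] <- first <= y
      }
    }
    data.frame(patient = clinical$patient,
               ilae_year1 = ilae,
               label = ifelse(ilae == 1, "seizure_free",
                              ifelse(ilae >= 3, "not_seizure_free", "ilae2")),
               followup_years = followup,
               relapse, latent = latent,
               stringsAsFactors = FALSE)
  })
}

# 13 clinical covariates: 9 named epilepsy variables + 4 generic fillers.
make_clinical <- function(cfg, seed = derive_seed(cfg$seed, 3)) {
  np <- cfg$n_patients
  with_seed(seed, {
    age_onset <- round(pmax(1, stats::rnorm(np, 14, 7)), 1)
    duration <- round(pmax(1, stats::rnorm(np, 18, 9)), 1)
    data.frame(
      patient = sprintf("patient_%02d", seq_len(np)),
      age_onset = age_onset,
      age_surgery = round(age_onset + duration, 1),
      duration = duration,
      n_AEDs = 1L + stats::rpois(np, 1.4),
      sex = stats::rbinom(np, 1, 0.5),
      side = stats::rbinom(np, 1, 0.5),          # 1 = right surgery
      HS = stats::rbinom(np, 1, 0.6),
      MRI_abnormal = stats::rbinom(np, 1, 0.8),
      GTCS_history = stats::rbinom(np, 1, 0.45),
      febrile_seizures = stats::rbinom(np, 1, 0.3),
      psychiatric_comorbidity = stats::rbinom(np, 1, 0.25),
      family_history = stats::rbinom(np, 1, 0.15),
      handedness = stats::rbinom(np, 1, 0.9),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates the generator end to end: shared scaffold, control cohort,
#' clinical table, per-patient planted nodes (sampled with extra weight on
#' nodes of the to-be-resected ipsilateral temporal lobe), patient networks
#' with resection-affected edge sets, and outcome/relapse labels derived from
#' the true spared abnormality load.
#'
#' @param cfg a [generator_config()].
#' @return list with `cfg`, `nodes`, `controls` (list of connectomes),
#'   `patients` (per patient: `connectome`, `resection`, `truth`), `clinical`,
#'   and `outcomes`.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  scaffold <- make_scaffold(cfg)
  controls <- generate_controls(cfg, scaffold)
  clinical <- make_clinical(cfg)
  lab <- scaffold$nodes$label
  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    side <- if (clinical$side[i] == 1) "right" else "left"
    planted <- with_seed(derive_seed(cfg$seed, 100 + i), {
      w <- ifelse(scaffold$nodes$area == cfg$resection_area &
                    scaffold$nodes$hemisphere == side,
                  cfg$plant_temporal_weight, 1)
      if (cfg$planted_nodes_per_patient == 0) character(0)
      else sample(lab, cfg$planted_nodes_per_patient, prob = w)
    })
    patients[[i]] <- generate_patient(cfg, scaffold, planted, side,
                                      seed = derive_seed(cfg$seed, 200 + i))
    patients[[i]]$id <- clinical$patient[i]
  }
  truths <- lapply(patients, `[[`, "truth")
  outcomes <- assign_outcomes(truths, clinical, cfg)
  list(cfg = cfg, nodes = scaffold$nodes, controls = controls,
       patients = patients, clinical = clinical, outcomes = outcomes)
}
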