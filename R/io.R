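# Matrices travel as TSV with node labels as header row and first column:
# human-diffable and atlas-size agnostic (114- or 82-node parcellations alike).

write_matrix_tsv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m)))
    stop(sprintf("%s: row and column labels differ", path), call. = FALSE)
  m
}

#' Read a connectome from delimited matrix files
#'
#' @param gfa_path TSV of mean-gFA edge weights (labeled square matrix).
#' @param streamline_path TSV of streamline counts (same order).
#' @param nodes_path TSV with columns `label`, `hemisphere`, `area`.
#' @return A validated [connectome()]; near-symmetric gFA input (within
#'   1e-9) is symmetrized by averaging with its transpose, larger asymmetry
#'   is an error.
#' @export
read_connectome <- function(gfa_path, streamline_path, nodes_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  gfa <- read_matrix_tsv(gfa_path)
  sc <- read_matrix_tsv(streamline_path)
  if (nrow(gfa) != nrow(nodes) || nrow(sc) != nrow(nodes))
    stop("matrix dimensions do not match the node table", call. = FALSE)
  check_same_nodes(nodes$label, rownames(gfa), "gFA matrix vs node table")
  check_same_nodes(nodes$label, rownames(sc), "streamline matrix vs node table")
  storage.mode(sc) <- "integer"
  connectome(gfa, sc, nodes)
}

write_connectome <- function(conn, gfa_path, streamline_path) {
  g <- conn$gfa
  g[is.na(g)] <- 0        # absent edges stored as 0 alongside streamline 0
  write_matrix_tsv(g, gfa_path)
  write_matrix_tsv(conn$streamline, streamline_path)
}

#' Read a surgery-affected edge list
#'
#' Tab-separated file with two node-label columns, one edge per row.
#'
#' @param path file path.
#' @param side resected side recorded on the returned object.
#' @param labels optional known node labels for validation.
#' @return A [resection_effect()].
#' @export
read_affected_edges <- function(path, side, labels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  resection_effect(df, side = side, labels = labels)
}

#' Write a synthetic cohort to a directory tree
#'
#' Layout: `nodes.tsv`, `clinical.csv`, `outcomes.csv`,
#' `ground_truth.json`, `controls/<id>.{gfa,streamline}.tsv` and
#' `patients/<id>.{gfa,streamline,affected_edges}.tsv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "controls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "patients"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$controls)) {
    id <- sprintf("control_%02d", i)
    write_connectome(cohort$controls[[i]],
                     file.path(dir, "controls", paste0(id, ".gfa.tsv")),
                     file.path(dir, "controls", paste0(id, ".streamline.tsv")))
  }
  for (p in cohort$patients) {
    write_connectome(p$connectome,
                     file.path(dir, "patients", paste0(p$id, ".gfa.tsv")),
                     file.path(dir, "patients", paste0(p$id, ".streamline.tsv")))
    utils::write.table(p$resection$edges,
                       file.path(dir, "patients",
                                 paste0(p$id, ".affected_edges.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- lapply(cohort$patients, function(p)
    c(p$truth[c("planted_nodes", "true_spared_nodes", "true_spared_load",
                "surgery_side")],
      list(planted_edges = p$truth$planted_edges)))
  names(truth) <- vapply(cohort$patients, `[[`, "", "id")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `nodes`, `clinical`, `outcomes`, `controls`, `patients`
#'   (each patient: `id`, `connectome`, `resection`) and, when present,
#'   `truth` parsed from `ground_truth.json`.
#' @export
read_cohort <- function(dir) {
  nodes_path <- file.path(dir, "nodes.tsv")
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"),
                              stringsAsFactors = FALSE)
  ctrl_files <- sort(list.files(file.path(dir, "controls"),
                                pattern = "\\.gfa\\.tsv$", full.names = TRUE))
  controls <- lapply(ctrl_files, function(f)
    read_connectome(f, sub("\\.gfa\\.tsv$", ".streamline.tsv", f), nodes_path))
  patients <- lapply(clinical$patient, function(id) {
    base <- file.path(dir, "patients", id)
    aff <- paste0(base, ".affected_edges.tsv")
    if (!file.exists(aff))
      stop(sprintf("missing affected-edge file for %s", id), call. = FALSE)
    side <- if (clinical$side[clinical$patient == id] == 1) "right" else "left"
    list(id = id,
         connectome = read_connectome(paste0(base, ".gfa.tsv"),
                                      paste0(base, ".streamline.tsv"),
                                      nodes_path),
         resection = read_affected_edges(aff, side, labels = nodes$label))
  })
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  list(nodes = nodes, clinical = clinical, outcomes = outcomes,
       controls = controls, patients = patients, truth = truth)
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Standardizes every patient against the controls, applies each patient's
#' resection, computes load grids, and runs the nested LOO prediction sweep,
#' writing result tables plus a provenance log (seed, config, stage timings)
#' under `out_dir`. Deterministic under a fixed seed.
#'
#' @param cohort_dir directory from [write_cohort()] (or equivalently
#'   structured real data).
#' @param out_dir output directory.
#' @param config a [predict_config()].
#' @param min_controls control-presence filter for z-scoring.
#' @return list with the intermediate objects (`reference`, `znets`,
#'   `spared`, `pre_grids`, `spared_grids`, `sweep`), invisibly.
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = predict_config(),
                         min_controls = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time(); timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }
  cohort <- read_cohort(cohort_dir); tick("read")
  ref <- build_reference(cohort$controls); tick("reference")
  stage <- function(what, id, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for %s: %s", what, id, conditionMessage(e)),
         call. = FALSE))
  znets <- lapply(cohort$patients, function(p)
    stage("zscore", p$id, z_score_network(p$connectome, ref, min_controls)))
  spared <- lapply(seq_along(znets), function(i)
    stage("spare", cohort$patients[[i]]$id,
          apply_resection(znets[[i]], cohort$patients[[i]]$resection)))
  tick("standardize")
  grid <- threshold_grid()
  pre_grids <- lapply(znets, load_grid, grid = grid,
                      direction = config$threshold_direction)
  spared_grids <- lapply(spared, load_grid, grid = grid,
                         direction = config$threshold_direction)
  tick("load_grids")
  ft <- feature_table(cohort$clinical, cohort$outcomes)
  sweep <- nested_loo_sweep(ft, pre_grids, spared_grids, config, grid)
  tick("predict")
  utils::write.table(sweep$metrics, file.path(out_dir, "sweep_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(patient = rownames(sweep$probabilities),
                              sweep$probabilities, check.names = FALSE),
                   file.path(out_dir, "probabilities.csv"), row.names = FALSE)
  utils::write.table(data.frame(feature = rownames(sweep$importances),
                                sweep$importances, check.names = FALSE),
                     file.path(out_dir, "importances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, min_controls = min_controls,
         c_grid = config$c_grid, inner_folds = config$inner_folds,
         class_weights = config$class_weights,
         threshold_direction = config$threshold_direction,
         timings_sec = timings),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, reference = ref, znets = znets,
                 spared = spared, pre_grids = pre_grids,
                 spared_grids = spared_grids, sweep = sweep))
}
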