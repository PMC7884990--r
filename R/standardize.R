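#' Build the per-edge control reference
#'
#' For every unordered node pair, records how many controls possess the edge
#' (streamline count > 0) and, over exactly those controls, the sample mean
#' and SD (n-1 denominator) of the edge's gFA weight. Absent edges are not
#' zero-imputed: deterministic tractography yields sparse networks and a
#' missing streamline is missing evidence, not a weight of zero.
#'
#' @param controls list of [connectome()] objects with identical node order.
#' @return A `control_reference`: matrices `count`, `mean`, `sd` (mean/SD are
#'   `NA` where fewer than 2 controls possess the edge) plus `n_controls` and
#'   the node table.
#' @export
build_reference <- function(controls) {
  if (length(controls) < 2)
    stop("at least 2 controls are required to build a reference", call. = FALSE)
  lab <- node_labels(controls[[1]])
  for (ct in controls[-1]) check_same_nodes(lab, node_labels(ct), "controls")
  n <- length(lab)
  present <- vapply(controls, function(ct) ct$streamline > 0,
                    matrix(TRUE, n, n))          # n x n x n_controls
  gfa <- vapply(controls, function(ct) ct$gfa, matrix(0, n, n))
  gfa[!present] <- NA_real_
  cnt <- apply(present, c(1, 2), sum)
  mu <- apply(gfa, c(1, 2), function(v) mean(v, na.rm = TRUE))
  sd_ <- apply(gfa, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  mu[cnt < 2] <- NA_real_
  sd_[cnt < 2] <- NA_real_
  mu[cnt == 0] <- NA_real_
  diag(cnt) <- 0L; diag(mu) <- diag(sd_) <- NA_real_
  dimnames(cnt) <- dimnames(mu) <- dimnames(sd_) <- list(lab, lab)
  structure(list(count = cnt, mean = mu, sd = sd_,
                 n_controls = length(controls),
                 nodes = controls[[1]]$nodes),
            class = "control_reference")
}

#' z-score a patient connectome against the control reference
#'
#' Each edge present in the patient whose equivalent connection exists in at
#' least `min_controls` controls (and whose control SD is positive) receives
#' `z = (w - mean) / sd`; all other pairs are invalid. Edges absent in the
#' patient are never scored: absence is not treated as abnormality. The
#' presurgical degree `k_i` (count of valid edges at node i) is fixed here
#' and carried unchanged into spared networks, so abnormality percentages
#' stay comparable before and after virtual resection.
#'
#' @param patient a [connectome()].
#' @param ref a `control_reference` from [build_reference()].
#' @param min_controls minimum number of edge-possessing controls required to
#'   score an edge (default 10, about 35% of a 29-control cohort).
#' @return A `znetwork`: matrices `z` and logical `valid`, vector `degree`
#'   (presurgical `k_i`), `kind = "presurgery"`, and the node table.
#' @export
z_score_network <- function(patient, ref, min_controls = 10) {
  stopifnot(inherits(ref, "control_reference"))
  if (min_controls > ref$n_controls)
    stop(sprintf("min_controls (%d) exceeds the number of controls (%d)",
                 min_controls, ref$n_controls), call. = FALSE)
  check_same_nodes(node_labels(patient), rownames(ref$count), "patient vs reference")
  valid <- patient$streamline > 0 & ref$count >= min_controls &
    !is.na(ref$sd) & ref$sd > 0
  z <- matrix(NA_real_, nrow(valid), ncol(valid), dimnames = dimnames(valid))
  z[valid] <- (patient$gfa[valid] - ref$mean[valid]) / ref$sd[valid]
  k <- rowSums(valid)
  names(k) <- rownames(valid)
  structure(list(z = z, valid = valid, degree = k, kind = "presurgery",
                 nodes = patient$nodes),
            class = "znetwork")
}

#' @export
print.znetwork <- function(x, ...) {
  cat(sprintf("znetwork (%s): %d nodes, %d valid edges\n",
              x$kind, nrow(x$z), sum(x$valid) / 2))
  invisible(x)
}
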