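#' The 2-D threshold grid for abnormality load
#'
#' z-score thresholds 2.1 to 4.5 in steps of 0.1 (25 values, generated by
#' integer indexing to avoid floating-point accumulation) crossed with
#' percentage thresholds 1% to 50% in steps of 1% (50 values).
#'
#' @return list with numeric vectors `tau_z` (length 25) and `tau_p`
#'   (length 50).
#' @export
threshold_grid <- function() {
  list(tau_z = (21:45) / 10, tau_p = as.numeric(1:50))
}

#' Per-node abnormality profile at a z threshold
#'
#' Counts, at each node, the valid links whose z-score exceeds `tau_z`
#' (by default in absolute value) and expresses the count as a percentage of
#' the node's presurgical degree `k_i`. Normalizing by the presurgical degree
#' keeps percentages comparable between presurgery and spared networks and
#' accounts for degree heterogeneity. Nodes with `k_i = 0` get 0%.
#'
#' @param zn a `znetwork`.
#' @param tau_z positive z threshold; a link is abnormal when
#'   `|z| >= tau_z` (inclusive).
#' @param direction `"abs"` (default), `"negative-only"` or
#'   `"positive-only"`: which tail of the z distribution counts as abnormal.
#' @return data.frame with `node`, abnormal link count `a`, presurgical
#'   degree `k`, and percentage `p` in `[0, 100]`.
#' @export
node_abnormality_profile <- function(zn, tau_z,
                                     direction = c("abs", "negative-only",
                                                   "positive-only")) {
  stopifnot(inherits(zn, "znetwork"), tau_z > 0)
  direction <- match.arg(direction)
  score <- switch(direction, "abs" = abs(zn$z), "negative-only" = -zn$z,
                  "positive-only" = zn$z)
  flag <- !is.na(score) & score >= tau_z & zn$valid
  a <- rowSums(flag)
  k <- zn$degree
  p <- ifelse(k > 0, 100 * a / k, 0)
  data.frame(node = rownames(zn$z), a = as.integer(a), k = as.integer(k),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Abnormality load at a percentage threshold
#'
#' A node is abnormal when its abnormality percentage is at least `tau_p`
#' (inclusive); the load is the number of abnormal nodes.
#'
#' @param profile output of [node_abnormality_profile()].
#' @param tau_p percentage threshold in (0, 100].
#' @return list with integer `load` and character `nodes` (the abnormal set).
#' @export
abnormality_load <- function(profile, tau_p) {
  stopifnot(tau_p > 0, tau_p <= 100)
  nodes <- profile$node[profile$p >= tau_p]
  list(load = length(nodes), nodes = nodes)
}

#' Abnormality load over the full threshold grid
#'
#' @param zn a `znetwork`.
#' @param grid a [threshold_grid()].
#' @param direction passed to [node_abnormality_profile()].
#' @return integer matrix `length(tau_z)` x `length(tau_p)` with dimnames the
#'   threshold values; entry (i, j) is the abnormality load at
#'   `(tau_z[i], tau_p[j])`. Non-increasing along both axes.
#' @export
load_grid <- function(zn, grid = threshold_grid(), direction = "abs") {
  stopifnot(inherits(zn, "znetwork"))
  tz <- grid$tau_z; tp <- grid$tau_p
  if (is.unsorted(tz, strictly = TRUE) || is.unsorted(tp, strictly = TRUE))
    stop("threshold grid values must be strictly increasing", call. = FALSE)
  score <- switch(direction, "abs" = abs(zn$z), "negative-only" = -zn$z,
                  "positive-only" = zn$z,
                  stop("unknown direction", call. = FALSE))
  score[!zn$valid | is.na(score)] <- -Inf
  k <- zn$degree
  out <- matrix(0L, length(tz), length(tp),
                dimnames = list(format(tz, nsmall = 1), format(tp)))
  for (i in seq_along(tz)) {
    a <- rowSums(score >= tz[i])
    p <- ifelse(k > 0, 100 * a / k, 0)
    # count nodes with p >= tau_p for all tau_p at once
    out[i, ] <- vapply(tp, function(t) sum(p >= t), integer(1))
  }
  out
}

#' Select the most discriminatory threshold pair on training data
#'
#' Scans every grid cell and returns the `(tau_z, tau_p)` pair whose
#' abnormality loads best separate the two outcome classes by rank-based AUC
#' across the training patients. Ties are broken deterministically towards
#' the lowest `tau_z`, then the lowest `tau_p`.
#'
#' @param grids list of load-grid matrices (one per training patient, equal
#'   dimensions, as from [load_grid()]).
#' @param labels binary vector (1 = positive class, e.g. not seizure-free);
#'   both classes must be present.
#' @param grid the [threshold_grid()] the matrices were computed on.
#' @return list with `tau_z`, `tau_p`, the achieved `auc`, and the grid
#'   indices `i`, `j`.
#' @export
select_threshold_pair <- function(grids, labels, grid = threshold_grid()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present to select thresholds",
         call. = FALSE)
  if (length(grids) != length(labels))
    stop("one load grid per label is required", call. = FALSE)
  loads <- vapply(grids, identity, grids[[1]])  # tz x tp x patients
  nz <- dim(loads)[1]; np <- dim(loads)[2]
  flat <- t(apply(loads, 3, as.vector))         # patients x cells (col-major)
  auc <- apply(flat, 2, function(v) auc_rank(v, labels))
  cand <- which(auc >= max(auc) - 1e-12)
  ij <- arrayInd(cand, c(nz, np))
  pick <- cand[order(ij[, 1], ij[, 2])[1]]      # tie-break: lowest tz, then tp
  ij <- arrayInd(pick, c(nz, np))
  list(tau_z = grid$tau_z[ij[1]], tau_p = grid$tau_p[ij[2]],
       auc = auc[pick], i = ij[1], j = ij[2])
}

# Rank-based AUC of score vs binary label; tied scores contribute 1/2.
auc_rank <- function(score, label) {
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
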