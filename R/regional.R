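#' Relabel hemispheres as ipsilateral / contralateral to surgery
#'
#' @param nodes node table with `hemisphere` per node.
#' @param surgery_side `"left"` or `"right"`.
#' @return character vector, `"ipsi"` or `"contra"` per node.
#' @export
relabel_ipsi_contra <- function(nodes, surgery_side) {
  if (!surgery_side %in% c("left", "right"))
    stop("surgery_side must be 'left' or 'right'", call. = FALSE)
  h <- nodes$hemisphere
  if (any(is.na(h)) || !all(h %in% c("left", "right")))
    stop("every node needs a hemisphere of 'left' or 'right'", call. = FALSE)
  ifelse(h == surgery_side, "ipsi", "contra")
}

.areas <- c("temporal", "subcortical", "parietal", "occipital", "frontal",
            "cingulate")

# per-patient proportion of abnormal nodes in each of the 12 side x area
# cells; abnormal_nodes is a character vector of node labels
area_proportions <- function(abnormal_nodes, nodes, surgery_side) {
  side <- relabel_ipsi_contra(nodes, surgery_side)
  cell <- interaction(factor(side, c("ipsi", "contra")),
                      factor(nodes$area, .areas), sep = ".", drop = FALSE)
  n_roi <- table(cell)
  abn <- table(cell[nodes$label %in% abnormal_nodes])
  list(count = as.vector(abn), n_roi = as.vector(n_roi),
       proportion = as.vector(abn) / pmax(as.vector(n_roi), 1),
       cell = levels(cell))
}

#' Regional change in abnormal-node proportions after virtual resection
#'
#' For a group of patients, compares the proportion of abnormal nodes in each
#' of 12 (ipsi/contra x area) cells between the presurgery and surgically
#' spared networks: group-mean proportions with across-patient standard
#' errors, the drop (pre - spared), and a paired t-test across patients on
#' the per-patient per-area proportions. p-values are two-sided and can be
#' BH-corrected with [bh_fdr()].
#'
#' @param pre_sets,spared_sets lists (one element per patient) of abnormal
#'   node-label vectors at a fixed threshold pair.
#' @param nodes node table (shared parcellation).
#' @param surgery_sides `"left"`/`"right"` per patient.
#' @return data.frame with one row per side x area cell: `side`, `area`,
#'   `n_roi`, mean proportions `pre` and `spared` with `pre_se`/`spared_se`,
#'   `drop`, and paired `t` / `p` (NA when the differences are constant).
#' @export
area_proportion_change <- function(pre_sets, spared_sets, nodes,
                                   surgery_sides) {
  np <- length(pre_sets)
  if (np == 0) stop("empty patient group", call. = FALSE)
  if (length(spared_sets) != np || length(surgery_sides) != np)
    stop("pre_sets, spared_sets and surgery_sides must have one entry per patient",
         call. = FALSE)
  pre_mat <- sp_mat <- matrix(0, np, 12)
  for (i in seq_len(np)) {
    ap <- area_proportions(pre_sets[[i]], nodes, surgery_sides[i])
    as_ <- area_proportions(spared_sets[[i]], nodes, surgery_sides[i])
    pre_mat[i, ] <- ap$proportion
    sp_mat[i, ] <- as_$proportion
    cells <- ap$cell; n_roi <- ap$n_roi
  }
  se <- function(m) apply(m, 2, stats::sd) / sqrt(np)
  tt <- lapply(seq_len(12), function(j) {
    d <- pre_mat[, j] - sp_mat[, j]
    if (np < 2 || stats::sd(d) == 0) return(list(statistic = NA_real_, p = NA_real_))
    paired_t(pre_mat[, j], sp_mat[, j])
  })
  parts <- strsplit(cells, ".", fixed = TRUE)
  data.frame(
    side = vapply(parts, `[`, "", 1), area = vapply(parts, `[`, "", 2),
    n_roi = n_roi,
    pre = colMeans(pre_mat), pre_se = se(pre_mat),
    spared = colMeans(sp_mat), spared_se = se(sp_mat),
    drop = colMeans(pre_mat) - colMeans(sp_mat),
    t = vapply(tt, function(x) x$statistic, numeric(1)),
    p = vapply(tt, function(x) x$p, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Compare abnormality-load reduction between outcome groups
#'
#' Per patient, the absolute reduction is `pre - spared` and the proportional
#' reduction is `(pre - spared) / pre` (0 when `pre = 0`). Groups are
#' compared with the one-tailed exact rank-sum test (alternative: group 1 has
#' the larger reduction) and Cohen's d, on both measures.
#'
#' @param pre_loads,spared_loads integer loads per patient at a fixed
#'   threshold pair.
#' @param group logical/0-1 vector: `TRUE` for group 1 (e.g. seizure-free).
#' @return list with per-patient `absolute` and `proportional` reductions and
#'   `tests`, a data.frame with the rank-sum p and Cohen's d per measure.
#' @export
reduction_comparison <- function(pre_loads, spared_loads, group) {
  stopifnot(length(pre_loads) == length(spared_loads),
            length(group) == length(pre_loads))
  group <- as.logical(group)
  absolute <- pre_loads - spared_loads
  proportional <- ifelse(pre_loads > 0, absolute / pre_loads, 0)
  one <- function(v) {
    rs <- ranksum_exact(v[group], v[!group], alternative = "greater")
    d <- cohen_d(v[group], v[!group])
    c(p = rs$p, d = d)
  }
  tests <- rbind(absolute = one(absolute), proportional = one(proportional))
  list(absolute = absolute, proportional = proportional,
       tests = data.frame(measure = rownames(tests), p = tests[, "p"],
                          d = tests[, "d"], row.names = NULL))
}
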