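#' Surgery-affected edge set
#'
#' The set of connections expected to change after surgery: edges whose
#' streamlines pass through or into the resection cavity. Stored with set
#' semantics over unordered node-label pairs.
#'
#' @param affected data.frame (or 2-column matrix) of node-label pairs.
#' @param side resected hemisphere, `"left"` or `"right"`.
#' @param labels optional character vector of known node labels; pairs naming
#'   unknown nodes raise an error.
#' @return A `resection_effect` with a deduplicated `edges` data.frame
#'   (lexicographically smaller label first) and `side`.
#' @export
resection_effect <- function(affected, side, labels = NULL) {
  affected <- as.data.frame(affected, stringsAsFactors = FALSE)
  if (nrow(affected) > 0 && ncol(affected) < 2)
    stop("affected edge table needs two node-label columns", call. = FALSE)
  if (!side %in% c("left", "right"))
    stop("side must be 'left' or 'right'", call. = FALSE)
  if (nrow(affected) == 0) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        stringsAsFactors = FALSE)
  } else {
    a <- as.character(affected[[1]]); b <- as.character(affected[[2]])
    if (!is.null(labels)) {
      bad <- setdiff(union(a, b), labels)
      if (length(bad))
        stop(sprintf("affected edges name unknown node(s): %s",
                     paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    }
    swap <- a > b
    edges <- unique(data.frame(node_a = ifelse(swap, b, a),
                               node_b = ifelse(swap, a, b),
                               stringsAsFactors = FALSE))
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, side = side), class = "resection_effect")
}

#' Construct the surgically spared z-network
#'
#' Removes the surgery-affected edges from a presurgery z-network. z-scores
#' on surviving edges and the presurgical degrees `k_i` are untouched, so the
#' spared network's node abnormality percentages are computed against the
#' same denominators as before surgery; abnormal links can only be removed,
#' never added.
#'
#' @param zn a presurgery `znetwork` from [z_score_network()].
#' @param effect a [resection_effect()].
#' @return A `znetwork` with `kind = "spared"`.
#' @export
apply_resection <- function(zn, effect) {
  stopifnot(inherits(zn, "znetwork"), inherits(effect, "resection_effect"))
  if (zn$kind != "presurgery")
    stop("apply_resection expects a presurgery z-network", call. = FALSE)
  lab <- rownames(zn$z)
  ed <- effect$edges
  bad <- setdiff(union(ed$node_a, ed$node_b), lab)
  if (length(bad))
    stop(sprintf("affected edges name unknown node(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  valid <- zn$valid
  if (nrow(ed) > 0) {
    ia <- match(ed$node_a, lab); ib <- match(ed$node_b, lab)
    valid[cbind(ia, ib)] <- FALSE
    valid[cbind(ib, ia)] <- FALSE
  }
  z <- zn$z
  z[!valid] <- NA_real_
  structure(list(z = z, valid = valid, degree = zn$degree, kind = "spared",
                 nodes = zn$nodes),
            class = "znetwork")
}
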