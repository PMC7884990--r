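#' Weighted structural connectome for one subject
#'
#' Bundles the two edge-weight matrices produced by diffusion tractography --
#' a streamline-count matrix and a mean generalized fractional anisotropy
#' (gFA) matrix -- together with the node metadata of the parcellation. Edges
#' are unordered node pairs; a gFA weight is defined exactly where the
#' streamline count is positive.
#'
#' @param gfa numeric symmetric matrix in (0,1) where defined, `NA` elsewhere;
#'   rows/columns named by node label.
#' @param streamline nonnegative integer symmetric matrix of streamline
#'   counts; zero where no edge.
#' @param nodes data.frame with columns `label`, `hemisphere`
#'   (`"left"`/`"right"`) and `area` (one of the six cortical/subcortical
#'   areas), in matrix row order.
#' @return An object of class `connectome`.
#' @seealso [read_connectome()], [build_reference()]
#' @export
connectome <- function(gfa, streamline, nodes) {
  stopifnot(is.matrix(gfa), is.matrix(streamline), is.data.frame(nodes))
  n <- nrow(nodes)
  if (!all(dim(gfa) == c(n, n)) || !all(dim(streamline) == c(n, n)))
    stop("matrix dimensions do not match the node table", call. = FALSE)
  if (!all(c("label", "hemisphere", "area") %in% names(nodes)))
    stop("node table must have columns label, hemisphere, area", call. = FALSE)
  lab <- as.character(nodes$label)
  if (anyDuplicated(lab)) stop("duplicate node labels", call. = FALSE)
  dimnames(gfa) <- dimnames(streamline) <- list(lab, lab)
  diag(streamline) <- 0L
  diag(gfa) <- NA_real_
  present <- streamline > 0
  if (any(present != t(present)))
    stop("streamline matrix is not symmetric in edge presence", call. = FALSE)
  bad <- abs(gfa - t(gfa)) > 1e-9
  if (any(bad, na.rm = TRUE))
    stop("gFA matrix asymmetric beyond tolerance 1e-9", call. = FALSE)
  gfa[present] <- (gfa[present] + t(gfa)[present]) / 2  # enforce exact symmetry
  gfa[!present] <- NA_real_
  w <- gfa[present]
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1))
    stop("gFA values must lie strictly in (0,1) wherever streamlines exist",
         call. = FALSE)
  structure(
    list(gfa = gfa, streamline = streamline,
         nodes = data.frame(label = lab,
                            hemisphere = as.character(nodes$hemisphere),
                            area = as.character(nodes$area),
                            stringsAsFactors = FALSE)),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$nodes)
  ne <- sum(x$streamline > 0) / 2
  cat(sprintf("connectome: %d nodes, %d edges (density %.2f)\n",
              n, ne, ne / choose(n, 2)))
  invisible(x)
}

node_labels <- function(x) x$nodes$label

check_same_nodes <- function(labels_a, labels_b, what = "subject") {
  if (!identical(labels_a, labels_b)) {
    bad <- union(setdiff(labels_a, labels_b), setdiff(labels_b, labels_a))
    if (length(bad) == 0) bad <- "(same labels, different order)"
    stop(sprintf("node sets of %s do not match: %s", what,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
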