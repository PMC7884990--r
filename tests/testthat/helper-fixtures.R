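# Fixtures are built in code; nothing is read from disk.

# small node table cycling through hemispheres and areas
toy_nodes <- function(n) {
  areas <- c("temporal", "subcortical", "parietal", "occipital", "frontal",
             "cingulate")
  data.frame(label = sprintf("n%02d", seq_len(n)),
             hemisphere = rep(c("left", "right"), length.out = n),
             area = rep(areas, length.out = n),
             stringsAsFactors = FALSE)
}

# build a connectome from an explicit gFA matrix; streamline = 1 where gfa
toy_connectome <- function(gfa, nodes = toy_nodes(nrow(gfa))) {
  gfa[lower.tri(gfa)] <- t(gfa)[lower.tri(gfa)]
  diag(gfa) <- NA
  sc <- matrix(0L, nrow(gfa), ncol(gfa))
  sc[!is.na(gfa) & gfa > 0] <- 5L
  gfa[sc == 0] <- NA
  connectome(gfa, sc, nodes)
}

# construct a znetwork object directly from a z matrix (toys for the
# abnormality/resection modules); degrees taken from the valid mask
toy_znetwork <- function(z, valid = NULL, nodes = toy_nodes(nrow(z))) {
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- NA
  if (is.null(valid)) valid <- !is.na(z)
  valid[lower.tri(valid)] <- t(valid)[lower.tri(valid)]
  diag(valid) <- FALSE
  z[!valid] <- NA
  dimnames(z) <- dimnames(valid) <- list(nodes$label, nodes$label)
  k <- rowSums(valid)
  names(k) <- nodes$label
  structure(list(z = z, valid = valid, degree = k, kind = "presurgery",
                 nodes = nodes), class = "znetwork")
}

random_toy_znetwork <- function(n = 20, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n, sd = 2), n, n)
  valid <- matrix(runif(n * n) < 0.6, n, n)
  toy_znetwork(z, valid)
}

# small full cohort for pipeline-level tests
small_cohort_config <- function(seed = 5, n_patients = 12)
  generator_config(n_nodes = 36, n_controls = 12, n_patients = n_patients,
                   seed = seed)

# brute-force rank-sum p by explicit enumeration of all C(n, nx) assignments
brute_ranksum_p <- function(x, y, alternative) {
  v <- c(x, y); n <- length(v); nx <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(nx)])
  ws <- apply(utils::combn(n, nx), 2, function(i) sum(r[i]))
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  switch(alternative, less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# brute-force AUC by pairwise comparison (O(n^2) oracle)
brute_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# brute-force abnormality load at one threshold pair, straight from the
# definition (per-node edge loop)
brute_load <- function(zn, tz, tp) {
  n <- nrow(zn$z)
  load <- 0
  for (i in seq_len(n)) {
    a <- 0
    for (j in seq_len(n)) {
      if (zn$valid[i, j] && !is.na(zn$z[i, j]) && abs(zn$z[i, j]) >= tz)
        a <- a + 1
    }
    k <- zn$degree[i]
    p <- if (k > 0) 100 * a / k else 0
    if (p >= tp) load <- load + 1
  }
  load
}
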