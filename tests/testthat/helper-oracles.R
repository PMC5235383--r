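# Independent oracles used across the suite. These deliberately avoid the
# package's own delta/e-distance/LW code paths: point distances come from
# stats::dist, cluster dissimilarities from direct block means of the point
# distance matrix, and sums of squares from explicit centroid arithmetic.

# Point distance matrix under a named metric, via stats::dist only.
oracle_point_dist <- function(x, metric, theta = NULL) {
  switch(metric,
    manhattan = as.matrix(dist(x, method = "manhattan")),
    euclidean = as.matrix(dist(x, method = "euclidean")),
    sqeuclidean = as.matrix(dist(x, method = "euclidean"))^2,
    power = as.matrix(dist(x, method = "euclidean"))^theta
  )
}

# Brute-force e-distance between member index sets, from the point distance
# matrix: (nA nB / (nA + nB)) (2 dAB - dAA - dBB) with dXY the block mean
# (within-blocks include self-pairs).
oracle_e_distance <- function(pd, a, b) {
  n_a <- length(a); n_b <- length(b)
  d_ab <- mean(pd[a, b, drop = FALSE])
  d_aa <- mean(pd[a, a, drop = FALSE])
  d_bb <- mean(pd[b, b, drop = FALSE])
  n_a * n_b / (n_a + n_b) * (2 * d_ab - d_aa - d_bb)
}

# Increase in within-cluster sum of squared errors caused by merging a and b
# (centroid form): nA nB / (nA + nB) * ||mean_a - mean_b||^2.
oracle_sse_increase <- function(x, a, b) {
  ca <- colMeans(x[a, , drop = FALSE])
  cb <- colMeans(x[b, , drop = FALSE])
  length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
}

# Audit a traced ward_cluster run: for every step, the LW-updated distances
# from the newly formed cluster to each survivor must match brute-force
# e-distance recomputed from raw members. Returns the max relative error.
audit_lw_run <- function(x, metric, theta = NULL) {
  wc <- if (metric == "power") {
    ward_cluster(x, metric = "power", theta = theta, trace = TRUE)
  } else {
    ward_cluster(x, metric = metric, trace = TRUE)
  }
  pd <- oracle_point_dist(x, metric, theta)
  max_rel <- 0
  for (st in wc$trace) {
    members <- st$members
    new <- length(members)           # new cluster occupies the last slot
    for (kk in seq_len(new - 1L)) {
      e_bf <- oracle_e_distance(pd, members[[new]], members[[kk]])
      e_lw <- st$d[new, kk]
      rel <- abs(e_lw - e_bf) / max(abs(e_bf), .Machine$double.eps)
      max_rel <- max(max_rel, rel)
    }
  }
  list(max_rel = max_rel, wc = wc)
}

rand_dataset <- function(n, p) {
  matrix(stats::runif(n * p), n, p)
}

# Nontrivial splits of a tree by explicit edge removal (independent of
# tree_splits): for every internal edge, bipartition the tips by
# connectivity in the edge-deleted graph.
oracle_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  edges <- tree$edge
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 2] <= n) next       # pendant edge -> trivial split
    # tips reachable from the child node without crossing edge e
    reach <- edges[e, 2]
    repeat {
      kids <- edges[edges[, 1] %in% reach & seq_len(nrow(edges)) != e, 2]
      nxt <- union(reach, kids)
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    side <- tree$tip.label[intersect(reach, seq_len(n))]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# A small in-memory corpus for signature tests.
toy_corpus <- function() {
  tibble::tibble(
    label = c("doc1", "doc2", "doc3"),
    text = c("abba abab", "Ba and Ab!", "bbbb aaaa")
  )
}
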