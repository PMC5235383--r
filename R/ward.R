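#' Mean pairwise distance within or between clusters (delta constant)
#'
#' The delta constants are the building blocks of the between-cluster
#' e-distance: `cluster_delta(x, a, b)` is the mean point distance over all
#' ordered pairs drawn from clusters `a` and `b` (denominator
#' \eqn{n_A n_B}); with `b = a` it is the within-cluster mean over all
#' ordered pairs including self-pairs (denominator \eqn{n_A^2}).
#'
#' @param x Data frame or numeric matrix of observations (rows = items).
#' @param a,b Integer index vectors of cluster members (rows of `x`).
#' @inheritParams distance_matrix
#' @return A nonnegative scalar.
#' @examples
#' x <- matrix(c(0, 2), ncol = 1)
#' cluster_delta(x, 1:2)  # (0 + 2 + 2 + 0) / 4 = 1
#' @export
cluster_delta <- function(x, a, b = a, metric = "manhattan",
                          r = NULL, theta = NULL) {
  m <- resolve_metric(metric, r = r, theta = theta)
  x <- extract_features(x)$x
  check_members(a, nrow(x)); check_members(b, nrow(x))
  pd <- pairwise_point_dist(x[a, , drop = FALSE], m,
                            y = x[b, , drop = FALSE])
  mean(pd)
}

check_members <- function(idx, n) {
  if (length(idx) == 0) abort_input("cluster must be nonempty.")
  if (!is.numeric(idx) || any(idx != round(idx)) ||
      any(idx < 1) || any(idx > n) || anyDuplicated(idx)) {
    abort_input("cluster members must be distinct row indices of `x`.")
  }
  invisible(TRUE)
}

#' Between-cluster e-distance
#'
#' The dissimilarity that generalised Ward linkage minimises at each merge:
#' \deqn{e(A,B) = \frac{n_A n_B}{n_A + n_B}\,
#'   (2\delta_{AB} - \delta_{AA} - \delta_{BB})}
#' where the deltas are mean pairwise point distances ([cluster_delta()]).
#' For two singletons it reduces to the point distance itself. With the
#' squared-Euclidean metric it equals twice the increase in within-cluster
#' sum of squares caused by merging (classical Ward); with the Manhattan
#' metric it drives the least-absolute-error Ward variant.
#'
#' @inheritParams cluster_delta
#' @return A nonnegative scalar.
#' @examples
#' x <- matrix(c(0, 2, 10), ncol = 1)
#' e_distance(x, 1:2, 3)  # 34/3
#' @export
e_distance <- function(x, a, b, metric = "manhattan", r = NULL, theta = NULL) {
  m <- resolve_metric(metric, r = r, theta = theta)
  x <- extract_features(x)$x
  check_members(a, nrow(x)); check_members(b, nrow(x))
  if (length(intersect(a, b)) > 0) {
    abort_input("clusters overlap: e-distance needs disjoint member sets.")
  }
  n_a <- length(a); n_b <- length(b)
  d_ab <- mean(pairwise_point_dist(x[a, , drop = FALSE], m,
                                   y = x[b, , drop = FALSE]))
  d_aa <- mean(pairwise_point_dist(x[a, , drop = FALSE], m,
                                   y = x[a, , drop = FALSE]))
  d_bb <- mean(pairwise_point_dist(x[b, , drop = FALSE], m,
                                   y = x[b, , drop = FALSE]))
  n_a * n_b / (n_a + n_b) * (2 * d_ab - d_aa - d_bb)
}

#' Ward's Lance-Williams parameters
#'
#' For merged clusters of sizes `n_a` and `n_b` and a third cluster of size
#' `n_c`, Ward's update coefficients are
#' \eqn{\alpha_A = (n_A + n_C)/S}, \eqn{\alpha_B = (n_B + n_C)/S},
#' \eqn{\beta = -n_C/S}, \eqn{\gamma = 0}, with \eqn{S = n_A + n_B + n_C}.
#' They satisfy \eqn{\alpha_A + \alpha_B + \beta = 1} exactly. Vectorised
#' over the three sizes.
#'
#' @param n_a,n_b,n_c Positive integer cluster sizes.
#' @return A tibble with columns `alpha_a`, `alpha_b`, `beta`, `gamma`
#'   (class `lw_params`).
#' @examples
#' ward_lw_parameters(1, 1, 1)  # 2/3, 2/3, -1/3, 0
#' @export
ward_lw_parameters <- function(n_a, n_b, n_c) {
  sizes <- vctrs_recycle(n_a, n_b, n_c)
  if (any(sizes$n_a < 1) || any(sizes$n_b < 1) || any(sizes$n_c < 1) ||
      any(sizes$n_a != round(sizes$n_a)) ||
      any(sizes$n_b != round(sizes$n_b)) ||
      any(sizes$n_c != round(sizes$n_c))) {
    abort_input("cluster sizes must be integers >= 1.")
  }
  s <- sizes$n_a + sizes$n_b + sizes$n_c
  out <- tibble(
    alpha_a = (sizes$n_a + sizes$n_c) / s,
    alpha_b = (sizes$n_b + sizes$n_c) / s,
    beta = -sizes$n_c / s,
    gamma = rep(0, length(s))
  )
  class(out) <- c("lw_params", class(out))
  out
}

vctrs_recycle <- function(n_a, n_b, n_c) {
  len <- max(length(n_a), length(n_b), length(n_c))
  list(n_a = rep_len(n_a, len), n_b = rep_len(n_b, len),
       n_c = rep_len(n_c, len))
}

#' Lance-Williams distance update
#'
#' Given current cluster distances `d_ac`, `d_bc`, `d_ab` and update
#' parameters, returns
#' \eqn{\alpha_A d_{AC} + \alpha_B d_{BC} + \beta d_{AB} +
#'   \gamma |d_{AC} - d_{BC}|},
#' the distance from the merged cluster \eqn{A \cup B} to `C`. With Ward's
#' parameters applied to e-distances this recurrence is exact: it reproduces
#' the e-distance recomputed from the raw members, for every Minkowski-power
#' metric in the supported family.
#'
#' @param d_ac,d_bc,d_ab Nonnegative current distances.
#' @param params One-row (or recycled) tibble from [ward_lw_parameters()],
#'   or any list with `alpha_a`, `alpha_b`, `beta`, `gamma`.
#' @return Updated distance(s).
#' @examples
#' lw_update(10, 8, 2, ward_lw_parameters(1, 1, 1))  # 34/3
#' @export
lw_update <- function(d_ac, d_bc, d_ab, params) {
  if (any(c(d_ac, d_bc, d_ab) < 0)) {
    abort_input("cluster distances must be nonnegative.")
  }
  params$alpha_a * d_ac + params$alpha_b * d_bc + params$beta * d_ab +
    params$gamma * abs(d_ac - d_bc)
}

#' Generalised Ward agglomeration
#'
#' Agglomerative hierarchical clustering under the generalised Ward
#' objective. `ward_cluster()` starts from an observation-by-feature table:
#' initial inter-singleton distances are the point metric (the e-distance of
#' singletons), after which each step merges the active pair with the
#' smallest current e-distance and updates distances to the survivors by the
#' Lance-Williams recurrence with Ward's parameters. `ward_cluster_d()`
#' applies the same engine to a precomputed symmetric distance matrix, whose
#' entries are taken as current e-distances between singletons (the standard
#' "Ward on a distance matrix" contract).
#'
#' Merge heights are the raw e-distance at the merge — no doubling, halving
#' or square-root rescaling — which is the convention under which the
#' recurrence is exact. Ties at the minimal distance are broken towards the
#' lexicographically smallest (smaller id, larger id) pair, ids being input
#' order for leaves and creation order for merged clusters.
#'
#' @inheritParams distance_matrix
#' @param trace Keep a per-step record of active cluster memberships and the
#'   current distance matrix (used for auditing the recurrence against
#'   brute-force recomputation).
#' @return A `ward_clust` object: list with `merge` (hclust convention),
#'   `height`, `order`, `labels`, `sizes` (size of each newly formed
#'   cluster), `metric`, `n`, and optionally `trace`. Methods exist for
#'   [generics::tidy()], [generics::glance()], [stats::as.hclust()],
#'   [ape::as.phylo()], [ggplot2::autoplot()] and [cut_tree()].
#' @examples
#' wc <- ward_cluster(data.frame(x = c(0, 2, 10)))
#' wc$height  # 2 and 34/3
#' @export
ward_cluster <- function(x, metric = "manhattan", r = NULL, theta = NULL,
                         labels = NULL, trace = FALSE) {
  m <- resolve_metric(metric, r = r, theta = theta)
  dat <- extract_features(x, labels)
  if (nrow(dat$x) < 2L) abort_input("need at least 2 items to cluster.")
  d0 <- pairwise_point_dist(dat$x, m)
  diag(d0) <- 0
  agglomerate_lw(d0, labels = dat$labels, metric = m, trace = trace)
}

#' @rdname ward_cluster
#' @param d Symmetric distance matrix with zero diagonal (a matrix, `dist`
#'   object, or anything [read_distance_matrix()] returns).
#' @export
ward_cluster_d <- function(d, labels = NULL, trace = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- validate_distance_matrix(d)
  if (!is.null(labels)) {
    if (length(labels) != nrow(d)) {
      abort_input("`labels` length must match the matrix.")
    }
    dimnames(d) <- list(labels, labels)
  }
  agglomerate_lw(d, labels = rownames(d),
                 metric = structure(list(name = "precomputed"),
                                    class = "wardl1_metric"),
                 trace = trace)
}

# The Lance-Williams engine. d: initial symmetric matrix of e-distances
# between singletons. Ids are 1..n for leaves (input order), n+step for
# merged clusters; the scan over the upper triangle in id order makes the
# lexicographic tie-break deterministic.
agglomerate_lw <- function(d, labels, metric, trace = FALSE) {
  n <- nrow(d)
  hid <- -seq_len(n)        # hclust-convention ids of active clusters
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  csize <- integer(n - 1L)
  steps <- if (trace) vector("list", n - 1L) else NULL

  for (s in seq_len(n - 1L)) {
    mdim <- nrow(d)
    du <- d
    du[lower.tri(du, diag = TRUE)] <- Inf
    k <- which.min(t(du))            # row-major scan: first (i, j) minimum
    i <- (k - 1L) %/% mdim + 1L
    j <- (k - 1L) %% mdim + 1L
    h <- d[i, j]
    if (!is.finite(h)) abort("non-finite cluster distance encountered.")

    keep <- setdiff(seq_len(mdim), c(i, j))
    newrow <- if (length(keep) > 0) {
      params <- ward_lw_parameters(size[i], size[j], size[keep])
      unname(lw_update(d[i, keep], d[j, keep], h, params))
    } else {
      numeric(0)
    }

    pair <- c(hid[i], hid[j])
    merge[s, ] <- pair[order(pair > 0, abs(pair))]  # hclust row convention
    height[s] <- h
    csize[s] <- size[i] + size[j]

    new_members <- c(members[[i]], members[[j]])
    members <- c(members[keep], list(new_members))
    size <- c(size[keep], size[i] + size[j])
    hid <- c(hid[keep], s)
    d <- if (length(keep) > 0) {
      unname(rbind(cbind(d[keep, keep, drop = FALSE], newrow),
                   c(newrow, 0)))
    } else {
      matrix(0, 1L, 1L)
    }
    if (trace) {
      steps[[s]] <- list(members = members, d = d, height = h)
    }
  }

  out <- structure(
    list(
      merge = merge, height = height, order = hclust_order(merge),
      labels = labels, sizes = csize, metric = metric, n = n,
      method = "ward.e", call = sys.call(-1)
    ),
    class = "ward_clust"
  )
  if (trace) out$trace <- steps
  out
}

# Leaf ordering for plotting: left-to-right traversal of the merge tree.
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1L]), expand(merge[id, 2L]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last `k - 1` merges and returns one cluster id per leaf.
#' Cluster ids are stable by first-leaf order: the cluster containing the
#' first input item is 1, the next new cluster encountered in input order
#' is 2, and so on (the same convention as [stats::cutree()]).
#'
#' @param wc A `ward_clust` object.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector of cluster ids (names = leaf labels).
#' @export
cut_tree <- function(wc, k) {
  stopifnot(inherits(wc, "ward_clust"))
  n <- wc$n
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > n) {
    abort_input(sprintf("`k` must be an integer in [1, %d].", n))
  }
  group_of <- seq_len(n)
  reps <- as.list(seq_len(n))  # leaf members of each merge-step cluster
  for (s in seq_len(n - as.integer(k))) {
    ch <- wc$merge[s, ]
    mem <- unlist(lapply(ch, function(id) {
      if (id < 0) -id else reps[[n + id]]
    }))
    reps[[n + s]] <- mem
    group_of[mem] <- min(group_of[mem])
  }
  # renumber by first appearance in input order
  ids <- match(group_of, unique(group_of))
  names(ids) <- wc$labels
  ids
}

#' Check dendrogram monotonicity and the Lance-Williams conditions
#'
#' `check_monotonic()` verifies that merge heights never decrease along the
#' agglomeration (the ultrametric / no-reversal property) within a
#' tolerance. `lw_monotonic_conditions()` evaluates, for given Ward
#' parameters, the sufficient conditions
#' \eqn{\alpha_A + \alpha_B + \beta \ge 1}, \eqn{\min(\alpha_A,\alpha_B)
#' \ge 0}, \eqn{\gamma \ge 0} that guarantee monotonicity.
#'
#' @param wc A `ward_clust` object (or any list with a numeric `height`).
#' @param tol Nonnegative tolerance on height decreases.
#' @return `check_monotonic()`: list with `monotone` (logical) and
#'   `violations` (tibble of offending steps). `lw_monotonic_conditions()`:
#'   tibble with one logical column per condition plus `monotone_guaranteed`.
#' @export
check_monotonic <- function(wc, tol = 1e-9) {
  h <- wc$height
  if (is.null(h)) abort_input("`wc` must carry merge heights.")
  dh <- diff(h)
  bad <- which(dh < -tol)
  list(
    monotone = length(bad) == 0,
    violations = tibble(
      step = bad + 1L,
      height = h[bad + 1L],
      previous = h[bad]
    )
  )
}

#' @rdname check_monotonic
#' @param params Tibble from [ward_lw_parameters()].
#' @export
lw_monotonic_conditions <- function(params, tol = 1e-12) {
  out <- tibble(
    sum_ge_one = params$alpha_a + params$alpha_b + params$beta >= 1 - tol,
    alphas_nonneg = pmin(params$alpha_a, params$alpha_b) >= -tol,
    gamma_nonneg = params$gamma >= -tol
  )
  out$monotone_guaranteed <- out$sum_ge_one & out$alphas_nonneg &
    out$gamma_nonneg
  out
}

#' Space-conservation classification of Lance-Williams parameters
#'
#' Evaluates the textbook sufficient conditions for a linkage to be
#' space-conserving: \eqn{\alpha_A + \alpha_B = 1}, \eqn{\beta = 0} and
#' \eqn{|\gamma| < \alpha_A}. Note that Ward's own parameters have
#' \eqn{\beta = -n_C/S \neq 0} and therefore fail the literal \eqn{\beta=0}
#' condition even though Ward's method is commonly described as
#' space-conserving; the checker reports the literal outcome of each
#' condition and flags this discrepancy rather than resolving it.
#'
#' @inheritParams lw_monotonic_conditions
#' @return Tibble with logical columns `alphas_sum_to_one`, `beta_zero`,
#'   `gamma_lt_alpha`, `conserving` and a `note` column flagging the Ward
#'   beta discrepancy where it applies.
#' @export
check_space_conditions <- function(params, tol = 1e-12) {
  out <- tibble(
    alphas_sum_to_one = abs(params$alpha_a + params$alpha_b - 1) <= tol,
    beta_zero = abs(params$beta) <= tol,
    gamma_lt_alpha = abs(params$gamma) < params$alpha_a
  )
  out$conserving <- out$alphas_sum_to_one & out$beta_zero & out$gamma_lt_alpha
  out$note <- ifelse(
    !out$beta_zero & params$beta < 0,
    "beta < 0: literal space-conserving condition fails (as it does for Ward's own parameters)",
    ""
  )
  out
}
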