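#' Per-item silhouette values
#'
#' For each item \eqn{i}, \eqn{a_i} is the mean distance to the other
#' members of its own cluster and \eqn{b_i} the smallest, over the other
#' clusters, of the mean distance to that cluster's members; the silhouette
#' is \eqn{S(i) = (b_i - a_i) / \max(a_i, b_i)}. Items forming singleton
#' clusters get \eqn{S(i) = 0} (the ratio is otherwise undefined). The
#' silhouette width is the mean of \eqn{S(i)} and lies in \eqn{[-1, 1]};
#' larger is better.
#'
#' @param d Symmetric distance matrix over the items
#'   (see [distance_matrix()]).
#' @param partition Vector of cluster memberships, one per item (integer,
#'   factor or character), or a named vector from [cut_tree()].
#' @return `cluster_silhouette()`: a tibble with columns `label`, `cluster`,
#'   `a`, `b`, `s`. `silhouette_width()`: the mean silhouette.
#' @examples
#' d <- distance_matrix(data.frame(x = c(0, 1, 10)))
#' cluster_silhouette(d, c(1, 1, 2))$s  # 0.9, 8/9, 0
#' @export
cluster_silhouette <- function(d, partition) {
  pp <- check_partition(d, partition)
  d <- pp$d; cl <- pp$cl; m <- nrow(d)
  if (length(unique(cl)) < 2) {
    abort_input("silhouette needs at least 2 clusters.")
  }
  a <- b <- s <- numeric(m)
  for (i in seq_len(m)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) {
      a[i] <- NA_real_
      b[i] <- min(vapply(setdiff(unique(cl), cl[i]),
                         function(g) mean(d[i, cl == g]), numeric(1)))
      s[i] <- 0
      next
    }
    a[i] <- mean(d[i, setdiff(own, i)])
    b[i] <- min(vapply(setdiff(unique(cl), cl[i]),
                       function(g) mean(d[i, cl == g]), numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  tibble(label = rownames(d), cluster = cl, a = a, b = b, s = s)
}

#' @rdname cluster_silhouette
#' @export
silhouette_width <- function(d, partition) {
  mean(cluster_silhouette(d, partition)$s)
}

check_partition <- function(d, partition) {
  d <- validate_distance_matrix(d)
  if (length(partition) != nrow(d)) {
    abort_input("`partition` must assign every item to a cluster.")
  }
  if (any(is.na(partition))) abort_input("`partition` contains NA.")
  list(d = d, cl = as.integer(factor(partition, levels = unique(partition))))
}

#' Dunn index of a partition
#'
#' The ratio of the smallest between-cluster point distance to the largest
#' within-cluster diameter (maximal pairwise distance inside a cluster).
#' Larger is better. When every cluster is a singleton the denominator is
#' empty and the index is reported as `Inf`.
#'
#' @inheritParams cluster_silhouette
#' @return A nonnegative scalar (possibly `Inf`).
#' @examples
#' d <- distance_matrix(data.frame(x = c(0, 1, 10)))
#' dunn_index(d, c(1, 1, 2))  # 9
#' @export
dunn_index <- function(d, partition) {
  pp <- check_partition(d, partition)
  d <- pp$d; cl <- pp$cl
  gs <- unique(cl)
  if (length(gs) < 2) abort_input("Dunn index needs at least 2 clusters.")
  between <- min(vapply(utils::combn(gs, 2, simplify = FALSE), function(pr) {
    min(d[cl == pr[1], cl == pr[2]])
  }, numeric(1)))
  diams <- vapply(gs, function(g) {
    idx <- which(cl == g)
    if (length(idx) < 2) return(NA_real_)
    max(d[idx, idx])
  }, numeric(1))
  if (all(is.na(diams)) || max(diams, na.rm = TRUE) == 0) {
    return(Inf)
  }
  between / max(diams, na.rm = TRUE)
}

#' Connectivity of a partition
#'
#' Sums, over every item `i` and its `L` nearest neighbours, a penalty of
#' `1/j` whenever the `j`-th nearest neighbour of `i` is assigned to a
#' different cluster (0 otherwise). Ranges from 0 upwards; smaller is
#' better. Neighbour ties are broken by item index and an item is never its
#' own neighbour.
#'
#' @inheritParams cluster_silhouette
#' @param L Neighbourhood size, `1 <= L <= m - 1`. Defaults to
#'   `min(10, m - 1)`.
#' @return A nonnegative scalar.
#' @examples
#' d <- distance_matrix(data.frame(x = c(0, 1, 10)))
#' connectivity(d, c(1, 1, 2), L = 1)  # 1
#' @export
connectivity <- function(d, partition, L = NULL) {
  pp <- check_partition(d, partition)
  d <- pp$d; cl <- pp$cl; m <- nrow(d)
  L <- L %||% min(10L, m - 1L)
  if (!is.numeric(L) || length(L) != 1L || L != round(L) ||
      L < 1 || L > m - 1) {
    abort_input(sprintf("`L` must be an integer in [1, %d].", m - 1L))
  }
  total <- 0
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    nn <- others[order(d[i, others], others)][seq_len(L)]
    cross <- cl[nn] != cl[i]
    total <- total + sum(ifelse(cross, 1 / seq_len(L), 0))
  }
  total
}

#' Internal validation report for one partition
#'
#' Computes the three internal cluster-validity measures — silhouette width,
#' Dunn index and connectivity — for a given partition of a distance matrix.
#'
#' @inheritParams connectivity
#' @return A one-row tibble: `k`, `silhouette_width`, `dunn`, `connectivity`,
#'   `L`. The per-item silhouettes are attached as attribute `"silhouette"`.
#' @export
validate_partition <- function(d, partition, L = NULL) {
  pp <- check_partition(d, partition)
  L_used <- L %||% min(10L, nrow(pp$d) - 1L)
  sil <- cluster_silhouette(d, partition)
  out <- tibble(
    k = length(unique(pp$cl)),
    silhouette_width = mean(sil$s),
    dunn = dunn_index(d, partition),
    connectivity = connectivity(d, partition, L = L_used),
    L = as.integer(L_used)
  )
  attr(out, "silhouette") <- sil
  class(out) <- c("ward_validation", class(out))
  out
}

#' Plot per-item silhouettes
#'
#' @param sil Tibble from [cluster_silhouette()] (or a
#'   [validate_partition()] result, whose per-item silhouettes are used).
#' @return A ggplot of per-item silhouette values grouped by cluster.
#' @export
plot_silhouette <- function(sil) {
  if (inherits(sil, "ward_validation")) sil <- attr(sil, "silhouette")
  sil <- dplyr::arrange(sil, .data$cluster, dplyr::desc(.data$s))
  sil$label <- factor(sil$label, levels = sil$label)
  ggplot2::ggplot(sil, ggplot2::aes(x = .data$label, y = .data$s,
                                    fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "silhouette S(i)", fill = "cluster") +
    ggplot2::theme_minimal()
}
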