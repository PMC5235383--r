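#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf(
    "Generalised Ward clustering (%s metric)\n%d items, %d merges, heights in [%.4g, %.4g]\n",
    metric_label(x$metric), x$n, length(x$height),
    min(x$height), max(x$height)
  ))
  invisible(x)
}

#' Tidy a Ward clustering into its merge table
#'
#' One row per merge: hclust-convention child ids (negative = leaf index,
#' positive = earlier merge step), the labels when a child is a leaf, the
#' e-distance at which the merge happened, and the size of the new cluster.
#'
#' @param x A `ward_clust` object.
#' @param ... Unused.
#' @return A tibble with columns `step`, `child1`, `child2`, `label1`,
#'   `label2`, `height`, `size`.
#' @export
tidy.ward_clust <- function(x, ...) {
  leaf_label <- function(id) {
    ifelse(id < 0, x$labels[pmax(-id, 1L)], NA_character_)
  }
  tibble(
    step = seq_along(x$height),
    child1 = x$merge[, 1L],
    child2 = x$merge[, 2L],
    label1 = leaf_label(x$merge[, 1L]),
    label2 = leaf_label(x$merge[, 2L]),
    height = x$height,
    size = x$sizes
  )
}

#' Glance at a Ward clustering
#'
#' @inheritParams tidy.ward_clust
#' @return A one-row tibble: item count, metric, root height, and whether
#'   the merge heights are monotone.
#' @export
glance.ward_clust <- function(x, ...) {
  tibble(
    n = x$n,
    metric = metric_label(x$metric),
    root_height = max(x$height),
    monotone = check_monotonic(x)$monotone
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
as.hclust.ward_clust <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order,
      labels = x$labels, method = x$method,
      call = x$call, dist.method = metric_label(x$metric)
    ),
    class = "hclust"
  )
}

#' Convert a Ward clustering to a leaf-labelled phylogenetic tree
#'
#' Each merge becomes an internal node of a rooted binary tree; the branch
#' length of a child edge is the parent's merge height minus the child's
#' (leaves sit at height 0).
#'
#' @param wc A `ward_clust` object.
#' @return An [ape::phylo] tree.
#' @export
dendrogram_to_tree <- function(wc) {
  stopifnot(inherits(wc, "ward_clust"))
  n <- wc$n
  # phylo numbering: tips 1..n, root n+1; the merge at step s becomes
  # internal node n + (n - s), so the final merge is the root
  node_id <- function(child) {
    ifelse(child < 0, -child, n + (n - child))
  }
  parent <- rep(node_id(seq_len(n - 1)), each = 2L)
  child <- node_id(as.vector(t(wc$merge)))
  child_height <- ifelse(as.vector(t(wc$merge)) < 0, 0,
                         wc$height[pmax(as.vector(t(wc$merge)), 1L)])
  len <- rep(wc$height, each = 2L) - child_height
  tr <- structure(
    list(
      edge = cbind(parent, child, deparse.level = 0),
      edge.length = len,
      Nnode = n - 1L,
      tip.label = wc$labels
    ),
    class = "phylo", order = "postorder"
  )
  stats::reorder(tr, "cladewise")
}

#' @method as.phylo ward_clust
#' @export
as.phylo.ward_clust <- function(x, ...) dendrogram_to_tree(x)

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Write a merge table to a delimited file
#'
#' Serialises the dendrogram as a TSV of merge records
#' (`step`, `child1`, `child2`, `height`, `size`).
#'
#' @inheritParams dendrogram_to_tree
#' @param path File path.
#' @export
write_merge_table <- function(wc, path) {
  readr::write_tsv(
    dplyr::select(tidy(wc), "step", "child1", "child2", "height", "size"),
    path
  )
  invisible(path)
}

#' Plot a Ward dendrogram with ggplot2
#'
#' @param object A `ward_clust` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ward_clust <- function(object, ...) {
  n <- object$n
  xpos <- numeric(n)                 # leaf x by display order
  xpos[object$order] <- seq_len(n)
  node_x <- numeric(n - 1)
  node_h <- object$height
  segs <- vector("list", n - 1)
  pos <- function(id) {
    if (id < 0) c(xpos[-id], 0) else c(node_x[id], node_h[id])
  }
  for (s in seq_len(n - 1)) {
    a <- pos(object$merge[s, 1]); b <- pos(object$merge[s, 2])
    node_x[s] <- mean(c(a[1], b[1]))
    h <- node_h[s]
    segs[[s]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h)
    )
  }
  leaves <- tibble(x = xpos, label = object$labels)
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "e-distance at merge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      panel.grid.major.x = ggplot2::element_blank(),
      axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
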