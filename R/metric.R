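#' Minkowski-family point distances
#'
#' `minkowski()` computes \eqn{(\sum_i |a_i - b_i|^r)^{1/r}} for \code{r > 0};
#' `manhattan()` is the \code{r = 1} case, `squared_euclidean()` is
#' \eqn{\sum_i (a_i - b_i)^2}, and `euclidean_power()` is the Euclidean
#' distance raised to a power \eqn{\theta \in (0, 2]}, the family for which
#' Ward's linkage admits an exact Lance-Williams recurrence through the
#' e-distance.
#'
#' @param a,b Numeric vectors of equal length.
#' @param r Minkowski exponent, \code{r > 0}.
#' @return A nonnegative scalar.
#' @examples
#' minkowski(c(0, 0), c(3, 4), 2)     # 5
#' manhattan(c(1, 2, 3), c(2, 0, 3))  # 3
#' squared_euclidean(c(0, 0), c(3, 4))  # 25
#' euclidean_power(c(0, 0), c(3, 4), 0.5)  # sqrt(5)
#' @export
minkowski <- function(a, b, r) {
  check_pair(a, b)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    abort_input("`r` must be a positive number.")
  }
  sum(abs(a - b)^r)^(1 / r)
}

#' @rdname minkowski
#' @export
manhattan <- function(a, b) {
  check_pair(a, b)
  sum(abs(a - b))
}

#' @rdname minkowski
#' @export
squared_euclidean <- function(a, b) {
  check_pair(a, b)
  sum((a - b)^2)
}

#' @rdname minkowski
#' @param theta Power of the Euclidean distance, in `(0, 2]`.
#' @export
euclidean_power <- function(a, b, theta) {
  check_pair(a, b)
  check_theta(theta)
  sum((a - b)^2)^(theta / 2)
}

check_pair <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    abort_input("`a` and `b` must be numeric vectors.")
  }
  if (length(a) != length(b)) {
    abort_input(sprintf("dimension mismatch: length(a) = %d, length(b) = %d.",
                        length(a), length(b)))
  }
  invisible(TRUE)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta > 2) {
    abort_input("`theta` must lie in (0, 2].")
  }
  invisible(TRUE)
}

# Resolve a metric name (+ parameter) into a canonical descriptor.
# Supported: manhattan, euclidean, sqeuclidean, minkowski (r), power (theta).
resolve_metric <- function(metric = c("manhattan", "euclidean", "sqeuclidean",
                                      "minkowski", "power"),
                           r = NULL, theta = NULL) {
  metric <- match.arg(metric)
  if (metric == "minkowski") {
    if (is.null(r)) abort_input("metric \"minkowski\" needs `r`.")
    if (!is.numeric(r) || length(r) != 1L || r <= 0) {
      abort_input("`r` must be a positive number.")
    }
  }
  if (metric == "power") {
    if (is.null(theta)) abort_input("metric \"power\" needs `theta`.")
    check_theta(theta)
  }
  pointfun <- switch(metric,
    manhattan = manhattan,
    euclidean = function(a, b) minkowski(a, b, 2),
    sqeuclidean = squared_euclidean,
    minkowski = function(a, b) minkowski(a, b, r),
    power = function(a, b) euclidean_power(a, b, theta)
  )
  structure(
    list(name = metric, r = r, theta = theta, pointfun = pointfun),
    class = "wardl1_metric"
  )
}

metric_label <- function(m) {
  switch(m$name,
    minkowski = sprintf("minkowski(r=%g)", m$r),
    power = sprintf("power(theta=%g)", m$theta),
    m$name
  )
}

# All pairwise point distances between the rows of x (and optionally y).
pairwise_point_dist <- function(x, m, y = NULL) {
  x <- as.matrix(x)
  if (is.null(y)) {
    d <- switch(m$name,
      manhattan = dist(x, method = "manhattan"),
      euclidean = dist(x, method = "euclidean"),
      sqeuclidean = dist(x, method = "euclidean")^2,
      minkowski = dist(x, method = "minkowski", p = m$r),
      power = dist(x, method = "euclidean")^m$theta
    )
    return(as.matrix(d))
  }
  y <- as.matrix(y)
  out <- matrix(0, nrow(x), nrow(y))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      out[i, j] <- m$pointfun(x[i, ], y[j, ])
    }
  }
  out
}

#' Labelled pairwise distance matrix
#'
#' Computes all pairwise distances between the rows of an
#' observation-by-feature table under a chosen metric. A character `label`
#' column (or row names) supplies the item labels.
#'
#' @param x Data frame or numeric matrix, one row per item. A column named
#'   `label` (or `labels` argument / row names) labels the items.
#' @param metric One of `"manhattan"`, `"euclidean"`, `"sqeuclidean"`,
#'   `"minkowski"` (with `r`), `"power"` (with `theta`).
#' @param r,theta Metric parameters, see [minkowski()] and
#'   [euclidean_power()].
#' @param labels Optional character vector of item labels.
#' @return A symmetric numeric matrix with zero diagonal and the labels as
#'   `dimnames`.
#' @examples
#' distance_matrix(data.frame(x = c(0, 2, 10)), labels = c("a", "b", "c"))
#' @export
distance_matrix <- function(x, metric = "manhattan", r = NULL, theta = NULL,
                            labels = NULL) {
  m <- resolve_metric(metric, r = r, theta = theta)
  dat <- extract_features(x, labels)
  if (nrow(dat$x) < 2L) {
    abort_input("need at least 2 items to build a distance matrix.")
  }
  d <- pairwise_point_dist(dat$x, m)
  diag(d) <- 0
  dimnames(d) <- list(dat$labels, dat$labels)
  d
}

# Split a tabular input into a numeric matrix + labels.
extract_features <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    lab_col <- intersect(c("label", "taxon", "item"), names(x))[1]
    if (is.null(labels) && !is.na(lab_col)) {
      labels <- as.character(x[[lab_col]])
    }
    x <- x[, setdiff(names(x), c("label", "taxon", "item")), drop = FALSE]
    if (!all(purrr::map_lgl(x, is.numeric))) {
      abort_input("all feature columns must be numeric.")
    }
    x <- as.matrix(x)
  } else if (is.matrix(x)) {
    if (is.null(labels)) labels <- rownames(x)
  } else {
    abort_input("`x` must be a data frame or numeric matrix.")
  }
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  if (length(labels) != nrow(x)) {
    abort_input("`labels` length must equal the number of rows.")
  }
  if (anyDuplicated(labels)) abort_input("item labels must be unique.")
  list(x = x, labels = labels)
}

# Validate a (square, symmetric, zero-diagonal, finite, nonnegative)
# distance matrix; mirrors a lower-triangle-only input.
validate_distance_matrix <- function(d, tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort_input("distance matrix must be square.")
  if (nrow(d) < 2L) abort_input("distance matrix must have at least 2 items.")
  upper_missing <- all(is.na(d[upper.tri(d)]))
  if (upper_missing) {
    d[upper.tri(d)] <- t(d)[upper.tri(d)]
  }
  if (any(!is.finite(d))) {
    abort_input("distance matrix contains missing or non-finite entries.")
  }
  if (any(d < 0)) abort_input("distances must be nonnegative.")
  if (max(abs(d - t(d))) > tol) {
    abort_input(sprintf("distance matrix is not symmetric (tolerance %g).",
                        tol))
  }
  if (any(diag(d) != 0)) {
    abort_input("distance matrix diagonal must be exactly zero.")
  }
  if (is.null(rownames(d))) {
    rn <- colnames(d) %||% as.character(seq_len(nrow(d)))
    dimnames(d) <- list(rn, rn)
  }
  d
}

#' Read and write labelled distance matrices
#'
#' Square delimited tables with a header row and a leading label column.
#' On input, a lower-triangle-only matrix (empty upper triangle) is accepted
#' and mirrored.
#'
#' @param d Distance matrix (see [distance_matrix()]).
#' @param path File path.
#' @return `read_distance_matrix()` returns a validated symmetric matrix.
#' @export
write_distance_matrix <- function(d, path) {
  d <- validate_distance_matrix(d)
  out <- dplyr::bind_cols(tibble(label = rownames(d)),
                          as_tibble(d, .name_repair = "minimal"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  labs <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labs, colnames(tab)[-1])
  validate_distance_matrix(m)
}
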