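#' Random first-order Markov character source
#'
#' Builds a row-stochastic transition table over the alphabet with
#' independent Dirichlet rows (all concentrations equal), plus the chain's
#' stationary distribution as initial distribution. This is the root
#' "language" from which a synthetic corpus evolves: texts drawn from such a
#' source have character statistics where the probability of a character
#' depends strongly on the preceding one, the premise under which bi-gram
#' signatures separate sources.
#'
#' @inheritParams clean_text
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param concentration Dirichlet concentration of the rows (default 1,
#'   uniform over the simplex).
#' @return A `markov_source`: list with `alphabet`, `trans` (row-stochastic
#'   matrix with symbol dimnames) and `init` (stationary distribution).
#' @export
markov_source <- function(alphabet, seed = NULL, concentration = 1) {
  stopifnot(inherits(alphabet, "sls_alphabet"))
  if (!is.null(seed)) set.seed(seed)
  k <- alphabet_size(alphabet)
  g <- matrix(stats::rgamma(k * k, shape = concentration), k, k)
  trans <- g / rowSums(g)
  dimnames(trans) <- list(alphabet$symbols, alphabet$symbols)
  new_markov_source(alphabet, trans)
}

new_markov_source <- function(alphabet, trans) {
  check_stochastic(trans)
  structure(
    list(alphabet = alphabet, trans = trans, init = stationary_dist(trans)),
    class = "markov_source"
  )
}

check_stochastic <- function(trans, tol = 1e-12) {
  if (!is.matrix(trans) || nrow(trans) != ncol(trans)) {
    abort_input("transition table must be a square matrix.")
  }
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > tol)) {
    abort_input("transition table rows must be nonnegative and sum to 1.")
  }
  invisible(TRUE)
}

# Stationary distribution of an ergodic chain (left Perron eigenvector).
stationary_dist <- function(trans) {
  ev <- eigen(t(trans))
  i <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

#' @export
print.markov_source <- function(x, ...) {
  cat(sprintf("<markov_source> alphabet of %d symbols\n",
              alphabet_size(x$alphabet)))
  invisible(x)
}

#' Plant a random binary tree over synthetic taxa
#'
#' Draws a random rooted binary topology (coalescent-shaped) over `n_taxa`
#' labelled tips `t1 ... tn`, reproducibly under `seed`, and makes it
#' ultrametric with geometrically spaced node heights: the `k`-th split
#' (counting from the shallowest) sits at height `level_ratio^(2 (k - m))`
#' with `m = n_taxa - 1`, so the root has height 1. Under the
#' branch-length-scaled divergence of [evolve_sources()] the expected
#' distance between leaves then grows like the square root of their
#' divergence time, and consecutive divergence levels keep a constant
#' *relative* separation of `level_ratio` — scale-free separation that is
#' what makes the planted hierarchy recoverable at every depth.
#'
#' @param n_taxa Number of tips, at least 3.
#' @inheritParams markov_source
#' @param level_ratio Geometric spacing of consecutive divergence levels in
#'   distance scale (default 2: each deeper level is twice as distant).
#' @return An [ape::phylo] tree (ultrametric, root height 1).
#' @export
plant_tree <- function(n_taxa, seed = NULL, level_ratio = 2) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 3 ||
      n_taxa != round(n_taxa)) {
    abort_input("`n_taxa` must be an integer >= 3.")
  }
  if (!is.numeric(level_ratio) || length(level_ratio) != 1L ||
      level_ratio < 1) {
    abort_input("`level_ratio` must be >= 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_taxa)
  tr <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  bt <- ape::branching.times(tr)
  h <- setNames(level_ratio^(2 * (rank(bt) - (n - 1L))), names(bt))
  node_height <- function(node) {
    if (node <= n) 0 else h[[as.character(node)]]
  }
  tr$edge.length <- apply(tr$edge, 1L, function(e) {
    node_height(e[1L]) - node_height(e[2L])
  })
  tr
}

#' Evolve Markov sources along a planted tree
#'
#' Starting from the root source, each edge perturbs the parent's transition
#' table by additive symmetric noise — uniform on
#' \eqn{[-\epsilon\sqrt{\ell}, \epsilon\sqrt{\ell}]} per entry, where
#' \eqn{\ell} is the edge's branch length (taken as 1 when the tree carries
#' no lengths) — then clips at zero and renormalises the rows. Scaling the
#' magnitude with the square root of branch length makes the divergence a
#' Brownian-like walk: perturbation *variance* accumulates linearly with
#' divergence time, so on an ultrametric tree the expected distance between
#' leaf sources depends only on the age of their most recent common
#' ancestor. `epsilon` is therefore the total root-to-leaf divergence
#' magnitude on a height-1 tree, and `epsilon = 0` leaves every leaf source
#' identical to the root.
#'
#' @param root A `markov_source` (see [markov_source()]).
#' @param tree An [ape::phylo] tree (see [plant_tree()]).
#' @param epsilon Divergence magnitude, `>= 0`.
#' @inheritParams markov_source
#' @return Named list of `markov_source` objects, one per tip.
#' @export
evolve_sources <- function(root, tree, epsilon, seed = NULL) {
  stopifnot(inherits(root, "markov_source"), inherits(tree, "phylo"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    abort_input("`epsilon` must be a nonnegative number.")
  }
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")  # parent-before-child edge walk
  k <- alphabet_size(root$alphabet)
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  lens <- tree$edge.length %||% rep(1, nrow(tree$edge))
  sources <- vector("list", max(tree$edge))
  sources[[root_node]] <- root$trans
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    sources[[child]] <- perturb_rows(sources[[parent]],
                                     epsilon * sqrt(lens[e]), k)
  }
  leaves <- purrr::map(seq_len(n_tip), function(i) {
    new_markov_source(root$alphabet, sources[[i]])
  })
  setNames(leaves, tree$tip.label)
}

perturb_rows <- function(trans, magnitude, k) {
  noisy <- trans + matrix(stats::runif(k * k, -magnitude, magnitude), k, k)
  noisy <- pmax(noisy, 0)
  zero <- rowSums(noisy) == 0
  noisy[zero, ] <- 1 / k
  noisy / rowSums(noisy)
}

#' Sample a text from a Markov source
#'
#' Draws a character chain of the given length from the source (initial
#' character from the stationary distribution, then first-order
#' transitions), reproducibly under `seed`.
#'
#' @param source A `markov_source`.
#' @param length Number of characters, at least 2.
#' @inheritParams markov_source
#' @param label Document label.
#' @return An `sls_document`.
#' @export
sample_text <- function(source, length, seed = NULL, label = "") {
  stopifnot(inherits(source, "markov_source"))
  if (!is.numeric(length) || length(length) != 1L || length < 2 ||
      length != round(length)) {
    abort_input("`length` must be an integer >= 2.")
  }
  if (!is.null(seed)) set.seed(seed)
  cum <- t(apply(source$trans, 1L, cumsum))
  idx <- markov_chain_sample(cum, cumsum(source$init), as.integer(length))
  new_document(label,
               paste(source$alphabet$symbols[idx], collapse = ""),
               n = as.integer(length))
}

#' Generate a synthetic corpus of related "languages"
#'
#' End-to-end fixture generator: plants a random binary tree over `n_taxa`
#' taxa, evolves a root Markov character source along it with per-edge
#' divergence `epsilon`, and samples one text per leaf. With strong
#' separation (the defaults) the planted topology is recoverable by
#' Manhattan-Ward clustering of the texts' bi-gram signatures, which is the
#' package's end-to-end correctness probe. All randomness flows from the
#' single `seed`.
#'
#' @param n_taxa Number of taxa (default 8).
#' @param length Characters per text (default `1e5`).
#' @param epsilon Root-to-leaf divergence magnitude (default 0.1; see
#'   [evolve_sources()]).
#' @param alphabet_size Number of symbols including the separator
#'   (default 12: eleven letters plus `"_"`).
#' @param seed Integer seed (default 1).
#' @param concentration Dirichlet concentration of the root source rows
#'   (default 10; larger keeps rows away from the simplex boundary so all
#'   bi-gram cells carry divergence signal).
#' @param level_ratio Geometric divergence-level spacing of the planted
#'   tree (default 2; see [plant_tree()]).
#' @param outdir Optional directory: one `<taxon>.txt` per leaf plus the
#'   planted tree as `planted_tree.nwk` are written there.
#' @return A list of class `synth_corpus`: `corpus` (tibble with `label`,
#'   `text`), `tree` (the planted [ape::phylo]), `alphabet`, `sources`,
#'   and the generating parameters.
#' @export
synth_corpus <- function(n_taxa = 8, length = 1e5, epsilon = 0.1,
                         alphabet_size = 12, seed = 1, concentration = 10,
                         level_ratio = 2, outdir = NULL) {
  if (alphabet_size < 3 || alphabet_size > 27) {
    abort_input("`alphabet_size` must be in [3, 27] (letters plus separator).")
  }
  alphabet <- build_alphabet(letters[seq_len(alphabet_size - 1L)],
                             separator = "_")
  set.seed(seed)
  tree <- plant_tree(n_taxa, seed = NULL, level_ratio = level_ratio)
  root <- markov_source(alphabet, seed = NULL,
                        concentration = concentration)
  sources <- evolve_sources(root, tree, epsilon, seed = NULL)
  docs <- purrr::imap(sources, function(src, lab) {
    sample_text(src, length, seed = NULL, label = lab)
  })
  corpus <- tibble(
    label = unname(purrr::map_chr(docs, "label")),
    text = unname(purrr::map_chr(docs, "chars"))
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    purrr::pwalk(corpus, function(label, text) {
      readr::write_lines(text, file.path(outdir, paste0(label, ".txt")))
    })
    write_newick(tree, file.path(outdir, "planted_tree.nwk"))
  }
  structure(
    list(corpus = corpus, tree = tree, alphabet = alphabet,
         sources = sources,
         params = list(n_taxa = n_taxa, length = length, epsilon = epsilon,
                       alphabet_size = alphabet_size, seed = seed,
                       concentration = concentration,
                       level_ratio = level_ratio)),
    class = "synth_corpus"
  )
}

#' @export
print.synth_corpus <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synth_corpus> %d taxa, %g chars each, epsilon %g, alphabet %d, seed %d\n",
    p$n_taxa, p$length, p$epsilon, p$alphabet_size, p$seed
  ))
  invisible(x)
}
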