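#' Parse and write Newick trees
#'
#' Thin, validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. `parse_newick()` checks parenthesis balance (the
#' first offending character position is reported) and duplicate leaf
#' labels before handing the string to ape; `write_newick()` serialises a
#' `phylo` (or `ward_clust`) to a Newick string or file.
#'
#' @param text A Newick string, or the path of a file containing one.
#' @return `parse_newick()` returns an [ape::phylo] tree; `write_newick()`
#'   returns the Newick string (invisibly when written to a file).
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' write_newick(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort_input("`text` must be a single Newick string or file path.")
  }
  if (!grepl("[();]", text) && file.exists(text)) {
    text <- paste(readr::read_lines(text), collapse = "")
  }
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort_input("could not parse Newick string.")
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) {
    abort_input(sprintf("duplicate leaf label(s): %s",
                        paste(sQuote(dup), collapse = ", ")))
  }
  tr
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort_input(sprintf("unbalanced ')' at position %d.", i))
      }
    }
  }
  if (depth != 0L) {
    abort_input(sprintf(
      "unbalanced parentheses: %d '(' left open at end of string.", depth
    ))
  }
  if (!grepl(";", text)) {
    abort_input("Newick string must end with ';'.")
  }
  invisible(TRUE)
}

#' @rdname parse_newick
#' @param tree An [ape::phylo] tree or a `ward_clust` object.
#' @param path Optional file path; when given the string is written there.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (inherits(tree, "ward_clust")) tree <- dendrogram_to_tree(tree)
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    readr::write_lines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Splits (bipartitions) or clades induced by a tree
#'
#' In the unrooted sense (default), every internal edge of the tree splits
#' the leaf set into two parts; splits are stored orientation-free (each is
#' canonicalised to the side not containing the alphabetically first leaf)
#' and trivial splits (one leaf against the rest) are excluded. With
#' `rooted = TRUE` the clades of internal non-root nodes are returned
#' instead (no complementing).
#'
#' @param tree An [ape::phylo] tree.
#' @param rooted Use rooted clades instead of unrooted splits.
#' @return A character vector of canonical split keys (sorted leaf labels
#'   joined by `"\\r"`).
#' @export
tree_splits <- function(tree, rooted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  ref <- min(labs)                 # orientation anchor
  clades <- ape::prop.part(tree)   # leaf-index sets of internal nodes
  keys <- character(0)
  for (cl in clades) {
    side <- labs[cl]
    if (!rooted) {
      if (ref %in% side) side <- setdiff(labs, side)
      if (length(side) < 2L || length(side) > n - 2L) next
    } else {
      if (length(side) < 2L || length(side) >= n) next
    }
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two leaf-labelled trees
#'
#' The size of the symmetric difference of the two trees' nontrivial split
#' sets: the number of bipartitions present in exactly one of the trees.
#' Only topology enters — branch lengths are ignored — and rooted inputs are
#' compared on their unrooted view unless `rooted_clades = TRUE`, in which
#' case unmatched rooted clades are counted instead. The distance is 0 iff
#' the (unrooted) topologies are identical, and is at most `2(n - 3)` for
#' two binary trees on `n` leaves. Multifurcating trees are supported.
#'
#' @param t1,t2 [ape::phylo] trees (or `ward_clust` objects) on the same
#'   leaf-label set.
#' @param rooted_clades Count unmatched rooted clades instead of unrooted
#'   splits.
#' @return A nonnegative integer.
#' @examples
#' robinson_foulds(parse_newick("((A,B),(C,D));"),
#'                 parse_newick("((A,C),(B,D));"))  # 2
#' @export
robinson_foulds <- function(t1, t2, rooted_clades = FALSE) {
  if (inherits(t1, "ward_clust")) t1 <- dendrogram_to_tree(t1)
  if (inherits(t2, "ward_clust")) t2 <- dendrogram_to_tree(t2)
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    abort_input(sprintf(
      "leaf sets differ. Only in tree 1: %s. Only in tree 2: %s.",
      paste(only1, collapse = ", ") %0% "(none)",
      paste(only2, collapse = ", ") %0% "(none)"
    ))
  }
  s1 <- tree_splits(t1, rooted = rooted_clades)
  s2 <- tree_splits(t2, rooted = rooted_clades)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

`%0%` <- function(x, fallback) if (nchar(x) == 0) fallback else x
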