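---
title: "Generalised Ward clustering with Manhattan distances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalised Ward clustering with Manhattan distances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardl1)
```

## The model

### From minimum variance to least absolute error

Classical Ward linkage merges, at every step of an agglomerative
hierarchical clustering, the pair of clusters $A$, $B$ whose union causes
the smallest increase

$$I_{AB} = \mathrm{SSE}_{AB} - \mathrm{SSE}_A - \mathrm{SSE}_B
        = \frac{n_A n_B}{n_A + n_B}\,\lVert \bar a - \bar b \rVert_2^2$$

in within-cluster sum of squared errors, which is why it is usually stated
to require squared Euclidean dissimilarities. The restriction is an
artefact of writing the objective through centroids. Writing it instead
through *all pairwise point distances* gives the between-cluster
**e-distance**

$$e(A, B) = \frac{n_A n_B}{n_A + n_B}
  \left( 2\delta_{AB} - \delta_{AA} - \delta_{BB} \right),
\qquad
\delta_{XY} = \frac{1}{n_X n_Y} \sum_{i \in X}\sum_{j \in Y} d(x_i, y_j),$$

where the within-cluster constants $\delta_{AA}$, $\delta_{BB}$ average
over *all ordered pairs including self-pairs* (denominator $n_A^2$). Three
instantiations of the point distance $d$ matter here:

* $d = \lVert\cdot\rVert_2^2$ (squared Euclidean): $e(A,B) = 2 I_{AB}$
  exactly, so the e-distance formulation *is* classical Ward up to a factor
  2 (`e_distance(..., metric = "sqeuclidean")`, and the package tests
  verify the identity against explicit centroid arithmetic);
* $d = \lVert\cdot\rVert_2^{\theta}$ for $0 < \theta \le 2$: the objective
  becomes a "mean error to the power θ" (`metric = "power"`);
* $d = \lVert\cdot\rVert_1$ (Manhattan): the objective becomes least
  absolute error (`metric = "manhattan"`, the package default).

For singleton clusters $e(\{a\},\{b\}) = d(a, b)$: raw-vector input is
therefore seeded with plain point distances.

### The exact recurrence

The practical content of the generalisation is that the e-distance obeys a
Lance–Williams recurrence *exactly*, for any point metric, because the
derivation only manipulates the $\delta$ sums:

$$e(A \cup B, C) =
  \frac{n_A + n_C}{S} e(A,C) + \frac{n_B + n_C}{S} e(B,C)
  - \frac{n_C}{S} e(A,B), \qquad S = n_A + n_B + n_C,$$

i.e. Ward's classical update coefficients
$\alpha_A = (n_A+n_C)/S$, $\alpha_B = (n_B+n_C)/S$, $\beta = -n_C/S$,
$\gamma = 0$ (`ward_lw_parameters()`). After the initial point-distance
matrix, the agglomeration never touches the raw data again. Since
$\alpha_A + \alpha_B + \beta = 1$, $\min(\alpha_A,\alpha_B) \ge 0$ and
$\gamma \ge 0$, the textbook sufficient conditions for monotonicity hold:
merge heights never decrease, dendrograms have no reversals
(`check_monotonic()`, `lw_monotonic_conditions()`).

This exactness is the package's central testable claim, and the test suite
treats it as such: randomized datasets are clustered while tracing every
Lance–Williams update (`ward_cluster(..., trace = TRUE)`), and each update
is compared against a brute-force e-distance recomputed from raw members
through an independent code path (block means of a `stats::dist` matrix).
Agreement is required to $10^{-8}$ relative error; in practice it sits at
the level of floating-point accumulation ($\sim 10^{-15}$), as there are no
iterative or approximate steps anywhere in the chain.

A terminological footnote: Ward's method is widely described as
space-conserving, yet its $\beta = -n_C/S \ne 0$ fails the textbook literal
condition $\beta = 0$ for space conservation.
`check_space_conditions()` reports each condition's literal truth value and
flags this discrepancy instead of resolving it.

### Merge heights and tie-breaking

Heights recorded in the dendrogram are the raw e-distance at the merge —
no doubling, halving, or square roots. Implementations of Ward linkage
disagree on this scaling; the raw convention is the one under which the
recurrence above is exact as written, and under which the squared-Euclidean
heights equal exactly $2 I_{AB}$. Ties at the minimal distance are broken
towards the lexicographically smallest (smaller id, larger id) pair, ids
being input order for leaves and creation order for merged clusters; this
makes runs deterministic and independent of floating-point scan order.
`dendrogram_to_tree()` converts merges to a rooted binary tree whose child
branch lengths are parent height minus child height, so leaf depth equals
the root's merge height.

## n-gram signatures

Documents are represented by the relative frequencies of their overlapping
character bi-grams: with $n_{\alpha\beta}$ occurrences of the ordered pair
$\alpha\beta$ in a cleaned document of $n$ characters (separators
included), the signature entry is $n_{\alpha\beta} / (n-1)$ — there are
exactly $n-1$ overlapping bi-grams, so entries sum to one. Signatures are
laid out row-major over the alphabet ordering (first symbol varies
slowest), and the layout is part of the on-disk contract so signature
tables from different runs are column-compatible. The packaged
`default_alphabet()` has 65 characters — the 26 basic Latin letters, the
word separator `_`, and 38 accented characters common across Latin-script
European languages — giving $p = 65^2 = 4225$ dimensions. The n-gram order
`k` is exposed (default 2); `k = 3` is the natural extension when
documents are long enough to populate $65^3$ cells.

Text cleaning is a declared convention of this package, not a property of
the method: input is Unicode-composed (NFC) and lower-cased, maximal
whitespace runs become one separator, characters outside the alphabet are
dropped (with a reported count), separator runs left behind by the drops
are collapsed, and leading/trailing separators are trimmed. Dropping
rather than failing suits mixed real-world text (digits, punctuation,
stray markup); the count lets a user notice when an alphabet is badly
mismatched to a corpus. Cleaning is idempotent, and a document with fewer
than two characters after cleaning is rejected rather than silently
yielding an empty signature.

## Validation measures

For a partition of a distance matrix, three standard internal measures are
provided. Silhouette: $S(i) = (b_i - a_i)/\max(a_i, b_i)$ with $a_i$ the
mean distance to co-members and $b_i$ the smallest mean distance to another
cluster; items in singleton clusters get $S(i) = 0$, the conventional value
where the ratio is undefined. Dunn index: smallest between-cluster point
distance over largest within-cluster diameter; an all-singleton partition
has an empty denominator and is reported as `Inf` rather than an error.
Connectivity: for each item, its `L` nearest neighbours are examined and a
penalty $1/j$ accrues when the $j$-th neighbour lies in another cluster;
neighbour ties break by item index, an item is never its own neighbour,
and `L` defaults to $\min(10, m-1)$ — the literal "all other items"
reading is available via `L = m - 1`.

## The synthetic corpus generator

`synth_corpus()` exists so that the whole pipeline — text files on disk →
cleaning → signatures → Manhattan–Ward → tree comparison — can be
exercised end to end with a known ground truth. It emulates a family of
related languages as first-order Markov character sources: the probability
of a character depends strongly on its predecessor, which is exactly the
structure bi-gram signatures capture, and the sources diverge along a
planted binary tree.

Design of the generator, fixed once:

* **Planted topology** (`plant_tree()`): a random coalescent-shaped binary
  topology, made ultrametric with *geometrically spaced* node heights —
  the $k$-th shallowest of the $m = n-1$ splits sits at height
  $\rho^{2(k-m)}$, default level ratio $\rho = 2$, root height 1.
* **Divergence** (`evolve_sources()`): along each edge of length $\ell$,
  every transition-table entry receives independent additive noise uniform
  on $[-\varepsilon\sqrt{\ell}, +\varepsilon\sqrt{\ell}]$, then rows are
  clipped at zero and renormalised. The $\sqrt{\ell}$ scaling makes the
  divergence a Brownian-like walk whose *variance* accumulates linearly
  with divergence time, so on an ultrametric tree the expected distance
  between two leaf sources depends only on the age of their most recent
  common ancestor — the planted hierarchy is a genuine ultrametric signal.
  Because expected distances then grow like the square root of divergence
  time, the geometric height spacing above translates into a constant
  *relative* gap (the level ratio) between consecutive divergence levels:
  separation is scale-free, equally strong at the shallowest and deepest
  splits. Ward linkage preserves an exactly ultrametric distance matrix
  step for step (the update coefficients sum to one), so recovery failures
  can only come from deviations around the expectation.
* **Root source** (`markov_source()`): independent Dirichlet rows; the
  corpus generator uses concentration 10 by default so rows stay away from
  the simplex boundary, all bi-gram cells carry divergence signal, and
  clipping stays rare. The initial character is drawn from the chain's
  stationary distribution, so empirical bi-gram frequencies converge to
  the stationary pair probabilities $\pi_\alpha P_{\alpha\beta}$ (a
  law-of-large-numbers test checks total variation < 0.05 at $10^5$
  characters).
* **Defaults as study conditions**: 8 taxa, $10^5$ characters per text,
  $\varepsilon = 0.1$ (the total root-to-leaf divergence magnitude on the
  height-1 tree), alphabet of 12 symbols (11 letters plus separator). The
  divergence magnitude is chosen for strong separation: about an order of
  magnitude above the sampling noise of bi-gram frequencies at $10^5$
  characters, while small enough that transition rows remain interior. All
  randomness flows from a single integer seed; the chain sampler is
  compiled (Rcpp) but draws from R's RNG, so `set.seed()` governs it.

What the generator does *not* emulate: real languages share vocabulary and
borrow words, alphabets differ across related languages, text lengths and
genres vary, and bi-gram distributions drift within a language. Passing
recovery tests on this corpus therefore demonstrates the correctness and
discriminating power of the pipeline under a clean hierarchical signal,
not the linguistic adequacy of bi-gram signatures on real corpora.

## Tree comparison

`robinson_foulds()` counts the bipartitions (nontrivial splits induced by
internal edges, in the unrooted sense) present in exactly one of two
leaf-labelled trees. Branch lengths are ignored; the distance is 0 exactly
when the unrooted topologies agree and is bounded by $2(n-3)$ for two
binary trees on $n$ leaves. Multifurcating trees are supported — the
symmetric difference of split sets remains well defined. Because
agglomerative dendrograms are rooted while the standard metric is
unrooted, a stricter variant counting unmatched *rooted clades* is
available via `rooted_clades = TRUE`; the two modes differ exactly when
two trees agree as unrooted topologies but are rooted differently.

## Numerical choices

* Distance-matrix symmetry is required within $10^{-12}$, the diagonal
  exactly zero; lower-triangle-only files are mirrored on read.
* The Lance–Williams-vs-brute-force audit uses $10^{-8}$ relative
  tolerance; monotonicity uses $10^{-9}$. Both are pure floating-point
  accumulation margins — there are no solvers or approximations whose
  error they would need to absorb.
* Powered Euclidean distances are computed as
  $(\sum_l (a_l-b_l)^2)^{\theta/2}$, i.e. the Euclidean distance raised to
  $\theta$, with $\theta \in (0, 2]$ enforced; `theta = 2` is squared
  Euclidean. Conventions in print sometimes read as the square or the
  θ-th power of the *squared* distance; this package's reading is declared
  here and applied consistently.
* Degenerate inputs fail fast with classed input errors (used by the CLI
  to distinguish exit code 2 from computation failures, exit 3): fewer
  than two items, overlapping cluster member sets, non-finite distances,
  out-of-range `k`/`L`/`theta`, unbalanced Newick, duplicate labels.

## Problem sizes used in the checks

The randomized audits run on datasets of up to 30 items and 10 features
(200 datasets across the four metric instantiations for the recurrence
audit, 100 for the squared-Euclidean equivalence, 500 size triples for the
parameter conditions, 100 random tree pairs with up to 12 leaves for
Robinson–Foulds). The end-to-end study uses 20 corpus replicates of 8 taxa
× $10^5$ characters, with 100 label permutations for the validation
comparison. These sizes exercise every code path at comfortably
interactive runtimes while keeping the brute-force oracles exact.

## Known limitations

* The agglomeration engine is the straightforward $O(N^3)$
  Lance–Williams loop, entirely adequate for the tens-to-hundreds of items
  this package targets, but not for $N \gg 10^3$ (nearest-neighbour-chain
  algorithms would be the upgrade path).
* Only Ward-parameter updates are wired into the public API, although the
  engine trivially admits other Lance–Williams schemes.
* Manhattan e-distances lack the centroid shortcut of squared Euclidean,
  so raw-vector mode materialises the full point-distance matrix.
* Robinson–Foulds counts topology only and has no significance scale of
  its own; equal leaf sets are required.
* The cleaning convention is deliberately simple; no transliteration
  between scripts is attempted.
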