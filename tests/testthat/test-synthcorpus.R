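test_that("planted trees are seeded, ultrametric, binary and geometric in height", {
  t1 <- plant_tree(6, seed = 1)
  t2 <- plant_tree(6, seed = 1)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_true(ape::is.binary(t1))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1)  # unit root height

  # different seeds give differing topologies at least sometimes
  rfs <- vapply(1:25, function(s) {
    robinson_foulds(plant_tree(8, seed = s), plant_tree(8, seed = s + 100))
  }, numeric(1))
  expect_gt(sum(rfs > 0), 0)

  expect_error(plant_tree(2), ">= 3")
})

test_that("markov sources are row-stochastic with a stationary initial law", {
  ab <- build_alphabet(letters[1:5])
  src <- markov_source(ab, seed = 7)
  expect_equal(rowSums(src$trans), setNames(rep(1, 6), ab$symbols))
  expect_true(all(src$trans >= 0))
  # init is stationary: pi P = pi
  expect_equal(as.numeric(src$init %*% src$trans), as.numeric(src$init),
               tolerance = 1e-10)
})

test_that("evolve_sources keeps rows stochastic and is the identity at epsilon 0", {
  ab <- build_alphabet(letters[1:5])
  root <- markov_source(ab, seed = 3)
  tree <- plant_tree(5, seed = 3)

  same <- evolve_sources(root, tree, epsilon = 0, seed = 3)
  for (leaf in same) expect_equal(leaf$trans, root$trans)

  moved <- evolve_sources(root, tree, epsilon = 0.2, seed = 3)
  for (leaf in moved) {
    expect_equal(unname(rowSums(leaf$trans)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(leaf$trans >= 0))
  }
  expect_false(identical(moved[[1]]$trans, root$trans))
})

test_that("sister taxa end up closer in signature space than non-sisters", {
  # Monte Carlo over replicates: compare the two most recently diverged taxa
  # against the pair spanning the root
  wins <- 0L
  for (s in 1:10) {
    sc <- synth_corpus(n_taxa = 4, length = 2e4, seed = s)
    sig <- sls_signatures(sc$corpus, sc$alphabet)
    d <- distance_matrix(sig, metric = "manhattan")
    co <- ape::cophenetic.phylo(sc$tree)[rownames(d), colnames(d)]
    sisters <- which(co == min(co[co > 0]), arr.ind = TRUE)[1, ]
    apart <- which(co == max(co), arr.ind = TRUE)[1, ]
    if (d[sisters[1], sisters[2]] < d[apart[1], apart[2]]) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("sampled texts are seeded, in-alphabet, and converge to stationary bi-gram law", {
  ab <- build_alphabet(letters[1:5])
  src <- markov_source(ab, seed = 11)
  d1 <- sample_text(src, 1000, seed = 4)
  d2 <- sample_text(src, 1000, seed = 4)
  expect_identical(d1$chars, d2$chars)
  expect_equal(d1$n, 1000)
  chars <- strsplit(d1$chars, "")[[1]]
  expect_true(all(chars %in% ab$symbols))
  expect_error(sample_text(src, 1), ">= 2")

  # law of large numbers: empirical bi-gram frequencies approach the
  # stationary pair probabilities pi_a P(a,b)
  long <- sample_text(src, 1e5, seed = 5)
  emp <- signature_of(long, ab)
  theo <- as.vector(t(src$trans * src$init))
  expect_lt(sum(abs(emp - theo)) / 2, 0.05)     # total variation
})

test_that("synth_corpus is reproducible and writes a complete corpus directory", {
  a <- synth_corpus(n_taxa = 4, length = 500, seed = 2)
  b <- synth_corpus(n_taxa = 4, length = 500, seed = 2)
  expect_identical(a$corpus, b$corpus)
  expect_equal(write_newick(a$tree), write_newick(b$tree))

  dir <- withr::local_tempdir()
  sc <- synth_corpus(n_taxa = 4, length = 500, seed = 9, outdir = dir)
  expect_setequal(list.files(dir),
                  c(paste0(sc$corpus$label, ".txt"), "planted_tree.nwk"))
  reread <- read_corpus(dir)
  expect_identical(sort(reread$label), sort(sc$corpus$label))
  planted <- parse_newick(file.path(dir, "planted_tree.nwk"))
  expect_equal(robinson_foulds(planted, sc$tree), 0)
})

test_that("Manhattan-Ward on signatures recovers a planted 6-taxon topology", {
  # smaller, faster spot-check; the full 8-taxon/1e5-character study runs in
  # the acceptance suite
  hits <- sum(vapply(1:5, function(s) {
    sc <- synth_corpus(n_taxa = 6, length = 3e4, seed = s)
    sig <- sls_signatures(sc$corpus, sc$alphabet)
    robinson_foulds(ward_cluster(sig), sc$tree) == 0
  }, logical(1)))
  expect_gte(hits, 4)
})
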