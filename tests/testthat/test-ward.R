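test_that("delta constants are block means including self-pairs", {
  x <- matrix(c(0, 2, 10), ncol = 1)
  expect_equal(cluster_delta(x, 1:2), 1)           # (0+2+2+0)/4
  expect_equal(cluster_delta(x, 1), 0)             # singleton self-distance
  expect_equal(cluster_delta(x, 1, 3), 10)         # single pair
  expect_error(cluster_delta(x, integer(0)), "nonempty")
})

test_that("e-distance matches its defining formula and the singleton limit", {
  x <- matrix(c(0, 2, 10), ncol = 1)
  expect_equal(e_distance(x, 1, 3), 10)            # singletons: point metric
  expect_equal(e_distance(x, 1:2, 3), 34 / 3)      # (2/3)(2*9 - 1 - 0)
  expect_error(e_distance(x, 1:2, 2:3), "overlap")

  # matches the brute-force block-mean oracle on random clusters
  withr::with_seed(21, {
    for (i in 1:20) {
      y <- rand_dataset(12, 4)
      a <- sample(12, 5); b <- setdiff(sample(12, 9), a)[1:3]
      pd <- oracle_point_dist(y, "manhattan")
      expect_equal(e_distance(y, a, b), oracle_e_distance(pd, a, b))
    }
  })
})

test_that("squared-Euclidean e-distance equals twice the centroid SSE increase", {
  withr::with_seed(31, {
    for (i in 1:25) {
      y <- rand_dataset(14, 5)
      a <- sample(14, 4); b <- setdiff(sample(14, 10), a)[1:4]
      expect_equal(
        e_distance(y, a, b, metric = "sqeuclidean"),
        2 * oracle_sse_increase(y, a, b),
        tolerance = 1e-9
      )
    }
  })
})

test_that("Ward Lance-Williams parameters match their closed form", {
  p <- ward_lw_parameters(1, 1, 1)
  expect_equal(p$alpha_a, 2 / 3)
  expect_equal(p$alpha_b, 2 / 3)
  expect_equal(p$beta, -1 / 3)
  expect_equal(p$gamma, 0)

  p2 <- ward_lw_parameters(2, 1, 1)
  expect_equal(unlist(p2), c(alpha_a = 3 / 4, alpha_b = 1 / 2,
                             beta = -1 / 4, gamma = 0))
  expect_error(ward_lw_parameters(0, 1, 1), ">= 1")
})

test_that("Ward parameters satisfy the monotonicity conditions for 500 random size triples", {
  withr::with_seed(13, {
    sizes <- matrix(sample(1:200, 1500, replace = TRUE), ncol = 3)
  })
  p <- ward_lw_parameters(sizes[, 1], sizes[, 2], sizes[, 3])
  expect_equal(p$alpha_a + p$alpha_b + p$beta, rep(1, 500), tolerance = 1e-12)
  expect_true(all(pmin(p$alpha_a, p$alpha_b) >= 0))
  expect_true(all(p$gamma == 0))
  expect_true(all(lw_monotonic_conditions(p)$monotone_guaranteed))
})

test_that("lw_update reproduces the hand-traced merge and handles zeros", {
  expect_equal(lw_update(10, 8, 2, ward_lw_parameters(1, 1, 1)), 34 / 3)
  expect_equal(lw_update(0, 0, 0, ward_lw_parameters(3, 2, 5)), 0)
  expect_error(lw_update(-1, 0, 0, ward_lw_parameters(1, 1, 1)),
               "nonnegative")
})

test_that("the LW recurrence equals brute-force e-distance recomputation", {
  # the exactness theorem, spot-checked here; the full randomized sweep
  # lives in the acceptance suite
  withr::with_seed(17, {
    for (metric in c("manhattan", "sqeuclidean", "power")) {
      res <- audit_lw_run(rand_dataset(12, 4), metric, theta = 1.5)
      expect_lt(res$max_rel, 1e-8)
    }
  })
})

test_that("agglomeration reproduces the 1-D hand trace {0, 2, 10}", {
  wc <- ward_cluster(data.frame(x = c(0, 2, 10)))
  expect_equal(wc$height, c(2, 34 / 3))
  expect_equal(wc$sizes, c(2L, 3L))
  expect_equal(wc$merge[1, ], c(-1L, -2L))
  expect_equal(cut_tree(wc, 2), c(`1` = 1L, `2` = 1L, `3` = 2L))
})

test_that("identical points merge at height zero", {
  wc <- ward_cluster(matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(wc$height, 0)
})

test_that("matrix mode agrees with hclust ward.D on the same dissimilarities", {
  withr::with_seed(23, {
    x <- rand_dataset(20, 6)
  })
  d <- distance_matrix(x, metric = "manhattan",
                       labels = paste0("i", 1:20))
  wc <- ward_cluster_d(d)
  hc <- hclust(as.dist(d), method = "ward.D")
  expect_equal(sort(wc$height), sort(hc$height))
  for (k in c(2, 4, 7)) {
    expect_equal(unname(cut_tree(wc, k)), unname(cutree(hc, k)))
  }
})

test_that("raw-vector mode seeds the engine with point distances", {
  withr::with_seed(29, {
    x <- rand_dataset(10, 3)
  })
  wc_vec <- ward_cluster(x, metric = "manhattan")
  wc_mat <- ward_cluster_d(distance_matrix(x, metric = "manhattan"))
  expect_equal(wc_vec$height, wc_mat$height)
  expect_equal(wc_vec$merge, wc_mat$merge)
})

test_that("relabelling the input yields an isomorphic dendrogram", {
  withr::with_seed(37, {
    x <- rand_dataset(15, 4)
    rownames(x) <- paste0("s", 1:15)
    perm <- sample(15)
  })
  wc1 <- ward_cluster(x)
  wc2 <- ward_cluster(x[perm, ])
  expect_equal(sort(wc1$height), sort(wc2$height), tolerance = 1e-12)
  for (k in 2:14) {
    p1 <- cut_tree(wc1, k)
    p2 <- cut_tree(wc2, k)[rownames(x)]
    # same set partition: co-membership must agree
    expect_true(all(outer(p1, p1, "==") == outer(p2, p2, "==")))
  }
  expect_equal(robinson_foulds(wc1, wc2), 0)
})

test_that("cut_tree spans from one cluster to singletons", {
  wc <- ward_cluster(data.frame(x = c(0, 2, 10)))
  expect_equal(unname(cut_tree(wc, 1)), c(1L, 1L, 1L))
  expect_equal(unname(cut_tree(wc, 3)), 1:3)
  expect_error(cut_tree(wc, 0), "\\[1, 3\\]")
  expect_error(cut_tree(wc, 4), "\\[1, 3\\]")
})

test_that("monotonicity checker flags hand-built reversals and passes Ward runs", {
  fake <- list(height = c(2, 1))
  chk <- check_monotonic(fake)
  expect_false(chk$monotone)
  expect_equal(chk$violations$step, 2L)

  withr::with_seed(41, {
    for (i in 1:10) {
      wc <- ward_cluster(rand_dataset(sample(5:25, 1), sample(2:8, 1)))
      expect_true(check_monotonic(wc, tol = 1e-9)$monotone)
    }
  })
})

test_that("space-conservation checker reports each condition literally", {
  flat <- tibble::tibble(alpha_a = 0.5, alpha_b = 0.5, beta = 0, gamma = 0)
  expect_true(check_space_conditions(flat)$conserving)

  ward111 <- ward_lw_parameters(1, 1, 1)
  chk <- check_space_conditions(ward111)
  expect_false(chk$beta_zero)
  expect_false(chk$conserving)
  expect_match(chk$note, "beta < 0")

  gamma_big <- tibble::tibble(alpha_a = 0.5, alpha_b = 0.5, beta = 0, gamma = 1)
  expect_false(check_space_conditions(gamma_big)$gamma_lt_alpha)
})

test_that("tidy and glance views expose the merge table and run summary", {
  wc <- ward_cluster(data.frame(label = c("a", "b", "c"), x = c(0, 2, 10)))
  td <- tidy(wc)
  expect_identical(names(td),
                   c("step", "child1", "child2", "label1", "label2",
                     "height", "size"))
  expect_equal(td$height, c(2, 34 / 3))
  expect_identical(td$label1[1], "a")

  gl <- glance(wc)
  expect_equal(gl$n, 3)
  expect_true(gl$monotone)
  expect_equal(gl$root_height, 34 / 3)

  p <- autoplot(wc)
  expect_s3_class(p, "ggplot")
})
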