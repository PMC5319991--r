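test_that("a single association edge yields exactly one path", {
  Y <- association_matrix(matrix(1, 1, 1), "m1", "d1")
  net <- build_hetnet(Y)
  p <- enumerate_paths(net, "m1", "d1", L = 1)
  expect_length(p, 1L)
  expect_equal(p[[1]]$names, c("microbe:m1", "disease:d1"))
  expect_equal(p[[1]]$weights, 1)
  expect_error(enumerate_paths(net, "mX", "d1"), "unknown")
})

test_that("the 3-node worked example enumerates and scores correctly", {
  net <- toy_net()
  p <- enumerate_paths(net, "m2", "d1", L = 2)
  sigs <- sort(vapply(p, function(q) paste(q$names, collapse = ">"),
                      character(1)))
  expect_equal(sigs, c("microbe:m2>disease:d1",
                       "microbe:m2>microbe:m1>disease:d1"))
  expect_equal(total_score(net, "m2", "d1", L = 2, alpha = 1), 1.25)
})

test_that("path scores follow the exponential length decay", {
  expect_equal(path_score(c(1), alpha = 5), 1)
  expect_equal(path_score(c(0.5, 1.0), alpha = 1), 0.25)
  # fixed path with weights < 1: strictly decreasing in alpha
  s <- vapply(c(0.5, 1, 2, 4), function(a) path_score(c(0.8, 0.6), a),
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(path_score(numeric(0)), "at least one edge")
  expect_error(path_score(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("DFS path sets equal the permutation brute force on random graphs", {
  n_checked <- 0L
  for (seed in 1:25) {
    Y <- random_assoc(4, 3, 0.45, seed = seed + 300)
    T <- c(0, 0.2, 0.5)[seed %% 3 + 1]
    net <- build_hetnet(Y, threshold = T)
    for (L in 1:4) {
      i <- seed %% 4 + 1
      j <- seed %% 3 + 1
      dfs <- dfs_path_signatures(net, enumerate_paths(net, i, j, L))
      bf <- brute_paths(net$W, i, 4 + j, L)
      expect_identical(dfs, bf)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("paths never repeat nodes and respect the length bound", {
  Y <- random_assoc(4, 4, 0.5, seed = 77)
  net <- build_hetnet(Y)
  for (L in 1:4) {
    paths <- enumerate_paths(net, 1, 1, L)
    for (p in paths) {
      expect_equal(anyDuplicated(p$names), 0L)
      expect_lte(p$length, L)
      expect_gte(p$length, 1L)
      expect_equal(length(p$weights), length(p$names) - 1L)
      expect_true(all(p$weights > 0 & p$weights <= 1))
    }
  }
})

test_that("total scores match brute-force evaluation and empty sums are 0", {
  Y <- association_matrix(cbind(c(1, 0), c(0, 1)), c("m1", "m2"),
                          c("d1", "d2"))
  net <- build_hetnet(Y, threshold = 1)  # only the two association edges
  expect_equal(total_score(net, "m1", "d2"), 0)
  for (seed in 1:10) {
    Y <- random_assoc(4, 3, 0.4, seed = seed + 400)
    net <- build_hetnet(Y, threshold = 0.1)
    for (L in c(2, 3, 4)) {
      expect_equal(total_score(net, 2, 2, L, alpha = 1.7),
                   brute_total(net$W, 2, 6, L, 1.7), tolerance = 1e-12)
    }
  }
})

test_that("the full score matrix matches brute force on small instances", {
  for (seed in 1:8) {
    Y <- random_assoc(4, 3, 0.4, seed = seed + 500)
    for (L in c(1, 2, 3, 4)) {
      cfg <- pmda_config(L = L, alpha = 2.26, threshold = 0.1)
      TS <- predict_associations(Y, cfg)
      net <- build_hetnet(Y, threshold = 0.1)
      for (i in 1:4) for (j in 1:3) {
        expect_equal(TS[i, j], brute_total(net$W, i, 4 + j, L, 2.26),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a lone known pair scores exactly 1 whatever L and alpha", {
  Y <- association_matrix(matrix(1, 1, 1), "m1", "d1")
  for (L in c(1, 3, 5)) for (a in c(0.5, 2.26)) {
    TS <- predict_associations(Y, pmda_config(L = L, alpha = a))
    expect_identical(dim(TS), c(1L, 1L))
    expect_equal(TS[1, 1], 1)
  }
})

test_that("total score is non-decreasing in L and under edge addition", {
  Y <- random_assoc(5, 4, 0.4, seed = 21)
  cfgs <- lapply(1:4, function(L) pmda_config(L = L, alpha = 1.5))
  TS <- lapply(cfgs, function(cfg) predict_associations(Y, cfg))
  for (k in 1:3) expect_true(all(TS[[k + 1]] - TS[[k]] >= -1e-14))
  # adding an association edge never decreases any total score
  Y2 <- Y
  zero <- which(unclass(Y) == 0)[1]
  Y2[zero] <- 1
  net1 <- build_hetnet(Y, KM = gip_kernel(Y, "microbe"),
                       KD = gip_kernel(Y, "disease"))
  W2 <- net1$W
  ij <- arrayInd(zero, dim(Y))
  W2[ij[1], 5 + ij[2]] <- W2[5 + ij[2], ij[1]] <- 1
  net2 <- net1
  net2$W <- W2
  net2$adj <- lapply(seq_len(nrow(W2)), function(i) which(W2[i, ] > 0))
  for (i in 1:5) for (j in 1:4) {
    expect_gte(total_score(net2, i, j, 3, 1.5) + 1e-14,
               total_score(net1, i, j, 3, 1.5))
  }
})

test_that("score matrices are equivariant under node relabeling", {
  Y <- random_assoc(6, 4, 0.5, seed = 31)
  set.seed(99)
  pm <- sample(6)
  pd <- sample(4)
  Yp <- association_matrix(unclass(Y)[pm, pd], rownames(Y)[pm],
                           colnames(Y)[pd])
  TS <- predict_associations(Y)
  TSp <- predict_associations(Yp)
  expect_equal(unclass(TSp)[, ], unclass(TS)[pm, pd], tolerance = 1e-12)
})

test_that("repeated runs produce bit-identical score matrices", {
  Y <- random_assoc(8, 5, 0.3, seed = 41)
  a <- predict_associations(Y)
  b <- predict_associations(Y)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
})
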