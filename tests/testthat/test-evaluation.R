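test_that("ROC construction handles perfect, random and hand-counted rankings", {
  # every positive ranked first among 100 candidates
  perfect <- data.frame(rank = rep(1, 25), n_candidates = rep(100, 25))
  expect_equal(roc_from_ranks(perfect)$auc, 1)
  # one positive ranked 2nd among 4 candidates: beats 3 of 4 by pair counting
  hand <- data.frame(rank = 2, n_candidates = 4)
  expect_equal(roc_from_ranks(hand)$auc, 3 / 4)
  # uniformly random ranks: AUC near 1/2
  set.seed(1)
  rnd <- data.frame(rank = sample.int(201, 2000, replace = TRUE),
                    n_candidates = 200)
  expect_lt(abs(roc_from_ranks(rnd)$auc - 0.5), 0.02)
  expect_error(roc_from_ranks(data.frame()), "non-empty")
  expect_error(roc_from_ranks(data.frame(rank = 6, n_candidates = 4)),
               "rank")
})

test_that("ROC staircases run (0,0) to (1,1) monotonically and integrate to the AUC", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(3:30, 1)
    ranks <- data.frame(n_candidates = sample(2:50, n, replace = TRUE))
    ranks$rank <- vapply(ranks$n_candidates,
                         function(m) sample.int(m + 1, 1), integer(1))
    roc <- roc_from_ranks(ranks)
    pts <- roc$roc_points
    expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    trapz <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                    utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trapz, roc$auc, tolerance = 1e-10)
  }
})

test_that("global LOOCV on the 2x2 identity matches the hand trace", {
  # removing either association leaves a 3-edge chain: the held-out pair is
  # reachable only through the length-3 path microbe-microbe-disease-disease
  # (score e^(-12*alpha)), while both unverified pairs score e^(-4*alpha),
  # so each test round ranks last among its 2 candidates + itself.
  Y <- association_matrix(diag(2), c("m1", "m2"), c("d1", "d2"))
  rep <- loocv(Y, pmda_config(), "global")
  expect_equal(rep$ranks$rank, c(3, 3))
  expect_equal(rep$ranks$n_candidates, c(2, 2))
  expect_equal(rep$auc, 0)
  a <- pmda_config()$alpha
  expect_equal(rep$ranks$score, rep(exp(-12 * a), 2), tolerance = 1e-12)
})

test_that("LOOCV recomputes scores from the reduced matrix (leakage safety)", {
  Y <- random_assoc(8, 4, 0.35, seed = 8)
  known <- which(unclass(Y) == 1)
  k <- 3L
  Ytr <- Y
  Ytr[known[k]] <- 0
  # kernels genuinely change when the held-out edge is removed
  expect_false(isTRUE(all.equal(unclass(gip_kernel(Ytr, "microbe")),
                                unclass(gip_kernel(Y, "microbe")))))
  cfg <- pmda_config()
  TS_tr <- predict_associations(Ytr, cfg)
  ij <- arrayInd(known[k], dim(Y))
  s <- TS_tr[ij[1], ij[2]]
  cand <- TS_tr[unclass(Y) == 0]
  expected_rank <- sum(cand > s) + sum(cand == s) / 2 + 1
  rep <- loocv(Y, cfg, "global", test_pairs = k)
  expect_equal(rep$ranks$rank, expected_rank)
  expect_equal(rep$ranks$score, s)
  # the full-data score differs, so ranking against it would leak
  TS_full <- predict_associations(Y, cfg)
  expect_false(isTRUE(all.equal(s, TS_full[ij[1], ij[2]])))
})

test_that("local LOOCV ranks within the test disease only", {
  Y <- random_assoc(8, 4, 0.35, seed = 8)
  g <- loocv(Y, pmda_config(), "global")
  l <- loocv(Y, pmda_config(), "local")
  # same test pairs, different candidate sets
  expect_equal(l$ranks[, c("microbe", "disease")],
               g$ranks[, c("microbe", "disease")])
  nz <- colSums(unclass(Y) == 0)
  expect_equal(l$ranks$n_candidates,
               unname(nz[match(l$ranks$disease, colnames(Y))]))
  expect_equal(unique(g$ranks$n_candidates), sum(Y == 0))
})

test_that("a forced singleton candidate set yields rank 1", {
  # d1 associated with all microbes except m3; hold out (m1, d1):
  # the only candidate is m3
  Y <- association_matrix(cbind(c(1, 1, 0), c(0, 1, 1)),
                          paste0("m", 1:3), c("d1", "d2"))
  l <- loocv(Y, pmda_config(), "local", test_pairs = 1)
  expect_equal(l$ranks$n_candidates, 1)
  expect_lte(l$ranks$rank, 2)
})

test_that("k-fold CV is reproducible from its seed and degenerates to LOOCV", {
  Y <- random_assoc(10, 5, 0.3, seed = 17)
  a <- kfold_cv(Y, k = 3, repeats = 2, seed = 7)
  b <- kfold_cv(Y, k = 3, repeats = 2, seed = 7)
  expect_identical(a$auc, b$auc)
  expect_identical(a$per_repeat_auc, b$per_repeat_auc)
  expect_equal(a$ranks, b$ranks)
  c <- kfold_cv(Y, k = 3, repeats = 2, seed = 8)
  expect_false(identical(a$per_repeat_auc, c$per_repeat_auc))
  # k = number of known pairs: partition reduces to leave-one-out
  n_known <- sum(Y)
  kf <- kfold_cv(Y, k = n_known, repeats = 1, seed = 1)
  g <- loocv(Y, pmda_config(), "global")
  expect_identical(kf$auc, g$auc)
  expect_equal(sort(kf$ranks$rank), sort(g$ranks$rank))
})

test_that("k-fold folds partition the known pairs with near-equal sizes", {
  Y <- random_assoc(10, 5, 0.3, seed = 17)
  kf <- kfold_cv(Y, k = 4, repeats = 3, seed = 5)
  expect_equal(nrow(kf$ranks), 3 * sum(Y))
  per_rep <- table(kf$ranks$repeat_id)
  expect_true(all(per_rep == sum(Y)))
  expect_length(kf$per_repeat_auc, 3)
  expect_equal(kf$auc, mean(kf$per_repeat_auc))
  expect_equal(kf$auc_sd, stats::sd(kf$per_repeat_auc))
})

test_that("degenerate inputs are rejected", {
  Y1 <- association_matrix(matrix(1, 1, 1), "m1", "d1")
  expect_error(loocv(Y1), "at least 2")
  Y <- random_assoc(5, 3, 0.4, seed = 2)
  expect_error(kfold_cv(Y, k = 1), ">= 2")
  expect_error(kfold_cv(Y, k = sum(Y) + 1), "fewer known associations")
  expect_error(loocv(Y, test_pairs = 999), "test_pairs")
})
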