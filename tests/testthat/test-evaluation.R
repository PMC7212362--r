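test_that("threshold-sweep AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(auc_from_ranks(c(2), c(1, 3))$auc, 0.5, tolerance = 1e-12)
  expect_equal(auc_from_ranks(c(1), c(1, 1))$auc, 0.5, tolerance = 1e-12)
  expect_equal(auc_from_ranks(c(5, 6), c(1, 2))$auc, 1)
  expect_equal(auc_from_ranks(rep(1, 3), rep(1, 7))$auc, 0.5)

  set.seed(47)
  for (rep in 1:15) {
    pos <- sample(0:20, sample(1:50, 1), replace = TRUE)
    cand <- sample(0:20, sample(1:500, 1), replace = TRUE)
    res <- auc_from_ranks(pos, cand)
    expect_lt(abs(res$auc - oracle_auc(pos, cand)), 1e-12)
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(unlist(res$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(res$roc_points[nrow(res$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(res$roc_points$fpr) >= 0))
    expect_true(all(diff(res$roc_points$tpr) >= 0))
  }
  expect_error(auc_from_ranks(numeric(), 1), "nonempty")
})

test_that("leave-one-out records one rank per known association", {
  A <- association_matrix(data.frame(m = c("m1", "m2", "m3"),
                                     d = c("d1", "d2", "d2")))
  res <- loocv(A)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(tidy(res)), 3L)
  expect_equal(glance(res)$n_test, 3L)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_true(all(tidy(res)$n_candidates == sum(A == 0)))

  two <- association_matrix(data.frame(m = c("m1", "m2"), d = c("d1", "d2")))
  expect_equal(nrow(tidy(loocv(two))), 2L)
  one <- association_matrix(data.frame(m = "m1", d = "d1"))
  expect_error(loocv(one), "at least two")
})

test_that("k-fold partitions are seeded, near-equal, and exhaustive", {
  set.seed(61)
  A <- rand_assoc(8, 6, 0.4)
  npos <- sum(A)
  r1 <- kfold_cv(A, k = 3, seed = 42)
  r2 <- kfold_cv(A, k = 3, seed = 42)
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(r1$auc, r2$auc)
  expect_equal(nrow(tidy(r1)), npos)

  # masked groups differ in size by at most one
  r5 <- kfold_cv(A, k = 5, seed = 7)
  expect_equal(nrow(tidy(r5)), npos)

  expect_error(kfold_cv(A, k = npos + 1), "exceeds")
  expect_error(kfold_cv(A, k = 1), class = "heatmda_config_error")
})

test_that("k equal to the positive count reduces to leave-one-out", {
  set.seed(9)
  A <- rand_assoc(5, 4, 0.4)
  npos <- sum(A)
  loo <- loocv(A)
  kf <- kfold_cv(A, k = npos, seed = 3)
  expect_equal(sort(tidy(kf)$u), sort(tidy(loo)$u), tolerance = 1e-12)
  expect_equal(kf$auc, loo$auc, tolerance = 1e-12)
})

test_that("the no-refit protocol scores folds with the full-data model", {
  set.seed(15)
  A <- rand_assoc(6, 5, 0.4)
  cfg <- run_config(refit_similarity = FALSE)
  res <- loocv(A, config = cfg)
  sims <- build_similarities(A, config = cfg)
  S <- bhc_scores(A, sims$sm, sims$sd, cfg)$scores
  cand <- S[A == 0]
  expected_u <- vapply(which(A == 1L), function(p) {
    (sum(cand < S[p]) + 0.5 * sum(cand == S[p])) / length(cand)
  }, 0)
  expect_equal(sort(tidy(res)$u), sort(expected_u), tolerance = 1e-12)
})

test_that("top-k ranks only unknown pairs, ties broken by id", {
  scores <- structure(list(
    scores = matrix(c(0.9, 0.5, 0.5, 0.1,
                      0.2, 0.4, 0.6, 0.8), 4, 2,
                    dimnames = list(c("mB", "mA", "mC", "mD"), c("d1", "d2"))),
    known = matrix(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L), 4, 2,
                   dimnames = list(c("mB", "mA", "mC", "mD"), c("d1", "d2"))),
    config = run_config()
  ), class = "score_matrix")

  got <- top_k(scores, "d1", 2)
  # mB is a known association and excluded; mA/mC tie at 0.5 -> mA first
  expect_equal(got$mirna_id, c("mA", "mC"))
  expect_equal(got$rank, 1:2)

  full <- top_k(scores, "d1", 99)
  expect_equal(nrow(full), 3L)
  expect_false("mB" %in% full$mirna_id)

  # row order of the matrix does not matter
  perm <- c(3, 1, 4, 2)
  scores_p <- scores
  scores_p$scores <- scores$scores[perm, ]
  scores_p$known <- scores$known[perm, ]
  expect_equal(top_k(scores_p, "d1", 2), got)

  expect_error(top_k(scores, "dX", 2), "unknown disease")
})

test_that("cv results expose tidy, glance, and a plottable ROC", {
  A <- association_matrix(data.frame(m = c("m1", "m2", "m3"),
                                     d = c("d1", "d2", "d2")))
  res <- loocv(A)
  g <- glance(res)
  expect_equal(g$method, "loocv")
  expect_equal(g$auc, mean(tidy(res)$u))
  expect_true(all(diff(res$roc_points$fpr) >= 0))
  expect_true(all(diff(res$roc_points$tpr) >= 0))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
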