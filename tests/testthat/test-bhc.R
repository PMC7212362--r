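# The 3 x 2 toy network: A = [[1,0],[1,1],[0,1]] with binary degrees
# d(m) = (1, 2, 1), d(d) = (2, 2).

test_that("augmentation at threshold 1 returns the association matrix", {
  A <- toy_assoc()
  sm <- rand_sim(rownames(A))
  aug <- augment_adjacency(A, sm, 1, "mirna")
  expect_equal(aug$values, unclass(A) * 1.0, ignore_attr = TRUE)
  expect_equal(unname(aug$mirna_degrees), c(1, 2, 1))
  expect_equal(unname(aug$disease_degrees), c(2, 2))
})

test_that("augmentation adds the best qualifying neighbour weight", {
  A <- toy_assoc()
  SM <- diag(3); SM[1, 3] <- SM[3, 1] <- 0.8
  dimnames(SM) <- list(rownames(A), rownames(A))
  sm <- similarity_matrix(SM, role = "SM")
  aug <- augment_adjacency(A, sm, 0.29, "mirna")
  # m3 is associated with d2 and similar to m1, so (m1, d2) gains 0.8
  expect_equal(aug$values["m1", "d2"], 0.8)
  expect_equal(aug$values["m3", "d1"], 0.8)
  # known associations stay exactly 1
  expect_equal(aug$values["m2", "d1"], 1)
  expect_true(all(aug$values[unclass(A) == 1L] == 1))
})

test_that("lowering the threshold is cellwise monotone on the augmented matrix", {
  set.seed(23)
  for (rep in 1:10) {
    A <- rand_assoc(6, 5, 0.3)
    sm <- rand_sim(rownames(A))
    thresholds <- sort(runif(3), decreasing = TRUE)
    prev <- augment_adjacency(A, sm, thresholds[1], "mirna")$values
    for (th in thresholds[-1]) {
      cur <- augment_adjacency(A, sm, th, "mirna")$values
      expect_true(all(cur >= prev - 1e-15))
      prev <- cur
    }
  }
})

test_that("forward conduction splits one unit of resource per source node", {
  A <- toy_assoc()
  sm <- rand_sim(rownames(A))
  aug <- augment_adjacency(A, sm, 1, "mirna")
  fd <- forward_conduction(aug, "mirnas")
  expect_equal(unname(c(fd[c("d1", "d2")])), c(1.5, 1.5))

  # conservation: with gamma irrelevant here, total received equals the
  # number of non-isolated sources
  set.seed(3)
  for (rep in 1:10) {
    B <- rand_assoc(7, 5, 0.3)
    augB <- augment_adjacency(B, rand_sim(rownames(B)), 1, "mirna")
    fdB <- forward_conduction(augB, "mirnas")
    expect_equal(sum(fdB), sum(rowSums(B) > 0))
  }
})

test_that("complete bipartite networks deliver exactly one unit everywhere", {
  for (k in 2:5) {
    A <- matrix(1L, k, k, dimnames = list(sprintf("m%d", 1:k),
                                          sprintf("d%d", 1:k)))
    class(A) <- c("assoc_matrix", class(matrix()))
    aug <- augment_adjacency(A, rand_sim(rownames(A)), 1, "mirna")
    expect_equal(unname(c(forward_conduction(aug, "mirnas"))), rep(1, k))
  }
})

test_that("biased return pass reproduces hand values and the gamma = 0 limit", {
  A <- toy_assoc()
  aug <- augment_adjacency(A, rand_sim(rownames(A)), 1, "mirna")
  fd <- forward_conduction(aug, "mirnas")
  fm0 <- biased_back_conduction(aug, fd, 0)
  expect_equal(unname(fm0[c("m1", "m2", "m3")]), c(0.75, 1.5, 0.75),
               tolerance = 1e-9)
  fm <- biased_back_conduction(aug, fd, 0.001)
  expect_equal(unname(fm["m2"]), 1.5 / 2^0.001, tolerance = 1e-9)
  # gamma = 0 equals plain heat conduction for any network
  set.seed(13)
  B <- rand_assoc(6, 5, 0.4)
  augB <- augment_adjacency(B, rand_sim(rownames(B)), 0.5, "mirna")
  fdB <- forward_conduction(augB, "mirnas")
  plain <- biased_back_conduction(augB, fdB, 0)
  manual <- sapply(seq_len(nrow(B)), function(i) {
    dm <- augB$mirna_degrees[i]
    if (dm == 0) return(0)
    sum(ifelse(augB$disease_degrees > 0,
               augB$values[i, ] * fdB / augB$disease_degrees, 0))
  })
  expect_equal(unname(c(plain)), unname(manual), tolerance = 1e-12)
  expect_error(biased_back_conduction(augB, fdB, -1),
               class = "heatmda_config_error")
})

test_that("isolated nodes neither send nor receive resources", {
  A <- association_matrix(data.frame(m = c("m1", "m2"), d = c("d1", "d1")))
  A <- cbind(A, d2 = c(0L, 0L))
  A <- rbind(A, m3 = c(0L, 0L))
  class(A) <- c("assoc_matrix", class(matrix()))
  aug <- augment_adjacency(A, rand_sim(rownames(A)), 1, "mirna")
  fd <- forward_conduction(aug, "mirnas")
  fm <- biased_back_conduction(aug, fd, 0.001)
  expect_equal(unname(fd["d2"]), 0)
  expect_equal(unname(fm["m3"]), 0)
  expect_true(all(is.finite(c(fd, fm))))
})

test_that("scores match the naive loop oracle on random networks", {
  set.seed(101)
  cfg <- run_config()
  for (rep in 1:25) {
    n <- sample(2:8, 1); q <- sample(2:6, 1)
    A <- rand_assoc(n, q, runif(1, 0.2, 0.6))
    sm <- rand_sim(rownames(A), "SM")
    sd_ <- rand_sim(colnames(A), "SD")
    S <- bhc_scores(A, sm, sd_, cfg)$scores
    S_oracle <- oracle_bhc(unclass(A), strip_sim(sm), strip_sim(sd_),
                           cfg$delta, cfg$eta, cfg$gamma)
    expect_lt(max(abs(S - S_oracle)), 1e-12)
  }
  # weighted degree mode agrees with its oracle too
  cfg_w <- run_config(degree_mode = "weighted")
  for (rep in 1:5) {
    A <- rand_assoc(5, 4, 0.4)
    sm <- rand_sim(rownames(A), "SM")
    sd_ <- rand_sim(colnames(A), "SD")
    S <- bhc_scores(A, sm, sd_, cfg_w)$scores
    S_oracle <- oracle_bhc(unclass(A), strip_sim(sm), strip_sim(sd_),
                           cfg_w$delta, cfg_w$eta, cfg_w$gamma, "weighted")
    expect_lt(max(abs(S - S_oracle)), 1e-12)
  }
})

test_that("scores are finite, nonnegative, and label-equivariant", {
  set.seed(77)
  A <- rand_assoc(6, 5, 0.4)
  sm <- rand_sim(rownames(A), "SM")
  sd_ <- rand_sim(colnames(A), "SD")
  S <- bhc_scores(A, sm, sd_)$scores
  expect_true(all(is.finite(S)) && all(S >= 0))

  perm <- sample(nrow(A))
  Ap <- unclass(A)[perm, ]
  class(Ap) <- c("assoc_matrix", class(matrix()))
  smp <- similarity_matrix(strip_sim(sm)[perm, perm], role = "SM")
  Sp <- bhc_scores(Ap, smp, sd_)$scores
  expect_equal(Sp, S[perm, ], tolerance = 1e-12)
})

test_that("an all-zero association matrix yields all-zero scores", {
  A <- matrix(0L, 3, 2, dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  class(A) <- c("assoc_matrix", class(matrix()))
  S <- bhc_scores(A, rand_sim(rownames(A), "SM"), rand_sim(colnames(A), "SD"))
  expect_true(all(S$scores == 0))
})

test_that("transposing the problem swaps the roles of the two passes", {
  set.seed(55)
  A <- rand_assoc(6, 4, 0.4)
  sm <- rand_sim(rownames(A), "SM")
  sd_ <- rand_sim(colnames(A), "SD")
  th <- 0.3

  a1 <- augment_adjacency(A, sm, th, "mirna")
  At <- t(unclass(A))
  dimnames(At) <- list(colnames(A), rownames(A))
  class(At) <- c("assoc_matrix", class(matrix()))
  a2 <- augment_adjacency(At, sm, th, "disease")
  expect_equal(t(a2$values), a1$values, tolerance = 1e-12)
})
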