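test_that("generation is reproducible from the seed", {
  spec <- synthetic_spec(n_mirnas = 12, n_diseases = 8, n_blocks = 2,
                         seed = 99)
  d1 <- gen_dataset(spec)
  d2 <- gen_dataset(spec)
  expect_identical(unclass(d1$assoc)[, ], unclass(d2$assoc)[, ])
  expect_equal(strip_sim(d1$fs), strip_sim(d2$fs))
  expect_identical(lapply(d1$dags, `[[`, "nodes"),
                   lapply(d2$dags, `[[`, "nodes"))
})

test_that("deterministic limits produce the exact block pattern", {
  spec <- synthetic_spec(n_mirnas = 8, n_diseases = 6, n_blocks = 2,
                         p_in = 1, p_out = 0, seed = 1)
  A <- gen_associations(spec)
  blocks <- attr(A, "blocks")
  expected <- outer(blocks$mirna, blocks$disease, `==`) * 1L
  expect_equal(unclass(A)[, ], expected, ignore_attr = TRUE)
})

test_that("equal rates give statistically uniform density", {
  p <- 0.25
  ins <- outs <- numeric(20)
  for (s in 1:20) {
    spec <- synthetic_spec(n_mirnas = 20, n_diseases = 16, n_blocks = 4,
                           p_in = p, p_out = p, seed = s)
    A <- gen_associations(spec)
    aligned <- outer(attr(A, "blocks")$mirna, attr(A, "blocks")$disease, `==`)
    ins[s] <- mean(A[aligned])
    outs[s] <- mean(A[!aligned])
  }
  n_in <- sum(outer(block_ref(20, 4), block_ref(16, 4), `==`)) * 20
  n_out <- 20 * 16 * 20 - n_in
  se <- sqrt(p * (1 - p) * (1 / n_in + 1 / n_out))
  expect_lt(abs(mean(ins) - mean(outs)), 3 * se)
})


test_that("DAG corpus shares ancestry within blocks and validates", {
  spec <- synthetic_spec(n_mirnas = 8, n_diseases = 6, n_blocks = 2,
                         dag_depth = 3, seed = 4)
  dags <- gen_dag_corpus(spec)
  expect_equal(length(dags), 6L)
  blocks <- block_ref(6, 2)
  ids <- names(dags)
  for (i in 1:5) for (j in (i + 1):6) {
    shared <- intersect(dags[[i]]$nodes, dags[[j]]$nodes)
    nonroot <- setdiff(shared, c("ROOT", ids[i], ids[j]))
    if (blocks[i] == blocks[j]) {
      expect_gt(length(nonroot), 0)
    } else {
      expect_equal(length(nonroot), 0L)
    }
  }

  flat <- synthetic_spec(n_mirnas = 4, n_diseases = 4, n_blocks = 2,
                         dag_depth = 1, seed = 4)
  for (dag in gen_dag_corpus(flat)) {
    expect_setequal(dag$nodes, c("ROOT", dag$target))
  }
})

test_that("functional similarity honours noise, coverage, and invariants", {
  spec0 <- synthetic_spec(n_mirnas = 10, n_diseases = 6, n_blocks = 2,
                          fs_noise = 0, seed = 2)
  fs0 <- gen_functional_similarity(spec0)
  off <- strip_sim(fs0)[upper.tri(fs0)]
  expect_setequal(unique(off), c(0.8, 0.1))
  expect_equal(unname(diag(strip_sim(fs0))), rep(1, 10))

  spec <- synthetic_spec(n_mirnas = 10, n_diseases = 6, n_blocks = 2,
                         fs_noise = 0.05, fs_coverage = 0, seed = 2)
  ds <- gen_dataset(spec)
  cov <- attr(ds$fs, "coverage")
  expect_false(any(cov[upper.tri(cov)]))
  # with zero coverage the fused miRNA similarity is exactly the kernel
  sims <- build_similarities(ds$assoc, fs = ds$fs, dags = ds$dags)
  expect_equal(strip_sim(sims$sm), strip_sim(sims$km), tolerance = 1e-12)

  ds_mid <- gen_dataset(synthetic_spec(n_mirnas = 10, n_diseases = 6,
                                       n_blocks = 2, fs_coverage = 0.5,
                                       seed = 3))
  cov_mid <- attr(ds_mid$fs, "coverage")
  expect_equal(cov_mid, t(cov_mid))
  expect_true(all(diag(cov_mid)))
})

test_that("generated datasets survive the file formats", {
  dir <- withr::local_tempdir()
  ds <- gen_dataset(synthetic_spec(n_mirnas = 8, n_diseases = 6,
                                   n_blocks = 2, fs_coverage = 0.8,
                                   seed = 12))
  write_dataset(ds, dir)
  A <- read_associations(file.path(dir, "assoc.tsv"))
  # the pair-list format cannot represent isolated nodes; compare the rest
  keep_m <- rownames(ds$assoc)[rowSums(ds$assoc) > 0]
  keep_d <- colnames(ds$assoc)[colSums(ds$assoc) > 0]
  expect_equal(unclass(A)[keep_m, keep_d],
               unclass(ds$assoc)[keep_m, keep_d])
  fs <- read_similarity_tsv(file.path(dir, "fs.tsv"), "FS",
                            file.path(dir, "fs_coverage.tsv"))
  expect_equal(strip_sim(fs)[rownames(ds$fs), rownames(ds$fs)],
               strip_sim(ds$fs), tolerance = 1e-12)
  expect_equal(attr(fs, "coverage")[rownames(ds$fs), rownames(ds$fs)],
               attr(ds$fs, "coverage"), ignore_attr = TRUE)
  dags <- read_dag_file(file.path(dir, "dags.tsv"))
  expect_setequal(names(dags), names(ds$dags))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 12L)
})

test_that("specification validation rejects impossible settings", {
  expect_error(synthetic_spec(p_in = 0.1, p_out = 0.5),
               class = "heatmda_config_error")
  expect_error(synthetic_spec(n_blocks = 99, n_mirnas = 10, n_diseases = 8),
               class = "heatmda_config_error")
  expect_error(synthetic_spec(n_mirnas = 0), class = "heatmda_config_error")
})
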