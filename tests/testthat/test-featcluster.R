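test_that("the two branches are twins in shape but not in weights", {
  cfg <- branch_config()
  m <- build_model(cfg, rng_seed = 4)
  expect_equal(dim(m$branch_t1[[1]]$W), dim(m$branch_t2[[1]]$W))
  expect_false(identical(m$branch_t1[[1]]$W, m$branch_t2[[1]]$W))
  m2 <- build_model(cfg, rng_seed = 4)
  expect_identical(m$branch_t1, m2$branch_t1)
  expect_error(branch_config(features_per_branch = 0, q_total = 0), ">= 1")
  expect_error(branch_config(features_per_branch = 20, q_total = 60), "q_total")
})

test_that("forward_embed produces a q-channel map of the input shape", {
  cfg <- branch_config(n_blocks = 2, features_per_branch = 4, q_total = 8)
  m <- build_model(cfg, rng_seed = 1)
  t1 <- array(rnorm(12 * 10 * 6), c(12, 10, 6))
  t2 <- array(rnorm(12 * 10 * 6), c(12, 10, 6))
  pair <- volume_pair(t1, t2)
  r <- forward_embed(pair, m)
  expect_equal(dim(r), c(8, 12, 10, 6))
  expect_true(all(is.finite(r)))
  expect_identical(forward_embed(pair, m), r)
  # branches are independent: swapping modalities changes the embedding
  swapped <- forward_embed(volume_pair(t2, t1), m)
  expect_false(isTRUE(all.equal(r, swapped)))
  expect_error(volume_pair(t1, t2[, , 1:5, drop = FALSE]), "identical shape")
})

test_that("assign_clusters takes the channel argmax with first-index ties", {
  r <- array(0, c(3, 2, 2, 1))
  r[2, , , ] <- 5
  expect_true(all(assign_clusters(r) == 1L))
  r2 <- array(c(0.1, 0.9), c(2, 1, 1, 1))
  expect_equal(as.integer(assign_clusters(r2)), 1L)
  # exact tie between channels 3 and 8 resolves to 2 (0-based)
  r3 <- array(0, c(10, 1, 1, 1))
  r3[c(3, 8), 1, 1, 1] <- 7
  expect_equal(as.integer(assign_clusters(r3)), 2L)
  r_bad <- r
  r_bad[1] <- NaN
  expect_error(assign_clusters(r_bad), "non-finite")
})

test_that("similarity loss matches closed forms", {
  # one voxel, logits (10, -10): loss = -log(e^10 / (e^10 + e^-10))
  r <- array(c(10, -10), c(2, 1, 1, 1))
  lab <- array(0L, c(1, 1, 1))
  expect_equal(similarity_loss(r, lab), log(1 + exp(-20)), tolerance = 1e-6)
  # uniform responses give log(q) for any labels
  for (q in c(2, 5, 60)) {
    rc <- array(1.3, c(q, 3, 2, 2))
    labc <- array(sample(0:(q - 1), 12, TRUE), c(3, 2, 2))
    expect_equal(similarity_loss(rc, labc), log(q), tolerance = 1e-12)
  }
  expect_error(similarity_loss(r, array(5L, c(1, 1, 1))), "outside")
})

test_that("similarity loss is non-negative on random maps", {
  for (i in 1:1000) {
    q <- sample(2:6, 1)
    r <- array(rnorm(q * 8), c(q, 2, 2, 2))
    expect_gte(similarity_loss(r, assign_clusters(r)), 0)
  }
})

test_that("continuity loss matches hand computations and the brute-force oracle", {
  expect_equal(continuity_loss(array(2.5, c(4, 3, 3, 2))), 0)
  # single pair along one axis with values (0, 3)
  expect_equal(continuity_loss(array(c(0, 3), c(1, 2, 1, 1))), 3)
  set.seed(99)
  for (i in 1:25) {
    r <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
    expect_equal(continuity_loss(r), continuity_oracle(r), tolerance = 1e-9)
  }
  expect_error(continuity_loss(array(1, c(3, 1, 1, 1))), "degenerate")
})

test_that("total loss composes similarity and continuity linearly in mu", {
  set.seed(5)
  r <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  lab <- assign_clusters(r)
  expect_equal(total_loss(r, lab, mu = 0), similarity_loss(r, lab))
  expect_equal(total_loss(r, lab, mu = 2) - total_loss(r, lab, mu = 1),
               continuity_loss(r), tolerance = 1e-12)
  rc <- array(0.7, c(6, 3, 3, 2))
  expect_equal(total_loss(rc, assign_clusters(rc), mu = 1), log(6))
  expect_error(total_loss(r, lab, mu = -1), "non-negative")
})

test_that("count_active_clusters unions distinct labels", {
  expect_equal(count_active_clusters(array(3L, c(4, 4, 2))), 1)
  m1 <- array(c(0L, 3L), c(2, 1, 1))
  m2 <- array(c(3L, 9L), c(2, 1, 1))
  expect_equal(count_active_clusters(list(m1, m2)), 3)
  expect_equal(count_active_clusters(array(0:59, c(60, 1, 1))), 60)
})

test_that("training records history, respects the cluster budget and the seed", {
  cohort <- lapply(make_cohort(2, shape = c(16, 16, 8), tumor_radius_range = c(3, 4), rng_seed = 1), prep_pair)
  cfg <- cluster_train_config(lr = 0.1, max_epochs = 1, rng_seed = 0)
  fit <- train_unsupervised(cohort, cfg)
  expect_equal(nrow(fit$history), 1)
  expect_lte(fit$history$n_active_clusters, 60)
  fit2 <- train_unsupervised(cohort, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params$branch_t1, fit2$params$branch_t1)
  expect_error(train_unsupervised(list(), cfg), "non-empty")
})

test_that("early stopping triggers after `patience` stagnant epochs", {
  cohort <- lapply(make_cohort(1, shape = c(12, 12, 8), tumor_radius_range = c(3, 3.5), rng_seed = 2), prep_pair)
  # an infinite min_delta means no epoch ever counts as an improvement
  cfg <- cluster_train_config(lr = 0.01, max_epochs = 50, patience = 3,
                              min_delta = Inf, rng_seed = 0)
  fit <- train_unsupervised(cohort, cfg)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$history$epochs_since_improvement, 1:3)
})

test_that("the loss decreases over a short training run", {
  cohort <- lapply(make_cohort(2, shape = c(16, 16, 8), tumor_radius_range = c(3, 4), rng_seed = 3), prep_pair)
  cfg <- cluster_train_config(lr = 0.1, max_epochs = 8, patience = 8, rng_seed = 1)
  fit <- train_unsupervised(cohort, cfg)
  expect_lt(fit$history$loss[8], fit$history$loss[1])
  expect_true(all(fit$history$n_active_clusters <= 60))
})
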