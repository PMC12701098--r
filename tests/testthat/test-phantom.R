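test_that("phantoms contain all six tissues and a reproducible tumor", {
  ph <- make_phantom(shape = c(48, 48, 16), rng_seed = 7)
  expect_setequal(unique(as.integer(ph$tissue_map)), 1:6)
  expect_gt(sum(ph$tumor_mask), 0)
  expect_identical(ph$tumor_mask,
                   array(as.integer(ph$tissue_map == 6), dim(ph$tissue_map)))
  # expert labels overlap the tumor
  expect_gt(sum(ph$el_t1 * ph$tumor_mask), 0)
  expect_gt(sum(ph$el_t2 * ph$tumor_mask), 0)
  ph2 <- make_phantom(shape = c(48, 48, 16), rng_seed = 7)
  expect_identical(ph$pair$t1, ph2$pair$t1)
  expect_identical(ph$el_t1, ph2$el_t1)
  expect_error(make_phantom(shape = c(12, 12, 8), tumor_radius_range = c(10, 12)),
               "does not fit")
})

test_that("tumor is the most heterogeneous tissue in every seed", {
  muscle_idx <- match("muscle", default_tissues()$name)
  for (seed in 1:10) {
    ph <- make_phantom(shape = c(48, 48, 16), rng_seed = seed)
    sd_tumor <- sd(ph$pair$t1[ph$tumor_mask == 1])
    sd_muscle <- sd(ph$pair$t1[ph$tissue_map == muscle_idx])
    expect_gt(sd_tumor, sd_muscle)
  }
})

test_that("default tissue table is clusterable and tumor-heterogeneous", {
  tis <- default_tissues()
  expect_true(all(tis$sd_t1[tis$name == "tumor"] > tis$sd_t1[tis$name != "tumor"]))
  expect_true(all(tis$sd_t2[tis$name == "tumor"] > tis$sd_t2[tis$name != "tumor"]))
  nt <- tis[tis$name != "tumor", ]
  for (i in seq_len(nrow(nt) - 1)) for (j in (i + 1):nrow(nt)) {
    sep1 <- abs(nt$mean_t1[i] - nt$mean_t1[j]) /
      sqrt((nt$sd_t1[i]^2 + nt$sd_t1[j]^2) / 2)
    sep2 <- abs(nt$mean_t2[i] - nt$mean_t2[j]) /
      sqrt((nt$sd_t2[i]^2 + nt$sd_t2[j]^2) / 2)
    expect_gte(max(sep1, sep2), 2)
  }
})

test_that("simulate_expert_label implements biased morphology plus jitter", {
  m <- array(0L, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- 1L  # 5x5x5 cube
  expect_identical(simulate_expert_label(m, 0L, 0), m)
  eroded <- simulate_expert_label(m, -1L, 0)
  expect_equal(sum(eroded), 27)  # 3x3x3 core of the cube
  dilated <- simulate_expert_label(m, 1L, 0)
  expect_true(all(dilated[m == 1L] == 1L))
  expect_gt(sum(dilated), sum(m))
  expect_error(simulate_expert_label(array(0L, c(4, 4, 4)), -1L, 0), "empty")
})

test_that("simulated expert labels are imperfect but faithful", {
  for (seed in 1:20) {
    ph <- make_phantom(shape = c(40, 40, 16), tumor_radius_range = c(4.5, 8),
                       rng_seed = seed)
    el <- simulate_expert_label(ph$tumor_mask, -1L, 0.05, rng_seed = seed)
    d <- dice(el, ph$tumor_mask)
    expect_lt(d, 1)
    expect_gt(d, 0.5)
  }
})

test_that("cohorts are reproducible with distinct cases", {
  co <- make_cohort(5, shape = c(32, 32, 12), rng_seed = 11)
  expect_length(co, 5)
  ids <- vapply(co, function(ph) ph$pair$case_id, "")
  expect_length(unique(ids), 5)
  co2 <- make_cohort(5, shape = c(32, 32, 12), rng_seed = 11)
  expect_identical(co[[3]]$pair$t2, co2[[3]]$pair$t2)
  # tumors land in different places for different cases
  centers <- vapply(co, function(ph) {
    idx <- which(ph$tumor_mask == 1, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(3))
  expect_gt(max(dist(t(centers))), 0)
  expect_error(make_cohort(0), ">= 1")
})
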