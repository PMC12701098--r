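test_that("isolate_tumor_region adds expert labels and masks the clusters", {
  cl <- array(rep(0:3, 16), c(4, 4, 4))
  el1 <- array(0L, c(4, 4, 4))
  el2 <- array(0L, c(4, 4, 4))
  el1[2, 3, 1] <- 1L
  iso <- isolate_tumor_region(el1, el2, cl)
  expect_equal(sum(iso$region), 1)
  expect_equal(iso$clusters_masked[2, 3, 1], cl[2, 3, 1])
  expect_equal(sum(iso$clusters_masked == -1L), 63)
  # disjoint labels combine by union
  el2[4, 4, 4] <- 1L
  iso2 <- isolate_tumor_region(el1, el2, cl)
  expect_equal(sum(iso2$region), 2)
  # full coverage keeps the whole map
  full <- array(1L, c(4, 4, 4))
  iso3 <- isolate_tumor_region(full, full, cl)
  expect_identical(iso3$clusters_masked, array(as.integer(cl), dim(cl)))
  expect_error(isolate_tumor_region(el1 * 0L, el2 * 0L, cl), "no expert label")
  expect_error(isolate_tumor_region(el1[1:2, , , drop = FALSE], el2, cl), "shape")
})

test_that("place_seeds is stratified, in-bounds and deterministic", {
  cl <- array(1L, c(6, 6, 4))
  cl[1:3, , ] <- 4L
  region <- array(FALSE, c(6, 6, 4))
  region[2:5, 2:5, 2:3] <- TRUE
  seeds <- place_seeds(region, cl, n_seeds = 2, rng_seed = 9)
  expect_equal(nrow(seeds), 2)
  got <- vapply(seq_len(2), function(i) cl[seeds[i, 1] + 1, seeds[i, 2] + 1, seeds[i, 3] + 1], 0L)
  expect_setequal(got, c(1L, 4L))  # one seed per cluster present in the region
  for (i in 1:2) expect_true(region[seeds[i, 1] + 1, seeds[i, 2] + 1, seeds[i, 3] + 1])
  expect_identical(place_seeds(region, cl, 2, rng_seed = 9), seeds)
  # forced choice on a single-voxel region
  r1 <- array(FALSE, c(6, 6, 4))
  r1[3, 4, 2] <- TRUE
  expect_equal(unclass(place_seeds(r1, cl, 1, 1)),
               cbind(x = 2L, y = 3L, z = 1L), ignore_attr = TRUE)
  expect_error(place_seeds(r1, cl, 2, 1), "exceeds")
})

test_that("region_grow returns the seed's 6-connected same-label component", {
  # uniform map: the whole volume is one component
  uni <- array(7L, c(4, 4, 2))
  g <- region_grow(uni, c(1, 2, 0))
  expect_equal(g$volume, 32)
  expect_true(all(g$mask == 1L))
  expect_equal(g$cluster_label, 7L)
  # two same-labelled blobs separated by another label stay separate
  cl <- array(0L, c(8, 8, 2))
  cl[1:3, 1:3, ] <- 5L
  cl[6:8, 6:8, ] <- 5L
  gA <- region_grow(cl, c(1, 1, 0))
  expect_equal(gA$volume, 18)
  expect_equal(sum(gA$mask[6:8, 6:8, ]), 0)
  # isolated single-voxel cluster
  cl[4, 4, 1] <- 9L
  g1 <- region_grow(cl, c(3, 3, 0))
  expect_equal(g1$volume, 1)
  expect_error(region_grow(cl, c(8, 0, 0)), "out of bounds")
})

test_that("region_grow agrees with the BFS oracle on random maps", {
  set.seed(12)
  for (i in 1:100) {
    labs <- array(sample(0:3, 8 * 8 * 4, TRUE), c(8, 8, 4))
    seed <- c(sample(0:7, 1), sample(0:7, 1), sample(0:3, 1))
    expect_identical(region_grow(labs, seed)$mask, bfs_component_oracle(labs, seed))
  }
})

test_that("filter_masks keeps volumes up to three times the estimate", {
  mk <- function(vol, lab = 1L, at = 1L) {
    mask <- array(0L, c(10, 10, 2))
    mask[seq_len(vol) + at] <- 1L
    structure(list(mask = mask, seed = c(0L, 0L, 0L), cluster_label = lab,
                   volume = vol), class = "grown_mask")
  }
  crit <- filter_criteria(tumor_volume_estimate = 10, max_volume_factor = 3)
  out <- filter_masks(list(mk(10), mk(29, 2L, 40L), mk(31, 3L, 80L)), crit)
  expect_equal(vapply(out, `[[`, 0, "volume"), c(10, 29))
  # the boundary case 3x is retained (non-strict)
  out2 <- filter_masks(list(mk(30)), crit)
  expect_length(out2, 1)
  expect_length(filter_masks(list(), crit), 0)
  # duplicates (same component from two seeds) collapse to one
  dup <- filter_masks(list(mk(10), mk(10)), crit)
  expect_length(dup, 1)
})

test_that("compose_ai_label unions masks idempotently", {
  m1 <- array(0L, c(5, 5, 2)); m1[1:5] <- 1L
  m2 <- array(0L, c(5, 5, 2)); m2[11:17] <- 1L
  gm <- function(m) structure(list(mask = m, seed = c(0L, 0L, 0L),
                                   cluster_label = 0L, volume = sum(m)),
                              class = "grown_mask")
  expect_identical(compose_ai_label(list(gm(m1))), m1)
  expect_equal(sum(compose_ai_label(list(gm(m1), gm(m2)))), 12)
  expect_identical(compose_ai_label(list(gm(m1), gm(m1))), m1)
  expect_error(compose_ai_label(list()), "no valid mask")
})

test_that("generate_ai_label recovers a clean cluster and filters oversized ones", {
  # tumor cluster coincides with the expert region
  cl <- array(0L, c(12, 12, 6))
  cl[4:8, 4:8, 2:4] <- 1L
  el <- array(0L, c(12, 12, 6))
  el[4:8, 4:8, 2:4] <- 1L
  res <- generate_ai_label(cl, el, el, n_seeds = 3, rng_seed = 1)
  expect_identical(res$ail, el)
  expect_false(res$provenance$fallback)
  # a component larger than 3x the region is excluded
  cl2 <- array(0L, c(12, 12, 6))   # label 0 spans 861 voxels >> 3 * small region
  cl2[6, 6, 3] <- 1L
  el2 <- array(0L, c(12, 12, 6))
  el2[5:7, 5:7, 3] <- 1L           # region of 9: the big component fails 3x
  res2 <- generate_ai_label(cl2, el2, el2, n_seeds = 2, rng_seed = 2)
  expect_true(any(!res2$provenance$retained))
  expect_false(any(res2$ail[cl2 == 0L & el2 == 0L] == 1L))
})

test_that("AI-L is a union of whole components, monotone in the filter factor", {
  set.seed(31)
  cl <- array(sample(0:2, 14 * 14 * 6, TRUE, prob = c(.5, .3, .2)), c(14, 14, 6))
  el1 <- array(0L, c(14, 14, 6)); el1[5:9, 5:9, 2:4] <- 1L
  el2 <- array(0L, c(14, 14, 6)); el2[6:10, 6:10, 3:5] <- 1L
  r3 <- generate_ai_label(cl, el1, el2, n_seeds = 5, max_volume_factor = 3, rng_seed = 4)
  r9 <- generate_ai_label(cl, el1, el2, n_seeds = 5, max_volume_factor = 9, rng_seed = 4)
  expect_true(all(r9$ail[r3$ail == 1L] == 1L))  # enlarging the factor never shrinks AI-L
  # every retained component lies wholly inside AI-L
  seeds <- r3$provenance$seeds
  keep <- which(r3$provenance$retained)
  for (i in keep) {
    g <- region_grow(cl, seeds[i, ])
    expect_true(all(r3$ail[g$mask == 1L] == 1L))
  }
})
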