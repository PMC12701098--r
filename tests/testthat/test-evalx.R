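mk_mask <- function(idx, dims = c(5, 5, 4)) {
  m <- array(0L, dims)
  m[idx] <- 1L
  m
}

test_that("dice matches hand-counted overlaps and its edge conventions", {
  a <- mk_mask(1:4)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mk_mask(1:3), mk_mask(10:12)), 0)
  # |pred| = 4, |ref| = 2, intersection 2 -> 2*2/(4+2)
  expect_equal(dice(mk_mask(1:4), mk_mask(1:2)), 2 / 3)
  expect_equal(dice(mk_mask(integer(0)), mk_mask(integer(0))), 1)
  expect_error(dice(a, array(0L, c(4, 4, 4))), "shape")
})

test_that("dice is symmetric on random mask pairs", {
  set.seed(7)
  for (i in 1:1000) {
    a <- array(rbinom(60, 1, 0.4), c(5, 4, 3))
    b <- array(rbinom(60, 1, 0.4), c(5, 4, 3))
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("fnr and fpr use the confusion-matrix normalizations", {
  a <- mk_mask(1:10)
  expect_equal(fnr(a, a), 0)
  expect_equal(fnr(mk_mask(integer(0)), a), 1)
  expect_equal(fnr(mk_mask(1:9), mk_mask(1:10)), 0.1)
  expect_equal(fnr(a, mk_mask(integer(0))), 0)       # empty reference
  expect_equal(fpr(a, a), 0)
  full <- array(1L, c(5, 5, 4))
  expect_equal(fpr(full, mk_mask(integer(0))), 1)
  # 100 voxels, ref 10, pred = ref + 9 extra -> 9/90
  expect_equal(fpr(mk_mask(1:19, c(10, 10, 1)), mk_mask(1:10, c(10, 10, 1))), 0.1)
})

test_that("dsc equals 1 exactly when fnr and fpr vanish at equal mask sizes", {
  set.seed(21)
  for (i in 1:200) {
    a <- array(rbinom(40, 1, 0.5), c(5, 4, 2))
    b <- array(rbinom(40, 1, 0.5), c(5, 4, 2))
    d1 <- dice(a, b) == 1
    d2 <- fnr(a, b) == 0 && fpr(a, b) == 0 && sum(a) == sum(b)
    expect_equal(d1, d2)
  }
  expect_equal(label_overlap(mk_mask(1:4), mk_mask(1:2)), 2 / 3)
})

test_that("intra-cluster homogeneity computes pooled population variances", {
  dims <- c(4, 4, 2)
  # half the voxels at 0, half at 2: z-normalized variance is exactly 1
  t1 <- array(rep(c(0, 2), 16), dims)
  pair <- volume_pair(t1, t1)
  cl <- array(0L, dims)
  rep0 <- intra_cluster_homogeneity(list(cl), list(pair))
  expect_equal(rep0$table$var_t1, 1, tolerance = 1e-12)
  # a constant cluster has zero variance; ranking puts the variable one first
  t1b <- array(rep(c(0, 2), 16), dims)
  t1b[17:32] <- 5
  clb <- array(0L, dims)
  clb[17:32] <- 1L
  pairb <- volume_pair(t1b, t1b)
  repb <- intra_cluster_homogeneity(list(clb), list(pairb))
  expect_equal(repb$table$var_t2[repb$table$cluster == 1], 0, tolerance = 1e-12)
  expect_equal(repb$ranking[1], 0)
  # case order does not matter
  two <- intra_cluster_homogeneity(list(clb, cl), list(pairb, pair))
  rev2 <- intra_cluster_homogeneity(list(cl, clb), list(pair, pairb))
  expect_equal(two$table, rev2$table)
  # sub-2-voxel clusters are flagged undefined and left out of the ranking
  cl1 <- clb
  cl1[1, 1, 1] <- 2L
  rep1 <- intra_cluster_homogeneity(list(cl1), list(pairb))
  expect_false(rep1$table$defined[rep1$table$cluster == 2])
  expect_false(2 %in% rep1$ranking)
  # exclusion drops labels from the report entirely
  repx <- intra_cluster_homogeneity(list(clb), list(pairb), exclude = 1L)
  expect_equal(repx$table$cluster, 0)
})

test_that("blind trials randomize order and colors without leaking identities", {
  preds <- replicate(60, mk_mask(1:3), simplify = FALSE)
  tr <- blind_trials(preds, preds, rng_seed = 13)
  expect_equal(tr$n_cases, 60)
  expect_equal(nrow(tr$sheet), 60)
  # the rater-facing sheet carries no model identifiers
  expect_false(any(c("A", "B") %in% unlist(tr$sheet)))
  expect_named(tr$sheet, c("case_id", "first_color", "second_color"))
  # both orders and both colors occur
  expect_setequal(unique(tr$key$first_model), c("A", "B"))
  tr2 <- blind_trials(preds, preds, rng_seed = 13)
  expect_identical(tr, tr2)
  expect_error(blind_trials(preds, preds[1:10]), "length")
})

test_that("tally counts votes, majorities and agreement correctly", {
  preds <- replicate(2, mk_mask(1:3), simplify = FALSE)
  tr <- blind_trials(preds, preds, rng_seed = 1, case_ids = c("c1", "c2"))
  # every rater picks model A on every case (via the position that shows A)
  pos_a <- ifelse(tr$key$first_model == "A", "first", "second")
  choices <- expand.grid(case_id = c("c1", "c2"), rater = paste0("r", 1:3),
                         stringsAsFactors = FALSE)
  choices$choice <- pos_a[match(choices$case_id, tr$key$case_id)]
  res <- tally(tr, choices)
  expect_equal(res$totals$count[res$totals$model == "A"], 6)
  expect_equal(res$totals$count[res$totals$model == "B"], 0)
  expect_true(all(res$majority$majority == "A"))
  expect_equal(unname(res$agreement["unanimous"]), 2)
  # a 2-vs-1 split gives the majority to the pair
  choices2 <- choices
  flip <- choices2$rater == "r3"
  choices2$choice[flip] <- ifelse(choices2$choice[flip] == "first", "second", "first")
  res2 <- tally(tr, choices2)
  expect_true(all(res2$majority$majority == "A"))
  expect_equal(unname(res2$agreement["split"]), 2)
  # with 3 raters and 2 models a majority always exists (pigeonhole)
  set.seed(3)
  choices3 <- choices
  choices3$choice <- sample(c("first", "second"), nrow(choices3), TRUE)
  res3 <- tally(tr, choices3)
  expect_true(all(res3$majority$majority %in% c("A", "B")))
  # per-rater counts sum to the number of cases
  expect_true(all(rowSums(res3$per_rater) == 2))
  expect_error(tally(tr, choices[-1, ]), "incomplete")
})
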