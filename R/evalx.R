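#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,ref Binary 3D arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  .assert(identical(dim(pred), dim(ref)), "pred/ref shape mismatch")
  p <- as.logical(pred)
  r <- as.logical(ref)
  np <- sum(p); nr <- sum(r)
  if (np + nr == 0) return(1)
  2 * sum(p & r) / (np + nr)
}

#' False negative rate
#'
#' `FN / (FN + TP)` over reference-positive voxels; defined as 0 when the
#' reference is empty.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
fnr <- function(pred, ref) {
  .assert(identical(dim(pred), dim(ref)), "pred/ref shape mismatch")
  p <- as.logical(pred)
  r <- as.logical(ref)
  if (sum(r) == 0) return(0)
  sum(r & !p) / sum(r)
}

#' False positive rate
#'
#' `FP / (FP + TN)` over reference-negative voxels; defined as 0 when there is
#' no reference-negative voxel.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
fpr <- function(pred, ref) {
  .assert(identical(dim(pred), dim(ref)), "pred/ref shape mismatch")
  p <- as.logical(pred)
  r <- as.logical(ref)
  neg <- sum(!r)
  if (neg == 0) return(0)
  sum(p & !r) / neg
}

#' All segmentation metrics for one case
#'
#' @inheritParams dice
#' @return List with `dsc`, `fnr`, `fpr`.
#' @export
seg_metrics <- function(pred, ref) {
  list(dsc = dice(pred, ref), fnr = fnr(pred, ref), fpr = fpr(pred, ref))
}

#' Overlap between two label masks
#'
#' Per-case similarity between an AI-assisted and an expert label, implemented
#' as the Dice coefficient; cohort-level summaries (mean +/- SD) are taken over
#' the per-case values.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
label_overlap <- function(pred, ref) dice(pred, ref)

#' Intra-cluster homogeneity analysis
#'
#' For every cluster label (except excluded ones, typically background) and
#' each modality, computes the population variance of z-normalized voxel
#' intensities pooled across cases, and ranks clusters by variance
#' (descending). A heterogeneous tissue such as tumor is expected to rank
#' first.
#'
#' @param cluster_maps List of integer cluster maps, case-aligned with `pairs`.
#' @param pairs List of [volume_pair()]s.
#' @param exclude Integer labels to drop from the report (e.g. background
#'   clusters).
#' @return A `homogeneity_report`: list with `table` (data frame: cluster,
#'   var_t1, var_t2, n_voxels, defined) and `ranking` (labels sorted by the
#'   mean of the two modality variances, descending; labels with fewer than 2
#'   voxels are flagged undefined and excluded from the ranking).
#' @export
intra_cluster_homogeneity <- function(cluster_maps, pairs, exclude = integer(0)) {
  .assert(length(cluster_maps) == length(pairs) && length(pairs) >= 1,
          "cluster_maps and pairs must be case-aligned and non-empty")
  labs_all <- sort(setdiff(unique(unlist(lapply(cluster_maps, function(m) unique(as.integer(m))))),
                           as.integer(exclude)))
  vals <- list(t1 = setNames(vector("list", length(labs_all)), labs_all),
               t2 = setNames(vector("list", length(labs_all)), labs_all))
  for (i in seq_along(pairs)) {
    z1 <- znormalize(pairs[[i]]$t1)
    z2 <- znormalize(pairs[[i]]$t2)
    m <- as.integer(cluster_maps[[i]])
    for (lab in labs_all) {
      sel <- m == lab
      if (any(sel)) {
        key <- as.character(lab)
        vals$t1[[key]] <- c(vals$t1[[key]], z1[sel])
        vals$t2[[key]] <- c(vals$t2[[key]], z2[sel])
      }
    }
  }
  popvar <- function(x) if (length(x) < 2) NA_real_ else mean((x - mean(x))^2)
  tab <- data.frame(
    cluster = labs_all,
    var_t1 = vapply(as.character(labs_all), function(k) popvar(vals$t1[[k]]), 0),
    var_t2 = vapply(as.character(labs_all), function(k) popvar(vals$t2[[k]]), 0),
    n_voxels = vapply(as.character(labs_all), function(k) length(vals$t1[[k]]), 0)
  )
  tab$defined <- !is.na(tab$var_t1) & !is.na(tab$var_t2)
  score <- (tab$var_t1 + tab$var_t2) / 2
  ok <- which(tab$defined)
  ranking <- tab$cluster[ok][order(score[ok], decreasing = TRUE)]
  structure(list(table = tab, ranking = ranking), class = "homogeneity_report")
}

#' Set up blinded comparison trials
#'
#' Prepares one trial per case for a blinded reader study comparing the
#' predictions of two models ("A" and "B"): per case, an independent random
#' presentation order and color assignment. The rater-facing sheet carries no
#' model identifiers; the un-blinding key is stored separately.
#'
#' @param preds_a,preds_b Case-aligned lists of prediction masks.
#' @param rng_seed Integer seed; the randomization is deterministic given it.
#' @param case_ids Optional case identifiers (default `case_1 ...`).
#' @param colors Two display colors to assign at random.
#' @return A `blind_trials` object: list with `sheet` (data frame: case_id,
#'   first_color, second_color — what raters see) and `key` (data frame:
#'   case_id, first_model, color_A, color_B — the un-blinding map).
#' @export
blind_trials <- function(preds_a, preds_b, rng_seed = 1L, case_ids = NULL,
                         colors = c("red", "blue")) {
  .assert(length(preds_a) == length(preds_b), "prediction lists differ in length")
  n <- length(preds_a)
  .assert(n >= 1, "need at least one case")
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(n))
  withr::with_seed(rng_seed, {
    first <- sample(c("A", "B"), n, replace = TRUE)
    col_a <- sample(colors, n, replace = TRUE)
  })
  col_b <- ifelse(col_a == colors[1], colors[2], colors[1])
  key <- data.frame(case_id = case_ids, first_model = first,
                    color_A = col_a, color_B = col_b,
                    stringsAsFactors = FALSE)
  sheet <- data.frame(case_id = case_ids,
                      first_color = ifelse(first == "A", col_a, col_b),
                      second_color = ifelse(first == "A", col_b, col_a),
                      stringsAsFactors = FALSE)
  structure(list(sheet = sheet, key = key, n_cases = n), class = "blind_trials")
}

#' Tally blinded evaluation choices
#'
#' Un-blinds rater choices and computes per-rater counts, overall totals with
#' percentages, the per-case majority vote (model chosen by at least 2 of 3
#' raters), and agreement statistics.
#'
#' @param trials A [blind_trials()] object.
#' @param choices Data frame with columns `case_id`, `rater`, `choice`, where
#'   `choice` is `"first"` or `"second"` (the presented position). Every rater
#'   must have chosen for every case.
#' @return List with `per_rater` (counts per rater per model), `totals`
#'   (counts and percentages per model), `majority` (data frame: case_id,
#'   majority), `majority_counts`, and `agreement` (`unanimous` / `split`
#'   case counts).
#' @export
tally <- function(trials, choices) {
  .assert(inherits(trials, "blind_trials"), "trials must be a blind_trials object")
  .assert(all(c("case_id", "rater", "choice") %in% names(choices)),
          "choices needs case_id, rater, choice columns")
  raters <- sort(unique(as.character(choices$rater)))
  for (cid in trials$key$case_id) {
    for (rt in raters) {
      hit <- choices$case_id == cid & choices$rater == rt
      if (sum(hit) != 1) {
        stop("incomplete choices: case ", cid, ", rater ", rt, call. = FALSE)
      }
    }
  }
  .assert(all(choices$choice %in% c("first", "second")),
          "choice must be 'first' or 'second'")
  first_model <- setNames(trials$key$first_model, trials$key$case_id)
  model <- ifelse(choices$choice == "first",
                  first_model[as.character(choices$case_id)],
                  ifelse(first_model[as.character(choices$case_id)] == "A", "B", "A"))
  choices$model <- factor(model, levels = c("A", "B"))
  per_rater <- table(rater = choices$rater, model = choices$model)
  totals <- table(choices$model)
  pct <- 100 * as.numeric(totals) / sum(totals)
  maj <- vapply(trials$key$case_id, function(cid) {
    votes <- table(choices$model[choices$case_id == cid])
    winner <- names(votes)[votes >= 2]
    if (length(winner) == 1) winner else "none"
  }, "")
  majority <- data.frame(case_id = trials$key$case_id, majority = unname(maj),
                         stringsAsFactors = FALSE)
  unan <- vapply(trials$key$case_id, function(cid) {
    v <- table(choices$model[choices$case_id == cid])
    max(v) == sum(v)
  }, TRUE)
  list(per_rater = per_rater,
       totals = data.frame(model = names(totals), count = as.numeric(totals),
                           pct = pct, stringsAsFactors = FALSE),
       majority = majority,
       majority_counts = table(factor(majority$majority, levels = c("A", "B", "none"))),
       agreement = c(unanimous = sum(unan), split = sum(!unan)))
}
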