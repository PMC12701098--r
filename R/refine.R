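#' Isolate the tumor region from expert labels
#'
#' Combines the per-modality expert labels by element-wise addition and
#' multiplies the result with the unsupervised segmentation: cluster labels are
#' kept where either expert label is positive and replaced by the sentinel
#' `-1L` ("outside") elsewhere.
#'
#' @param el_t1,el_t2 Binary 3D arrays (expert labels per modality).
#' @param clusters Integer 3D cluster map (0-based labels).
#' @return List with `clusters_masked` (integer array, `-1` outside the
#'   region) and `region` (logical array, the combined expert region).
#' @export
isolate_tumor_region <- function(el_t1, el_t2, clusters) {
  .assert(identical(dim(el_t1), dim(clusters)) && identical(dim(el_t2), dim(clusters)),
          "el_t1, el_t2 and clusters must share one shape")
  .assert(.is_binary(el_t1) && .is_binary(el_t2), "expert labels must be binary")
  region <- (el_t1 + el_t2) > 0
  if (!any(region)) {
    stop("degenerate input: no expert label present", call. = FALSE)
  }
  masked <- array(as.integer(clusters), dim(clusters))
  masked[!region] <- -1L
  list(clusters_masked = masked, region = region)
}

#' Place seed voxels inside the isolated region
#'
#' Draws `n_seeds` voxels from the region without replacement, stratified so
#' that every seed-eligible cluster label occurring in the region receives at
#' least one seed when `n_seeds` permits (labels are served in order of
#' decreasing voxel count within the region); remaining seeds are sampled
#' uniformly from the eligible remainder of the region.
#'
#' With `min_containment > 0` a cluster label is eligible only if at least
#' that fraction of the cluster's voxels (over the whole map) lies inside the
#' region — an expert clicks clusters that the region of interest captures,
#' not clusters that merely graze it. At the default 0 every label occurring
#' in the region is eligible.
#'
#' @param region Logical/binary 3D array, non-empty.
#' @param clusters Integer 3D cluster map aligned with `region`.
#' @param n_seeds Number of seeds (>= 1, at most the region size).
#' @param rng_seed Integer seed; deterministic given the seed.
#' @param min_containment Minimum in-region fraction of a cluster for it to
#'   receive seeds, in `[0, 1]`; if no label qualifies, all labels become
#'   eligible again.
#' @return A `seed_set`: integer matrix with columns `x`, `y`, `z` (0-based
#'   voxel coordinates).
#' @export
place_seeds <- function(region, clusters, n_seeds = 5L, rng_seed = 1L,
                        min_containment = 0) {
  .assert(identical(dim(region) * 1, dim(clusters) * 1), "region/clusters shape mismatch")
  region <- array(as.logical(region), dim(clusters))
  .assert(any(region), "region must be non-empty")
  .assert(n_seeds >= 1, "n_seeds must be >= 1")
  .assert(min_containment >= 0 && min_containment <= 1,
          "min_containment must be in [0, 1]")
  vox <- which(region)
  if (n_seeds > length(vox)) {
    stop("n_seeds exceeds the number of region voxels", call. = FALSE)
  }
  labs_all <- as.integer(clusters)
  labs_in <- labs_all[vox]
  in_counts <- table(labs_in)
  eligible <- as.integer(names(in_counts))
  if (min_containment > 0) {
    tot <- table(factor(labs_all, levels = names(in_counts)))
    frac <- as.numeric(in_counts) / as.numeric(tot)
    keep <- frac >= min_containment
    if (any(keep)) eligible <- eligible[keep]
  }
  withr::with_seed(rng_seed, {
    counts <- sort(in_counts[as.character(eligible)], decreasing = TRUE)
    strata <- as.integer(names(counts))
    picked <- integer(0)
    for (lab in head(strata, n_seeds)) {
      cand <- vox[labs_in == lab]
      picked <- c(picked, if (length(cand) == 1) cand else sample(cand, 1))
    }
    remaining <- n_seeds - length(picked)
    if (remaining > 0) {
      pool <- setdiff(vox[labs_in %in% strata], picked)
      if (length(pool) < remaining) pool <- c(pool, setdiff(vox, c(picked, pool)))
      picked <- c(picked, if (length(pool) == 1) pool else sample(pool, remaining))
    }
    picked
  }) -> picked
  dm <- dim(clusters)
  i0 <- picked - 1L
  coords <- cbind(x = i0 %% dm[1],
                  y = (i0 %/% dm[1]) %% dm[2],
                  z = i0 %/% (dm[1] * dm[2]))
  structure(coords, class = "seed_set")
}

#' Grow a mask from a seed within its cluster
#'
#' Expands from the seed voxel to the full 6-connected component of voxels
#' sharing the seed's cluster label — region growing driven by cluster
#' membership rather than image intensity. Growth may extend beyond the
#' expert-isolated region; the volume filter downstream handles over-growth.
#'
#' @param clusters Integer 3D cluster map.
#' @param seed Length-3 integer vector, 0-based voxel coordinate.
#' @return A `grown_mask`: list with `mask` (binary array), `seed`,
#'   `cluster_label` and `volume` (voxel count).
#' @export
region_grow <- function(clusters, seed) {
  dm <- dim(clusters)
  .assert(length(dm) == 3, "clusters must be a 3D array")
  seed <- as.integer(seed)
  .assert(length(seed) == 3, "seed must be a length-3 coordinate")
  if (any(seed < 0) || any(seed >= dm)) {
    stop("seed coordinate out of bounds", call. = FALSE)
  }
  flat0 <- seed[1] + dm[1] * (seed[2] + dm[2] * seed[3])
  labs <- array(as.integer(clusters), dm)
  mask <- cpp_region_grow(labs, flat0)
  structure(list(mask = array(as.integer(mask), dm),
                 seed = seed,
                 cluster_label = labs[flat0 + 1],
                 volume = sum(mask)),
            class = "grown_mask")
}

#' Volume-filter criteria for grown masks
#'
#' @param tumor_volume_estimate Estimated tumor volume in voxels (>= 1); in the
#'   pipeline this is the voxel count of the combined expert region.
#' @param max_volume_factor Masks with volume above
#'   `max_volume_factor * tumor_volume_estimate` are discarded (default 3; the
#'   comparison is non-strict, so exactly 3x is retained).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(tumor_volume_estimate, max_volume_factor = 3) {
  .assert(max_volume_factor > 0, "max_volume_factor must be > 0")
  .assert(tumor_volume_estimate >= 1, "tumor_volume_estimate must be >= 1")
  structure(list(max_volume_factor = max_volume_factor,
                 tumor_volume_estimate = as.integer(tumor_volume_estimate)),
            class = "filter_criteria")
}

#' Filter grown masks by volume
#'
#' Deduplicates masks that are the same connected component reached from
#' different seeds, then retains masks whose volume does not exceed
#' `max_volume_factor` times the tumor volume estimate. Order is preserved.
#'
#' @param masks List of `grown_mask` objects.
#' @param criteria A [filter_criteria()].
#' @return Filtered list of `grown_mask` objects.
#' @export
filter_masks <- function(masks, criteria) {
  .assert(inherits(criteria, "filter_criteria"), "criteria must be filter_criteria")
  if (length(masks) == 0) return(masks)
  key <- vapply(masks, function(m) {
    paste(m$cluster_label, m$volume, which.max(m$mask), sep = "/")
  }, "")
  masks <- masks[!duplicated(key)]
  keep <- vapply(masks, function(m) {
    m$volume <= criteria$max_volume_factor * criteria$tumor_volume_estimate
  }, TRUE)
  masks[keep]
}

#' Compose the AI-assisted label from valid masks
#'
#' @param valid_masks Non-empty list of `grown_mask` objects sharing one shape.
#' @return Binary 3D array: the voxelwise union (sum clipped to `{0, 1}`).
#' @export
compose_ai_label <- function(valid_masks) {
  if (length(valid_masks) == 0) {
    stop("degenerate input: no valid mask survived filtering", call. = FALSE)
  }
  acc <- valid_masks[[1]]$mask
  for (m in valid_masks[-1]) {
    .assert(identical(dim(m$mask), dim(acc)), "masks must share one shape")
    acc <- acc + m$mask
  }
  array(as.integer(acc > 0), dim(acc))
}

#' Generate the AI-assisted label for one case
#'
#' Full refinement pipeline: isolate the tumor region from the combined expert
#' labels, place stratified seeds, grow one mask per seed within its cluster,
#' discard masks larger than `max_volume_factor` times the region volume, and
#' take the union of the survivors. If no mask survives the filter, the
#' isolated expert region itself is returned and flagged in the provenance.
#'
#' @param clusters Integer 3D cluster map.
#' @param el_t1,el_t2 Binary expert labels (non-empty union).
#' @param n_seeds Number of seed clicks to simulate.
#' @param max_volume_factor Volume filter factor (default 3).
#' @param rng_seed Integer seed for the seed placement.
#' @param min_containment Seed-eligibility containment threshold passed to
#'   [place_seeds()]; the pipeline default 0.5 restricts clicks to clusters
#'   lying mostly inside the expert region (the clusters an expert would
#'   identify as segmenting the tumor).
#' @return An `ai_label`: list with `ail` (binary array) and `provenance`
#'   (seeds, per-mask cluster labels and volumes, retained flags,
#'   `tumor_volume_estimate`, `fallback`).
#' @export
generate_ai_label <- function(clusters, el_t1, el_t2, n_seeds = 5L,
                              max_volume_factor = 3, rng_seed = 1L,
                              min_containment = 0.5) {
  iso <- isolate_tumor_region(el_t1, el_t2, clusters)
  n_seeds <- min(n_seeds, sum(iso$region))
  seeds <- place_seeds(iso$region, clusters, n_seeds, rng_seed, min_containment)
  grown <- lapply(seq_len(nrow(seeds)), function(i) region_grow(clusters, seeds[i, ]))
  est <- sum(iso$region)
  crit <- filter_criteria(est, max_volume_factor)
  kept <- filter_masks(grown, crit)
  fallback <- length(kept) == 0
  ail <- if (fallback) {
    array(as.integer(iso$region), dim(clusters))
  } else {
    compose_ai_label(kept)
  }
  kept_keys <- vapply(kept, function(m) paste(m$cluster_label, m$volume, which.max(m$mask), sep = "/"), "")
  prov <- list(
    seeds = unclass(seeds),
    cluster_labels = vapply(grown, `[[`, 0L, "cluster_label"),
    volumes = vapply(grown, `[[`, 0, "volume"),
    retained = vapply(grown, function(m) {
      paste(m$cluster_label, m$volume, which.max(m$mask), sep = "/") %in% kept_keys
    }, TRUE),
    tumor_volume_estimate = est,
    max_volume_factor = max_volume_factor,
    fallback = fallback
  )
  structure(list(ail = ail, provenance = prov), class = "ai_label")
}
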