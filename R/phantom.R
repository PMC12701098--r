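#' Default tissue intensity table
#'
#' Modality-specific intensity statistics for the six simulated tissue classes.
#' Non-tumor tissues are well separated (>= 2 pooled SDs apart in at least one
#' modality) so they are clusterable; the tumor has a strictly larger intensity
#' SD than every other tissue in both modalities, emulating the heterogeneity
#' of cartilaginous bone tumors.
#'
#' @return Data frame with columns `name`, `mean_t1`, `sd_t1`, `mean_t2`,
#'   `sd_t2`. Row order defines the integer tissue index used in tissue maps
#'   (1 = background ... 6 = tumor).
#' @export
default_tissues <- function() {
  data.frame(
    name    = c("background", "fat", "muscle", "bone", "vessel", "tumor"),
    mean_t1 = c(5,  90, 45, 70, 20,  55),
    sd_t1   = c(2,   4,  4,  4,  4,  12),
    mean_t2 = c(5,  60, 35, 20, 80, 105),
    sd_t2   = c(2,   4,  4,  4,  4,  12),
    stringsAsFactors = FALSE
  )
}

.tissue_index <- function(tissues, name) match(name, tissues$name)

# Shift a 3D logical array by one voxel along one axis, filling with FALSE.
.shift3d <- function(m, dh = 0, dw = 0, dd = 0) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  src <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  dst <- src
  sh <- c(dh, dw, dd)
  for (ax in 1:3) {
    if (sh[ax] > 0) { dst[[ax]] <- (1 + sh[ax]):dm[ax]; src[[ax]] <- 1:(dm[ax] - sh[ax]) }
    if (sh[ax] < 0) { dst[[ax]] <- 1:(dm[ax] + sh[ax]); src[[ax]] <- (1 - sh[ax]):dm[ax] }
    if (abs(sh[ax]) >= dm[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

.neighbors6 <- function(m) {
  .shift3d(m, 1, 0, 0) | .shift3d(m, -1, 0, 0) |
    .shift3d(m, 0, 1, 0) | .shift3d(m, 0, -1, 0) |
    .shift3d(m, 0, 0, 1) | .shift3d(m, 0, 0, -1)
}

.erode6 <- function(m) {
  m & .shift3d(m, 1, 0, 0) & .shift3d(m, -1, 0, 0) &
      .shift3d(m, 0, 1, 0) & .shift3d(m, 0, -1, 0) &
      .shift3d(m, 0, 0, 1) & .shift3d(m, 0, 0, -1)
}

.dilate6 <- function(m) m | .neighbors6(m)

#' Simulate an expert tumor label
#'
#' Perturbs a ground-truth tumor mask the way a human annotation deviates from
#' it: a systematic under- or over-segmentation bias (morphological erosion or
#' dilation with the 6-connected structuring element) followed by independent
#' random flips of boundary voxels.
#'
#' @param tumor_mask Non-empty binary/logical 3D array.
#' @param bias_voxels Signed integer; negative erodes, positive dilates, by
#'   `abs(bias_voxels)` iterations.
#' @param jitter_prob Probability in `[0, 1]` of flipping each boundary voxel
#'   (inner boundary voxels may drop out, outer boundary voxels may be added).
#' @param rng_seed Integer seed; deterministic given the seed.
#' @return Binary 3D array (integer 0/1) of the same shape.
#' @export
simulate_expert_label <- function(tumor_mask, bias_voxels = 0L, jitter_prob = 0,
                                  rng_seed = 1L) {
  .assert(length(dim(tumor_mask)) == 3, "tumor_mask must be a 3D array")
  m <- array(as.logical(tumor_mask), dim(tumor_mask))
  if (!any(m)) stop("degenerate input: empty tumor mask", call. = FALSE)
  .assert(jitter_prob >= 0 && jitter_prob <= 1, "jitter_prob must be in [0, 1]")
  for (i in seq_len(abs(as.integer(bias_voxels)))) {
    m <- if (bias_voxels < 0) .erode6(m) else .dilate6(m)
  }
  if (jitter_prob > 0) {
    inner <- m & .neighbors6(!m)
    outer <- !m & .neighbors6(m)
    flips <- withr::with_seed(rng_seed, {
      runif(sum(inner) + sum(outer)) < jitter_prob
    })
    fi <- flips[seq_len(sum(inner))]
    fo <- flips[sum(inner) + seq_len(sum(outer))]
    m[which(inner)[fi]] <- FALSE
    m[which(outer)[fo]] <- TRUE
  }
  array(as.integer(m), dim(tumor_mask))
}

# In-plane elliptical cylinder mask.
.cylinder <- function(shape, ch, cw, rh, rw) {
  h <- seq_len(shape[1]); w <- seq_len(shape[2])
  plane <- outer(((h - ch) / rh)^2, ((w - cw) / rw)^2, `+`) <= 1
  array(rep(plane, shape[3]), shape)
}

.ellipsoid <- function(shape, c0, r0) {
  h <- ((seq_len(shape[1]) - c0[1]) / r0[1])^2
  w <- ((seq_len(shape[2]) - c0[2]) / r0[2])^2
  d <- ((seq_len(shape[3]) - c0[3]) / r0[3])^2
  array(outer(outer(h, w, `+`), d, `+`) <= 1, shape)
}

# Smooth low-frequency multiplicative field: a few random 3D cosine components.
.lowfreq_field <- function(shape, n_comp = 3) {
  f <- array(0, shape)
  gh <- seq_len(shape[1]) / shape[1]
  gw <- seq_len(shape[2]) / shape[2]
  gd <- seq_len(shape[3]) / shape[3]
  for (j in seq_len(n_comp)) {
    k <- runif(3, 1.5, 4)          # cycles per volume extent
    ph <- runif(3, 0, 2 * pi)
    f <- f + outer(outer(cos(2 * pi * k[1] * gh + ph[1]),
                         cos(2 * pi * k[2] * gw + ph[2])),
                   cos(2 * pi * k[3] * gd + ph[3]))
  }
  f / sqrt(n_comp / 2)             # approximately unit variance
}

#' Generate a synthetic multi-modal MRI phantom
#'
#' Builds a paired T1/T2 case with known ground truth: a background shell, a
#' subcutaneous fat rim, a muscle bulk, a bone cylinder, two vessel tubes, and
#' one ellipsoidal tumor placed at a seed-dependent position inside bone or
#' muscle. Voxel intensities are drawn from each tissue's modality-specific
#' normal distribution; tumor voxels are additionally modulated by a smooth
#' low-frequency field so the tumor is the most heterogeneous class. Simulated
#' expert labels for each modality are derived from the ground-truth tumor by
#' biased morphology plus boundary jitter.
#'
#' @param shape Volume shape `(H, W, D)`, all components >= 8.
#' @param tissues Tissue intensity table, see [default_tissues()].
#' @param tumor_radius_range In-plane tumor semi-axis range in voxels; the
#'   through-plane semi-axis is half the in-plane draw (anisotropic slices).
#' @param rng_seed Integer seed; the case is deterministic given the seed.
#' @param el_bias Length-2 bias (voxels) for the simulated T1 and T2 expert
#'   labels (default: T1 under-segments by 1, T2 over-segments by 1).
#' @param el_jitter Boundary flip probability for expert labels.
#' @param tumor_mod_amp Amplitude of the intra-tumor modulation field, in
#'   multiples of the tumor intensity SD.
#' @return A `phantom_case`: list with `pair` ([volume_pair()]), `tissue_map`
#'   (integer array, indices into `tissues`), `tumor_mask`, `el_t1`, `el_t2`
#'   (binary arrays) and `rng_seed`.
#' @export
make_phantom <- function(shape = c(48, 48, 16), tissues = default_tissues(),
                         tumor_radius_range = c(5, 9), rng_seed = 1L,
                         el_bias = c(-1, 1), el_jitter = 0.05,
                         tumor_mod_amp = 1.5) {
  .assert(length(shape) == 3 && all(shape >= 8), "shape components must be >= 8")
  .assert(length(tumor_radius_range) == 2 && all(tumor_radius_range > 0),
          "tumor_radius_range must be 2 positive values")
  rmax <- max(tumor_radius_range)
  if (2 * rmax + 4 > min(shape[1], shape[2]) || rmax / 2 * 2 + 2 > shape[3]) {
    stop("tumor radius range does not fit inside the volume", call. = FALSE)
  }
  ti <- function(nm) .tissue_index(tissues, nm)
  withr::with_seed(rng_seed, {
    H <- shape[1]; W <- shape[2]; D <- shape[3]
    tmap <- array(ti("background"), shape)
    body <- .cylinder(shape, (H + 1) / 2, (W + 1) / 2, 0.44 * H, 0.44 * W)
    inner <- .cylinder(shape, (H + 1) / 2, (W + 1) / 2, 0.36 * H, 0.36 * W)
    tmap[body] <- ti("fat")
    tmap[inner] <- ti("muscle")
    bone <- .cylinder(shape, 0.5 * H, 0.42 * W, 0.11 * H, 0.11 * W)
    tmap[bone & inner] <- ti("bone")
    v1 <- .cylinder(shape, 0.32 * H, 0.62 * W, max(1.2, 0.03 * H), max(1.2, 0.03 * W))
    v2 <- .cylinder(shape, 0.68 * H, 0.60 * W, max(1.2, 0.03 * H), max(1.2, 0.03 * W))
    tmap[(v1 | v2) & inner] <- ti("vessel")

    r <- runif(1, tumor_radius_range[1], tumor_radius_range[2])
    rz <- max(2, r / 2)
    host <- tmap == ti("bone") | tmap == ti("muscle")
    ok <- FALSE
    for (try in 1:1000) {
      c0 <- c(runif(1, r + 2, H - r - 1), runif(1, r + 2, W - r - 1),
              runif(1, rz + 1, D - rz))
      ci <- round(c0)
      if (host[ci[1], ci[2], ci[3]]) { ok <- TRUE; break }
    }
    .assert(ok, "could not place tumor inside bone or muscle")
    tumor <- .ellipsoid(shape, c0, c(r, r, rz))
    tmap[tumor] <- ti("tumor")
    tumor_mask <- array(as.integer(tmap == ti("tumor")), shape)

    n <- prod(shape)
    t1 <- array(tissues$mean_t1[tmap] + tissues$sd_t1[tmap] * rnorm(n), shape)
    t2 <- array(tissues$mean_t2[tmap] + tissues$sd_t2[tmap] * rnorm(n), shape)
    fld <- .lowfreq_field(shape)
    sel <- tumor_mask == 1
    t1[sel] <- t1[sel] + tumor_mod_amp * tissues$sd_t1[ti("tumor")] * fld[sel]
    t2[sel] <- t2[sel] + tumor_mod_amp * tissues$sd_t2[ti("tumor")] * fld[sel]

    el_seeds <- c(.sub_seed(rng_seed, 101), .sub_seed(rng_seed, 202))
    el_t1 <- simulate_expert_label(tumor_mask, el_bias[1], el_jitter, el_seeds[1])
    el_t2 <- simulate_expert_label(tumor_mask, el_bias[2], el_jitter, el_seeds[2])

    structure(list(
      pair = volume_pair(t1, t2, spacing = c(1, 1, 2),
                         case_id = paste0("phantom_", rng_seed),
                         patient_id = paste0("pat_", rng_seed)),
      tissue_map = tmap, tumor_mask = tumor_mask,
      el_t1 = el_t1, el_t2 = el_t2, rng_seed = as.integer(rng_seed)
    ), class = "phantom_case")
  })
}

#' Generate a phantom cohort
#'
#' @param n_cases Number of independent cases (>= 1).
#' @param shape,tissues,... Passed to [make_phantom()].
#' @param rng_seed Master seed; per-case sub-seeds are derived from it
#'   deterministically, so cases differ but the cohort is reproducible.
#' @return List of `phantom_case` objects with unique case and patient ids.
#' @export
make_cohort <- function(n_cases, shape = c(48, 48, 16), tissues = default_tissues(),
                        rng_seed = 1L, ...) {
  .assert(n_cases >= 1, "n_cases must be >= 1")
  lapply(seq_len(n_cases), function(i) {
    ph <- make_phantom(shape = shape, tissues = tissues,
                       rng_seed = .sub_seed(rng_seed, i), ...)
    ph$pair$case_id <- sprintf("case_%03d", i)
    ph$pair$patient_id <- sprintf("pat_%03d", i)
    ph
  })
}

#' Write a phantom cohort to disk
#'
#' Writes per-case NIfTI volumes (T1, T2), masks (ground truth, expert labels)
#' and a CSV manifest.
#'
#' @param cohort List of `phantom_case` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    id <- ph$pair$case_id
    write_volume(ph$pair$t1, file.path(dir, paste0(id, "_t1.nii.gz")), ph$pair$spacing)
    write_volume(ph$pair$t2, file.path(dir, paste0(id, "_t2.nii.gz")), ph$pair$spacing)
    write_volume(ph$tumor_mask, file.path(dir, paste0(id, "_tumor.nii.gz")),
                 ph$pair$spacing, datatype = "uint8")
    write_volume(ph$el_t1, file.path(dir, paste0(id, "_el_t1.nii.gz")),
                 ph$pair$spacing, datatype = "uint8")
    write_volume(ph$el_t2, file.path(dir, paste0(id, "_el_t2.nii.gz")),
                 ph$pair$spacing, datatype = "uint8")
    data.frame(case_id = id, patient_id = ph$pair$patient_id,
               rng_seed = ph$rng_seed, tumor_volume = sum(ph$tumor_mask))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
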