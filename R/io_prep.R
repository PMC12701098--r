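#' Read a 3D NIfTI volume
#'
#' Reads a single 3D image from a NIfTI-1 file and returns the voxel array
#' together with the voxel spacing from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A list with `data` (numeric array, `(H, W, D)` index order, 0-based
#'   voxel semantics) and `spacing` (length-3 numeric, mm).
#' @export
read_volume <- function(path) {
  .assert(is.character(path) && length(path) == 1, "path must be a single string")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3) {
    stop("expected a 3D image, got rank ", nd, " in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), dim = dim(img)), spacing = as.numeric(sp))
}

#' Write a 3D volume as NIfTI
#'
#' @param vol Numeric (or integer/logical) 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm (length 3).
#' @param datatype NIfTI on-disk datatype; binary masks are stored as `uint8`,
#'   cluster maps as `uint16`, intensities as `double`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1), datatype = "double") {
  .assert(length(dim(vol)) == 3, "vol must be a 3D array")
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Construct a co-registered T1/T2 volume pair
#'
#' @param t1,t2 3D numeric arrays of identical shape.
#' @param spacing Voxel spacing in mm (length 3, all positive).
#' @param case_id,patient_id Identifier strings.
#' @return A `volume_pair` object.
#' @export
volume_pair <- function(t1, t2, spacing = c(1, 1, 1),
                        case_id = "case", patient_id = case_id) {
  .assert(length(dim(t1)) == 3 && length(dim(t2)) == 3, "t1 and t2 must be 3D arrays")
  .assert(identical(dim(t1), dim(t2)), "t1 and t2 must have identical shape")
  .assert(all(dim(t1) >= 1), "all dimensions must be >= 1")
  .assert(length(spacing) == 3 && all(spacing > 0), "spacing must be 3 positive values")
  structure(list(t1 = t1, t2 = t2, spacing = as.numeric(spacing),
                 case_id = as.character(case_id),
                 patient_id = as.character(patient_id)),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat("<volume_pair> ", x$case_id, " (patient ", x$patient_id, "): ",
      paste(dim(x$t1), collapse = "x"),
      ", spacing ", paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

# Resample a 3D array to a target shape. Pixel-centre alignment; trilinear for
# intensities, nearest-neighbour for label volumes.
.resample3d <- function(a, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  dm <- dim(a)
  .assert(length(dm) == 3, "input must be a 3D array")
  .assert(length(target) == 3 && all(target >= 1), "target shape must be 3 values >= 1")
  target <- as.integer(target)
  if (identical(as.integer(dm), target)) return(a)
  g <- lapply(1:3, function(ax) (seq_len(target[ax]) - 0.5) * dm[ax] / target[ax] - 0.5)
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(g[[ax]]) + 1, 1), dm[ax]))
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(g, floor)
  fr <- lapply(1:3, function(ax) g[[ax]] - lo[[ax]])
  i0 <- lapply(1:3, function(ax) pmin(pmax(lo[[ax]], 0), dm[ax] - 1) + 1)
  i1 <- lapply(1:3, function(ax) pmin(pmax(lo[[ax]] + 1, 0), dm[ax] - 1) + 1)
  out <- array(0, dim = target)
  for (ch in 0:1) for (cw in 0:1) for (cd in 0:1) {
    ih <- if (ch == 0) i0[[1]] else i1[[1]]
    iw <- if (cw == 0) i0[[2]] else i1[[2]]
    id <- if (cd == 0) i0[[3]] else i1[[3]]
    wh <- if (ch == 0) 1 - fr[[1]] else fr[[1]]
    ww <- if (cw == 0) 1 - fr[[2]] else fr[[2]]
    wd <- if (cd == 0) 1 - fr[[3]] else fr[[3]]
    wgt <- outer(outer(wh, ww), wd)
    out <- out + wgt * a[ih, iw, id, drop = FALSE]
  }
  out
}

#' Harmonize two modalities to a common shape
#'
#' Resamples both modalities to `target_shape` with trilinear interpolation so
#' the paired volumes can be stacked as network input. Spacing is rescaled so
#' the physical extent of the volume is preserved.
#'
#' @param t1_raw,t2_raw Either a 3D array or a list with `data` and `spacing`
#'   as returned by [read_volume()].
#' @param target_shape Integer length-3 target shape; the clinical default is
#'   `c(512, 512, 32)` (in-plane matrix x depth slices).
#' @param case_id,patient_id Identifiers attached to the resulting pair.
#' @return A [volume_pair()] with both modalities at `target_shape`.
#' @export
match_dimensions <- function(t1_raw, t2_raw, target_shape = c(512, 512, 32),
                             case_id = "case", patient_id = case_id) {
  .assert(length(target_shape) == 3 && all(target_shape >= 1),
          "target_shape components must be >= 1")
  unwrap <- function(x) {
    if (is.list(x)) list(data = x$data, spacing = x$spacing)
    else list(data = x, spacing = c(1, 1, 1))
  }
  a <- unwrap(t1_raw); b <- unwrap(t2_raw)
  .assert(length(dim(a$data)) == 3 && length(dim(b$data)) == 3,
          "both inputs must be 3D arrays")
  t1 <- .resample3d(a$data, target_shape, "trilinear")
  t2 <- .resample3d(b$data, target_shape, "trilinear")
  spacing <- a$spacing * dim(a$data) / target_shape
  volume_pair(t1, t2, spacing = spacing, case_id = case_id, patient_id = patient_id)
}

#' Z-normalize a volume
#'
#' Standardizes voxel intensities to zero mean and unit (population) standard
#' deviation, computed over all voxels of the volume.
#'
#' @param vol Numeric array with at least 2 voxels.
#' @return Array of the same shape with mean 0 and population SD 1.
#' @export
znormalize <- function(vol) {
  .assert(length(vol) >= 2, "volume must have at least 2 voxels")
  m <- mean(vol)
  s <- sqrt(mean((vol - m)^2))
  if (s == 0) stop("degenerate input: volume has zero intensity variance", call. = FALSE)
  (vol - m) / s
}

#' Patient-safe cohort split
#'
#' Splits a cohort into train/validation/test partitions at the patient level:
#' every case of a patient lands in the same partition, so no patient leaks
#' across partitions. Partition sizes follow `ratios` as closely as integer
#' patient counts allow (largest-remainder rounding).
#'
#' @param cases Data frame with columns `case_id` and `patient_id`, or a list
#'   of `c(case_id, patient_id)` pairs.
#' @param ratios Length-3 positive weights summing to 1 (train, val, test).
#' @param rng_seed Integer seed; the split is deterministic given the seed.
#' @return A `cohort_split`: list of `case_id` vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(cases, ratios = c(0.8, 0.1, 0.1), rng_seed = 1L) {
  if (is.list(cases) && !is.data.frame(cases)) {
    cases <- data.frame(case_id = vapply(cases, `[[`, "", 1),
                        patient_id = vapply(cases, `[[`, "", 2))
  }
  .assert(is.data.frame(cases) && nrow(cases) >= 1,
          "cases must contain at least one (case_id, patient_id) record")
  .assert(length(ratios) == 3 && abs(sum(ratios) - 1) < 1e-9,
          "ratios must be 3 values summing to 1")
  patients <- unique(as.character(cases$patient_id))
  np <- length(patients)
  perm <- withr::with_seed(rng_seed, sample(patients))
  base <- floor(np * ratios)
  rem <- np - sum(base)
  if (rem > 0) {
    frac <- np * ratios - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  part <- list(train = perm[seq_len(base[1])],
               val = perm[base[1] + seq_len(base[2])],
               test = perm[base[1] + base[2] + seq_len(base[3])])
  out <- lapply(part, function(p) as.character(cases$case_id[cases$patient_id %in% p]))
  structure(out, class = "cohort_split")
}
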