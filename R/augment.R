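# Data augmentation shared by the unsupervised clustering network and the
# supervised U-Net: a horizontal flip (along the W axis) with fixed
# probability, and an in-plane rotation about the depth axis by an angle drawn
# uniformly from [-max_rot_deg, +max_rot_deg]. Both modalities (and any label)
# receive the identical transform; intensities are interpolated bilinearly
# in-plane, labels with nearest neighbour.

.flip_w <- function(a) a[, dim(a)[2]:1, , drop = FALSE]

# Out-of-frame source coordinates are clamped to the border (replicate
# padding), so rotation introduces no artificial intensity region.
.rotate_inplane <- function(a, deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (deg == 0) return(a)
  dm <- dim(a)
  H <- dm[1]; W <- dm[2]; D <- dm[3]
  th <- deg * pi / 180
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  g <- expand.grid(h = seq_len(H), w = seq_len(W))
  # inverse mapping: output pixel -> source coordinate
  hs <- pmin(pmax(ch + cos(th) * (g$h - ch) - sin(th) * (g$w - cw), 1), H)
  ws <- pmin(pmax(cw + sin(th) * (g$h - ch) + cos(th) * (g$w - cw), 1), W)
  out <- array(0, dm)
  if (method == "nearest") {
    idx <- cbind(round(hs), round(ws))
    for (d in seq_len(D)) {
      sl <- a[, , d][idx]
      dim(sl) <- c(H, W)
      out[, , d] <- sl
    }
    return(out)
  }
  h0 <- pmin(floor(hs), H - 1); w0 <- pmin(floor(ws), W - 1)
  fh <- hs - h0; fw <- ws - w0
  wts <- cbind((1 - fh) * (1 - fw), (1 - fh) * fw, fh * (1 - fw), fh * fw)
  i00 <- cbind(h0, w0)
  i01 <- cbind(h0, w0 + 1)
  i10 <- cbind(h0 + 1, w0)
  i11 <- cbind(h0 + 1, w0 + 1)
  for (d in seq_len(D)) {
    sl2 <- a[, , d]
    sl <- wts[, 1] * sl2[i00] + wts[, 2] * sl2[i01] +
          wts[, 3] * sl2[i10] + wts[, 4] * sl2[i11]
    dim(sl) <- c(H, W)
    out[, , d] <- sl
  }
  out
}

# Draw one augmentation from the current RNG stream and apply it jointly.
# vols: list of 3D intensity arrays; label: optional 3D binary array.
.augment_sample <- function(vols, label = NULL, flip_prob = 0.3, max_rot_deg = 15) {
  do_flip <- runif(1) < flip_prob
  ang <- if (max_rot_deg > 0) runif(1, -max_rot_deg, max_rot_deg) else 0
  tx <- function(a, method) {
    if (do_flip) a <- .flip_w(a)
    .rotate_inplane(a, ang, method)
  }
  vols <- lapply(vols, tx, method = "bilinear")
  if (!is.null(label)) label <- tx(label, "nearest")
  list(vols = vols, label = label)
}
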