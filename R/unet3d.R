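#' Configuration of the dual-modality 3D U-Net
#'
#' @param in_channels Number of input channels; this artifact is two-modality
#'   (T1 + T2) by contract, so any other value is rejected.
#' @param depth Number of resolution levels (>= 2); spatial dimensions must be
#'   divisible by `2^(depth - 1)`.
#' @param base_width Feature channels at the finest level; width doubles per
#'   level.
#' @param lr Adam learning rate.
#' @param batch_size Volumes per update.
#' @param flip_prob,max_rot_deg Shared augmentation parameters.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience on the validation loss.
#' @param rng_seed Integer seed.
#' @return A `unet_config` list.
#' @export
unet_config <- function(in_channels = 2L, depth = 4L, base_width = 16L,
                        lr = 0.001, batch_size = 4L, flip_prob = 0.3,
                        max_rot_deg = 15, max_epochs = 50L, patience = 10L,
                        rng_seed = 1L) {
  if (in_channels != 2L) {
    stop("in_channels must be 2 (paired T1 + T2 input)", call. = FALSE)
  }
  .assert(depth >= 2, "depth must be >= 2")
  .assert(base_width >= 1, "base_width must be >= 1")
  structure(list(in_channels = 2L, depth = as.integer(depth),
                 base_width = as.integer(base_width), lr = lr,
                 batch_size = as.integer(batch_size), flip_prob = flip_prob,
                 max_rot_deg = max_rot_deg, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), rng_seed = as.integer(rng_seed)),
            class = "unet_config")
}

#' Build the dual-modality 3D U-Net
#'
#' Encoder-decoder with skip connections: one conv -> ReLU -> batch-norm block
#' per level, 2x max pooling down, nearest-neighbour upsampling and channel
#' concatenation up, and a final 1x1x1 convolution with a logistic output for
#' voxelwise tumor probability. Xavier-initialized.
#'
#' @param config A [unet_config()].
#' @return A `unet_model` parameter list (deterministic given
#'   `config$rng_seed`).
#' @export
build_unet <- function(config = unet_config()) {
  d <- config$depth
  w <- config$base_width * 2^(seq_len(d) - 1)
  withr::with_seed(config$rng_seed, {
    blk <- function(c_out, c_in) list(W = .xavier_conv(c_out, c_in, 3L),
                                      b = numeric(c_out),
                                      gamma = rep(1, c_out), beta = rep(0, c_out))
    enc <- vector("list", d - 1)
    c_in <- config$in_channels
    for (l in seq_len(d - 1)) {
      enc[[l]] <- blk(w[l], c_in)
      c_in <- w[l]
    }
    bott <- blk(w[d], c_in)
    dec <- vector("list", d - 1)
    for (l in rev(seq_len(d - 1))) {
      c_up <- if (l == d - 1) w[d] else w[l + 1]
      dec[[l]] <- blk(w[l], c_up + w[l])
    }
    fin <- list(W = .xavier_conv(1L, w[1], 1L), b = numeric(1))
    structure(list(enc = enc, bottleneck = bott, dec = dec, final = fin,
                   config = config), class = "unet_model")
  })
}

.unet_block_fwd <- function(blk, x, keep_cache) {
  y <- cpp_conv3d_fwd(x, blk$W, blk$b)
  r <- .relu_fwd(y)
  bn <- .bn_fwd(r$y, blk$gamma, blk$beta)
  list(out = bn$y,
       cache = if (keep_cache) list(x_in = x, relu_mask = r$mask,
                                    bn = bn[c("xhat", "inv")]) else NULL)
}

.unet_block_bwd <- function(blk, cache, gout) {
  bn <- .bn_bwd(cache$bn, blk$gamma, gout)
  g <- .relu_bwd(cache$relu_mask, bn$gx)
  cv <- cpp_conv3d_bwd(cache$x_in, blk$W, g)
  list(grads = list(W = cv$gw, b = cv$gb, gamma = bn$ggamma, beta = bn$gbeta),
       gx = cv$gx)
}

# Forward pass; x is (2, H, W, D). Returns voxel probabilities (1, H, W, D).
.unet_forward <- function(params, x, keep_cache = FALSE) {
  d <- params$config$depth
  dmx <- dim(x)[-1]
  .assert(all(dmx %% 2^(d - 1) == 0),
          sprintf("spatial dimensions must be divisible by %d", 2^(d - 1)))
  skips <- vector("list", d - 1)
  caches <- list(enc = vector("list", d - 1), pool = vector("list", d - 1),
                 dec = vector("list", d - 1))
  h <- x
  for (l in seq_len(d - 1)) {
    bl <- .unet_block_fwd(params$enc[[l]], h, keep_cache)
    skips[[l]] <- bl$out
    caches$enc[[l]] <- bl$cache
    pl <- cpp_maxpool3d_fwd(bl$out)
    caches$pool[[l]] <- list(idx = pl$idx, xdim = dim(bl$out))
    h <- pl$y
  }
  bb <- .unet_block_fwd(params$bottleneck, h, keep_cache)
  caches$bottleneck <- bb$cache
  h <- bb$out
  for (l in rev(seq_len(d - 1))) {
    up <- cpp_upsample3d_fwd(h)
    cat_in <- array(0, c(dim(up)[1] + dim(skips[[l]])[1], dim(up)[-1]))
    cat_in[seq_len(dim(up)[1]), , , ] <- up
    cat_in[dim(up)[1] + seq_len(dim(skips[[l]])[1]), , , ] <- skips[[l]]
    bl <- .unet_block_fwd(params$dec[[l]], cat_in, keep_cache)
    caches$dec[[l]] <- c(bl$cache, list(c_up = dim(up)[1]))
    h <- bl$out
  }
  logits <- cpp_conv3d_fwd(h, params$final$W, params$final$b)
  prob <- 1 / (1 + exp(-logits))
  caches$final_in <- if (keep_cache) h else NULL
  list(prob = prob, cache = if (keep_cache) caches else NULL)
}

# Backward from gradient w.r.t. probabilities.
.unet_backward <- function(params, cache, gprob, prob) {
  d <- params$config$depth
  glogits <- gprob * prob * (1 - prob)
  cv <- cpp_conv3d_bwd(cache$final_in, params$final$W, glogits)
  grads <- list(enc = vector("list", d - 1), bottleneck = NULL,
                dec = vector("list", d - 1),
                final = list(W = cv$gw, b = cv$gb))
  g <- cv$gx
  gskips <- vector("list", d - 1)
  for (l in seq_len(d - 1)) {
    bb <- .unet_block_bwd(params$dec[[l]], cache$dec[[l]], g)
    grads$dec[[l]] <- bb$grads
    c_up <- cache$dec[[l]]$c_up
    gup <- bb$gx[seq_len(c_up), , , , drop = FALSE]
    gskips[[l]] <- bb$gx[c_up + seq_len(dim(bb$gx)[1] - c_up), , , , drop = FALSE]
    g <- cpp_upsample3d_bwd(gup)
  }
  bb <- .unet_block_bwd(params$bottleneck, cache$bottleneck, g)
  grads$bottleneck <- bb$grads
  g <- bb$gx
  for (l in rev(seq_len(d - 1))) {
    g <- cpp_maxpool3d_bwd(cache$pool[[l]]$idx, g, cache$pool[[l]]$xdim)
    g <- g + gskips[[l]]
    bb <- .unet_block_bwd(params$enc[[l]], cache$enc[[l]], g)
    grads$enc[[l]] <- bb$grads
    g <- bb$gx
  }
  grads
}

# Soft Dice loss on probabilities vs a binary target; returns loss and dL/dp.
.dice_loss_grad <- function(prob, target, smooth = 1) {
  p <- as.numeric(prob)
  g <- as.numeric(target)
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  loss <- 1 - num / den
  grad <- -(2 * g * den - num) / den^2
  list(loss = loss, grad = array(grad, dim(prob)))
}

.stack_pair <- function(pair) {
  x <- array(0, c(2L, dim(pair$t1)))
  x[1, , , ] <- pair$t1
  x[2, , , ] <- pair$t2
  x
}

#' Train the supervised segmentation model
#'
#' Adam optimization of a soft Dice loss on the training partition, with the
#' shared augmentation (joint flip/rotation of both modalities and the label),
#' and early stopping on the validation loss.
#'
#' @param cohort List of cases, each a list with `pair` (a [volume_pair()])
#'   and `label` (binary 3D array matching the volume shape).
#' @param split A [split_cohort()] result; cases are matched by `case_id`.
#'   Training uses the `train` partition, early stopping watches `val` (when
#'   empty, the training loss is watched instead).
#' @param config A [unet_config()].
#' @param label_source Provenance tag recorded on the model: `"EL"` (expert
#'   labels) or `"AI-L"` (AI-assisted labels).
#' @param verbose Print one line per epoch.
#' @return A `trained_segmenter`: list with `params`, `label_source` and
#'   `history` (epoch, train_loss, val_loss).
#' @export
train_supervised <- function(cohort, split, config = unet_config(),
                             label_source = c("EL", "AI-L"), verbose = FALSE) {
  label_source <- match.arg(label_source)
  ids <- vapply(cohort, function(cs) cs$pair$case_id, "")
  tr <- which(ids %in% split$train)
  va <- which(ids %in% split$val)
  if (length(tr) == 0) stop("empty training partition", call. = FALSE)
  for (cs in cohort) {
    .assert(identical(dim(cs$label), dim(cs$pair$t1)), "label/volume shape mismatch")
  }
  if (all(vapply(cohort[tr], function(cs) sum(cs$label) == 0, TRUE))) {
    stop("degenerate labels: no positive voxel in any training label", call. = FALSE)
  }
  withr::with_seed(config$rng_seed, {
    params <- build_unet(config)
    opt <- .adam_init(params[c("enc", "bottleneck", "dec", "final")])
    best <- Inf
    best_params <- params
    since <- 0L
    hist <- vector("list", config$max_epochs)
    eval_loss <- function(i) {
      x <- .stack_pair(cohort[[i]]$pair)
      fw <- .unet_forward(params, x)
      .dice_loss_grad(fw$prob, cohort[[i]]$label)$loss
    }
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(length(ord), b0 + config$batch_size - 1)]
        bgrad <- NULL
        for (i in idx) {
          aug <- .augment_sample(list(cohort[[i]]$pair$t1, cohort[[i]]$pair$t2),
                                 label = cohort[[i]]$label,
                                 flip_prob = config$flip_prob,
                                 max_rot_deg = config$max_rot_deg)
          x <- array(0, c(2L, dim(aug$vols[[1]])))
          x[1, , , ] <- aug$vols[[1]]
          x[2, , , ] <- aug$vols[[2]]
          fw <- .unet_forward(params, x, keep_cache = TRUE)
          dl <- .dice_loss_grad(fw$prob, aug$label)
          losses <- c(losses, dl$loss)
          g <- .unet_backward(params, fw$cache, dl$grad, fw$prob)
          bgrad <- if (is.null(bgrad)) g else .add_params(bgrad, g)
        }
        bgrad <- .scale_params(bgrad, 1 / length(idx))
        st <- .adam_step(params[c("enc", "bottleneck", "dec", "final")],
                         bgrad, opt, config$lr)
        params[names(st$params)] <- st$params
        opt <- st$state
      }
      train_loss <- mean(losses)
      val_loss <- if (length(va) > 0) mean(vapply(va, eval_loss, 0)) else train_loss
      if (val_loss < best - 1e-6) {
        best <- val_loss
        best_params <- params
        since <- 0L
      } else {
        since <- since + 1L
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, train_loss, val_loss))
      }
      if (since >= config$patience) break
    }
    structure(list(params = best_params, label_source = label_source,
                   history = do.call(rbind, hist)),
              class = "trained_segmenter")
  })
}

#' Predict tumor probabilities for one case
#'
#' @param model A `trained_segmenter`.
#' @param pair A [volume_pair()] preprocessed as in training.
#' @return Numeric 3D array of voxelwise tumor probabilities.
#' @export
predict_prob <- function(model, pair) {
  x <- .stack_pair(pair)
  fw <- .unet_forward(model$params, x)
  array(fw$prob, dim(pair$t1))
}

#' Predict a binary tumor mask
#'
#' @param object A `trained_segmenter`.
#' @param pair A [volume_pair()] preprocessed as in training.
#' @param threshold Probability threshold in `(0, 1)`; voxels at or above it
#'   are labeled tumor.
#' @param ... Unused.
#' @return Binary integer 3D array.
#' @export
predict.trained_segmenter <- function(object, pair, threshold = 0.5, ...) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be inside (0, 1)", call. = FALSE)
  }
  p <- predict_prob(object, pair)
  array(as.integer(p >= threshold), dim(p))
}
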