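#' Configuration of the dual-branch feature-clustering network
#'
#' Two structurally identical, independently initialized 3D CNN branches (one
#' per modality) each produce `features_per_branch` feature channels per voxel;
#' the concatenated embedding has `q_total` channels and each voxel's cluster
#' is the argmax channel.
#'
#' @param n_blocks Convolution blocks per branch (conv -> ReLU -> batch norm;
#'   the final block has no ReLU before concatenation).
#' @param features_per_branch Channels per branch; `2 * features_per_branch`
#'   must equal `q_total`.
#' @param kernel_size Odd convolution kernel size (stride 1, same padding).
#' @param q_total Size of the concatenated per-voxel embedding, which is also
#'   the maximum number of clusters.
#' @return A `branch_config` list.
#' @export
branch_config <- function(n_blocks = 3L, features_per_branch = 30L,
                          kernel_size = 3L, q_total = 60L) {
  .assert(n_blocks >= 1, "n_blocks must be >= 1")
  .assert(features_per_branch >= 1, "features_per_branch must be >= 1")
  .assert(2L * features_per_branch == q_total,
          "2 * features_per_branch must equal q_total")
  .assert(kernel_size %% 2 == 1, "kernel_size must be odd")
  structure(list(n_blocks = as.integer(n_blocks),
                 features_per_branch = as.integer(features_per_branch),
                 kernel_size = as.integer(kernel_size),
                 q_total = as.integer(q_total)), class = "branch_config")
}

.build_branch <- function(config) {
  f <- config$features_per_branch
  k <- config$kernel_size
  blocks <- vector("list", config$n_blocks)
  c_in <- 1L
  for (i in seq_len(config$n_blocks)) {
    blk <- list(W = .xavier_conv(f, c_in, k), b = numeric(f))
    if (i < config$n_blocks) {
      blk$gamma <- rep(1, f)
      blk$beta <- rep(0, f)
    }
    blocks[[i]] <- blk
    c_in <- f
  }
  blocks
}

#' Build the dual-branch clustering model
#'
#' Creates two parallel CNN branches without shared weights (Xavier-initialized
#' independently) plus the batch-norm parameters of the concatenated embedding.
#'
#' @param config A [branch_config()].
#' @param rng_seed Integer seed; initialization is deterministic given the seed.
#' @return A `cluster_model` parameter list.
#' @export
build_model <- function(config = branch_config(), rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    structure(list(
      branch_t1 = .build_branch(config),
      branch_t2 = .build_branch(config),
      bn_gamma = rep(1, config$q_total),
      bn_beta = rep(0, config$q_total),
      config = config
    ), class = "cluster_model")
  })
}

# Forward through one branch; returns output and (optionally) caches.
.branch_fwd <- function(blocks, x, keep_cache = FALSE) {
  n <- length(blocks)
  caches <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    blk <- blocks[[i]]
    y <- cpp_conv3d_fwd(x, blk$W, blk$b)
    cc <- list(x_in = if (keep_cache) x else NULL)
    if (i < n) {
      r <- .relu_fwd(y)
      bn <- .bn_fwd(r$y, blk$gamma, blk$beta)
      if (keep_cache) { cc$relu_mask <- r$mask; cc$bn <- bn[c("xhat", "inv")] }
      x <- bn$y
    } else {
      x <- y
    }
    if (keep_cache) caches[[i]] <- cc
  }
  list(out = x, caches = caches)
}

.branch_bwd <- function(blocks, caches, gout) {
  n <- length(blocks)
  grads <- vector("list", n)
  g <- gout
  for (i in rev(seq_len(n))) {
    blk <- blocks[[i]]
    cc <- caches[[i]]
    gblk <- list()
    if (i < n) {
      bn <- .bn_bwd(cc$bn, blk$gamma, g)
      gblk$gamma <- bn$ggamma
      gblk$beta <- bn$gbeta
      g <- .relu_bwd(cc$relu_mask, bn$gx)
    }
    cv <- cpp_conv3d_bwd(cc$x_in, blk$W, g)
    grads[[i]] <- c(list(W = cv$gw, b = cv$gb), gblk)
    # match list element order with params for .map2_params
    grads[[i]] <- grads[[i]][names(blk)]
    g <- cv$gx
  }
  grads
}

.fc_forward <- function(params, t1, t2, keep_cache = FALSE) {
  f <- params$config$features_per_branch
  q <- params$config$q_total
  x1 <- array(t1, c(1L, dim(t1)))
  x2 <- array(t2, c(1L, dim(t2)))
  b1 <- .branch_fwd(params$branch_t1, x1, keep_cache)
  b2 <- .branch_fwd(params$branch_t2, x2, keep_cache)
  dm <- dim(b1$out)
  emb <- array(0, c(q, dm[2], dm[3], dm[4]))
  emb[seq_len(f), , , ] <- b1$out
  emb[f + seq_len(f), , , ] <- b2$out
  bn <- .bn_fwd(emb, params$bn_gamma, params$bn_beta)
  list(response = bn$y,
       cache = if (keep_cache) list(b1 = b1$caches, b2 = b2$caches,
                                    bn = bn[c("xhat", "inv")]) else NULL)
}

.fc_backward <- function(params, cache, gresp) {
  f <- params$config$features_per_branch
  bn <- .bn_bwd(cache$bn, params$bn_gamma, gresp)
  g1 <- bn$gx[seq_len(f), , , , drop = FALSE]
  g2 <- bn$gx[f + seq_len(f), , , , drop = FALSE]
  list(branch_t1 = .branch_bwd(params$branch_t1, cache$b1, g1),
       branch_t2 = .branch_bwd(params$branch_t2, cache$b2, g2),
       bn_gamma = bn$ggamma, bn_beta = bn$gbeta)
}

#' Compute the per-voxel feature embedding (response map)
#'
#' Runs each modality through its own branch, concatenates the two feature
#' stacks channel-wise and applies a final batch normalization over the
#' concatenated embedding.
#'
#' @param pair A [volume_pair()] with z-normalized intensities.
#' @param params A `cluster_model` from [build_model()].
#' @return 4D numeric array `(q_total, H, W, D)` of channel responses.
#' @export
forward_embed <- function(pair, params) {
  .assert(inherits(params, "cluster_model"), "params must be a cluster_model")
  .assert(identical(dim(pair$t1), dim(pair$t2)), "t1/t2 shape mismatch")
  .fc_forward(params, pair$t1, pair$t2)$response
}

#' Assign voxels to clusters by channel argmax
#'
#' @param response 4D array `(q, H, W, D)`; must be finite.
#' @return Integer 3D array of 0-based cluster labels in `[0, q)`; ties break
#'   to the lowest channel index.
#' @export
assign_clusters <- function(response) {
  .assert(length(dim(response)) == 4, "response must be a 4D array")
  if (anyNA(response) || any(!is.finite(response))) {
    stop("response map contains non-finite values", call. = FALSE)
  }
  dm <- dim(response)
  xm <- matrix(response, dm[1], prod(dm[-1]))
  lab <- max.col(t(xm), ties.method = "first") - 1L
  array(as.integer(lab), dm[-1])
}

# Column-wise max of a (q x V) matrix without transposing.
.colmax <- function(xm) {
  m <- xm[1, ]
  q <- nrow(xm)
  for (i in seq_len(q)[-1]) m <- pmax(m, xm[i, ])
  m
}

#' Feature-similarity (cross-entropy) loss
#'
#' Softmax cross-entropy between the per-voxel channel responses and the argmax
#' cluster labels of the same forward pass (labels act as constant targets, so
#' the network sharpens its own assignments).
#'
#' @param response 4D array `(q, H, W, D)`.
#' @param labels Integer 3D array of 0-based labels from [assign_clusters()].
#' @return Non-negative scalar (mean over voxels of `-log softmax[label]`).
#' @export
similarity_loss <- function(response, labels) {
  .sim_loss_grad(response, labels, want_grad = FALSE)$loss
}

.sim_loss_grad <- function(response, labels, want_grad = TRUE) {
  dm <- dim(response)
  q <- dm[1]; V <- prod(dm[-1])
  lab <- as.integer(labels)
  .assert(length(lab) == V, "labels shape does not match response")
  if (any(lab < 0L | lab >= q)) stop("label outside [0, q)", call. = FALSE)
  xm <- matrix(response, q, V)
  m <- .colmax(xm)
  ex <- exp(xm - rep(m, each = q))
  Z <- colSums(ex)
  picked <- xm[cbind(lab + 1L, seq_len(V))]
  loss <- mean(m + log(Z) - picked)
  if (!want_grad) return(list(loss = loss))
  sm <- ex / rep(Z, each = q)
  sm[cbind(lab + 1L, seq_len(V))] <- sm[cbind(lab + 1L, seq_len(V))] - 1
  list(loss = loss, grad = array(sm / V, dm))
}

#' Spatial-continuity loss
#'
#' L1 smoothness penalty on the response map built from absolute forward
#' differences of channel responses along the horizontal, vertical and depth
#' axes. Two reductions are provided: `"pairs"` (default) pools every
#' `(channel, neighbour-pair)` term into one overall mean; `"axis"` takes the
#' mean within each axis and sums the three per-axis means — the per-axis L1
#' form that the unsupervised training objective uses.
#'
#' @param response 4D array `(q, H, W, D)`; at least one spatial dimension must
#'   be >= 2.
#' @param reduction `"pairs"` or `"axis"` (see above).
#' @return Non-negative scalar; zero iff the response is constant along all
#'   three spatial axes.
#' @export
continuity_loss <- function(response, reduction = c("pairs", "axis")) {
  .cont_loss_grad(response, FALSE, match.arg(reduction))$loss
}

.cont_loss_grad <- function(response, want_grad = TRUE, reduction = "pairs") {
  dm <- dim(response)
  .assert(length(dm) == 4, "response must be a 4D array")
  cpp_cont_loss_grad(response, want_grad, identical(reduction, "axis"))
}

#' Combined clustering loss
#'
#' @param response 4D response map.
#' @param labels Argmax labels of the same forward pass.
#' @param mu Non-negative weight of the continuity term (default 1).
#' @param reduction Continuity reduction, see [continuity_loss()].
#' @return `similarity_loss(response, labels) + mu * continuity_loss(response)`.
#' @export
total_loss <- function(response, labels, mu = 1, reduction = c("pairs", "axis")) {
  .assert(mu >= 0, "mu must be non-negative")
  similarity_loss(response, labels) +
    mu * continuity_loss(response, match.arg(reduction))
}

#' Count distinct cluster labels
#'
#' @param cluster_maps Non-empty list of integer cluster maps (or one map).
#' @return Number of distinct label values across all maps.
#' @export
count_active_clusters <- function(cluster_maps) {
  if (!is.list(cluster_maps)) cluster_maps <- list(cluster_maps)
  .assert(length(cluster_maps) >= 1, "need at least one cluster map")
  length(unique(unlist(lapply(cluster_maps, function(m) unique(as.integer(m))))))
}

#' Training configuration for the unsupervised model
#'
#' @param mu Continuity-loss weight (>= 0).
#' @param lr Learning rate of stochastic gradient descent.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size (volumes per update).
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Epoch budget.
#' @param min_delta Minimum loss improvement that resets the patience counter.
#' @param flip_prob Probability of a horizontal flip per sample.
#' @param max_rot_deg Maximum in-plane rotation (degrees).
#' @param continuity_reduction Reduction of the continuity term inside the
#'   training objective: `"axis"` (default; sum of the per-axis L1 means, the
#'   form of the underlying differentiable-clustering objective) or
#'   `"pairs"` (one pooled mean).
#' @param rng_seed Integer seed controlling initialization, batching and
#'   augmentation.
#' @return A `cluster_train_config` list.
#' @export
cluster_train_config <- function(mu = 1, lr = 0.001, momentum = 0.9,
                                 batch_size = 4L, patience = 10L,
                                 max_epochs = 100L, min_delta = 1e-4,
                                 flip_prob = 0.3, max_rot_deg = 15,
                                 continuity_reduction = c("axis", "pairs"),
                                 rng_seed = 1L) {
  .assert(mu >= 0, "mu must be >= 0")
  .assert(flip_prob >= 0 && flip_prob <= 1, "flip_prob must be in [0, 1]")
  .assert(patience >= 1, "patience must be >= 1")
  structure(list(mu = mu, lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), min_delta = min_delta,
                 flip_prob = flip_prob, max_rot_deg = max_rot_deg,
                 continuity_reduction = match.arg(continuity_reduction),
                 rng_seed = as.integer(rng_seed)),
            class = "cluster_train_config")
}

#' Train the unsupervised clustering model
#'
#' Minimizes `similarity + mu * continuity` by mini-batch SGD with momentum.
#' Every sample is augmented per epoch (joint flip/rotation of both
#' modalities). Training stops early when the epoch loss has not improved by
#' `min_delta` for `patience` epochs. The number of active clusters (distinct
#' argmax labels over the whole, un-augmented cohort) is recorded per epoch:
#' clusters "merge" by extinction, when a channel stops winning any voxel.
#'
#' @param cohort Non-empty list of [volume_pair()]s at a common shape with
#'   z-normalized intensities.
#' @param config A [cluster_train_config()].
#' @param branch A [branch_config()].
#' @param cluster_count How to count active clusters per epoch: `"train"`
#'   (default) reuses the argmax maps of the epoch's training passes (no extra
#'   cost), `"eval"` recomputes cluster maps for the un-augmented cohort after
#'   each epoch.
#' @param verbose Print one line per epoch.
#' @return List with `params` (trained `cluster_model`) and `history` (data
#'   frame: epoch, loss, n_active_clusters, best_loss,
#'   epochs_since_improvement).
#' @export
train_unsupervised <- function(cohort, config = cluster_train_config(),
                               branch = branch_config(),
                               cluster_count = c("train", "eval"),
                               verbose = FALSE) {
  cluster_count <- match.arg(cluster_count)
  .assert(length(cohort) >= 1, "cohort must be non-empty")
  shp <- dim(cohort[[1]]$t1)
  for (p in cohort) .assert(identical(dim(p$t1), shp) && identical(dim(p$t2), shp),
                            "all volumes must share one shape")
  n <- length(cohort)
  withr::with_seed(config$rng_seed, {
    params <- structure(list(branch_t1 = .build_branch(branch),
                             branch_t2 = .build_branch(branch),
                             bn_gamma = rep(1, branch$q_total),
                             bn_beta = rep(0, branch$q_total),
                             config = branch), class = "cluster_model")
    opt <- .sgd_init(params[c("branch_t1", "branch_t2", "bn_gamma", "bn_beta")])
    best <- Inf
    since <- 0L
    hist <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      losses <- numeric(0)
      seen_labels <- integer(0)
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(n, b0 + config$batch_size - 1)]
        bgrad <- NULL
        for (i in idx) {
          aug <- .augment_sample(list(cohort[[i]]$t1, cohort[[i]]$t2),
                                 flip_prob = config$flip_prob,
                                 max_rot_deg = config$max_rot_deg)
          fw <- .fc_forward(params, aug$vols[[1]], aug$vols[[2]], keep_cache = TRUE)
          labels <- assign_clusters(fw$response)
          seen_labels <- union(seen_labels, unique(as.integer(labels)))
          sim <- .sim_loss_grad(fw$response, labels)
          cont <- .cont_loss_grad(fw$response,
                                  reduction = config$continuity_reduction)
          losses <- c(losses, sim$loss + config$mu * cont$loss)
          gresp <- sim$grad + config$mu * cont$grad
          g <- .fc_backward(params, fw$cache, gresp)
          bgrad <- if (is.null(bgrad)) g else .add_params(bgrad, g)
        }
        bgrad <- .scale_params(bgrad, 1 / length(idx))
        st <- .sgd_step(params[c("branch_t1", "branch_t2", "bn_gamma", "bn_beta")],
                        bgrad, opt, config$lr, config$momentum)
        params[names(st$params)] <- st$params
        opt <- st$state
      }
      nk <- if (cluster_count == "eval") {
        count_active_clusters(lapply(cohort, function(p) {
          assign_clusters(forward_embed(p, params))
        }))
      } else {
        length(seen_labels)
      }
      loss <- mean(losses)
      if (best - loss > config$min_delta) {
        best <- loss
        since <- 0L
      } else {
        since <- since + 1L
      }
      hist[[epoch]] <- data.frame(epoch = epoch, loss = loss,
                                  n_active_clusters = nk, best_loss = best,
                                  epochs_since_improvement = since)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  clusters %d", epoch, loss, nk))
      }
      if (since >= config$patience) break
    }
    list(params = params, history = do.call(rbind, hist))
  })
}

#' Predict a cluster map for one case
#'
#' @param params Trained `cluster_model`.
#' @param pair A [volume_pair()] preprocessed as in training.
#' @return Integer 3D array of 0-based cluster labels.
#' @export
predict_clusters <- function(params, pair) {
  assign_clusters(forward_embed(pair, params))
}
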