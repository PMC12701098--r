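# Shared neural-network primitives: Xavier initialization, per-sample 3D batch
# normalization, ReLU, and SGD/Adam parameter updates. Volumes carry channels
# first: (C, H, W, D). Convolution kernels live in src/kernels.cpp.

.xavier_conv <- function(c_out, c_in, k) {
  fan_in <- c_in * k^3
  fan_out <- c_out * k^3
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(c_out * c_in * k^3, -lim, lim), dim = c(c_out, c_in, k, k, k))
}

.relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

.relu_bwd <- function(mask, gy) gy * mask

# Batch normalization over the voxels of one sample (per-channel statistics).
# The same statistics are used in training and inference, which keeps forward
# passes deterministic without running averages.
.bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  dm <- dim(x)
  C <- dm[1]; V <- prod(dm[-1])
  xm <- matrix(x, C, V)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- gamma * xhat + beta
  list(y = array(y, dm), xhat = xhat, inv = inv)
}

.bn_bwd <- function(cache, gamma, gy) {
  dm <- dim(gy)
  C <- dm[1]; V <- prod(dm[-1])
  gym <- matrix(gy, C, V)
  gbeta <- rowSums(gym)
  ggamma <- rowSums(gym * cache$xhat)
  gx <- (gamma * cache$inv) * (gym - gbeta / V - cache$xhat * (ggamma / V))
  list(gx = array(gx, dm), ggamma = ggamma, gbeta = gbeta)
}

# Parameter containers are nested lists of numeric arrays; these helpers walk
# them uniformly.
.map_params <- function(p, f) {
  if (is.list(p)) lapply(p, .map_params, f = f) else f(p)
}

.map2_params <- function(p, q, f) {
  if (is.list(p)) mapply(.map2_params, p, q, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(p, q)
}

.zeros_like <- function(p) .map_params(p, function(x) x * 0)

# SGD with momentum: v <- mom * v - lr * g; p <- p + v.
.sgd_step <- function(params, grads, state, lr, momentum) {
  state$v <- .map2_params(state$v, grads, function(v, g) momentum * v - lr * g)
  params <- .map2_params(params, state$v, function(p, v) p + v)
  list(params = params, state = state)
}

.sgd_init <- function(params) list(v = .zeros_like(params))

.adam_init <- function(params) list(m = .zeros_like(params), v = .zeros_like(params), t = 0)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .map2_params(state$m, state$v,
                      function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# Sum two gradient trees (for mini-batch accumulation).
.add_params <- function(a, b) .map2_params(a, b, `+`)
.scale_params <- function(a, s) .map_params(a, function(x) x * s)
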