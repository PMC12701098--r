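# Independent oracles used by unit and acceptance tests. These deliberately
# use naive algorithms (queue-based BFS, triple loops) so they share no code
# with the implementation they check.

# Breadth-first search over 6-connected voxels sharing the seed's label.
# labels: integer 3D array; seed: 0-based coordinate. Returns binary array.
bfs_component_oracle <- function(labels, seed) {
  dm <- dim(labels)
  lab <- labels[seed[1] + 1, seed[2] + 1, seed[3] + 1]
  mask <- array(0L, dm)
  queue <- list(seed)
  mask[seed[1] + 1, seed[2] + 1, seed[3] + 1] <- 1L
  steps <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (df in steps) {
      u <- v + df
      if (any(u < 0) || any(u >= dm)) next
      if (mask[u[1] + 1, u[2] + 1, u[3] + 1] == 0L &&
          labels[u[1] + 1, u[2] + 1, u[3] + 1] == lab) {
        mask[u[1] + 1, u[2] + 1, u[3] + 1] <- 1L
        queue <- c(queue, list(u))
      }
    }
  }
  mask
}

# Triple-loop forward-difference L1 continuity, mean over all (channel, pair)
# terms.
continuity_oracle <- function(r) {
  dm <- dim(r)
  tot <- 0
  n <- 0
  for (cc in seq_len(dm[1])) for (h in seq_len(dm[2])) {
    for (w in seq_len(dm[3])) for (d in seq_len(dm[4])) {
      if (h < dm[2]) { tot <- tot + abs(r[cc, h + 1, w, d] - r[cc, h, w, d]); n <- n + 1 }
      if (w < dm[3]) { tot <- tot + abs(r[cc, h, w + 1, d] - r[cc, h, w, d]); n <- n + 1 }
      if (d < dm[4]) { tot <- tot + abs(r[cc, h, w, d + 1] - r[cc, h, w, d]); n <- n + 1 }
    }
  }
  tot / n
}

# z-normalize both modalities of a phantom's pair.
prep_pair <- function(ph) {
  p <- ph$pair
  p$t1 <- znormalize(p$t1)
  p$t2 <- znormalize(p$t2)
  p
}

# Dice of the best-matching single cluster against a reference mask.
best_cluster_dice <- function(map, ref) {
  labs <- unique(as.integer(map))
  max(vapply(labs, function(L) {
    dice(array(as.integer(map == L), dim(map)), ref)
  }, 0))
}
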