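# Independent oracles and small fixtures shared across tests.

# Queue-based flood fill, 8-connectivity: independent of the package's
# graph-based component labelling.
flood_label <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(b > 0)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (lab[v] > 0) next
      lab[v] <- cur
      i <- (v - 1) %% nr + 1
      j <- (v - 1) %/% nr + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            b[ii, jj] > 0 && lab[ii, jj] == 0) {
          q <- c(q, (jj - 1) * nr + ii)
        }
      }
    }
  }
  lab
}

# Two labelings induce the same partition of the foreground?
same_partition <- function(l1, l2, fg) {
  all(tapply(l1[fg], l2[fg], function(v) length(unique(v))) == 1) &&
    all(tapply(l2[fg], l1[fg], function(v) length(unique(v))) == 1)
}

# Central finite-difference gradient of a scalar function of one layer
# parameter; used to validate analytic backprop.
numeric_grad <- function(layer, name, i, loss_fn, eps = 1e-5) {
  p0 <- layer[[name]][i]
  layer[[name]][i] <- p0 + eps
  f1 <- loss_fn()
  layer[[name]][i] <- p0 - eps
  f2 <- loss_fn()
  layer[[name]][i] <- p0
  (f1 - f2) / (2 * eps)
}

# Tiny phantom set for fast training fixtures.
tiny_phantoms <- function(n, size = 32, seed0 = 100) {
  lapply(seq_len(n), function(s) {
    generate_vessel_tree(phantom_config(image_size = size,
                                        n_seed_vessels = 4,
                                        fov_margin = 2,
                                        rng_seed = seed0 + s))
  })
}

# Raster-order (row-major) flatten of a matrix.
raster_vec <- function(m) as.vector(t(m))
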