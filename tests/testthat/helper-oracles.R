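# Independent brute-force oracles for the min-max weight solvers: dense
# simplex grid search, refined locally down to a 1e-3 step. The deviation
# functions restate the BWM and FUCOM programs directly and share no code
# with the package solvers.

simplex_grid_points <- function(n, step) {
  ticks <- seq(step, 1 - (n - 1) * step, by = step)
  if (n == 2) return(cbind(ticks, 1 - ticks))
  g <- as.matrix(do.call(expand.grid, rep(list(ticks), n - 1)))
  last <- 1 - rowSums(g)
  keep <- last >= step - 1e-12
  unname(cbind(g[keep, , drop = FALSE], last[keep]))
}

box_grid_points <- function(center, halfwidth, step) {
  n <- length(center)
  axes <- lapply(center[-n], function(x)
    seq(max(x - halfwidth, step / 10), min(x + halfwidth, 1 - step / 10),
        by = step))
  g <- as.matrix(do.call(expand.grid, axes))
  last <- 1 - rowSums(g)
  keep <- last > 0
  unname(cbind(g[keep, , drop = FALSE], last[keep]))
}

# dev_rows: function(W) -> max deviation per row of candidate matrix W.
# Refines around several coarse candidates so a rugged objective cannot trap
# the search in one basin.
grid_minimax_oracle <- function(dev_rows, n, coarse = 0.01, final = 0.001,
                                n_candidates = 15L) {
  W <- simplex_grid_points(n, coarse)
  v <- dev_rows(W)
  seeds <- W[order(v)[seq_len(min(n_candidates, nrow(W)))], , drop = FALSE]
  best <- NULL
  best_val <- Inf
  for (s in seq_len(nrow(seeds))) {
    center <- seeds[s, ]
    step <- coarse
    val <- dev_rows(matrix(center, 1))
    while (step > final) {
      prev <- step
      step <- max(step / 5, final)
      Wb <- box_grid_points(center, 2.5 * prev, step)
      vb <- dev_rows(Wb)
      center <- Wb[which.min(vb), ]
      val <- min(vb)
    }
    if (val < best_val) {
      best_val <- val
      best <- center
    }
  }
  list(weights = best, value = best_val)
}

row_max <- function(m) Reduce(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

bwm_dev_rows <- function(b, w, a_b, a_w) {
  function(W) {
    n <- ncol(W)
    d1 <- abs(W[, b] / W - matrix(a_b, nrow(W), n, byrow = TRUE))
    d2 <- abs(W / W[, w] - matrix(a_w, nrow(W), n, byrow = TRUE))
    pmax(row_max(d1), row_max(d2))
  }
}

fucom_dev_rows <- function(phi) {
  function(W) {
    n <- ncol(W)
    d <- abs(W[, -n, drop = FALSE] / W[, -1, drop = FALSE] -
               matrix(phi, nrow(W), n - 1, byrow = TRUE))
    dev <- row_max(d)
    if (n > 2) {
      k <- seq_len(n - 2)
      d2 <- abs(W[, k, drop = FALSE] / W[, k + 2, drop = FALSE] -
                  matrix(phi[k] * phi[k + 1], nrow(W), n - 2, byrow = TRUE))
      dev <- pmax(dev, row_max(d2))
    }
    dev
  }
}
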