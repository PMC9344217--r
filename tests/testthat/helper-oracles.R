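# Independent oracles and small fixture builders shared across tests.

# Exhaustive dynamic-programming oracle for the minimum-cost seam: same cost
# function as the A* search (sum of node costs + lambda * |row jump|), solved
# column by column over the full state space.
dp_min_cost <- function(cost, lambda, max_jump) {
  H <- nrow(cost); W <- ncol(cost)
  prev <- cost[, 1]
  for (cl in seq_len(W)[-1]) {
    cur <- rep(Inf, H)
    for (dr in -max_jump:max_jump) {
      src <- seq_len(H) - dr
      ok <- src >= 1 & src <= H
      cand <- rep(Inf, H)
      cand[ok] <- prev[src[ok]] + lambda * abs(dr)
      cur <- pmin(cur, cand)
    }
    prev <- cur + cost[, cl]
  }
  min(prev)
}

# Closed-form ordinary-least-squares quadratic oracle (normal equations).
quad_ls_oracle <- function(x, y) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[3]
}

# Two-band piecewise-constant test image: bright band rows r1..r2.
two_band_image <- function(H = 90, W = 48, r1 = 30, r2 = 59,
                           low = 20, high = 200, below = 35) {
  img <- matrix(low, H, W)
  img[r1:r2, ] <- high
  if (r2 < H) img[(r2 + 1):H, ] <- below
  img
}

# A small synthetic ILM/RPE surface pair (no rendering) for morphometry tests.
flat_surfaces <- function(n_slices = 128, width = 512, ilm = 300, rpe = 410) {
  list(ilm = matrix(ilm, n_slices, width), rpe = matrix(rpe, n_slices, width))
}

# Cached noiseless default scene + center B-scan (built once per test run).
default_clean_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- scene_truth(noise_sigma = 0, seed = 1)
      cache <<- list(scene = sc, bscan = render_bscan(sc, 64))
    }
    cache
  }
})
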