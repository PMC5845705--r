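# Independent oracles used across tests.

# Exhaustive min-cost matching with per-item unassignment cost: enumerates
# every injective partial matching.
brute_force_assignment_cost <- function(cost_matrix, cna) {
  n <- nrow(cost_matrix); m <- ncol(cost_matrix)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- min(best, acc + cna * (m - sum(used)))
      return()
    }
    rec(i + 1, used, acc + cna)
    for (j in which(!used)) {
      u <- used; u[j] <- TRUE
      rec(i + 1, u, acc + cost_matrix[i, j])
    }
  }
  rec(1, logical(m), 0)
  best
}

# O(n^2) topographic prominence: for each strict local maximum walk out in
# both directions until higher terrain, tracking the minima.
oracle_peak_prominences <- function(x) {
  n <- length(x)
  out <- NULL
  if (n < 3) return(out)
  for (p in 2:(n - 1)) {
    if (x[p] > x[p - 1] && x[p] > x[p + 1]) {
      h <- x[p]
      lmin <- h; i <- p
      while (i > 1) {
        i <- i - 1
        if (x[i] > h) break
        lmin <- min(lmin, x[i])
      }
      rmin <- h; i <- p
      while (i < n) {
        i <- i + 1
        if (x[i] > h) break
        rmin <- min(rmin, x[i])
      }
      out <- rbind(out, data.frame(index = p, prominence = h - max(lmin, rmin)))
    }
  }
  out
}

# Exhaustive two-tailed signed-rank p-value over all 2^n sign patterns.
oracle_signed_rank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# tiny two-blob reference image for segmentation tests
make_blob_image <- function(centers, sigma = 3, size = 80, noise_sd = 0.01,
                            seed = 7) {
  set.seed(seed)
  img <- matrix(0, size, size)
  rr <- matrix(0:(size - 1), size, size)
  cc <- t(rr)
  for (k in seq_len(nrow(centers))) {
    img <- img + exp(-((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2) /
                       (2 * sigma^2))
  }
  minmax_scale(img + matrix(rnorm(size^2, 0, noise_sd), size, size))
}
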