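# Independent brute-force oracles used across test files. These stay
# deliberately naive (loops, enumeration, grid search) and never call the
# package functions they check.

# Triple-loop topological overlap.
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + A[i, u] * A[u, j]
      }
      out[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# Sort / step-up / cummin Benjamini-Hochberg.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Hypergeometric enumeration of the one-sided over-representation tail.
fisher_oracle <- function(overlap, set_size, bg_size, module_size) {
  xs <- overlap:min(set_size, module_size)
  sum(vapply(xs, function(x) {
    choose(set_size, x) * choose(bg_size - set_size, module_size - x) /
      choose(bg_size, module_size)
  }, numeric(1)))
}

# NB log-likelihood on the log2-coefficient scale (as reported by
# fit_nb_glm), maximized by a two-stage grid search for a two-group
# intercept + indicator design with unit size factors.
nb_ll <- function(y, group, b0, b1, alpha) {
  mu <- 2^(b0 + b1 * group)
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}
nb_grid_oracle <- function(y, group, alpha) {
  best <- c(b0 = log2(mean(y[group == 0])),
            b1 = log2(mean(y[group == 1]) / mean(y[group == 0])))
  width <- 1
  for (step in c(0.01, 0.0005)) {
    b0s <- seq(best["b0"] - width, best["b0"] + width, by = step)
    b1s <- seq(best["b1"] - width, best["b1"] + width, by = step)
    ll <- outer(b0s, b1s, Vectorize(function(a, b) nb_ll(y, group, a, b,
                                                         alpha)))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0 = b0s[idx[1]], b1 = b1s[idx[2]])
    width <- 5 * step
  }
  nb_ll(y, group, best["b0"], best["b1"], alpha)
}

# Naive O(n^3) agglomerative average-linkage merge heights.
avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  active <- seq_len(n)
  dist_cl <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        dd <- dist_cl(active[i], active[j])
        if (dd < bd) { bd <- dd; best <- c(active[i], active[j]) }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active <- setdiff(active, best[2])
  }
  heights
}

# Small simulation shortcut: one-tissue design with structure knobs off
# unless asked for.
flat_sim <- function(n_genes, seed, ...) {
  args <- list(n_genes = n_genes, tissues = "B", tissue_effect_sd = 0,
               batch_effect_sd = 0, pi_de = 0,
               library_size_range = c(1, 1), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  simulate_counts(do.call(sim_config, args))
}

# Drop every attribute except dim (for matrix value comparisons).
strip_attrs <- function(m) {
  out <- as.vector(m)
  dim(out) <- dim(m)
  out
}
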