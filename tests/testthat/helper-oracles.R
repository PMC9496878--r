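# Independent brute-force oracles. These deliberately share no code with the
# package internals they are used to check.

# two-pass Pearson correlation of two vectors
naive_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# quadruple-loop nodal temporal correlation on a list of adjacency matrices
naive_temporal_correlation <- function(layers,
                                       isolated = "zero",
                                       denominator = "geometric") {
  n <- nrow(layers[[1]])
  w <- length(layers)
  out <- numeric(n)
  for (i in seq_len(n)) {
    total <- 0
    used <- 0
    for (t in seq_len(w - 1)) {
      num <- 0
      ki <- 0
      ki1 <- 0
      for (j in seq_len(n)) {
        num <- num + layers[[t]][i, j] * layers[[t + 1]][i, j]
        ki <- ki + layers[[t]][i, j]
        ki1 <- ki1 + layers[[t + 1]][i, j]
      }
      den <- if (denominator == "geometric") sqrt(ki * ki1) else ki * ki1
      if (den > 0) {
        total <- total + num / den
        used <- used + 1
      }
    }
    div <- if (isolated == "zero") w - 1 else used
    out[i] <- if (div > 0) total / div else 0
  }
  out
}

# random symmetric hollow binary adjacency stack
random_layers <- function(n, w, p = 0.3) {
  lapply(seq_len(w), function(t) {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- rbinom(length(up), 1, p)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    a
  })
}

# partial F of the group coefficient by explicit normal equations:
# full and reduced residual sums of squares via solve(t(X) X) = t(X) y
ols_partial_f <- function(y, x_group, covars) {
  xf <- cbind(1, x_group, covars)
  xr <- cbind(1, covars)
  rss <- function(x) {
    beta <- solve(t(x) %*% x, t(x) %*% y)
    sum((y - x %*% beta)^2)
  }
  rss_f <- rss(xf)
  rss_r <- rss(xr)
  df2 <- length(y) - ncol(xf)
  ((rss_r - rss_f) / 1) / (rss_f / df2)
}

# proportional-odds log-likelihood for response levels 0..(k-1)
polr_loglik <- function(y, x, zeta, beta) {
  k <- length(zeta) + 1
  eta <- x * beta
  ll <- 0
  for (i in seq_along(y)) {
    upper <- if (y[i] == k - 1) 1 else plogis(zeta[y[i] + 1] - eta[i])
    lower <- if (y[i] == 0) 0 else plogis(zeta[y[i]] - eta[i])
    ll <- ll + log(max(upper - lower, 1e-300))
  }
  ll
}

# brute-force ML slope: grid over beta, cutpoints profiled by Nelder-Mead
polr_grid_slope <- function(y, x, beta_grid) {
  k <- length(unique(y))
  prof <- vapply(beta_grid, function(b) {
    start <- qlogis(cumsum(prop.table(table(factor(y, levels = 0:(k - 1)))))
                    [seq_len(k - 1)])
    fit <- optim(start, function(z) {
      if (is.unsorted(z)) return(1e10)
      -polr_loglik(y, x, z, b)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    -fit$value
  }, numeric(1))
  beta_grid[which.max(prof)]
}

# deterministic periodic subject whose windowed correlations are identical
# in every window (period divides the window step)
periodic_subject <- function(n_nodes = 5, n_rep = 8, period = 3) {
  base <- matrix(rnorm(n_nodes * period), n_nodes, period)
  data <- base[, rep(seq_len(period), n_rep)]
  subject_time_series(data, "periodic", tr_seconds = 1)
}

# tiny deterministic dynamic network from explicit edge lists (1-based pairs)
layers_from_edges <- function(n, edge_lists) {
  lapply(edge_lists, function(edges) {
    a <- matrix(0L, n, n)
    for (e in edges) {
      a[e[1], e[2]] <- 1L
      a[e[2], e[1]] <- 1L
    }
    a
  })
}
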