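# Independent oracles, deliberately coded without reference to the package
# implementations they check.

## Brute-force re-statement of the recursive outlier removal: work on an
## explicit multiset, remove extremes, test each against the remaining
## distribution, recurse.
oracle_trim <- function(values) {
  xs <- values[is.finite(values)]
  if (length(xs) < 3) return(sort(xs))
  step <- function(xs) {
    xs <- sort(xs)
    low <- xs[1]
    high <- xs[length(xs)]
    remaining <- xs[-c(1, length(xs))]
    mu <- sum(remaining) / length(remaining)
    if (length(remaining) >= 2) {
      sdv <- sqrt(sum((remaining - mu)^2) / (length(remaining) - 1))
    } else {
      sdv <- Inf
    }
    keep_low <- abs(low - mu) <= 3 * sdv
    keep_high <- abs(high - mu) <= 3 * sdv
    result <- remaining
    if (keep_low) result <- c(result, low)
    if (keep_high) result <- c(result, high)
    if (keep_low && keep_high) return(sort(result))
    if (length(result) < 3) return(sort(result))
    step(result)
  }
  step(xs)
}

## Dense-matrix equilibrium solver for the two-pass graph activation:
## explicit transition matrices and plain power iteration, no closed forms,
## no Kronecker factorization.
oracle_activation <- function(m, sigma = 0.15 * ncol(m), tol = 1e-12) {
  ny <- nrow(m); nx <- ncol(m); n <- nx * ny
  xs <- rep(0:(nx - 1), each = ny)
  ys <- rep(0:(ny - 1), times = nx)
  fall <- exp(-(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2) / (2 * sigma^2))
  v <- as.vector(m)
  if (max(v) - min(v) <= 1e-12 * max(1, abs(mean(v)))) return(matrix(1 / n, ny, nx))
  stationary <- function(W) {
    P <- sweep(W, 2, colSums(W), "/")
    # lazy chain: same stationary distribution, aperiodic even when the
    # dissimilarity graph is bipartite (two-valued maps)
    p <- rep(1 / n, n)
    for (i in 1:50000) {
      p2 <- 0.5 * p + 0.5 * as.vector(P %*% p)
      p2 <- p2 / sum(p2)
      if (max(abs(p2 - p)) < tol) return(p2)
      p <- p2
    }
    p
  }
  A <- stationary(abs(outer(v, v, "-")) * fall)
  # concentration pass: weight into node i proportional to A(i) * falloff
  conc <- stationary(A * fall)
  matrix(conc, ny, nx)
}

## Multi-resolution grid search maximizing the probit log-likelihood.
oracle_probit_grid <- function(y, X, span = 3, rounds = 14, pts = 11) {
  k <- ncol(X) + 1
  centre <- rep(0, k)
  width <- span
  ll <- function(beta) {
    eta <- beta[1] + X %*% beta[-1]
    p <- pnorm(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  for (r in 1:rounds) {
    for (j in 1:k) {
      grid <- centre[j] + seq(-width, width, length.out = pts)
      vals <- sapply(grid, function(g) {
        b <- centre; b[j] <- g; ll(b)
      })
      centre[j] <- grid[which.max(vals)]
    }
    width <- width * 0.45
  }
  centre
}

## ICC(2,1) via stats::aov mean squares (Shrout & Fleiss).
oracle_icc_anova <- function(x) {
  d <- data.frame(y = as.vector(x),
                  target = factor(rep(seq_len(nrow(x)), ncol(x))),
                  rater = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(x); k <- ncol(x)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

## direct discrete convolution with an edge-renormalized Gaussian kernel
oracle_temporal_profile <- function(series, sd) {
  n <- length(series)
  r <- ceiling(4 * sd)
  w <- dnorm(-r:r, sd = sd)
  w <- w / sum(w)
  sapply(seq_len(n), function(t) {
    ks <- max(1, t - r):min(n, t + r)
    wk <- w[ks - t + r + 1]
    sum(series[ks] * wk) / sum(wk)
  })
}

## exhaustive enumeration oracle, written independently of the implementation
oracle_reclassify <- function(ratings) {
  best <- NULL
  for (t1 in 1:7) for (t2 in (t1 + 1):8) {
    sizes <- c(sum(ratings <= t1), sum(ratings > t1 & ratings <= t2),
               sum(ratings > t2))
    obj <- sum(abs(outer(sizes, sizes, "-"))) / 2
    prior <- abs(t1 - 3) + abs(t2 - 6)
    cand <- c(obj, prior, t1, t2)
    if (is.null(best) ||
        cand[1] < best[1] ||
        (cand[1] == best[1] && cand[2] < best[2]) ||
        (cand[1] == best[1] && cand[2] == best[2] &&
           (cand[3] < best[3] || (cand[3] == best[3] && cand[4] < best[4]))))
      best <- cand
  }
  best
}

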