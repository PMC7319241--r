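# Independent oracles used to cross-check the package implementations, plus
# shared fixtures. Each oracle is written from first principles, not by
# calling the code path it checks.

# --- dense-grid root oracle for g(Y) = a - b Y + r f(Y) -----------------------
# sign scan on a fine grid with manual bisection; independent of equilibria()
oracle_roots <- function(a, p, b = 1, r = 1, h = 1, grid_n = 1e5, tol = 1e-12) {
  g <- function(y) {
    f <- if (p == 0) 0.5 else {
      z <- (y / h)^p
      ifelse(is.infinite(z), 1, z / (z + 1))
    }
    if (p > 0) f[y == 0] <- 0
    a - b * y + r * f
  }
  upper <- (a + r) / b + 1
  ys <- seq(0, upper, length.out = grid_n)
  gv <- g(ys)
  roots <- ys[abs(gv) < 1e-13]
  for (i in which(gv[-grid_n] * gv[-1] < 0)) {
    lo <- ys[i]; hi <- ys[i + 1]
    glo <- gv[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (gm == 0) { lo <- hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  roots
}

oracle_stable <- function(roots, a, p, b = 1, r = 1, h = 1, eps = 1e-6) {
  g <- function(y) {
    f <- if (p == 0) 0.5 else {
      z <- (pmax(y, 0) / h)^p
      ifelse(is.infinite(z), 1, z / (z + 1))
    }
    a - b * y + r * f
  }
  vapply(roots, function(y) g(y + eps) - g(max(y - eps, 0)) < 0, logical(1))
}

# --- exhaustive warping-path DTW oracle --------------------------------------
# enumerates every monotone warping path from (1, 1) to (n, m) and returns the
# minimum summed |x_i - y_j| cost; feasible for short series only
oracle_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return(invisible())  # prune: costs only grow
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# --- closed-form Bernoulli deviance oracle -----------------------------------
oracle_lrt_deviance <- function(successes, totals) {
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  ll <- function(k, n) xlx(k) + xlx(n - k) - xlx(n)
  2 * (sum(ll(successes, totals)) - ll(sum(successes), sum(totals)))
}

# --- textbook sums-of-squares one-way ANOVA oracle ---------------------------
oracle_anova_F <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  n_g <- tapply(y, g, length)
  ss_between <- sum(n_g * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_b <- nlevels(g) - 1
  df_w <- length(y) - nlevels(g)
  (ss_between / df_b) / (ss_within / df_w)
}

# --- shared fixtures ---------------------------------------------------------
# small experiment used by module tests (2 replicates keeps them fast)
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_experiment(microcosm_config(n_replicates = 2), seed = 7)
    cache
  }
})

# the acceptance suite re-uses one set of default experiments across blocks
acceptance_seeds <- 1:20
acceptance_experiments <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(acceptance_seeds, function(s)
        generate_experiment(microcosm_config(), seed = s))
    cache
  }
})

# fast/slow feedback-strength sweeps shared by the acceptance blocks
acceptance_sweeps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p_grid <- seq(0, 10, by = 0.5)
      cache <<- list(
        fast = run_sweep(p_grid = p_grid, step_grid = 200),
        slow = run_sweep(p_grid = p_grid, step_grid = 20000)
      )
    }
    cache
  }
})
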