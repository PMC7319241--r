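# Minimal ecosystem model: dY/dt = a - b*Y + r*f(Y), f(Y) = Y^p / (Y^p + h^p).
# The driver a is ramped linearly up and down (or down and up); p is the
# feedback-strength exponent whose value controls whether alternative stable
# states exist.

#' Parameters of the minimal ecosystem model
#'
#' Bundles the four parameters of the minimal ecosystem model
#' \eqn{dY/dt = a - bY + r f(Y)} with sigmoidal self-replacement
#' \eqn{f(Y) = Y^p / (Y^p + h^p)}: the decay rate `b`, the self-replacement
#' rate `r`, the shift threshold `h` and the feedback-strength exponent `p`.
#' The conventional reference case sets `b = r = h = 1` and varies `p`.
#'
#' @param p Feedback-strength exponent (dimensionless, `p >= 0`).
#' @param b Decay rate of the state `Y` (per unit time, `b > 0`).
#' @param r Self-replacement rate (per unit time, nonnegative).
#' @param h Threshold state value at which the self-replacement function is
#'   half-saturated (`h > 0`).
#'
#' @return An object of class `minimal_model_params`.
#' @examples
#' minimal_model_params(p = 8)
#' @export
minimal_model_params <- function(p, b = 1, r = 1, h = 1) {
  stopifnot(is.numeric(p), length(p) == 1, is.finite(p),
            is.numeric(b), length(b) == 1, is.finite(b),
            is.numeric(r), length(r) == 1, is.finite(r),
            is.numeric(h), length(h) == 1, is.finite(h))
  if (p < 0) stop("`p` must be >= 0")
  if (b <= 0) stop("`b` must be > 0")
  if (r < 0) stop("`r` must be >= 0")
  if (h <= 0) stop("`h` must be > 0")
  structure(list(p = p, b = b, r = r, h = h), class = "minimal_model_params")
}

#' @export
print.minimal_model_params <- function(x, ...) {
  cat(sprintf("Minimal ecosystem model: p = %g, b = %g, r = %g, h = %g\n",
              x$p, x$b, x$r, x$h))
  invisible(x)
}

#' Triangular driver ramp
#'
#' Describes a piecewise-linear up-and-down (or down-and-up) sweep of the
#' environmental driver `a`: starting from one extreme, `a` reaches the far
#' extreme at `total_steps / 2` and returns to the start at `total_steps`.
#' A short ramp (e.g. 200 steps) is a fast rate of environmental change
#' relative to the ecosystem's relaxation time; a long ramp (e.g. 20000
#' steps) is a slow, quasi-static change.
#'
#' @param total_steps Even integer number of unit timesteps for the full
#'   sweep (`>= 2`).
#' @param direction `"up_first"` (default) starts at `a_low`; `"down_first"`
#'   starts at `a_high`.
#' @param a_low,a_high Driver extremes, `a_low < a_high`.
#'
#' @return An object of class `driver_ramp`.
#' @examples
#' driver_ramp(200)
#' driver_at(driver_ramp(200), c(0, 50, 100, 150, 200))
#' @export
driver_ramp <- function(total_steps, direction = c("up_first", "down_first"),
                        a_low = 0, a_high = 1) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(total_steps), length(total_steps) == 1,
            is.numeric(a_low), is.numeric(a_high))
  total_steps <- as.integer(total_steps)
  if (total_steps < 2 || total_steps %% 2 != 0)
    stop("`total_steps` must be an even integer >= 2")
  if (!(a_low < a_high)) stop("`a_low` must be < `a_high`")
  structure(list(total_steps = total_steps, direction = direction,
                 a_low = a_low, a_high = a_high),
            class = "driver_ramp")
}

#' @export
print.driver_ramp <- function(x, ...) {
  cat(sprintf("Driver ramp: %s, a in [%g, %g], %d timesteps\n",
              x$direction, x$a_low, x$a_high, x$total_steps))
  invisible(x)
}

#' Driver value along a ramp
#'
#' @param ramp A [driver_ramp()].
#' @param t Time(s) in `[0, total_steps]`.
#' @return Numeric vector of driver values.
#' @export
driver_at <- function(ramp, t) {
  stopifnot(inherits(ramp, "driver_ramp"))
  if (any(t < 0 | t > ramp$total_steps))
    stop("`t` must lie in [0, total_steps]")
  tri <- 1 - abs(1 - 2 * t / ramp$total_steps)
  tri <- pmin(pmax(tri, 0), 1)
  if (ramp$direction == "up_first") ramp$a_low + (ramp$a_high - ramp$a_low) * tri
  else ramp$a_high - (ramp$a_high - ramp$a_low) * tri
}

#' Sigmoidal self-replacement function
#'
#' Evaluates \eqn{f(Y) = Y^p / (Y^p + h^p)}, the saturating positive feedback
#' of the minimal ecosystem model, computed on the \eqn{(Y/h)^p} ratio scale
#' for numerical stability at large `p`. For `p = 0` the function is defined
#' as the constant 1/2 (the continuous limit for `Y > 0`).
#'
#' @param Y State value(s), `Y >= 0`.
#' @param p Feedback exponent, `p >= 0`.
#' @param h Threshold, `h > 0`.
#' @return Value(s) in `[0, 1]`.
#' @examples
#' self_replacement(1, p = 3)      # 0.5 at Y = h
#' self_replacement(2, p = 10)     # 1024/1025
#' @export
self_replacement <- function(Y, p, h = 1) {
  stopifnot(is.numeric(Y), is.numeric(p), length(p) == 1,
            is.numeric(h), length(h) == 1)
  if (any(!is.finite(Y)) || any(Y < 0)) stop("`Y` must be finite and >= 0")
  if (h <= 0) stop("`h` must be > 0")
  if (p < 0) stop("`p` must be >= 0")
  if (p == 0) return(rep(0.5, length(Y)))
  z <- (Y / h)^p
  out <- ifelse(is.infinite(z), 1, z / (z + 1))
  out[Y == 0] <- 0
  out
}

#' Drift of the minimal ecosystem model
#'
#' Rate of change \eqn{dY/dt = a - bY + r f(Y)} at state `Y` under driver `a`.
#'
#' @param Y State value(s), `Y >= 0`.
#' @param a Driver value.
#' @param params A [minimal_model_params()].
#' @return Numeric drift value(s).
#' @examples
#' drift(1, a = 1, minimal_model_params(p = 4))  # 0.5
#' @export
drift <- function(Y, a, params) {
  stopifnot(inherits(params, "minimal_model_params"), is.numeric(a))
  a - params$b * Y + params$r * self_replacement(Y, params$p, params$h)
}

#' Simulate the minimal model under a ramped driver
#'
#' Integrates the model with a classical fixed-step fourth-order Runge-Kutta
#' scheme (`substeps` substeps per unit timestep, piecewise-linear driver)
#' and returns the state at every unit timestep together with the driver
#' value and a phase label (`"ascending"` for the first half of the sweep,
#' `"descending"` after).
#'
#' @param params A [minimal_model_params()].
#' @param ramp A [driver_ramp()].
#' @param Y0 Initial state, or `"auto"` (default) for the lowest stable
#'   equilibrium at the starting driver value, so the sweep starts on the
#'   branch that is stable where it begins.
#' @param substeps Integration substeps per unit timestep (default 10).
#' @return A `data.frame` of class `oef_trajectory` with columns `t`, `a`,
#'   `Y`, `phase`; the parameters and ramp are kept as attributes.
#' @examples
#' traj <- simulate_model(minimal_model_params(p = 8), driver_ramp(200))
#' head(traj)
#' @export
simulate_model <- function(params, ramp, Y0 = "auto", substeps = 10) {
  stopifnot(inherits(params, "minimal_model_params"),
            inherits(ramp, "driver_ramp"))
  substeps <- as.integer(substeps)
  if (substeps < 1) stop("`substeps` must be >= 1")
  a0 <- driver_at(ramp, 0)
  if (identical(Y0, "auto")) {
    eq <- equilibria(a0, params)
    stable <- eq$Y[eq$stable]
    if (length(stable) == 0) stop("no stable equilibrium at the starting driver value")
    y0 <- min(stable)
  } else {
    stopifnot(is.numeric(Y0), length(Y0) == 1, Y0 >= 0)
    y0 <- Y0
  }
  Y <- rk4_ramp(y0, params$b, params$r, params$h, params$p,
                ramp$a_low, ramp$a_high, ramp$total_steps, substeps,
                ramp$direction == "up_first")
  t <- 0:ramp$total_steps
  first_half <- t <= ramp$total_steps / 2
  phase <- if (ramp$direction == "up_first") {
    ifelse(first_half, "ascending", "descending")
  } else {
    ifelse(first_half, "descending", "ascending")
  }
  out <- data.frame(
    t = t,
    a = driver_at(ramp, t),
    Y = as.numeric(Y),
    phase = phase,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  attr(out, "ramp") <- ramp
  class(out) <- c("oef_trajectory", "data.frame")
  out
}

#' Equilibria of the minimal model at a fixed driver value
#'
#' Finds all roots of \eqn{g(Y) = a - bY + r f(Y)} on
#' \eqn{[0, (a + r)/b + 1]} by a dense sign scan refined with bisection, and
#' classifies each root's local stability from the sign of \eqn{g'(Y^*)}
#' (negative slope = stable).
#'
#' @param a Driver value, `a >= 0`.
#' @param params A [minimal_model_params()].
#' @param grid_n Number of scan points (default 10000).
#' @param tol Root tolerance on `|g|` (roots refined to machine-level
#'   bracketing; default residual check `1e-10`).
#' @return A `data.frame` of class `equilibrium_set` with columns `Y`
#'   (ascending) and `stable` (logical).
#' @examples
#' equilibria(0.5, minimal_model_params(p = 8))  # three roots, outer two stable
#' @export
equilibria <- function(a, params, grid_n = 10000, tol = 1e-10) {
  stopifnot(inherits(params, "minimal_model_params"),
            is.numeric(a), length(a) == 1, a >= 0)
  upper <- (a + params$r) / params$b + 1
  ys <- seq(0, upper, length.out = grid_n)
  g <- drift(ys, a, params)
  roots <- numeric(0)
  # exact zeros on the grid
  zero_idx <- which(abs(g) < tol)
  roots <- c(roots, ys[zero_idx])
  # sign changes between adjacent non-zero grid values
  sgn <- sign(g)
  for (i in which(sgn[-length(sgn)] * sgn[-1] < 0)) {
    root <- uniroot(function(y) drift(y, a, params),
                    lower = ys[i], upper = ys[i + 1],
                    tol = .Machine$double.eps^0.75)$root
    roots <- c(roots, root)
  }
  roots <- sort(roots)
  if (length(roots) > 1) {
    # de-duplicate roots found both as grid zeros and bracketed roots
    keep <- c(TRUE, diff(roots) > upper / grid_n * 1e-3)
    roots <- roots[keep]
  }
  if (length(roots) == 0) stop("no equilibrium found: root scan failed")
  if (any(abs(drift(roots, a, params)) > 1e-8))
    stop("root tolerance not reached")
  eps <- upper / grid_n / 10
  stable <- vapply(roots, function(y) {
    drift(y + eps, a, params) - drift(max(y - eps, 0), a, params) < 0
  }, logical(1))
  out <- data.frame(Y = roots, stable = stable)
  class(out) <- c("equilibrium_set", "data.frame")
  out
}

#' Number of stable equilibria at a driver value
#'
#' @inheritParams equilibria
#' @return Integer count of locally stable equilibria.
#' @export
n_stable_states <- function(a, params, grid_n = 10000) {
  sum(equilibria(a, params, grid_n = grid_n)$stable)
}

#' Driver interval with alternative stable states
#'
#' Computes the interval of driver values with more than one stable
#' equilibrium directly from the fold (saddle-node) bifurcations. At a fold
#' the equilibrium condition degenerates, which happens exactly where
#' \eqn{r f'(Y) = b} --- a condition independent of the driver --- and the
#' fold driver values follow as \eqn{a = bY - rf(Y)} at those critical
#' states. Locating the critical states by a dense scan of \eqn{rf'(Y) - b}
#' with bisection resolves the bistable interval even arbitrarily close to
#' the critical exponent, where its width shrinks below any practical
#' driver grid.
#'
#' @param params A [minimal_model_params()].
#' @param a_range Driver range of interest (default `c(0, 1)`).
#' @param scan_n Number of scan points for the critical-state search
#'   (default `1e5`).
#' @param tol Root tolerance for the critical states (default `1e-10`).
#' @return A numeric vector `c(a_fold_low, a_fold_high)` clipped to
#'   `a_range`, or an empty numeric vector when the model is monostable
#'   throughout `a_range`.
#' @examples
#' bistable_interval(minimal_model_params(p = 8))
#' bistable_interval(minimal_model_params(p = 2))  # empty: no feedback strong enough
#' @export
bistable_interval <- function(params, a_range = c(0, 1), scan_n = 1e5,
                              tol = 1e-10) {
  stopifnot(inherits(params, "minimal_model_params"),
            is.numeric(a_range), length(a_range) == 2, a_range[1] < a_range[2])
  p <- params$p; b <- params$b; r <- params$r; h <- params$h
  # for p <= 1 the self-replacement slope is monotone in Y, so the drift is
  # unimodal and at most one stable equilibrium exists
  if (p <= 1 || r == 0) return(numeric(0))
  fprime <- function(Y) {
    z <- (Y / h)^p
    p * z / Y / (z + 1)^2
  }
  slope_margin <- function(Y) r * fprime(Y) - b
  ys <- seq(h * 1e-8, 20 * h, length.out = scan_n)
  sm <- slope_margin(ys)
  idx <- which(sm[-scan_n] * sm[-1] < 0)
  if (length(idx) < 2) return(numeric(0))
  crit <- vapply(idx[c(1, length(idx))], function(i)
    uniroot(slope_margin, c(ys[i], ys[i + 1]), tol = tol)$root, numeric(1))
  a_folds <- sort(b * crit - r * self_replacement(crit, p, h))
  lo <- max(a_folds[1], a_range[1])
  hi <- min(a_folds[2], a_range[2])
  if (!(lo < hi)) return(numeric(0))
  c(lo, hi)
}

#' Tangency condition for the onset of bistability (b = r = h = 1)
#'
#' For `b = r = h = 1` the model first acquires alternative stable states at
#' the exponent where the maximal slope of the self-replacement function
#' reaches the decay rate: \eqn{\max_Y f'(Y) = 1}, attained at
#' \eqn{Y^p = (p-1)/(p+1)}. This function evaluates the margin
#' \eqn{\phi(p) = p ((p-1)/(p+1))^{(p-1)/p} ((p+1)/(2p))^2 - 1}, negative
#' below the critical exponent and positive above it.
#'
#' @param p Feedback exponent(s), `p > 1`.
#' @return Value(s) of the tangency margin.
#' @export
bistability_margin <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 1)) stop("the tangency margin is defined for p > 1")
  p * ((p - 1) / (p + 1))^((p - 1) / p) * ((p + 1) / (2 * p))^2 - 1
}

#' Critical feedback exponent for alternative stable states
#'
#' The smallest `p` at which the minimal model admits more than one stable
#' equilibrium. For the reference case `b = r = h = 1` (default) the value is
#' the root of the closed-form tangency margin [bistability_margin()] on
#' (1, 10); it lies between 3 and 4, consistent with alternative stable
#' states appearing only for feedback exponents above about 4 on an integer
#' scan. For other parameter values the transition is located numerically by
#' bisection on the emptiness of [bistable_interval()].
#'
#' @param b,r,h Model parameters (defaults 1).
#' @param a_range Driver range considered when solving numerically.
#' @param tol Tolerance on `p` (default `1e-9` closed form, `1e-4` numeric).
#' @return The critical exponent `p_crit`.
#' @examples
#' critical_p()  # about 3.72
#' @export
critical_p <- function(b = 1, r = 1, h = 1, a_range = c(0, 1), tol = NULL) {
  if (b == 1 && r == 1 && h == 1) {
    if (is.null(tol)) tol <- 1e-9
    uniroot(bistability_margin, c(1 + 1e-6, 10), tol = tol)$root
  } else {
    if (is.null(tol)) tol <- 1e-4
    lo <- 1; hi <- 10
    bistable_at <- function(p) {
      length(bistable_interval(minimal_model_params(p, b, r, h),
                               a_range = a_range)) > 0
    }
    if (!bistable_at(hi)) stop("no bistability found for p up to 10")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (bistable_at(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
}
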