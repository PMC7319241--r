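# Ecosystem-response statistics: absolute nonlinearity of state-vs-driver
# relationships (RMS difference between a penalized-spline and a straight-line
# fit) and hysteresis (mean absolute up-down difference at matched driver
# levels).

#' Driver-response path
#'
#' A labelled state-versus-driver path: driver values `E` (a model driver or
#' a temperature), state values `Y`, and a per-point phase label marking
#' whether the driver was on its ascending or descending leg. Both response
#' statistics consume this object.
#'
#' @param E Driver values.
#' @param Y State values (same length as `E`).
#' @param phase Character vector of `"ascending"` / `"descending"` labels.
#' @param id Optional replicate label (default `"path"`).
#' @return A `data.frame` of class `response_path`.
#' @export
response_path <- function(E, Y, phase, id = "path") {
  stopifnot(is.numeric(E), is.numeric(Y), length(E) == length(Y),
            length(phase) == length(E))
  phase <- as.character(phase)
  if (!all(phase %in% c("ascending", "descending")))
    stop("`phase` must be 'ascending' or 'descending'")
  if (any(!is.finite(E)) || any(!is.finite(Y)))
    stop("`E` and `Y` must be finite")
  for (ph in unique(phase)) {
    if (sum(phase == ph) < 4)
      stop("each phase needs at least 4 points for the line + smoother fits")
  }
  out <- data.frame(E = E, Y = Y, phase = phase, stringsAsFactors = FALSE)
  attr(out, "id") <- id
  class(out) <- c("response_path", "data.frame")
  out
}

#' Convert a simulated trajectory to a response path
#'
#' @param traj An `oef_trajectory` from [simulate_model()].
#' @param id Replicate label.
#' @return A [response_path()] with `E = a`.
#' @export
as_response_path <- function(traj, id = "trajectory") {
  stopifnot(inherits(traj, "oef_trajectory"))
  response_path(traj$a, traj$Y, traj$phase, id = id)
}

#' Straight-line fit
#'
#' Ordinary least-squares line of `Y` on `E`, returning the fitted values at
#' the observed `E`.
#'
#' @param E Driver values (at least 2 distinct).
#' @param Y State values.
#' @return Numeric vector of fitted values.
#' @export
fit_line <- function(E, Y) {
  stopifnot(is.numeric(E), is.numeric(Y), length(E) == length(Y))
  if (length(unique(E)) < 2)
    stop("degenerate design: all `E` values identical")
  as.numeric(fitted(lm(Y ~ E)))
}

#' Penalized-spline fit
#'
#' Penalized cubic regression-spline fit of `Y` on `E` with automatic
#' smoothness selection by generalized cross-validation (the default smoother
#' of [mgcv::gam()]). The penalty null space contains all straight lines, so
#' noise-free linear data reproduce the least-squares line. When fewer
#' distinct `E` values than `basis_dim` are available the basis dimension
#' falls back accordingly; with fewer than 4 distinct values the straight
#' line is returned.
#'
#' @param E Driver values.
#' @param Y State values.
#' @param basis_dim Spline basis dimension (default 10).
#' @return Numeric vector of fitted values at the observed `E`.
#' @export
fit_smooth <- function(E, Y, basis_dim = 10) {
  stopifnot(is.numeric(E), is.numeric(Y), length(E) == length(Y))
  n_distinct <- length(unique(E))
  if (n_distinct < 2) stop("degenerate design: all `E` values identical")
  k <- min(basis_dim, n_distinct - 1)
  if (k < 4) return(fit_line(E, Y))
  dat <- data.frame(E = E, Y = Y)
  fit <- mgcv::gam(Y ~ s(E, k = k, bs = "cr"), data = dat, method = "GCV.Cp")
  as.numeric(fitted(fit))
}

#' Absolute nonlinearity of a state-driver relationship
#'
#' Root-mean-square difference between the penalized-spline and straight-line
#' fitted values over the observed driver values. The response is not
#' standardized, so the statistic is in state units (absolute, not relative,
#' nonlinearity); it is invariant to adding a constant to `Y` and scales
#' linearly with `Y`.
#'
#' @inheritParams fit_smooth
#' @return A nonnegative scalar.
#' @examples
#' E <- seq(0, 1, 0.05)
#' nonlinearity(E, 2 * E + 1)  # 0: an exact line has no nonlinearity
#' nonlinearity(E, E^2) > 0
#' @export
nonlinearity <- function(E, Y, basis_dim = 10) {
  sqrt(mean((fit_smooth(E, Y, basis_dim) - fit_line(E, Y))^2))
}

#' Pair ascending and descending observations at matched driver levels
#'
#' Builds the up/down pairs that the hysteresis statistic averages over.
#' Driver levels observed repeatedly within a phase are averaged first;
#' levels equal to the path's turning extreme (the far end of the sweep,
#' e.g. the temperature plateau) are excluded; remaining levels present in
#' both phases are matched exactly. If no exact matches exist (asymmetric
#' grids), the descending path is linearly interpolated onto the ascending
#' driver values interior to its range.
#'
#' @param path A [response_path()].
#' @param match_tol Relative tolerance for treating two driver levels as
#'   equal (default `1e-8` of the driver range).
#' @return A `data.frame` with columns `E`, `Y_up`, `Y_down`.
#' @export
pair_updown <- function(path, match_tol = 1e-8) {
  stopifnot(inherits(path, "response_path"))
  up <- path[path$phase == "ascending", ]
  dn <- path[path$phase == "descending", ]
  if (nrow(up) == 0 || nrow(dn) == 0)
    stop("both phases must be present to pair up and down observations")
  rng <- diff(range(path$E))
  if (rng == 0) stop("driver is constant: nothing to pair")
  key <- function(E) round(E / (rng * match_tol)) * (rng * match_tol)
  up_agg <- aggregate(Y ~ key, data.frame(key = key(up$E), Y = up$Y), mean)
  dn_agg <- aggregate(Y ~ key, data.frame(key = key(dn$E), Y = dn$Y), mean)
  # the turning extreme (driver value where the sweep reverses) is excluded
  first_phase <- path$phase[1]
  turn_idx <- which(path$phase != first_phase)[1]
  extreme <- if (is.na(turn_idx)) stop("both phases must be present")
             else path$E[turn_idx - 1]
  drop <- abs(up_agg$key - extreme) <= rng * match_tol
  up_agg <- up_agg[!drop, , drop = FALSE]
  dn_agg <- dn_agg[!(abs(dn_agg$key - extreme) <= rng * match_tol), , drop = FALSE]
  m <- merge(up_agg, dn_agg, by = "key", suffixes = c("_up", "_down"))
  if (nrow(m) == 0) {
    # asymmetric grids: interpolate the descending path onto ascending levels
    ord <- order(dn_agg$key)
    inside <- up_agg$key >= min(dn_agg$key) & up_agg$key <= max(dn_agg$key)
    if (!any(inside)) stop("no driver levels could be paired, even by interpolation")
    yi <- approx(dn_agg$key[ord], dn_agg$Y[ord], xout = up_agg$key[inside])$y
    m <- data.frame(key = up_agg$key[inside], Y_up = up_agg$Y[inside], Y_down = yi)
  }
  data.frame(E = m$key, Y_up = m$Y_up, Y_down = m$Y_down)
}

#' Hysteresis of a driver-response path
#'
#' Mean absolute difference between the ascending-phase and descending-phase
#' state values paired at equal driver levels (see [pair_updown()]). Zero
#' when the state is a function of the driver alone; positive when the path
#' depends on the direction of environmental change.
#'
#' @inheritParams pair_updown
#' @return A nonnegative scalar in state units.
#' @export
hysteresis <- function(path, match_tol = 1e-8) {
  pairs <- pair_updown(path, match_tol)
  mean(abs(pairs$Y_up - pairs$Y_down))
}

#' Both response metrics for one path
#'
#' Computes phase-wise absolute nonlinearity, hysteresis and the number of
#' matched driver levels for a driver-response path.
#'
#' @inheritParams pair_updown
#' @param basis_dim Spline basis dimension passed to [nonlinearity()].
#' @return A one-row `data.frame`: `id`, `nonlinearity_up`,
#'   `nonlinearity_down`, `hysteresis`, `n_pairs`.
#' @examples
#' traj <- simulate_model(minimal_model_params(p = 8), driver_ramp(200))
#' response_metrics(as_response_path(traj))
#' @export
response_metrics <- function(path, basis_dim = 10, match_tol = 1e-8) {
  stopifnot(inherits(path, "response_path"))
  up <- path[path$phase == "ascending", ]
  dn <- path[path$phase == "descending", ]
  pairs <- pair_updown(path, match_tol)
  data.frame(
    id = attr(path, "id") %||% "path",
    nonlinearity_up = nonlinearity(up$E, up$Y, basis_dim),
    nonlinearity_down = nonlinearity(dn$E, dn$Y, basis_dim),
    hysteresis = mean(abs(pairs$Y_up - pairs$Y_down)),
    n_pairs = nrow(pairs),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
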