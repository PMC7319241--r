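# The feedback-strength x ramp-rate x direction sweep of the minimal model:
# for every combination, simulate the forced system, measure nonlinearity and
# hysteresis, and record whether alternative stable states exist in the swept
# driver range.

#' Classify the minimal model as monostable or bistable
#'
#' A parameterization is "bistable" when more than one stable equilibrium
#' exists for some driver value in the swept range (see
#' [bistable_interval()]).
#'
#' @param p Feedback exponent.
#' @param b,r,h Remaining model parameters (defaults 1).
#' @param a_range Driver range (default `c(0, 1)`).
#' @return `"monostable"` or `"bistable"`.
#' @examples
#' classify_regime(2)   # monostable
#' classify_regime(8)   # bistable
#' @export
classify_regime <- function(p, b = 1, r = 1, h = 1, a_range = c(0, 1)) {
  params <- minimal_model_params(p, b, r, h)
  if (length(bistable_interval(params, a_range)) > 0) "bistable" else "monostable"
}

#' Feedback-strength and ramp-rate sweep
#'
#' Runs the forced minimal model over a grid of feedback exponents, ramp
#' lengths and forcing directions. For each cell it simulates the
#' trajectory, splits the phases, computes the absolute nonlinearity of each
#' phase and the hysteresis of the full path, and records the maximum number
#' of stable equilibria over the swept driver values. Cells whose
#' computation fails are recorded with `NA` metrics and an error message
#' rather than aborting the sweep; results do not depend on evaluation
#' order.
#'
#' @param p_grid Feedback exponents (default 0 to 10 by 0.5).
#' @param step_grid Ramp lengths in timesteps (default `c(200, 20000)`:
#'   fast and slow rates of environmental change).
#' @param directions Forcing directions (default `"up_first"`).
#' @param b,r,h Remaining model parameters (defaults 1).
#' @param a_low,a_high Driver extremes.
#' @param substeps Integration substeps per unit timestep.
#' @param basis_dim Spline basis dimension for the nonlinearity smoother.
#' @param stability_scan_n Number of driver values scanned when counting
#'   stable states (default 101).
#' @return A `data.frame` with one row per sweep cell: `p`, `total_steps`,
#'   `direction`, `nonlinearity_up`, `nonlinearity_down`, `hysteresis`,
#'   `max_stable_states`, `error`.
#' @examples
#' run_sweep(p_grid = c(0, 4, 8), step_grid = 200)
#' @export
run_sweep <- function(p_grid = seq(0, 10, by = 0.5),
                      step_grid = c(200, 20000),
                      directions = "up_first",
                      b = 1, r = 1, h = 1, a_low = 0, a_high = 1,
                      substeps = 10, basis_dim = 10,
                      stability_scan_n = 101) {
  stopifnot(all(directions %in% c("up_first", "down_first")))
  cells <- expand.grid(p = p_grid, total_steps = step_grid,
                       direction = directions, stringsAsFactors = FALSE)
  # the stable-state count depends on p only, not on the ramp rate
  count_cache <- new.env(parent = emptyenv())
  max_stable <- function(p) {
    key <- format(p, digits = 15)
    if (!is.null(count_cache[[key]])) return(count_cache[[key]])
    params <- minimal_model_params(p, b, r, h)
    grid <- seq(a_low, a_high, length.out = stability_scan_n)
    n <- max(vapply(grid, function(a) n_stable_states(a, params), integer(1)))
    count_cache[[key]] <- n
    n
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    rec <- data.frame(p = cell$p, total_steps = cell$total_steps,
                      direction = cell$direction,
                      nonlinearity_up = NA_real_, nonlinearity_down = NA_real_,
                      hysteresis = NA_real_, max_stable_states = NA_integer_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      params <- minimal_model_params(cell$p, b, r, h)
      ramp <- driver_ramp(cell$total_steps, cell$direction, a_low, a_high)
      traj <- simulate_model(params, ramp, substeps = substeps)
      met <- response_metrics(as_response_path(traj), basis_dim = basis_dim)
      rec$nonlinearity_up <- met$nonlinearity_up
      rec$nonlinearity_down <- met$nonlinearity_down
      rec$hysteresis <- met$hysteresis
      rec$max_stable_states <- max_stable(cell$p)
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
  })
  do.call(rbind, rows)
}

#' State range of a sweep's slow strong-feedback run
#'
#' Scale reference used for relative tolerances: the range of the state
#' variable over a slow ramp at the strongest feedback in the grid.
#'
#' @param p Feedback exponent of the reference run (default 10).
#' @param total_steps Ramp length (default 20000).
#' @param ... Passed to [minimal_model_params()].
#' @return `max(Y) - min(Y)` of the reference trajectory.
#' @export
state_range <- function(p = 10, total_steps = 20000, ...) {
  traj <- simulate_model(minimal_model_params(p, ...), driver_ramp(total_steps))
  diff(range(traj$Y))
}
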