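# Seeded generator emulating a temperature-ramped microcosm experiment: a
# predator-prey-bacteria community coupled to two-compartment oxygen whose
# exchange with the atmosphere is set by a gas-exchange treatment. The
# generator's defaults are chosen to reproduce the qualitative phenomenology
# of such experiments (divergent persistence/extinction regimes, oxygen
# drawdown under weak exchange), not to estimate any real system.

#' Temperature protocol of the ramped experiment
#'
#' A stepped triangular temperature schedule: from `t_start`, an increase of
#' `step` degrees every `step_interval` days for `ramp_days` days, a plateau
#' at `t_peak` for `hold_days` days, then the mirror-image decrease back to
#' `t_start` on the final day. The profile is piecewise constant between
#' scheduled steps and capped at `t_peak`.
#'
#' @param t_start Starting (and final) temperature, degrees C (default 15).
#' @param t_peak Plateau temperature (default 25).
#' @param step Temperature increment per scheduled step (default 0.7).
#' @param step_interval Days between steps (default 2).
#' @param ramp_days Duration of each ramp leg (default 30).
#' @param hold_days Plateau duration (default 7).
#' @return An object of class `temperature_protocol`; its `length_days`
#'   field is `2 * ramp_days + hold_days`.
#' @examples
#' pr <- temperature_protocol()
#' temperature_at(c(0, 2, 34, 66), pr)
#' @export
temperature_protocol <- function(t_start = 15, t_peak = 25, step = 0.7,
                                 step_interval = 2, ramp_days = 30,
                                 hold_days = 7) {
  stopifnot(t_start < t_peak, step > 0, step_interval > 0,
            ramp_days > 0, hold_days >= 0)
  structure(list(t_start = t_start, t_peak = t_peak, step = step,
                 step_interval = step_interval, ramp_days = ramp_days,
                 hold_days = hold_days,
                 length_days = 2 * ramp_days + hold_days),
            class = "temperature_protocol")
}

#' Temperature on a given experiment day
#'
#' @param day Day(s) within `[0, length_days]`.
#' @param protocol A [temperature_protocol()] (default the standard one).
#' @return Temperature(s) in degrees C.
#' @export
temperature_at <- function(day, protocol = temperature_protocol()) {
  stopifnot(inherits(protocol, "temperature_protocol"), is.numeric(day))
  if (any(day < 0 | day > protocol$length_days))
    stop("`day` must lie within [0, ", protocol$length_days, "]")
  d <- pmin(day, protocol$length_days - day)
  pmin(protocol$t_peak,
       protocol$t_start + protocol$step * floor(d / protocol$step_interval))
}

#' Gas-exchange treatments
#'
#' The five oxygen-exchange levels of the experimental design, ordered from
#' weakest to strongest feedback: a continuously ventilated `open` system, three
#' air-addition treatments serviced every two days (`add200`, `add100`,
#' `add50`, with headspace-refresh fractions mapping the added air volumes to
#' a roughly 150 ml headspace), and a `closed` system with only a small leak
#' (no jar is perfectly sealed). `k_atm` is the continuous
#' headspace-atmosphere exchange rate (per day); `pulse_fraction` is the
#' fraction of the headspace gas refreshed toward atmospheric at each
#' service event (the bubbled air also refreshes the liquid directly, at
#' `liquid_pulse_scale` times the headspace fraction).
#'
#' @param k_atm_open,k_atm_leak Continuous exchange rates for the open system
#'   and for the residual leak of all stoppered systems.
#' @param pulse_fractions Named fractions for the air-addition treatments.
#' @return A `data.frame` with columns `label`, `k_atm`, `pulse_fraction`.
#' @export
gas_exchange_treatments <- function(k_atm_open = 20, k_atm_leak = 0.08,
                                    pulse_fractions = c(add200 = 0.8,
                                                        add100 = 0.5,
                                                        add50 = 0.3)) {
  stopifnot(k_atm_open > k_atm_leak, k_atm_leak >= 0,
            all(c("add200", "add100", "add50") %in% names(pulse_fractions)))
  pf <- pulse_fractions
  if (!(pf[["add200"]] > pf[["add100"]] && pf[["add100"]] > pf[["add50"]]))
    stop("pulse fractions must decrease with the added air volume")
  data.frame(
    label = c("open", "add200", "add100", "add50", "closed"),
    k_atm = c(k_atm_open, k_atm_leak, k_atm_leak, k_atm_leak, k_atm_leak),
    pulse_fraction = c(0, pf[["add200"]], pf[["add100"]], pf[["add50"]], 0),
    stringsAsFactors = FALSE
  )
}

#' Default microcosm generator configuration
#'
#' Assembles the full configuration of the synthetic experiment: design
#' (treatments, replicates, temperature protocol, sampling interval),
#' community dynamics parameters, oxygen physics, regime-planting
#' probabilities, noise scales and observation model. Any entry can be
#' overridden through `...` (nested lists are merged). The defaults encode
#' the emulated design: 5 gas-exchange treatments x 6 replicates sampled
#' every 2 days under the standard 15-25-15 degree protocol, with initial
#' conditions near 10 %O2, 1e6 bacteria/ml, 1000 prey/ml and 10
#' predators/ml.
#'
#' @param ... Named overrides of the default entries.
#' @return A list of class `microcosm_config`.
#' @examples
#' cfg <- microcosm_config(n_replicates = 2)
#' cfg$n_replicates
#' @export
microcosm_config <- function(...) {
  cfg <- list(
    protocol = temperature_protocol(),
    treatments = gas_exchange_treatments(),
    n_replicates = 6,
    sample_interval = 2,
    dt = 0.1,
    # probability that a replicate carries the heat-tolerant (persistent)
    # community, by treatment; weaker exchange makes persistence more likely
    persist_prob = c(open = 0, add200 = 0.15, add100 = 0.2,
                     add50 = 0.35, closed = 0.8),
    initial_state = c(O_liq = 10, O_head = 20, B = 1e6,
                      N1 = 400, N2 = 600, P = 10, cyst = 0),
    biology = list(
      # oxygen physics (%O2 sensor scale; atmospheric equilibrium reads 21)
      O_atm = 21, kLH = 6, beta = 0.67,
      # bacteria: logistic resupply and grazing by prey
      rB = 1.0, KB = 2e6, gB = 2e-4, KBN = 4e5,
      # prey: thermal performance (asymmetric: broad below the optimum,
      # sharp above), shared carrying capacity, heat mortality scaled by the
      # replicate's planted tolerance, predation refuge
      rN = 1.4, ToptN1 = 24, ToptN2 = 25, sigN_lo = 8, sigN_hi = 4,
      KN = 10000, mN0 = 0.05, Tcrit = 23.5, mH = 0.6,
      S_persist = 0.15, S_extinct = 1.5, refuge = 30,
      # predator: oxygen-limited saturating predation, interference-capped
      # mortality, hypoxia mortality, and a sharp thermal decline above the
      # (lower) predator optimum
      aP = 45, KNP = 600, eP = 0.05, mP = 0.12, KP = 60,
      ToptP = 20, sigP_lo = 6, sigP_hi = 2.2,
      KO = 4, mPO = 0.8, O_hyp = 4, mPH = 0.15, TcritP = 23,
      # community respiration weights (per reference density) and Q10
      rhoB = 0.05, rhoN = 0.7, rhoP = 0.1, Q10 = 2, T_ref = 15,
      # extinction floors and the predator cyst pool
      floorN = 0.5, floorP = 0.05, N_recover = 200, cyst_inoc = 0.2,
      liquid_pulse_scale = 0.3
    ),
    noise = list(sigma_env = 0.3, sigma_obs = 0.1, sigma_O = 0.2),
    morphology = list(
      prey1 = c(width = 25, length = 55),
      prey2 = c(width = 18, length = 40),
      predator = c(width = 45, length = 120),
      cv = 0.08, n_draws = 10
    )
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0)
      stop("unknown configuration entries: ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]) &&
          !inherits(cfg[[nm]], "temperature_protocol")) {
        cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
      } else {
        cfg[[nm]] <- overrides[[nm]]
      }
    }
  }
  class(cfg) <- "microcosm_config"
  validate_microcosm_config(cfg)
  cfg
}

#' Validate a microcosm configuration
#'
#' Checks structural and scientific invariants of a generator configuration
#' and reports all offending entries at once.
#'
#' @param cfg A configuration list as produced by [microcosm_config()].
#' @return `cfg`, invisibly, if valid; otherwise an error listing the
#'   offending keys.
#' @export
validate_microcosm_config <- function(cfg) {
  problems <- character(0)
  need <- c("protocol", "treatments", "n_replicates", "sample_interval", "dt",
            "persist_prob", "initial_state", "biology", "noise", "morphology")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    problems <- c(problems, paste("missing entries:", paste(missing, collapse = ", ")))
  if (!inherits(cfg$protocol, "temperature_protocol"))
    problems <- c(problems, "protocol: not a temperature_protocol")
  if (!is.data.frame(cfg$treatments) ||
      !all(c("label", "k_atm", "pulse_fraction") %in% names(cfg$treatments)))
    problems <- c(problems, "treatments: needs columns label, k_atm, pulse_fraction")
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 1)
    problems <- c(problems, "n_replicates: must be >= 1")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0 || cfg$dt > 0.1)
    problems <- c(problems, "dt: must be in (0, 0.1]")
  if (is.data.frame(cfg$treatments) &&
      !all(names(cfg$persist_prob) %in% cfg$treatments$label))
    problems <- c(problems, "persist_prob: names must match treatment labels")
  if (any(cfg$persist_prob < 0 | cfg$persist_prob > 1))
    problems <- c(problems, "persist_prob: probabilities must lie in [0, 1]")
  st <- cfg$initial_state
  if (!all(c("O_liq", "O_head", "B", "N1", "N2", "P") %in% names(st)))
    problems <- c(problems, "initial_state: needs O_liq, O_head, B, N1, N2, P")
  else if (any(st[c("B", "N1", "N2", "P")] < 0) ||
           any(st[c("O_liq", "O_head")] < 0 | st[c("O_liq", "O_head")] > 22))
    problems <- c(problems, "initial_state: densities must be >= 0 and oxygen in [0, 22]")
  if (any(unlist(cfg$noise) < 0))
    problems <- c(problems, "noise: scales must be >= 0")
  if (length(problems) > 0)
    stop("invalid microcosm configuration:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(cfg)
}

# asymmetric (left-skewed) thermal performance curve
thermal_performance <- function(temp, t_opt, sig_lo, sig_hi) {
  s <- ifelse(temp <= t_opt, sig_lo, sig_hi)
  exp(-(temp - t_opt)^2 / (2 * s^2))
}

#' One stochastic update of the microcosm dynamics
#'
#' Advances the community-oxygen state by one Euler-Maruyama step of length
#' `dt` days: logistic bacterial resupply grazed by prey; prey growth with
#' asymmetric thermal performance and heat mortality scaled by the
#' replicate's thermal `tolerance`; saturating predation limited by
#' dissolved oxygen; predator mortality with interference, hypoxia and heat
#' components; temperature-scaled (Q10) community respiration draining
#' liquid oxygen; liquid-headspace diffusion and continuous
#' headspace-atmosphere exchange. Densities falling below the extinction
#' floor are set to zero; the bacteria and prey floors are absorbing while
#' the predator may re-enter from its cyst pool when prey recover.
#'
#' @param state Named numeric vector with elements `O_liq`, `O_head`, `B`,
#'   `N1`, `N2`, `P`, `cyst` (cyst is 0/1).
#' @param treatment Treatment label (resolved against `config$treatments`)
#'   or a one-row treatment data frame.
#' @param temperature Current temperature, degrees C.
#' @param dt Step length in days (`<= 0.1`).
#' @param config A [microcosm_config()].
#' @param tolerance Heat-mortality multiplier of this replicate (the planted
#'   regime: `biology$S_persist` for heat-tolerant communities,
#'   `biology$S_extinct` otherwise). Default is the tolerant value.
#' @param noise If `TRUE`, multiplicative lognormal environmental noise is
#'   applied to the biotic rates (uses the R random number generator).
#' @return The updated state vector.
#' @examples
#' st <- c(O_liq = 5, O_head = 21, B = 0, N1 = 0, N2 = 0, P = 0, cyst = 0)
#' step_dynamics(st, "closed", 15, 0.1, noise = FALSE)["O_liq"] > 5
#' @export
step_dynamics <- function(state, treatment, temperature, dt,
                          config = microcosm_config(),
                          tolerance = config$biology$S_persist,
                          noise = TRUE) {
  if (dt > 0.1) stop("`dt` must be <= 0.1 day")
  if (any(!is.finite(state)))
    stop("nonfinite state passed to step_dynamics")
  trt <- resolve_treatment(treatment, config)
  bio <- config$biology
  e <- if (noise) {
    s <- config$noise$sigma_env
    exp(s * sqrt(dt) * rnorm(4) - 0.5 * s^2 * dt)
  } else rep(1, 4)
  Ol <- state[["O_liq"]]; Oh <- state[["O_head"]]
  B <- state[["B"]]; N1 <- state[["N1"]]; N2 <- state[["N2"]]
  P <- state[["P"]]; cyst <- state[["cyst"]]
  Nt <- N1 + N2
  phi <- Ol / (Ol + bio$KO)  # oxygen limitation of predation
  WP <- thermal_performance(temperature, bio$ToptP, bio$sigP_lo, bio$sigP_hi)
  Q <- bio$Q10^((temperature - bio$T_ref) / 10)
  grow1 <- bio$rN * thermal_performance(temperature, bio$ToptN1, bio$sigN_lo, bio$sigN_hi) *
    B / (B + bio$KBN) * max(0, 1 - Nt / bio$KN) * e[1]
  grow2 <- bio$rN * thermal_performance(temperature, bio$ToptN2, bio$sigN_lo, bio$sigN_hi) *
    B / (B + bio$KBN) * max(0, 1 - Nt / bio$KN) * e[1]
  m_heat <- bio$mH * tolerance * max(0, temperature - bio$Tcrit)^2
  av1 <- max(0, N1 - bio$refuge); av2 <- max(0, N2 - bio$refuge)
  pred_cap <- bio$aP * phi * WP * P / (bio$KNP + Nt) * e[2]
  m_hyp <- bio$mPO * max(0, 1 - Ol / bio$O_hyp)^2 +
    bio$mPH * max(0, temperature - bio$TcritP)^2
  dN1 <- (grow1 - bio$mN0 - m_heat) * N1 - pred_cap * av1
  dN2 <- (grow2 - bio$mN0 - m_heat) * N2 - pred_cap * av2
  dP <- (bio$eP * bio$aP * phi * WP * (av1 + av2) / (bio$KNP + Nt) * e[3] -
           bio$mP * (1 + P / bio$KP) - m_hyp) * P
  dB <- bio$rB * B * (1 - B / bio$KB) * e[4] - bio$gB * Nt * B
  resp <- Q * (bio$rhoB * B / bio$KB + bio$rhoN * Nt / 1000 + bio$rhoP * P / 10) *
    Ol / (Ol + 0.5)
  dOl <- bio$kLH * (Oh - Ol) - resp
  dOh <- bio$kLH * bio$beta * (Ol - Oh) + trt$k_atm * (bio$O_atm - Oh)
  out <- c(
    O_liq = min(max(Ol + dt * dOl, 0), 22),
    O_head = min(max(Oh + dt * dOh, 0), 22),
    B = max(B + dt * dB, 0),
    N1 = max(N1 + dt * dN1, 0),
    N2 = max(N2 + dt * dN2, 0),
    P = max(P + dt * dP, 0),
    cyst = cyst
  )
  if (out[["N1"]] < bio$floorN) out[["N1"]] <- 0
  if (out[["N2"]] < bio$floorN) out[["N2"]] <- 0
  if (out[["P"]] < bio$floorP) {
    if (out[["P"]] > 0) out[["cyst"]] <- 1
    out[["P"]] <- 0
  }
  if (out[["cyst"]] == 1 && out[["P"]] == 0 &&
      out[["N1"]] + out[["N2"]] > bio$N_recover) {
    out[["P"]] <- bio$cyst_inoc  # emergence from the cyst pool
  }
  if (any(!is.finite(out)))
    stop("generator produced a nonfinite state at temperature ", temperature)
  out
}

#' Pulsed gas-exchange service event
#'
#' Applies the two-daily air addition of the quantified exchange treatments:
#' the headspace moves toward atmospheric oxygen by the treatment's
#' `pulse_fraction`, and the bubbled liquid by `liquid_pulse_scale` times
#' that fraction. Treatments with `pulse_fraction = 0` (open, closed) are
#' unchanged.
#'
#' @inheritParams step_dynamics
#' @return The updated state vector.
#' @examples
#' st <- c(O_liq = 5, O_head = 10, B = 0, N1 = 0, N2 = 0, P = 0, cyst = 0)
#' service_event(st, "add200")
#' @export
service_event <- function(state, treatment, config = microcosm_config()) {
  trt <- resolve_treatment(treatment, config)
  O_atm <- config$biology$O_atm
  f <- trt$pulse_fraction
  state[["O_head"]] <- state[["O_head"]] + f * (O_atm - state[["O_head"]])
  state[["O_liq"]] <- state[["O_liq"]] +
    config$biology$liquid_pulse_scale * f * (O_atm - state[["O_liq"]])
  state
}

resolve_treatment <- function(treatment, config) {
  if (is.character(treatment)) {
    i <- match(treatment, config$treatments$label)
    if (is.na(i)) stop("unknown treatment label: ", treatment)
    config$treatments[i, ]
  } else if (is.data.frame(treatment) && nrow(treatment) == 1) {
    treatment
  } else stop("`treatment` must be a label or a one-row treatment data frame")
}

#' Ellipsoid biovolume from cell dimensions
#'
#' Biovolume proxy for an organism of measured width `a` and length `b`
#' assuming an ellipsoid shape: \eqn{(4/3) \pi (a/2)^2 (b/2)}.
#'
#' @param width,length Cell dimensions in micrometres (`> 0`).
#' @return Biovolume in cubic micrometres.
#' @examples
#' biovolume(2, 2)    # sphere of diameter 2: 4*pi/3
#' biovolume(20, 50)  # 10000*pi/3
#' @export
biovolume <- function(width, length) {
  stopifnot(is.numeric(width), is.numeric(length))
  if (any(width <= 0) || any(length <= 0))
    stop("`width` and `length` must be > 0")
  (4 / 3) * pi * (width / 2)^2 * (length / 2)
}

#' Observe a microcosm state
#'
#' Emulates one sampling event: densities are reported with multiplicative
#' lognormal observation noise, oxygen with additive sensor noise, and
#' individual widths and lengths of each protist species present are drawn
#' from species-specific normal distributions. Total biomass is the sum over
#' species of reported density times the mean biovolume of that sample's
#' morphology draws. With `noise = FALSE` the observations equal the latent
#' state and the morphology draws sit at the species means.
#'
#' @inheritParams step_dynamics
#' @return A list with `measurements` (named numeric vector: `O_liq`,
#'   `O_head`, `B`, `N1`, `N2`, `P`, `total_biomass`) and `morphology`
#'   (data frame of individual `species`, `width`, `length` draws).
#' @export
observe_sample <- function(state, config = microcosm_config(), noise = TRUE) {
  ns <- config$noise
  mo <- config$morphology
  dens <- state[c("B", "N1", "N2", "P")]
  if (noise && ns$sigma_obs > 0)
    dens <- dens * exp(rnorm(4, -0.5 * ns$sigma_obs^2, ns$sigma_obs))
  o <- state[c("O_liq", "O_head")]
  if (noise && ns$sigma_O > 0)
    o <- pmin(pmax(o + rnorm(2, 0, ns$sigma_O), 0), 22)
  species <- c("prey1", "prey2", "predator")
  dens_protist <- dens[c("N1", "N2", "P")]
  morph <- do.call(rbind, lapply(seq_along(species), function(i) {
    if (dens_protist[i] <= 0) return(NULL)
    m <- mo[[species[i]]]
    n <- if (noise) mo$n_draws else 1L
    w <- if (noise) rnorm(n, m[["width"]], mo$cv * m[["width"]]) else m[["width"]]
    l <- if (noise) rnorm(n, m[["length"]], mo$cv * m[["length"]]) else m[["length"]]
    data.frame(species = species[i], width = pmax(w, 1), length = pmax(l, 1),
               stringsAsFactors = FALSE)
  }))
  if (is.null(morph))
    morph <- data.frame(species = character(0), width = numeric(0),
                        length = numeric(0), stringsAsFactors = FALSE)
  biomass <- 0
  for (i in seq_along(species)) {
    if (dens_protist[i] > 0) {
      rows <- morph$species == species[i]
      biomass <- biomass +
        unname(dens_protist[i]) * mean(biovolume(morph$width[rows], morph$length[rows]))
    }
  }
  list(
    measurements = c(O_liq = unname(o[["O_liq"]]), O_head = unname(o[["O_head"]]),
                     B = unname(dens[["B"]]), N1 = unname(dens[["N1"]]),
                     N2 = unname(dens[["N2"]]), P = unname(dens[["P"]]),
                     total_biomass = biomass),
    morphology = morph
  )
}

# deterministic per-microcosm substream seed: depends only on the root seed
# and the (treatment, replicate) position, so adding replicates or
# treatments never perturbs existing microcosms
microcosm_seed <- function(seed, trt_idx, rep_idx) {
  (seed + 1000003 * (trt_idx * 1000 + rep_idx)) %% 2147483647
}

#' Generate a synthetic microcosm experiment
#'
#' Simulates the full experimental design: for every treatment x replicate a
#' latent thermal-tolerance draw plants the replicate's dynamic regime
#' (persistence of the predator-prey system through the heat peak versus
#' functional extinction), with persistence more likely under weaker gas
#' exchange; the community-oxygen dynamics are then integrated over the
#' temperature protocol with environmental noise, serviced every sampling
#' interval, and observed every `sample_interval` days with measurement
#' noise. Each microcosm uses an independent random substream derived from
#' `seed`, so the output is reproducible and adding replicates never changes
#' existing ones. With `noise = FALSE` the dynamics are deterministic, the
#' regime is the treatment's majority regime, and replicates within a
#' treatment are identical.
#'
#' @param config A [microcosm_config()].
#' @param seed Integer root seed.
#' @param noise Master noise switch (default `TRUE`).
#' @return An object of class `microcosm_experiment`: a list with
#'   `samples` (long-format data frame: `microcosm`, `treatment`,
#'   `replicate`, `day`, `temperature`, `O_liq`, `O_head`, `B`, `N1`, `N2`,
#'   `P`, `total_biomass`), `morphology` (individual width/length draws per
#'   microcosm and day), `microcosms` (one row per microcosm with the hidden
#'   `regime` ground truth: `"persistence"`, the low-oxygen regime, or
#'   `"extinction"`), plus the `config` and `seed`.
#' @examples
#' ex <- generate_experiment(microcosm_config(n_replicates = 1), seed = 1)
#' table(ex$microcosms$regime)
#' @export
generate_experiment <- function(config = microcosm_config(), seed = 1,
                                noise = TRUE) {
  validate_microcosm_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  seed <- as.integer(seed)
  proto <- config$protocol
  days <- proto$length_days
  sample_days <- seq(0, days, by = config$sample_interval)
  sample_days <- sample_days[sample_days + config$sample_interval <= days + 1e-9 |
                               sample_days <= days]
  n_steps_per_day <- round(1 / config$dt)
  labels <- config$treatments$label
  samples <- list(); morph_all <- list(); micro_rows <- list()
  idx <- 0
  for (ti in seq_along(labels)) {
    trt <- labels[ti]
    p_persist <- if (trt %in% names(config$persist_prob))
      config$persist_prob[[trt]] else 0
    for (ri in seq_len(config$n_replicates)) {
      idx <- idx + 1
      set.seed(microcosm_seed(seed, ti, ri))
      persist <- if (noise) runif(1) < p_persist else p_persist > 0.5
      tolerance <- if (persist) config$biology$S_persist else config$biology$S_extinct
      state <- config$initial_state
      if (!("cyst" %in% names(state))) state <- c(state, cyst = 0)
      id <- sprintf("%s_%d", trt, ri)
      rows <- list(); morphs <- list()
      for (d_i in seq_along(sample_days)) {
        day <- sample_days[d_i]
        obs <- observe_sample(state, config, noise = noise)
        rows[[d_i]] <- data.frame(
          microcosm = id, treatment = trt, replicate = ri, day = day,
          temperature = temperature_at(day, proto),
          O_liq = obs$measurements[["O_liq"]],
          O_head = obs$measurements[["O_head"]],
          B = obs$measurements[["B"]], N1 = obs$measurements[["N1"]],
          N2 = obs$measurements[["N2"]], P = obs$measurements[["P"]],
          total_biomass = obs$measurements[["total_biomass"]],
          stringsAsFactors = FALSE
        )
        if (nrow(obs$morphology) > 0) {
          obs$morphology$microcosm <- id
          obs$morphology$day <- day
          morphs[[d_i]] <- obs$morphology
        }
        if (d_i == length(sample_days)) break
        state <- service_event(state, trt, config)
        next_day <- sample_days[d_i + 1]
        n_sub <- round((next_day - day) * n_steps_per_day)
        for (k in seq_len(n_sub)) {
          temp <- temperature_at(day + (k - 1) * config$dt, proto)
          state <- step_dynamics(state, trt, temp, config$dt, config,
                                 tolerance = tolerance, noise = noise)
        }
      }
      samples[[idx]] <- do.call(rbind, rows)
      mm <- do.call(rbind, morphs)
      if (!is.null(mm)) morph_all[[idx]] <- mm
      micro_rows[[idx]] <- data.frame(
        microcosm = id, treatment = trt, replicate = ri,
        regime = if (persist) "persistence" else "extinction",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(
    samples = do.call(rbind, samples),
    morphology = do.call(rbind, morph_all),
    microcosms = do.call(rbind, micro_rows),
    config = config,
    seed = seed
  )
  rownames(out$samples) <- NULL
  rownames(out$microcosms) <- NULL
  if (!is.null(out$morphology)) rownames(out$morphology) <- NULL
  class(out) <- "microcosm_experiment"
  out
}

#' @export
print.microcosm_experiment <- function(x, ...) {
  cat(sprintf(paste0("Synthetic microcosm experiment: %d microcosms ",
                     "(%d treatments x %d replicates), %d sampling days, seed %d\n"),
              nrow(x$microcosms), length(unique(x$microcosms$treatment)),
              x$config$n_replicates, length(unique(x$samples$day)), x$seed))
  print(table(x$microcosms$treatment, x$microcosms$regime))
  invisible(x)
}

#' Write / read a microcosm experiment as CSV
#'
#' `write_experiment()` writes the sample table, the morphology draws and
#' the microcosm metadata (including the hidden regime labels) as three CSV
#' files `<prefix>_samples.csv`, `<prefix>_morphology.csv`,
#' `<prefix>_microcosms.csv`. `read_experiment()` reads them back; the
#' configuration is not serialized.
#'
#' @param x A `microcosm_experiment`.
#' @param prefix File-path prefix.
#' @return `read_experiment()` returns a `microcosm_experiment` (with
#'   `config = NULL`); `write_experiment()` returns `prefix` invisibly.
#' @export
write_experiment <- function(x, prefix) {
  stopifnot(inherits(x, "microcosm_experiment"))
  write.csv(x$samples, paste0(prefix, "_samples.csv"), row.names = FALSE)
  if (!is.null(x$morphology))
    write.csv(x$morphology, paste0(prefix, "_morphology.csv"), row.names = FALSE)
  write.csv(x$microcosms, paste0(prefix, "_microcosms.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(prefix) {
  samples <- read.csv(paste0(prefix, "_samples.csv"), stringsAsFactors = FALSE)
  morph_path <- paste0(prefix, "_morphology.csv")
  morphology <- if (file.exists(morph_path))
    read.csv(morph_path, stringsAsFactors = FALSE) else NULL
  microcosms <- read.csv(paste0(prefix, "_microcosms.csv"),
                         stringsAsFactors = FALSE)
  structure(list(samples = samples, morphology = morphology,
                 microcosms = microcosms, config = NULL, seed = NA_integer_),
            class = "microcosm_experiment")
}

#' Extract per-microcosm driver-response paths from an experiment
#'
#' Converts the sampled time series of one measured variable into
#' [response_path()] objects against temperature, splitting phases at the
#' schedule midpoint (ascending up to day 33, descending from day 34).
#'
#' @param x A `microcosm_experiment` or its `samples` data frame.
#' @param variable `"O_liq"` (dissolved oxygen) or `"total_biomass"`.
#' @return A named list of `response_path` objects, one per microcosm.
#' @export
microcosm_paths <- function(x, variable = c("O_liq", "total_biomass")) {
  variable <- match.arg(variable)
  samples <- if (inherits(x, "microcosm_experiment")) x$samples else x
  split_day <- 33  # schedule midpoint: days <= 33 ascending, >= 34 descending
  out <- lapply(split(samples, samples$microcosm), function(d) {
    d <- d[order(d$day), ]
    response_path(d$temperature, d[[variable]],
                  ifelse(d$day <= split_day, "ascending", "descending"),
                  id = d$microcosm[1])
  })
  out[unique(samples$microcosm)]
}

#' Response metrics for every microcosm in an experiment
#'
#' Applies [response_metrics()] to each microcosm's temperature-response
#' path for the requested variables.
#'
#' @inheritParams microcosm_paths
#' @param variables Measured variables to analyse.
#' @param basis_dim Spline basis dimension for the nonlinearity smoother.
#' @return A `data.frame` with one row per microcosm and variable, including
#'   the treatment label.
#' @export
experiment_metrics <- function(x, variables = c("O_liq", "total_biomass"),
                               basis_dim = 10) {
  samples <- if (inherits(x, "microcosm_experiment")) x$samples else x
  meta <- unique(samples[, c("microcosm", "treatment")])
  out <- do.call(rbind, lapply(variables, function(v) {
    paths <- microcosm_paths(samples, v)
    met <- do.call(rbind, lapply(paths, response_metrics, basis_dim = basis_dim))
    met$variable <- v
    met
  }))
  rownames(out) <- NULL
  names(out)[names(out) == "id"] <- "microcosm"
  merge(meta, out, by = "microcosm")
}
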