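test_that("temperature protocol follows the stepped triangular schedule", {
  expect_equal(temperature_at(0), 15)
  expect_equal(temperature_at(2), 15.7)
  expect_equal(temperature_at(34), 25)   # inside the plateau week
  expect_equal(temperature_at(66), 15)   # back to the start by the last sample
  days <- seq(0, 67, by = 0.5)
  temps <- temperature_at(days)
  expect_true(all(temps >= 15 & temps <= 25))
  # nondecreasing on the way up, nonincreasing on the way down
  expect_true(all(diff(temps[days <= 30]) >= 0))
  expect_true(all(diff(temps[days >= 37]) <= 0))
  expect_true(all(temps[days >= 30 & days <= 37] == 25))
  expect_error(temperature_at(-1), "day")
})

test_that("gas-exchange treatments are ordered by openness", {
  trt <- gas_exchange_treatments()
  expect_equal(trt$label, c("open", "add200", "add100", "add50", "closed"))
  expect_equal(trt$pulse_fraction[trt$label == "open"], 0)
  expect_equal(trt$pulse_fraction[trt$label == "closed"], 0)
  expect_gt(trt$k_atm[trt$label == "open"], max(trt$k_atm[trt$label != "open"]))
  pf <- setNames(trt$pulse_fraction, trt$label)
  expect_true(pf["add200"] > pf["add100"] && pf["add100"] > pf["add50"])
  expect_error(gas_exchange_treatments(pulse_fractions = c(add200 = 0.1,
                                                           add100 = 0.5,
                                                           add50 = 0.3)))
})

test_that("ellipsoid biovolume matches its formula and scaling laws", {
  expect_equal(biovolume(2, 2), 4 * pi / 3)
  expect_equal(biovolume(20, 50), 10000 * pi / 3)
  expect_equal(biovolume(10, 25) * 4, biovolume(20, 25))  # width squares
  expect_equal(biovolume(10, 25) * 2, biovolume(10, 50))  # length is linear
  expect_error(biovolume(0, 5), "width")
})

test_that("service events pull oxygen toward the atmosphere, monotonely in volume", {
  cfg <- microcosm_config()
  st <- c(O_liq = 4, O_head = 8, B = 0, N1 = 0, N2 = 0, P = 0, cyst = 0)
  full <- service_event(st, "add200",
                        microcosm_config(treatments = gas_exchange_treatments(
                          pulse_fractions = c(add200 = 1, add100 = 0.5, add50 = 0.3))))
  expect_equal(full[["O_head"]], 21)  # complete headspace replacement
  none <- service_event(st, "closed", cfg)
  expect_equal(none, st)
  s200 <- service_event(st, "add200", cfg)
  s50 <- service_event(st, "add50", cfg)
  expect_gte(s200[["O_liq"]], s50[["O_liq"]])
  expect_gte(s200[["O_head"]], s50[["O_head"]])
})

test_that("abiotic microcosms relax toward atmospheric oxygen", {
  cfg <- microcosm_config()
  st <- c(O_liq = 5, O_head = 21, B = 0, N1 = 0, N2 = 0, P = 0, cyst = 0)
  st2 <- step_dynamics(st, "closed", 15, 0.1, cfg, noise = FALSE)
  expect_gt(st2[["O_liq"]], st[["O_liq"]])
  expect_equal(unname(st2[c("B", "N1", "N2", "P")]), c(0, 0, 0, 0))
  # recovery speed ordered by treatment openness
  run_to <- function(trt) {
    s <- c(O_liq = 5, O_head = 5, B = 0, N1 = 0, N2 = 0, P = 0, cyst = 0)
    for (i in 1:100) {  # 10 days at dt = 0.1, serviced every 2 days
      if (i %% 20 == 1 && i > 1) s <- service_event(s, trt, cfg)
      s <- step_dynamics(s, trt, 15, 0.1, cfg, noise = FALSE)
    }
    s[["O_liq"]]
  }
  o <- vapply(c("open", "add200", "add100", "add50", "closed"), run_to, numeric(1))
  expect_true(all(diff(o) < 0))  # open recovers fastest, closed slowest
  expect_true(all(o >= 0 & o <= 22))
})

test_that("closed communities draw oxygen lower than open ones", {
  cfg <- microcosm_config()
  run_min <- function(trt) {
    s <- cfg$initial_state
    lo <- s[["O_liq"]]
    for (i in 1:300) {  # 30 days at dt = 0.1, serviced every 2 days
      if (i %% 20 == 1 && i > 1) s <- service_event(s, trt, cfg)
      s <- step_dynamics(s, trt, temperature_at((i - 1) * 0.1), 0.1, cfg,
                         tolerance = cfg$biology$S_persist, noise = FALSE)
      lo <- min(lo, s[["O_liq"]])
    }
    lo
  }
  expect_lt(run_min("closed"), run_min("open"))
})

test_that("step_dynamics rejects oversized steps and nonfinite states", {
  cfg <- microcosm_config()
  st <- cfg$initial_state
  expect_error(step_dynamics(st, "open", 15, 0.5, cfg), "dt")
  st_bad <- st; st_bad[["B"]] <- NaN
  expect_error(step_dynamics(st_bad, "open", 15, 0.1, cfg), "nonfinite")
})

test_that("observation without noise reports the latent state exactly", {
  cfg <- microcosm_config()
  st <- c(O_liq = 12, O_head = 19, B = 5e5, N1 = 1000, N2 = 0, P = 0, cyst = 0)
  obs <- observe_sample(st, cfg, noise = FALSE)
  expect_equal(obs$measurements[["N1"]], 1000)
  expect_equal(obs$measurements[["O_liq"]], 12)
  # biomass composes density with the ellipsoid biovolume of the draws
  m <- cfg$morphology$prey1
  expect_equal(obs$measurements[["total_biomass"]],
               1000 * biovolume(m[["width"]], m[["length"]]))
  expect_equal(unique(obs$morphology$species), "prey1")
})

test_that("experiment generation is deterministic and substream-stable", {
  cfg <- microcosm_config(n_replicates = 2)
  a <- generate_experiment(cfg, seed = 3)
  b <- generate_experiment(cfg, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$microcosms, b$microcosms)
  # adding replicates never perturbs existing microcosms
  c4 <- generate_experiment(microcosm_config(n_replicates = 4), seed = 3)
  shared <- c4$samples[c4$samples$microcosm %in% a$samples$microcosm, ]
  rownames(shared) <- NULL
  expect_equal(a$samples, shared)
})

test_that("switching noise off makes replicates identical within treatments", {
  ex <- generate_experiment(microcosm_config(n_replicates = 2), seed = 1,
                            noise = FALSE)
  for (trt in unique(ex$microcosms$treatment)) {
    reps <- split(ex$samples[ex$samples$treatment == trt, ],
                  ex$samples$replicate[ex$samples$treatment == trt])
    expect_equal(reps[[1]]$O_liq, reps[[2]]$O_liq)
    expect_equal(reps[[1]]$total_biomass, reps[[2]]$total_biomass)
  }
})

test_that("generated experiments satisfy the design and bounds invariants", {
  ex <- small_experiment()
  expect_equal(nrow(ex$microcosms), 5 * 2)
  expect_equal(sort(unique(ex$samples$day)), seq(0, 66, by = 2))
  expect_true(all(ex$samples$O_liq >= 0 & ex$samples$O_liq <= 22))
  expect_true(all(ex$samples$O_head >= 0 & ex$samples$O_head <= 22))
  expect_true(all(ex$samples[, c("B", "N1", "N2", "P", "total_biomass")] >= 0))
  expect_true(all(ex$microcosms$regime %in% c("persistence", "extinction")))
  # starting conditions near the nominal initial state
  d0 <- ex$samples[ex$samples$day == 0, ]
  expect_true(all(abs(d0$O_liq - 10) < 2))
  expect_true(all(d0$B > 5e5 & d0$B < 2e6))
  expect_true(all(d0$N1 + d0$N2 > 500 & d0$N1 + d0$N2 < 2000))
  expect_true(all(d0$P > 5 & d0$P < 20))
})

test_that("an experiment round-trips losslessly through CSV", {
  ex <- small_experiment()
  prefix <- tempfile()
  write_experiment(ex, prefix)
  back <- read_experiment(prefix)
  expect_equal(back$samples, ex$samples, tolerance = 1e-12)
  expect_identical(back$microcosms, ex$microcosms)
  expect_equal(back$morphology, ex$morphology, tolerance = 1e-12)
})

test_that("invalid configurations are rejected with the offending keys", {
  expect_error(microcosm_config(nonsense = 1), "nonsense")
  expect_error(microcosm_config(dt = 0.5), "dt")
  cfg <- microcosm_config()
  cfg$persist_prob[1] <- 2
  expect_error(validate_microcosm_config(cfg), "persist_prob")
  cfg <- microcosm_config()
  cfg$initial_state[["B"]] <- -1
  expect_error(validate_microcosm_config(cfg), "initial_state")
})

test_that("mean oxygen decreases from open to closed treatments", {
  # expectation over seeds; averaged over the small shared experiments
  exps <- lapply(1:4, function(s)
    generate_experiment(microcosm_config(n_replicates = 2), seed = s))
  samples <- do.call(rbind, lapply(exps, `[[`, "samples"))
  means <- tapply(samples$O_liq, samples$treatment, mean)
  means <- means[c("open", "add200", "add100", "add50", "closed")]
  expect_true(all(diff(means) < 0))
})
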