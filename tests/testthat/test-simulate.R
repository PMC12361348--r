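test_that("no diagnosis hazard and no prevalence means no diagnoses", {
  cfg <- sim_config(n_subjects = 300, seed = 2, lambda_dx = 0,
                    prevalent_prob = 0)
  rec <- simulate_cohort(cfg)
  expect_true(all(is.na(rec$dx_age_any_mental)))
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 500, seed = 13)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # and differs under a different seed
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg, seed = 14)))
})

test_that("invalid configurations fail before any draw", {
  expect_error(sim_config(hazards_unexposed = c(natural_cd4_lt200 = -0.01)),
               "invalid hazard")
  expect_error(sim_config(prevalent_prob = 1.5), "probability")
  expect_error(sim_config(hazards_unexposed = c(natural_cd4_lt200 = 0),
                          hazards_exposed = c(natural_cd4_lt200 = 0)),
               "total death hazard")
  expect_error(sim_config(lambda_dx = list(breaks = c(40), rates = c(0.1))),
               "piecewise")
})

test_that("mean observed lifetime matches the truncated-exponential expectation", {
  # fixed entry, single natural cause, no dropout, no prevalent diagnoses
  mu <- 0.03; a <- 50; tau <- 85
  cfg <- sim_config(n_subjects = 20000, seed = 31,
                    entry_age = list(dist = "fixed", age = a),
                    prevalent_prob = 0, lambda_dx = 0, dropout = 0,
                    hazards_unexposed = c(natural_cd4_ge350 = mu),
                    hazards_exposed = c(natural_cd4_ge350 = mu),
                    calendar_open = "1970-01-01",
                    enrollment_close = "1971-01-01",
                    calendar_close = "2030-01-01", cutoff = tau)
  rec <- simulate_cohort(cfg)
  obs <- rec$exit_age - rec$entry_age
  truth <- (1 - exp(-mu * (tau - a))) / mu   # E[min(T, tau - a)]
  mc_se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - truth), 3 * mc_se)
})

test_that("simulated death codes round-trip the cause classifier", {
  cfg <- sim_config(n_subjects = 4000, seed = 17)
  rec <- add_cause_category(simulate_cohort(cfg), cause_taxonomy("grouped"))
  dead <- rec[rec$event == "death", ]
  expect_true(all(dead$cause_category %in% cause_taxonomy("grouped")$labels))
  # CD4-banded natural deaths carry a CD4 compatible with their band
  lt <- dead[dead$cause_category == "natural_cd4_lt200", "cd4_at_death"]
  expect_true(all(lt < 200))
  ge <- dead[dead$cause_category == "natural_cd4_ge350", "cd4_at_death"]
  expect_true(all(ge >= 350))
  # unnatural hazard emits codes in the printed unnatural ranges
  expect_true(all(dead$cause_category != "unknown_cause" | is.na(dead$death_icd)))
})

test_that("piecewise diagnosis hazard and Gompertz death hazards draw correctly", {
  # piecewise lambda: zero before age 50 -> no incident diagnosis before 50
  cfg <- sim_config(n_subjects = 2000, seed = 23, prevalent_prob = 0,
                    lambda_dx = list(breaks = 50, rates = c(0, 0.3)),
                    entry_age = list(dist = "uniform", min = 30, max = 45))
  rec <- simulate_cohort(cfg)
  dx <- rec$dx_age_any_mental
  expect_true(all(is.na(dx) | dx >= 50))
  expect_gt(sum(!is.na(dx)), 0)

  # Gompertz clock: empirical survival matches exp(-H) at a probe age
  set.seed(41)
  a0 <- 1e-4; b <- 0.09; x0 <- 45; t_probe <- 15
  draws <- lylcohort:::draw_event_time(list(a = a0, b = b), rep(x0, 30000))
  H <- a0 / b * (exp(b * (x0 + t_probe)) - exp(b * x0))
  p_emp <- mean(draws > t_probe)
  p_true <- exp(-H)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / 30000))
})

test_that("analytic truth: null contrast, closed forms, grid agreement", {
  cfg0 <- sim_config(n_subjects = 10, seed = 1,
                     entry_age = list(dist = "fixed", age = 45),
                     hazards_unexposed = c(natural_cd4_lt200 = 0.02),
                     hazards_exposed = c(natural_cd4_lt200 = 0.02),
                     lambda_dx = 0.05)
  tr0 <- analytic_lyl(cfg0, onset_ages = c(45, 55, 65))
  expect_equal(tr0$delta_total, 0)
  expect_true(all(tr0$delta_at_age == 0))

  # closed form: mu = 0.02, a = 45, tau = 85 -> LYL = 12.466
  expect_equal(tr0$lyl_unexposed < 40, TRUE)
  tr1 <- analytic_lyl(cfg0, onset_ages = 45)
  expect_equal(tr1$lyl_unexposed, 40 - (1 - exp(-0.8)) / 0.02, tolerance = 1e-9)

  # per-cause shares mu_c / mu, checked against the printed worked values
  cfg2 <- sim_config(n_subjects = 10, seed = 1,
                     entry_age = list(dist = "fixed", age = 45),
                     hazards_unexposed = c(natural_cd4_lt200 = 0.005,
                                           unnatural = 0.015),
                     hazards_exposed = c(natural_cd4_lt200 = 0.005,
                                         unnatural = 0.015))
  tr2 <- analytic_lyl(cfg2, onset_ages = 45)
  shares <- c(0.005, 0.015) / 0.02 * tr2$lyl_unexposed
  expect_equal(tr2$lyl_unexposed, 12.46645, tolerance = 1e-5)
  expect_equal(unname(shares), c(3.116614, 9.349841), tolerance = 1e-4)

  # dense-grid numeric mode agrees with the constant closed form
  trc <- analytic_lyl(const_scenario(10, 1), onset_ages = 45)
  trn <- analytic_lyl(const_scenario(10, 1), onset_ages = 45, mode = "numeric",
                      step = 1e-4)
  expect_equal(trn$delta_total, trc$delta_total, tolerance = 1e-6)
  expect_equal(trn$delta_by_cause, trc$delta_by_cause, tolerance = 1e-6)
})

test_that("onset-age law quadrature integrates to a proper distribution", {
  cfg <- sim_config(n_subjects = 10, seed = 1)
  law <- lylcohort:::onset_age_law(cfg, tau = 85)
  expect_equal(sum(law$weights), 1, tolerance = 1e-12)
  expect_true(all(law$ages >= 18 & law$ages < 85))
  tr <- analytic_lyl(cfg)   # averaged truth over the model onset law
  expect_true(is.finite(tr$delta_total))
  expect_equal(sum(tr$delta_by_cause), tr$delta_total, tolerance = 1e-9)
})
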