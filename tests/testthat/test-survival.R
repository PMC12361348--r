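# Independent brute-force oracle: explicit loops over death ages, counting
# the risk set {i : enter_i < t <= exit_i} directly.
brute_km_cif <- function(eps, causes) {
  dt <- sort(unique(eps$exit[eps$status == "death"]))
  S <- 1; s_out <- numeric(0)
  cif <- matrix(0, length(dt), length(causes), dimnames = list(NULL, causes))
  f <- rep(0, length(causes))
  for (j in seq_along(dt)) {
    t <- dt[j]
    at_risk <- sum(eps$enter < t & t <= eps$exit)
    for (ci in seq_along(causes)) {
      d_c <- sum(eps$exit == t & eps$status == "death" & eps$cause == causes[ci])
      f[ci] <- f[ci] + S * d_c / at_risk
    }
    d <- sum(eps$exit == t & eps$status == "death")
    S <- S * (1 - d / at_risk)
    s_out <- c(s_out, S)
    cif[j, ] <- f
  }
  list(time = dt, surv = s_out, cif = cif)
}

test_that("single-subject and all-censored limits", {
  one <- data.frame(subject_id = "1", enter = 30, exit = 40, status = "death",
                    cause = "A", stringsAsFactors = FALSE)
  km <- km_left_truncated(one)
  expect_equal(km$time, 40)
  expect_equal(km$surv, 0)
  expect_equal(km$start, 30)
  cens <- data.frame(subject_id = 1:3, enter = c(30, 31, 32),
                     exit = c(40, 41, 42), status = "censored",
                     cause = NA_character_)
  flat <- km_left_truncated(cens)
  expect_length(flat$time, 0)
  expect_equal(surv_at(flat, c(35, 41.9)), c(1, 1))
})

test_that("worked five-episode example matches the hand computation", {
  eps <- worked_episodes()
  km <- km_left_truncated(eps)
  expect_equal(km$time, c(40, 45, 60))
  expect_equal(km$n_risk, c(5, 3, 1))
  expect_equal(km$surv, c(0.8, 0.8 * 2/3, 0), tolerance = 1e-12)
  cif <- cause_specific_cif(eps)
  expect_equal(unname(cif$cif[3, "X"]), 0.2 + 0.8 * 2/3, tolerance = 1e-12)
  expect_equal(unname(cif$cif[3, "Y"]), 0.8 / 3, tolerance = 1e-12)
})

test_that("estimates match brute-force risk-set counting on small cohorts", {
  for (s in 1:25) {
    eps <- random_episodes(sample(3:12, 1), seed = s)
    causes <- sort(unique(eps$cause[eps$status == "death"]))
    if (!length(causes)) next
    got <- cause_specific_cif(eps, causes = causes)
    want <- brute_km_cif(eps, causes)
    expect_equal(got$surv, want$surv, tolerance = 1e-12)
    expect_equal(unname(got$cif), unname(want$cif), tolerance = 1e-12)
  }
})

test_that("estimates agree with survival::survfit under left truncation", {
  skip_if_not_installed("survival")
  eps <- random_episodes(400, seed = 42)
  km <- km_left_truncated(eps)
  sf <- survival::survfit(survival::Surv(enter, exit, status == "death") ~ 1,
                          data = eps)
  sf_s <- summary(sf, times = km$time)$surv
  expect_equal(km$surv, sf_s, tolerance = 1e-10)

  # multi-state Aalen-Johansen cross-check
  eps$state <- factor(ifelse(eps$status == "death", eps$cause, "censored"),
                      levels = c("censored", "A", "B"))
  aj <- survival::survfit(survival::Surv(enter, exit, state) ~ 1, data = eps,
                          id = subject_id)
  cif <- cause_specific_cif(eps, causes = c("A", "B"))
  pst <- summary(aj, times = cif$time)$pstate
  expect_equal(unname(cif$cif[, "A"]), pst[, match("A", aj$states)],
               tolerance = 1e-10)
  expect_equal(unname(cif$cif[, "B"]), pst[, match("B", aj$states)],
               tolerance = 1e-10)
})

test_that("without truncation or censoring, KM is the empirical survival function", {
  set.seed(3)
  exit <- 30 + rexp(60, 0.1)
  eps <- data.frame(subject_id = as.character(1:60), enter = 30, exit = exit,
                    status = "death", cause = "A", stringsAsFactors = FALSE)
  km <- km_left_truncated(eps)
  emp <- vapply(km$time, function(t) mean(exit > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("conservation: cause CIFs and survival sum to one at every event age", {
  for (s in 1:10) {
    eps <- random_episodes(50, causes = c("A", "B", "C"), seed = 100 + s)
    cif <- cause_specific_cif(eps, causes = c("A", "B", "C"))
    expect_lt(max(abs(rowSums(cif$cif) + cif$surv - 1)), 1e-12)
  }
})

test_that("conditioning rescales correctly and preserves conservation", {
  eps <- worked_episodes()
  cif <- cause_specific_cif(eps)
  cond <- condition_at(cif, 40)
  expect_equal(cond$surv[cond$time == 45], (0.8 * 2/3) / 0.8, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(cond$cif) + cond$surv - 1)), 1e-12)
  # identity at the curve start
  same <- condition_at(cif, cif$start)
  expect_equal(same$surv, cif$surv)
  expect_equal(same$cif, cif$cif)
  # errors where there is no risk information
  expect_error(condition_at(cif, 60), "no risk information")   # S(60) = 0
  expect_error(condition_at(cif, 20), "no risk information")   # before start
})

test_that("tidy export carries risk sets and step values", {
  df <- as.data.frame(cause_specific_cif(worked_episodes()))
  expect_named(df, c("age", "n_risk", "n_event", "S", "F_X", "F_Y"))
  expect_equal(df$n_risk, c(5, 3, 1))
})
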