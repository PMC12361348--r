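fake_excess <- function(delta, n, by_cause = NULL) {
  structure(list(delta_total = delta, delta_by_cause = by_cause,
                 n_exposed = n, n_excluded = 0L, onset_ages = rep(50, n),
                 cutoff = 85, lyl_exposed = delta + 1, lyl_unexposed = 1,
                 high_exclusion = FALSE),
            class = "lyl_excess")
}

test_that("pooling is the exposed-count weighted mean", {
  pooled <- pooled_excess_lyl(list(fake_excess(2.0, 100), fake_excess(4.0, 300)))
  expect_equal(pooled$delta_total, 3.5)
  expect_equal(pooled$n_exposed, 400)
  # single stratum is the identity
  one <- fake_excess(2.7, 55, by_cause = c(a = 1.7, b = 1.0))
  same <- pooled_excess_lyl(list(one))
  expect_equal(same$delta_total, one$delta_total)
  expect_equal(same$delta_by_cause, one$delta_by_cause)
  # zero-exposed strata are dropped; all-empty errors
  keep <- pooled_excess_lyl(list(fake_excess(2.0, 100), fake_excess(9.9, 0)))
  expect_equal(keep$delta_total, 2.0)
  expect_error(pooled_excess_lyl(list(fake_excess(1, 0))), "zero exposed")
})

test_that("pooled per-cause components sum to the pooled total on random inputs", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    strata <- lapply(seq_len(sample(1:4, 1)), function(i) {
      bc <- rnorm(k)
      fake_excess(sum(bc), sample(10:500, 1),
                  by_cause = stats::setNames(bc, letters[1:k]))
    })
    pooled <- pooled_excess_lyl(strata)
    expect_equal(sum(pooled$delta_by_cause), pooled$delta_total,
                 tolerance = 1e-9)
  }
})

test_that("stratified estimation never mixes strata and pools by exposed count", {
  rec <- random_records(600, seed = 77, strata = c("s1", "s2"))
  tax <- cause_taxonomy("grouped")
  rec <- add_cause_category(rec, tax)
  full <- analyze_group(rec, "any_mental", tax)
  expect_setequal(names(full$per_stratum), c("s1", "s2"))
  # each stratum estimate equals the estimate from that stratum's rows alone
  for (s in c("s1", "s2")) {
    solo <- analyze_group(rec[rec$stratum_id == s, ], "any_mental", tax)
    expect_equal(full$per_stratum[[s]]$delta_total, solo$pooled$delta_total,
                 tolerance = 1e-12)
  }
  w <- full$weights / sum(full$weights)
  manual <- sum(w * vapply(full$per_stratum, function(x) x$delta_total,
                           numeric(1)))
  expect_equal(full$pooled$delta_total, manual, tolerance = 1e-12)
})

test_that("the fast bootstrap engine reproduces analyze_group exactly", {
  tax <- cause_taxonomy("detailed")
  for (s in c(5, 6)) {
    rec <- add_cause_category(random_records(400, seed = s), tax)
    eng <- lylcohort:::make_boot_engine(rec, "any_mental", tax, 85, "any_mental")
    id <- eng(resample = FALSE)
    ref <- analyze_group(rec, "any_mental", tax)$pooled
    expect_equal(unname(id["total"]), ref$delta_total, tolerance = 1e-12)
    expect_equal(id[-1], ref$delta_by_cause, tolerance = 1e-12)
  }
})

test_that("bootstrap is deterministic under a fixed seed", {
  rec <- add_cause_category(random_records(300, seed = 3),
                            cause_taxonomy("grouped"))
  b1 <- bootstrap_ci(rec, "any_mental", cause_taxonomy("grouped"), B = 40,
                     seed = 9)
  b2 <- bootstrap_ci(rec, "any_mental", cause_taxonomy("grouped"), B = 40,
                     seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_ci(rec, "any_mental", cause_taxonomy("grouped"), B = 40,
                     seed = 10)
  expect_false(identical(b1$ci, b3$ci))
  expect_true(all(b1$ci["low", ] <= b1$ci["high", ]))
})

test_that("a cohort of identical subjects gives a zero-width CI", {
  n <- 16
  rec <- make_records(entry = rep(40, n), exit = rep(60, n),
                      event = "death", death_icd = "B24", cd4 = 300,
                      dx = list(any_mental = c(rep(35, n / 2), rep(NA, n / 2))))
  rec <- add_cause_category(rec, cause_taxonomy("grouped"))
  b <- bootstrap_ci(rec, "any_mental", cause_taxonomy("grouped"), B = 60,
                    seed = 4)
  expect_equal(unname(b$ci["low", "total"]), unname(b$ci["high", "total"]),
               tolerance = 1e-12)
  expect_equal(unname(b$ci["low", "total"]), b$point$pooled$delta_total,
               tolerance = 1e-12)
})

test_that("per-cause components sum to the total in every bootstrap replicate", {
  rec <- add_cause_category(random_records(250, seed = 12),
                            cause_taxonomy("detailed"))
  b <- bootstrap_ci(rec, "any_mental", cause_taxonomy("detailed"), B = 50,
                    seed = 2)
  ok <- !is.na(b$replicates[, "total"])
  gap <- abs(rowSums(b$replicates[ok, -1, drop = FALSE]) -
               b$replicates[ok, "total"])
  expect_lt(max(gap), 1e-9)
})

test_that("run_pipeline drives the full analysis reproducibly", {
  config <- list(
    simulate = list(n_subjects = 900),
    groups = "any_mental", taxonomy = "grouped",
    sexes = c("male", "female"), tau = 85, seed = 6,
    bootstrap = list(B = 25, seed = 6)
  )
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  res1 <- run_pipeline(config, output_dir = out1)
  res2 <- run_pipeline(config, output_dir = out2)
  # byte-identical outputs under identical config + seed
  for (f in c("results.csv", "prevalence.csv", "deaths.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  expect_setequal(res1$results$label,
                  c("any_mental:male", "any_mental:female"))
  expect_true(all(c("total", cause_taxonomy("grouped")$labels) %in%
                    res1$results$cause))
  # sex separation: the male row equals a male-only bootstrap run
  recs <- res1$records
  male <- bootstrap_ci(recs[recs$sex == "male", ], "any_mental",
                       cause_taxonomy("grouped"), B = 25, seed = 6)
  got <- res1$results[res1$results$label == "any_mental:male" &
                        res1$results$cause == "total", ]
  expect_equal(got$estimate, male$point$pooled$delta_total, tolerance = 1e-12)
  expect_equal(got$ci_low, unname(male$ci["low", "total"]), tolerance = 1e-12)
})

test_that("study windows in the pipeline only change window-dependent output", {
  base <- list(simulate = list(n_subjects = 1200), groups = "any_mental",
               taxonomy = "grouped", sexes = "male", seed = 8,
               bootstrap = list(B = 10, seed = 8))
  with_window <- base
  with_window$study_window <- list(open = "2011-01-01", close = "2020-03-01")
  r0 <- run_pipeline(base)
  r1 <- run_pipeline(with_window)
  expect_true(all(r1$records$exit_date <= as.Date("2020-03-01")))
  expect_lte(nrow(r1$records), nrow(r0$records))
  # a window wider than the data changes nothing
  wide <- base
  wide$study_window <- list(open = "2000-01-01", close = "2040-01-01")
  r2 <- run_pipeline(wide)
  expect_equal(r2$results$estimate, r0$results$estimate, tolerance = 1e-12)
})

test_that("pipeline configs are validated exhaustively before running", {
  err <- tryCatch(run_pipeline(list(groups = "psychosis", taxonomy = "nope",
                                    simulate = list(n_subjects = 10),
                                    bootstrap = list(B = 0))),
                  error = conditionMessage)
  expect_match(err, "unknown disorder group")
  expect_match(err, "unknown taxonomy")
  expect_match(err, "bootstrap B")
})
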