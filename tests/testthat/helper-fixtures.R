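# Shared fixtures, built in code.

# Five-episode worked example with hand-computed product-limit values:
# risk sets 5, 3, 1 at death ages 40, 45, 60.
worked_episodes <- function() {
  data.frame(
    subject_id = as.character(1:5),
    enter = c(30, 30, 35, 38, 32),
    exit = c(40, 50, 45, 60, 44),
    status = c("death", "censored", "death", "death", "censored"),
    cause = c("X", NA, "Y", "X", NA),
    stringsAsFactors = FALSE
  )
}

# Minimal subject-record constructor in the package schema.
make_records <- function(entry, exit, event = "censored", sex = "male",
                         stratum = "all", death_icd = NA_character_,
                         cd4 = NA_real_, entry_date = as.Date("2012-01-01"),
                         dx = list()) {
  n <- length(entry)
  rec <- data.frame(
    subject_id = sprintf("p%03d", seq_len(n)),
    sex = rep_len(sex, n), stratum_id = rep_len(stratum, n),
    entry_age = entry, exit_age = exit, event = rep_len(event, n),
    death_icd = rep_len(death_icd, n), cd4_at_death = rep_len(cd4, n),
    entry_date = rep_len(entry_date, n),
    stringsAsFactors = FALSE
  )
  rec$exit_date <- rec$entry_date + round((exit - entry) * 365.25)
  for (g in disorder_groups()) rec[[paste0("dx_age_", g)]] <- NA_real_
  for (g in names(dx)) rec[[paste0("dx_age_", g)]] <- dx[[g]]
  rec
}

# Constant-hazard recovery scenario: everyone enters at age 45, half carry a
# prevalent diagnosis (exposed, all-cause hazard 0.05/yr in two causes),
# half are never diagnosed (0.02/yr); no dropout, no administrative
# censoring before age 85. Analytic excess LYL = 10.24026 years.
const_scenario <- function(n, seed) {
  sim_config(
    n_subjects = n, seed = seed,
    entry_age = list(dist = "fixed", age = 45),
    prevalent_prob = 0.5, lambda_dx = 0, dropout = 0,
    hazards_unexposed = c(natural_cd4_ge350 = 0.005, natural_cd4_lt200 = 0.015),
    hazards_exposed = c(natural_cd4_ge350 = 0.0125, natural_cd4_lt200 = 0.0375),
    calendar_open = "1975-01-01", enrollment_close = "1980-01-01",
    calendar_close = "2030-01-01"
  )
}

# Random small episode table for property tests (left truncation, censoring,
# several causes).
random_episodes <- function(n, causes = c("A", "B"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enter <- runif(n, 25, 55)
  exit <- enter + rexp(n, 0.15) + 0.05
  status <- sample(c("death", "censored"), n, replace = TRUE, prob = c(0.6, 0.4))
  data.frame(
    subject_id = as.character(seq_len(n)), enter = enter, exit = exit,
    status = status,
    cause = ifelse(status == "death",
                   sample(causes, n, replace = TRUE), NA_character_),
    stringsAsFactors = FALSE
  )
}

# Random subject-record table exercising prevalent/incident diagnoses,
# competing causes and strata.
random_records <- function(n, seed = NULL, strata = c("s1", "s2")) {
  if (!is.null(seed)) set.seed(seed)
  entry <- runif(n, 20, 60)
  fu <- rexp(n, 0.08) + 0.1
  exit <- pmin(entry + fu, 85)
  dead <- runif(n) < 0.35 & exit < 85
  icd_pool <- c("B24", "C50.1", "I21.9", "X70", "X95", "W13", "X64", NA)
  icd <- ifelse(dead, sample(icd_pool, n, replace = TRUE), NA)
  cd4 <- ifelse(dead & runif(n) < 0.8, runif(n, 10, 900), NA)
  rec <- make_records(entry, exit, event = ifelse(dead, "death", "censored"),
                      sex = sample(c("male", "female"), n, replace = TRUE),
                      stratum = sample(strata, n, replace = TRUE),
                      death_icd = icd, cd4 = cd4)
  has_dx <- runif(n) < 0.55
  dx_any <- ifelse(has_dx, pmax(entry + runif(n, -8, 0.9 * (exit - entry)), 18), NA)
  rec$dx_age_any_mental <- dx_any
  has_dep <- has_dx & runif(n) < 0.6
  rec$dx_age_depressive <- ifelse(has_dep, pmin(dx_any + rexp(n, 0.5), 84.9), NA)
  rec
}
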