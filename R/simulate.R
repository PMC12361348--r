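# Representative ICD-10 codes emitted per simulated cause of death, chosen so
# that classify_death() round-trips each category.
SIM_CAUSE_CODES <- list(
  natural_cd4_lt200 = "B24", natural_cd4_200_349 = "C34.9",
  natural_cd4_ge350 = "I21.9", natural_cd4_unknown = "J18.9",
  suicide = "X70", homicide = "X95", accident = "W13",
  unnatural_other = "X64", unknown_cause = NA_character_
)

#' Configuration of the illness-death cohort simulator
#'
#' Parameterizes an illness-death model with competing causes of death:
#' subjects enter at an entry age and calendar date, acquire a first
#' mental-disorder diagnosis with hazard `lambda_dx` (or carry a prevalent
#' diagnosis from before entry), and die from competing causes whose hazards
#' switch from `hazards_unexposed` to `hazards_exposed` at diagnosis, subject
#' to constant dropout and administrative closing. Defaults define the
#' package's desk-scale scenario: n = 5000, entry ages uniform on 18-60,
#' diagnosis hazard 0.08/year, prevalent probability 0.15, unexposed
#' cause-specific hazards (natural <200: 0.004, natural 200-349: 0.002,
#' natural >=350: 0.004, unnatural: 0.002) per year, exposed hazards 1.8x
#' natural and 3x unnatural, dropout 0.05/year, cutoff 85 - chosen to yield
#' excess LYL of a few years at realistic event counts.
#'
#' @param n_subjects Number of subjects.
#' @param seed Default seed used by [simulate_cohort()].
#' @param entry_age List: `list(dist = "uniform", min=, max=)`,
#'   `list(dist = "truncnorm", mean=, sd=, min=, max=)` or
#'   `list(dist = "fixed", age=)`.
#' @param sex_mix Named probabilities for `male`/`female`.
#' @param strata Data frame with columns `id`, `prob`, `multiplier`
#'   (multiplier scales all death hazards in that stratum).
#' @param prevalent_prob Probability of a diagnosis carried from before entry.
#' @param lambda_dx Diagnosis hazard per year: a constant, or
#'   `list(breaks=, rates=)` for a piecewise-constant hazard in age
#'   (`rates` has one more element than `breaks`).
#' @param hazards_unexposed,hazards_exposed Named per-cause death hazards
#'   (names from the detailed or grouped cause labels; "unnatural" is drawn
#'   across representative sub-cause codes). Each element is a constant or
#'   `list(a=, b=)` for a Gompertz hazard a*exp(b*age). `hazards_exposed =
#'   NULL` derives exposed hazards from the multipliers.
#' @param hr_natural,hr_unnatural Exposed/unexposed hazard ratios used when
#'   `hazards_exposed` is NULL (applied to natural and unnatural/unknown
#'   causes respectively).
#' @param dropout Constant censoring hazard per year.
#' @param calendar_open,calendar_close Administrative study window.
#' @param enrollment_close Last calendar date of enrollment (entry dates are
#'   drawn uniformly on `[calendar_open, enrollment_close)`); defaults to
#'   `calendar_close`. Set it earlier to guarantee a minimum potential
#'   follow-up for every subject.
#' @param cutoff Maximum age (followed to the cutoff birthday).
#' @param dx_code_probs Named probabilities of the ICD-10 code assigned to
#'   the first diagnosis (all must map into `any_mental`).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5000, seed = 1L,
                       entry_age = list(dist = "uniform", min = 18, max = 60),
                       sex_mix = c(male = 0.5, female = 0.5),
                       strata = data.frame(id = "main", prob = 1, multiplier = 1),
                       prevalent_prob = 0.15,
                       lambda_dx = 0.08,
                       hazards_unexposed = c(natural_cd4_lt200 = 0.004,
                                             natural_cd4_200_349 = 0.002,
                                             natural_cd4_ge350 = 0.004,
                                             unnatural = 0.002),
                       hazards_exposed = NULL,
                       hr_natural = 1.8, hr_unnatural = 3,
                       dropout = 0.05,
                       calendar_open = "2011-01-01",
                       calendar_close = "2021-01-26",
                       enrollment_close = NULL,
                       cutoff = 85,
                       dx_code_probs = c("F32.9" = 0.40, "F41.2" = 0.30,
                                         "F10.2" = 0.15, "F20.9" = 0.10,
                                         "F31.9" = 0.05)) {
  if (is.null(hazards_exposed)) {
    hazards_exposed <- lapply(stats::setNames(names(hazards_unexposed),
                                              names(hazards_unexposed)),
      function(nm) {
        hr <- if (startsWith(nm, "natural")) hr_natural else hr_unnatural
        scale_hazard(hazards_unexposed[[nm]], hr)
      })
    if (all(vapply(hazards_exposed, is.numeric, logical(1))))
      hazards_exposed <- unlist(hazards_exposed)
  }
  cfg <- structure(list(
    n_subjects = n_subjects, seed = seed, entry_age = entry_age,
    sex_mix = sex_mix, strata = strata, prevalent_prob = prevalent_prob,
    lambda_dx = lambda_dx, hazards_unexposed = as.list(hazards_unexposed),
    hazards_exposed = as.list(hazards_exposed), dropout = dropout,
    calendar_open = as.Date(calendar_open),
    calendar_close = as.Date(calendar_close),
    enrollment_close = as.Date(enrollment_close %||% calendar_close),
    cutoff = cutoff, dx_code_probs = dx_code_probs
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

scale_hazard <- function(h, f) {
  if (is.numeric(h)) h * f else list(a = h$a * f, b = h$b)
}

hazard_is_constant <- function(h) is.numeric(h) && length(h) == 1L

validate_sim_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  chk(cfg$prevalent_prob >= 0 && cfg$prevalent_prob <= 1,
      "prevalent_prob must be a probability")
  chk(abs(sum(cfg$sex_mix) - 1) < 1e-9, "sex_mix must sum to 1")
  chk(abs(sum(cfg$strata$prob) - 1) < 1e-9, "strata probabilities must sum to 1")
  chk(all(cfg$strata$multiplier >= 0), "strata multipliers must be >= 0")
  chk(cfg$dropout >= 0, "dropout hazard must be >= 0")
  for (set in c("hazards_unexposed", "hazards_exposed")) {
    hz <- cfg[[set]]
    chk(length(hz) > 0, paste(set, "must be nonempty"))
    for (nm in names(hz)) {
      h <- hz[[nm]]
      ok <- (hazard_is_constant(h) && h >= 0) ||
        (is.list(h) && all(c("a", "b") %in% names(h)) && h$a >= 0)
      chk(ok, paste0("invalid hazard ", set, "$", nm))
    }
    tot <- sum(vapply(hz, function(h) if (is.numeric(h)) h else h$a, numeric(1)))
    chk(tot > 0, paste("total death hazard must be positive in", set))
  }
  if (is.list(cfg$lambda_dx))
    chk(length(cfg$lambda_dx$rates) == length(cfg$lambda_dx$breaks) + 1 &&
          all(cfg$lambda_dx$rates >= 0), "invalid piecewise lambda_dx")
  else chk(cfg$lambda_dx >= 0, "lambda_dx must be >= 0")
  chk(identical(names(cfg$hazards_unexposed), names(cfg$hazards_exposed)),
      "exposed and unexposed hazards must name the same causes")
  chk(cfg$calendar_open < cfg$calendar_close, "calendar window must be nonempty")
  chk(cfg$calendar_open < cfg$enrollment_close &&
        cfg$enrollment_close <= cfg$calendar_close,
      "enrollment_close must lie inside the calendar window")
  if (length(errs)) stop("invalid simulator config:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(cfg)
}

# Event-time draw from age x0 with a constant or Gompertz a*exp(b*age)
# hazard, scaled by `mult`, via inversion of the cumulative hazard.
draw_event_time <- function(h, x0, mult = 1) {
  n <- length(x0)
  u <- stats::rexp(n)
  if (hazard_is_constant(h)) {
    rate <- h * mult
    return(if (all(rate == 0)) rep(Inf, n) else ifelse(rate > 0, u / rate, Inf))
  }
  a <- h$a * mult; b <- h$b
  if (b == 0) return(ifelse(a > 0, u / a, Inf))
  # H(t) = a/b (exp(b(x0+t)) - exp(b x0)) = u  =>  closed-form inverse
  arg <- exp(b * x0) + b * u / a
  ifelse(a > 0 & arg > 0, log(arg) / b - x0, Inf)
}

# Diagnosis waiting time from entry age x0 for constant or piecewise-constant
# (in age) diagnosis hazard.
draw_dx_time <- function(lambda, x0, cutoff) {
  n <- length(x0)
  u <- stats::rexp(n)
  if (!is.list(lambda))
    return(if (lambda == 0) rep(Inf, n) else u / lambda)
  breaks <- c(lambda$breaks, Inf)
  rates <- lambda$rates
  out <- rep(Inf, n)
  for (i in seq_len(n)) {
    age <- x0[i]; H <- u[i]
    repeat {
      j <- findInterval(age, lambda$breaks) + 1L
      seg_end <- breaks[j]
      r <- rates[j]
      if (r > 0 && H <= r * (seg_end - age)) { out[i] <- age + H / r - x0[i]; break }
      if (!is.finite(seg_end)) break
      H <- H - r * (seg_end - age)
      age <- seg_end
    }
  }
  out
}

#' Simulate a subject-level cohort from an illness-death model
#'
#' Draws, per subject: sex, stratum, entry age and calendar entry date;
#' a prevalent diagnosis or an incident first-diagnosis time; competing
#' cause-specific death times with the hazard set switching at diagnosis;
#' dropout; and administrative censoring at the calendar closing date or the
#' cutoff birthday. Deaths receive a representative ICD-10 code and a CD4
#' count consistent with their cause band, so the record round-trips
#' [classify_death()]. Fully reproducible under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Subject records in the package schema (see [load_cohort()]),
#'   validated, with diagnosis-age columns for all groups implied by the
#'   assigned diagnosis codes.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_subjects
  sex <- sample(names(config$sex_mix), n, replace = TRUE, prob = config$sex_mix)
  si <- sample.int(nrow(config$strata), n, replace = TRUE, prob = config$strata$prob)
  stratum <- as.character(config$strata$id[si])
  mult <- config$strata$multiplier[si]

  ea <- config$entry_age
  E <- switch(ea$dist,
    uniform = stats::runif(n, ea$min, ea$max),
    fixed = rep(ea$age, n),
    truncnorm = {
      lo <- stats::pnorm(ea$min, ea$mean, ea$sd)
      hi <- stats::pnorm(ea$max, ea$mean, ea$sd)
      stats::qnorm(stats::runif(n, lo, hi), ea$mean, ea$sd)
    },
    stop("unknown entry age distribution: ", ea$dist))

  span <- as.numeric(config$enrollment_close - config$calendar_open)
  entry_date <- config$calendar_open + floor(stats::runif(n, 0, span))
  max_fu <- pmin(as.numeric(config$calendar_close - entry_date) / DAYS_PER_YEAR,
                 config$cutoff - E)

  prevalent <- stats::runif(n) < config$prevalent_prob
  t_dx <- rep(0, n)
  t_dx[!prevalent] <- draw_dx_time(config$lambda_dx, E[!prevalent], config$cutoff)

  causes <- names(config$hazards_unexposed)
  draw_phase <- function(hz, x0, mult) {
    tm <- vapply(causes, function(c_) draw_event_time(hz[[c_]], x0, mult),
                 numeric(length(x0)))
    if (length(x0) == 1) tm <- matrix(tm, 1, dimnames = list(NULL, causes))
    tm
  }
  t0 <- draw_phase(config$hazards_unexposed, E, mult)
  t0_min <- do.call(pmin, as.data.frame(t0))
  t0_cause <- causes[max.col(-t0, ties.method = "first")]
  t_drop <- if (config$dropout > 0) stats::rexp(n) / config$dropout else rep(Inf, n)

  # unexposed phase outcome (before any diagnosis)
  end0 <- pmin(t0_min, t_drop, max_fu)
  becomes_exposed <- (prevalent | t_dx < end0) & t_dx < max_fu

  exit_rel <- end0
  event <- ifelse(end0 == t0_min, "death", "censored")
  cause <- ifelse(end0 == t0_min, t0_cause, NA_character_)

  # exposed phase for prevalent subjects and incident converts
  idx <- which(becomes_exposed)
  if (length(idx)) {
    A <- E[idx] + t_dx[idx]
    t1 <- draw_phase(config$hazards_exposed, A, mult[idx])
    t1_min <- do.call(pmin, as.data.frame(t1))
    t1_cause <- causes[max.col(-t1, ties.method = "first")]
    rem <- pmin(t_drop[idx] - t_dx[idx], max_fu[idx] - t_dx[idx])
    end1 <- pmin(t1_min, rem)
    exit_rel[idx] <- t_dx[idx] + end1
    event[idx] <- ifelse(end1 == t1_min, "death", "censored")
    cause[idx] <- ifelse(end1 == t1_min, t1_cause, NA_character_)
  }

  exit_age <- E + pmax(exit_rel, 1e-6)   # guard zero-length follow-up
  dead <- event == "death"

  death_icd <- rep(NA_character_, n)
  cd4 <- rep(NA_real_, n)
  if (any(dead)) {
    cz <- cause[dead]
    unnat_codes <- c("X70", "X95", "W13", "X64")
    code <- vapply(cz, function(c_) {
      if (c_ == "unnatural") sample(unnat_codes, 1)
      else if (!is.null(SIM_CAUSE_CODES[[c_]])) SIM_CAUSE_CODES[[c_]]
      else NA_character_
    }, character(1))
    death_icd[dead] <- code
    nd <- sum(dead)
    cd4[dead] <- ifelse(cz == "natural_cd4_lt200", stats::runif(nd, 10, 199),
                 ifelse(cz == "natural_cd4_200_349", stats::runif(nd, 200, 349),
                 ifelse(cz == "natural_cd4_ge350", stats::runif(nd, 350, 1200),
                        NA_real_)))
  }

  rec <- data.frame(
    subject_id = sprintf("s%06d", seq_len(n)),
    sex = sex, stratum_id = stratum,
    entry_age = E, exit_age = exit_age, event = event,
    death_icd = death_icd, cd4_at_death = cd4,
    entry_date = entry_date,
    exit_date = entry_date + round((exit_age - E) * DAYS_PER_YEAR),
    stringsAsFactors = FALSE
  )

  diagnosed <- prevalent | becomes_exposed
  dx_age <- rep(NA_real_, n)
  dx_age[prevalent] <- E[prevalent] -
    stats::runif(sum(prevalent), 0, pmin(10, pmax(E[prevalent] - 18, 0)))
  inc <- diagnosed & !prevalent
  dx_age[inc] <- E[inc] + t_dx[inc]
  dx_code <- rep(NA_character_, n)
  dx_code[diagnosed] <- sample(names(config$dx_code_probs), sum(diagnosed),
                               replace = TRUE, prob = config$dx_code_probs)
  for (g in disorder_groups()) rec[[dx_col(g)]] <- NA_real_
  if (any(diagnosed)) {
    mem <- disorder_membership(dx_code[diagnosed])
    for (g in disorder_groups())
      rec[[dx_col(g)]][diagnosed][mem[, g]] <- dx_age[diagnosed][mem[, g]]
  }
  validate_cohort(rec, cutoff = config$cutoff)
}
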