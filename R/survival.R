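# Number at risk at each age in `at`: episodes with enter < t <= exit.
# O((n+m) log n) via sorted entry/exit vectors.
risk_set_sizes <- function(enter, exit, at) {
  se <- sort(enter); sx <- sort(exit)
  n_entered <- findInterval(at, se, left.open = TRUE)   # enter <  t
  n_left <- findInterval(at, sx, left.open = TRUE)      # exit  <  t
  n_entered - n_left
}

#' Left-truncated Kaplan-Meier estimator on the age timescale
#'
#' Product-limit estimate with delayed entry: the risk set at age t contains
#' episodes with enter < t <= exit (half-open intervals), so subjects enter
#' the risk set only from their entry age and deaths at t are processed
#' before censorings at the same age. Jumps occur only at death ages; with
#' all-censored input the curve is flat at 1.
#'
#' @param episodes Data frame with columns `enter`, `exit`, `status`
#'   ("death"/"censored"); typically from [split_exposure_episodes()].
#' @return Object of class `lyl_km`: list with `start` (earliest entry age),
#'   `time` (death ages), `n_risk`, `n_event`, `surv`, `n_episodes`,
#'   `max_exit`.
#' @export
km_left_truncated <- function(episodes) {
  stopifnot(nrow(episodes) > 0, all(episodes$enter < episodes$exit))
  death <- episodes$status == "death"
  dt <- sort(unique(episodes$exit[death]))
  n_risk <- risk_set_sizes(episodes$enter, episodes$exit, dt)
  n_event <- as.integer(table(factor(episodes$exit[death], levels = dt)))
  if (any(n_risk < n_event) || any(n_risk <= 0 & n_event > 0))
    stop("empty or deficient risk set at a death age")
  surv <- cumprod(1 - n_event / pmax(n_risk, 1))
  structure(list(start = min(episodes$enter), time = dt, n_risk = n_risk,
                 n_event = n_event, surv = surv,
                 n_episodes = nrow(episodes), max_exit = max(episodes$exit)),
            class = "lyl_km")
}

#' Aalen-Johansen cause-specific cumulative incidence
#'
#' Computes, on the same risk sets as [km_left_truncated()], the cumulative
#' incidence function of each cause: F_c(t) = sum over death ages u <= t of
#' S(u-) d_c(u) / n(u). The overall survival curve is carried alongside so
#' that the conservation identity sum_c F_c(t) + S(t) = 1 holds at every
#' event age.
#'
#' @param episodes Episode table; every death must carry a `cause` label.
#' @param causes Cause labels defining the column order; defaults to the
#'   labels observed. Supply `taxonomy$labels` for a fixed order.
#' @return Object of class `lyl_cif` extending `lyl_km` with `causes`,
#'   `cif` (matrix: death ages x causes) and `n_event_cause`.
#' @export
cause_specific_cif <- function(episodes, causes = NULL) {
  death <- episodes$status == "death"
  if (any(death & (is.na(episodes$cause) | !nzchar(episodes$cause)))) {
    bad <- episodes$subject_id[death & is.na(episodes$cause)]
    stop("death without a cause label for subject(s): ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  km <- km_left_truncated(episodes)
  if (is.null(causes)) causes <- sort(unique(episodes$cause[death]))
  m <- length(km$time)
  d_c <- matrix(0L, m, length(causes), dimnames = list(NULL, causes))
  if (m > 0 && any(death)) {
    tab <- table(factor(episodes$exit[death], levels = km$time),
                 factor(episodes$cause[death], levels = causes))
    d_c <- matrix(as.integer(tab), m, length(causes), dimnames = list(NULL, causes))
  }
  if (m == 0) {
    cif <- matrix(numeric(0), 0, length(causes), dimnames = list(NULL, causes))
  } else {
    s_minus <- c(1, km$surv)[seq_len(m)]
    inc <- d_c / pmax(km$n_risk, 1) * s_minus
    cif <- apply(inc, 2, cumsum)
    if (m == 1) cif <- matrix(cif, 1, length(causes), dimnames = list(NULL, causes))
  }
  km$causes <- causes
  km$cif <- cif
  km$n_event_cause <- d_c
  class(km) <- c("lyl_cif", "lyl_km")
  km
}

#' Evaluate a survival curve or CIF set at arbitrary ages
#'
#' Right-continuous step evaluation. Ages before the curve start give `NA`;
#' beyond the last jump the last value is carried forward (constant-tail
#' rule).
#'
#' @param curve A `lyl_km` or `lyl_cif` object.
#' @param t Ages.
#' @return `surv_at`: numeric vector of survival probabilities. `cif_at`:
#'   matrix (ages x causes) of cumulative incidences.
#' @export
surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  out <- c(1, curve$surv)[idx + 1L]
  out[t < curve$start] <- NA_real_
  out
}

#' @rdname surv_at
#' @export
cif_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  vals <- rbind(rep(0, length(curve$causes)), curve$cif)
  out <- vals[idx + 1L, , drop = FALSE]
  out[t < curve$start, ] <- NA_real_
  dimnames(out) <- list(NULL, curve$causes)
  out
}

#' Condition a survival curve or CIF set on being alive at an age
#'
#' Returns the curve seen from age `a`: S(t|a) = S(t)/S(a) and
#' F_c(t|a) = (F_c(t) - F_c(a))/S(a) for t >= a. Conservation is preserved.
#'
#' @param x A `lyl_km` or `lyl_cif` object.
#' @param a Conditioning age; requires S(a) > 0 and a within the curve's
#'   support (at or after its start).
#' @return An object of the same class starting at `a`.
#' @export
condition_at <- function(x, a) {
  UseMethod("condition_at")
}

#' @export
condition_at.lyl_km <- function(x, a) {
  if (a < x$start) stop("no risk information at age ", a)
  sa <- surv_at(x, a)
  if (is.na(sa) || sa <= 0) stop("no risk information at age ", a, " (S(a) = 0)")
  keep <- x$time > a
  out <- x
  out$start <- a
  out$time <- x$time[keep]
  out$n_risk <- x$n_risk[keep]
  out$n_event <- x$n_event[keep]
  out$surv <- x$surv[keep] / sa
  if (inherits(x, "lyl_cif")) {
    fa <- cif_at(x, a)
    out$cif <- sweep(x$cif[keep, , drop = FALSE], 2, as.numeric(fa)) / sa
    out$n_event_cause <- x$n_event_cause[keep, , drop = FALSE]
  }
  out
}

#' @export
print.lyl_km <- function(x, ...) {
  cat("Left-truncated ", if (inherits(x, "lyl_cif")) "Aalen-Johansen" else "Kaplan-Meier",
      " curve: start age ", format(x$start), ", ", length(x$time),
      " death ages, ", x$n_episodes, " episodes\n", sep = "")
  invisible(x)
}

#' Tidy export of a survival curve or CIF set
#'
#' @param x A `lyl_km` or `lyl_cif` object.
#' @param row.names,optional Unused (method signature).
#' @param ... Unused.
#' @return Data frame with `age`, `n_risk`, `n_event`, `S` and, for CIF
#'   sets, one `F_<cause>` column per cause.
#' @export
as.data.frame.lyl_km <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(age = x$time, n_risk = x$n_risk, n_event = x$n_event,
                    S = x$surv)
  if (inherits(x, "lyl_cif")) {
    cif <- as.data.frame(x$cif)
    names(cif) <- paste0("F_", x$causes)
    out <- cbind(out, cif)
  }
  out
}
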