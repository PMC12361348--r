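# Internal vectorized engine for bootstrap replicates.
#
# Re-running episode splitting -> curves -> excess LYL -> pooling hundreds of
# times dominates the bootstrap cost, so the replicate path works on plain
# pre-extracted vectors instead of data-frame rows. Semantics are identical
# to split_exposure_episodes() + cause_specific_cif() + excess_lyl() +
# pooled_excess_lyl(); a regression test asserts the identity-resample
# replicate reproduces analyze_group() exactly.

cif_core <- function(enter, exit, isd, cid, k) {
  dt <- sort(unique(exit[isd]))
  m <- length(dt)
  n_risk <- risk_set_sizes(enter, exit, dt)
  if (m > 0) {
    idx_t <- match(exit[isd], dt)
    d_c <- matrix(tabulate((cid[isd] - 1L) * m + idx_t, nbins = m * k), m, k)
    n_event <- rowSums(d_c)
    if (any(n_risk < n_event)) stop("deficient risk set")
    surv <- cumprod(1 - n_event / n_risk)
    s_minus <- c(1, surv)[seq_len(m)]
    inc <- d_c * (s_minus / n_risk)
    cif <- inc
    for (j in seq_len(k)) cif[, j] <- cumsum(inc[, j])
  } else {
    surv <- numeric(0)
    cif <- matrix(numeric(0), 0, k)
  }
  structure(list(start = min(enter), time = dt, surv = surv, cif = cif,
                 max_exit = max(exit)),
            class = c("lyl_cif", "lyl_km"))
}

# Excess LYL between two cif_core objects at the exposed onset ages;
# returns c(n_valid, total, per-cause) or NULL when no valid onset age.
excess_core <- function(ex, un, onset, tau, k) {
  ok <- onset < tau &
    onset >= ex$start & onset >= un$start
  if (any(ok)) {
    se <- surv_at(ex, onset[ok]); su <- surv_at(un, onset[ok])
    ok[ok] <- !is.na(se) & se > 0 & !is.na(su) & su > 0
  }
  if (!any(ok)) return(NULL)
  a <- onset[ok]
  ex$causes <- seq_len(k); un$causes <- seq_len(k)   # lyl_eval needs a cause list
  le <- lyl_eval(ex, a, tau)
  lu <- lyl_eval(un, a, tau)
  c(length(a), mean(le$total - lu$total), colMeans(le$by_cause - lu$by_cause))
}

make_boot_engine <- function(records, group, taxonomy, tau, comparator) {
  if (is.null(records$cause_category))
    records <- add_cause_category(records, taxonomy)
  k <- length(taxonomy$labels)
  cid <- match(records$cause_category, taxonomy$labels)
  e <- records$entry_age; x <- records$exit_age
  dead <- records$event == "death"
  n <- nrow(records)
  ga <- if (dx_col(group) %in% names(records)) records[[dx_col(group)]] else rep(NA_real_, n)
  ca <- if (dx_col(comparator) %in% names(records)) records[[dx_col(comparator)]] else rep(NA_real_, n)
  ca <- pmin(ca, ga, na.rm = TRUE)
  ca_inf <- ifelse(is.na(ca), Inf, ca)
  strata_idx <- split(seq_len(n), records$stratum_id)

  run <- function(resample = TRUE) {
    tot <- 0; bc <- numeric(k); wsum <- 0
    for (ii in strata_idx) {
      idx <- if (resample) ii[sample.int(length(ii), length(ii), replace = TRUE)] else ii
      es <- e[idx]; xs <- x[idx]; ds <- dead[idx]; cs <- cid[idx]
      gas <- ga[idx]; cas <- ca_inf[idx]
      u_end <- pmin(cas, xs)
      sel_u <- u_end > es
      sel_e <- !is.na(gas) & gas < xs
      if (!any(sel_u) || !any(sel_e)) next
      du <- ds[sel_u] & u_end[sel_u] >= xs[sel_u]
      un <- cif_core(es[sel_u], u_end[sel_u], du, cs[sel_u], k)
      onset <- pmax(es[sel_e], gas[sel_e])
      ex <- cif_core(onset, xs[sel_e], ds[sel_e], cs[sel_e], k)
      res <- excess_core(ex, un, onset, tau, k)
      if (is.null(res)) next
      w <- res[1]
      tot <- tot + w * res[2]
      bc <- bc + w * res[-(1:2)]
      wsum <- wsum + w
    }
    if (wsum == 0) return(NULL)
    stats::setNames(c(tot, bc) / wsum, c("total", taxonomy$labels))
  }
  run
}
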