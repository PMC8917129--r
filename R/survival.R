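# Kaplan-Meier survival with log-rank tests and evaporation-corrected
# per-bee food consumption.

#' Kaplan-Meier product-limit survival curve
#'
#' @param deaths integer deaths per day (days `1..horizon`).
#' @param initial_n bees at risk at day 0.
#' @param horizon administrative censoring day (defaults to
#'   `length(deaths)`).
#' @return data frame `day`, `at_risk`, `deaths`, `surv` with
#'   `surv = prod(1 - d_i/n_i)` over event days.
#' @export
kaplan_meier <- function(deaths, initial_n, horizon = length(deaths)) {
  deaths <- deaths[seq_len(horizon)]
  at_risk <- initial_n - cumsum(c(0, deaths[-horizon]))
  if (any(deaths > at_risk))
    stop("deaths exceed the number at risk on day ",
         which(deaths > at_risk)[1])
  surv <- cumprod(1 - deaths / pmax(at_risk, 1))
  surv[at_risk == 0] <- 0
  data.frame(day = seq_len(horizon), at_risk = at_risk,
             deaths = deaths, surv = surv)
}

# expand an aggregated survival log to per-bee event times with
# administrative censoring at the horizon
expand_events <- function(deaths, initial_n, horizon = length(deaths)) {
  times <- rep(seq_len(horizon), deaths[seq_len(horizon)])
  status <- rep(1L, length(times))
  surviving <- initial_n - sum(deaths[seq_len(horizon)])
  if (surviving > 0) {
    times <- c(times, rep(horizon, surviving))
    status <- c(status, rep(0L, surviving))
  }
  data.frame(time = times, status = status)
}

logrank_chisq <- function(time, status, group) {
  group <- as.character(group)
  lev <- sort(unique(group))
  k <- length(lev)
  ev_times <- sort(unique(time[status == 1]))
  O <- E <- stats::setNames(rep(0, k), lev)
  V <- matrix(0, k, k, dimnames = list(lev, lev))
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(status == 1 & time == t)
    ng <- vapply(lev, function(g) sum(at_risk & group == g), numeric(1))
    dg <- vapply(lev, function(g) sum(at_risk & group == g &
                                        status == 1 & time == t), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(ng / n, k) - tcrossprod(ng / n))
    }
  }
  if (sum(O) == 0)
    return(list(statistic = 0, df = k - 1L, p = 1, degenerate = TRUE))
  u <- (O - E)[-k]
  vsub <- V[-k, -k, drop = FALSE]
  qv <- tryCatch(solve(vsub, u), error = function(e) NULL)
  if (is.null(qv))
    return(list(statistic = 0, df = k - 1L, p = 1, degenerate = TRUE))
  x2 <- sum(u * qv)
  list(statistic = x2, df = k - 1L,
       p = stats::pchisq(x2, k - 1, lower.tail = FALSE), degenerate = FALSE)
}

#' Log-rank test with pairwise post hoc comparisons
#'
#' Mantel-Cox observed-versus-expected chi-square across pooled event
#' times, with pairwise log-rank tests adjusted by Benjamini-Hochberg.
#'
#' @param time event or censoring times.
#' @param status 1 = death, 0 = censored.
#' @param group group labels.
#' @return a `beegut_test` with a `posthoc` table attached.
#' @export
logrank <- function(time, status, group) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) < 2) stop("need at least two groups")
  main <- logrank_chisq(time, status, group)
  res <- new_test_result(main$statistic, main$p, main$df, "Log-rank",
                         degenerate = main$degenerate)
  pairs <- utils::combn(lev, 2)
  praw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    sel <- group %in% pairs[, j]
    praw[j] <- logrank_chisq(time[sel], status[sel], group[sel])$p
  }
  res$posthoc <- new_posthoc_table(pairs[1, ], pairs[2, ], NA_real_, praw,
                                   adjust_p(praw, "benjamini-hochberg"),
                                   "benjamini-hochberg")
  res
}

#' Evaporation-corrected per-bee consumption series
#'
#' Daily feeder mass changes are corrected by the mean evaporation-control
#' change of the same day, divided by the number of bees alive at the start
#' of the day, and accumulated into a per-bee running total. Negative
#' corrected values are clipped to 0 with a warning.
#'
#' @param feeder_log data frame `cage`, `day`, `mass_change` for bee cages
#'   (rows with `role == "evaporation"` are treated as controls if no
#'   separate `evaporation_log` is given).
#' @param evaporation_log optional data frame `day`, `mass_change`.
#' @param survival_log data frame `cage`, `day`, `deaths`, `alive`.
#' @return data frame per cage and day: `raw`, `evaporation`, `consumed`,
#'   `alive_start`, `per_bee`, `cumulative_per_bee`.
#' @export
consumption_series <- function(feeder_log, evaporation_log = NULL,
                               survival_log) {
  if (is.null(evaporation_log) && "role" %in% names(feeder_log)) {
    evaporation_log <- feeder_log[feeder_log$role == "evaporation", ]
    feeder_log <- feeder_log[feeder_log$role == "feeder", ]
  }
  if (is.null(evaporation_log) || !nrow(evaporation_log))
    stop("an evaporation-control series is required")
  evap_day <- tapply(evaporation_log$mass_change, evaporation_log$day, mean)
  out <- list(); clipped <- 0
  for (cage in unique(feeder_log$cage)) {
    f <- feeder_log[feeder_log$cage == cage, ]
    s <- survival_log[survival_log$cage == cage, ]
    f <- f[order(f$day), ]; s <- s[order(s$day), ]
    days <- f$day
    if (!identical(as.integer(days), seq_len(length(days))) ||
        !identical(as.integer(s$day), as.integer(days)))
      stop("missing or misaligned days for cage ", cage, ": have ",
           paste(days, collapse = ","))
    alive_start <- c(s$alive[1] + s$deaths[1],
                     if (nrow(s) > 1) s$alive[-nrow(s)])
    ev <- as.numeric(evap_day[as.character(days)])
    if (any(is.na(ev))) stop("evaporation control missing for day(s) ",
                             paste(days[is.na(ev)], collapse = ","))
    consumed <- f$mass_change - ev
    clipped <- clipped + sum(consumed < 0)
    consumed <- pmax(consumed, 0)
    per_bee <- ifelse(alive_start > 0, consumed / alive_start, 0)
    out[[cage]] <- data.frame(cage = cage, day = days, raw = f$mass_change,
                              evaporation = ev, consumed = consumed,
                              alive_start = alive_start, per_bee = per_bee,
                              cumulative_per_bee = cumsum(per_bee),
                              stringsAsFactors = FALSE)
  }
  if (clipped > 0)
    warning(clipped, " day(s) with evaporation exceeding the feeder change",
            " clipped to 0")
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Kruskal-Wallis comparison of cumulative consumption
#'
#' Compares cage-level cumulative per-bee consumption over the exposure
#' period between treatments (the cage is the experimental unit: bees
#' share feeders).
#'
#' @param series output of [consumption_series()].
#' @param treatment_of named character vector mapping cage to treatment.
#' @return a `beegut_test`.
#' @export
compare_consumption <- function(series, treatment_of) {
  last <- series[order(series$cage, series$day), ]
  totals <- tapply(last$per_bee, last$cage, sum)
  trt <- treatment_of[names(totals)]
  if (any(is.na(trt))) stop("treatment missing for cage(s): ",
                            paste(names(totals)[is.na(trt)], collapse = ", "))
  kruskal_wallis(as.numeric(totals), trt)
}
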