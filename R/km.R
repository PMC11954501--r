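#' Digitized Kaplan-Meier curve
#'
#' Container for a digitized survival curve: click-point coordinates plus
#' the published number-at-risk table. Survival must be non-increasing (tiny
#' digitization-noise increases up to 1e-6 are clamped flat), numbers at
#' risk non-increasing.
#'
#' @param times click-point times (months), non-decreasing.
#' @param surv survival probabilities at the click points.
#' @param risk_times times of the number-at-risk table rows.
#' @param n_risk numbers at risk at `risk_times`.
#' @param total_events optional reported total number of events, used by the
#'   constrained reconstruction variant.
#' @return object of class `km_curve`.
#' @export
km_curve <- function(times, surv, risk_times, n_risk, total_events = NULL) {
  stopifnot(length(times) == length(surv),
            length(risk_times) == length(n_risk),
            length(risk_times) >= 2L)
  o <- order(times)
  times <- times[o]; surv <- surv[o]
  if (any(surv < 0) || any(surv > 1)) stop("survival outside [0, 1]")
  if (any(diff(surv) > 1e-6)) stop("survival increases along the curve")
  inc <- which(diff(surv) > 0)
  for (i in inc) surv[i + 1L] <- surv[i]   # clamp digitization noise flat
  if (is.unsorted(risk_times)) stop("risk-table times must increase")
  if (any(diff(n_risk) > 0)) stop("numbers at risk increase over time")
  if (risk_times[1L] > times[1L]) {
    stop("first risk-table time must not exceed the first click point")
  }
  structure(list(times = times, surv = surv,
                 risk_times = risk_times, n_risk = n_risk,
                 total_events = total_events),
            class = "km_curve")
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Iterative reconstruction of per-patient event and censor times from a
#' digitized Kaplan-Meier curve and its number-at-risk table. Within each
#' interval between consecutive risk-table times, the number of censored
#' patients is adjusted until the implied number at risk at the interval end
#' matches the published table; censor times are spread evenly across the
#' interval, and the event count at each click point is chosen so the
#' product-limit estimate tracks the digitized survival. A survival drop at
#' a risk-table time is attributed to the interval ending there (the
#' published count at that time already reflects it). When `total_events`
#' is recorded on the curve, event counts are re-balanced against final
#' censorings so the total matches the report. Patients still at risk after
#' the last click point are censored at that time.
#'
#' @param curve a [km_curve()].
#' @return data.frame of class `pseudo_ipd` with columns `time` and
#'   `status` (1 = event, 0 = censored); one row per patient at risk at the
#'   first risk-table time.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  t_s <- curve$times; s <- curve$surv
  t_r <- curve$risk_times; n_r <- curve$n_risk
  n_int <- length(t_r)
  n_clicks <- length(t_s)
  half_up <- function(x) floor(x + 0.5)

  # interval i owns clicks with t in (t_r[i], t_r[i+1]]; the first interval
  # also owns t = t_r[1]; the last owns everything past t_r[n_int]
  own <- findInterval(t_s, t_r, left.open = TRUE) # 0 for t == t_r[1]
  own[own == 0L] <- 1L

  d_k <- integer(n_clicks)          # events at click k
  c_k <- integer(n_clicks)          # censors in (click k, click k+1]
  extra_cen <- numeric(0L)          # censors in click-free intervals

  run_interval <- function(idx, n_cen, n_start, km_start, span) {
    m <- length(idx)
    cen_alloc <- integer(m)
    if (n_cen > 0L) {
      cent <- span[1L] + diff(span) * (seq_len(n_cen) - 0.5) / n_cen
      bounds <- t_s[idx]                 # censor in (click k-1, click k]
      slot <- findInterval(cent, bounds, left.open = TRUE) + 1L
      slot[slot > m] <- m
      cen_alloc <- tabulate(slot, nbins = m)
    }
    n_cur <- n_start; km <- km_start
    dd <- integer(m)
    for (j in seq_len(m)) {
      k <- idx[j]
      d <- if (n_cur > 0L && km > 0) {
        max(0L, min(as.integer(half_up(n_cur * (1 - s[k] / km))), n_cur))
      } else 0L
      dd[j] <- d
      if (d > 0L) km <- km * (1 - d / n_cur)
      n_cur <- n_cur - d - cen_alloc[j]
      if (n_cur < 0L) n_cur <- 0L
    }
    list(n_end = n_cur, d = dd, cen = cen_alloc, km = km)
  }

  km <- 1
  n_cur <- n_r[1L]
  for (i in seq_len(n_int)) {
    idx <- which(own == i)
    target <- if (i < n_int) n_r[i + 1L] else NA_integer_
    if (length(idx) == 0L) {
      if (i < n_int && n_cur > target) {
        # no curve information: the whole drop is censoring mid-interval
        gap <- n_cur - target
        extra_cen <- c(extra_cen, rep((t_r[i] + t_r[i + 1L]) / 2, gap))
        n_cur <- target
      }
      next
    }
    span <- c(t_r[i], if (i < n_int) t_r[i + 1L] else max(t_s[idx]))
    n_cen <- 0L
    res <- run_interval(idx, n_cen, n_cur, km, span)
    if (i < n_int) {
      seen <- integer(0L)
      while (res$n_end != target) {
        n_cen <- n_cen + (res$n_end - target)
        if (n_cen < 0L) { n_cen <- 0L }
        if (n_cen %in% seen) break     # oscillation from rounding; accept
        seen <- c(seen, n_cen)
        res <- run_interval(idx, n_cen, n_cur, km, span)
      }
    }
    d_k[idx] <- res$d
    c_k[idx] <- res$cen
    km <- res$km
    n_cur <- res$n_end
  }

  n_tail <- n_r[1L] - sum(d_k) - sum(c_k) - length(extra_cen)
  if (!is.null(curve$total_events) && is.finite(curve$total_events)) {
    need <- as.integer(curve$total_events) - sum(d_k)
    if (need > 0L) {
      add <- min(need, n_tail)          # convert tail censorings to events
      d_k[n_clicks] <- d_k[n_clicks] + add
      n_tail <- n_tail - add
      need <- need - add
      for (k in rev(seq_len(n_clicks))) {     # then interval censorings
        if (need <= 0L) break
        take <- min(need, c_k[k])
        c_k[k] <- c_k[k] - take
        d_k[k] <- d_k[k] + take
        need <- need - take
      }
    } else if (need < 0L) {
      for (k in rev(seq_len(n_clicks))) {     # surplus events -> censorings
        if (need >= 0L) break
        give <- min(-need, d_k[k])
        d_k[k] <- d_k[k] - give
        c_k[k] <- c_k[k] + give
        need <- need + give
      }
    }
  }

  cen_in <- unlist(lapply(which(c_k > 0L), function(k) {
    lo <- if (k > 1L) t_s[k - 1L] else t_r[1L]
    hi <- t_s[k]
    if (hi <= lo) hi <- lo + 1e-6
    lo + (hi - lo) * seq_len(c_k[k]) / (c_k[k] + 1L)
  }))
  times <- c(rep(t_s, d_k), cen_in, extra_cen, rep(max(t_s), max(0L, n_tail)))
  status <- c(rep(1L, sum(d_k)),
              rep(0L, length(cen_in) + length(extra_cen) + max(0L, n_tail)))
  out <- data.frame(time = times, status = status)
  out <- out[order(out$time, -out$status), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Product-limit survival estimate from pseudo-IPD
#'
#' Conventional Kaplan-Meier estimator; at tied times events are processed
#' before censorings.
#'
#' @param ipd data.frame with `time` and `status` (1 = event, 0 censored).
#' @param risk_times optional times at which to tabulate numbers at risk;
#'   defaults to `0` plus the event times.
#' @return a [km_curve()] evaluated at 0 and the distinct observed times.
#' @export
km_from_ipd <- function(ipd, risk_times = NULL) {
  stopifnot(nrow(ipd) > 0L)
  tt <- sort(unique(ipd$time))
  n_at <- vapply(tt, function(u) sum(ipd$time >= u), numeric(1L))
  d_at <- vapply(tt, function(u) sum(ipd$time == u & ipd$status == 1L),
                 numeric(1L))
  s_hat <- cumprod(1 - d_at / n_at)
  if (is.null(risk_times)) {
    risk_times <- unique(c(0, tt[d_at > 0]))
    if (length(risk_times) < 2L) risk_times <- unique(c(0, max(tt)))
  }
  n_risk <- vapply(risk_times, function(u) sum(ipd$time >= u), numeric(1L))
  km_curve(times = c(0, tt), surv = c(1, s_hat),
           risk_times = risk_times, n_risk = n_risk)
}

#' Read digitized KM curves from CSV files
#'
#' @param points_csv CSV with columns `trial_id`, `arm`, `time`,
#'   `survival`.
#' @param risk_csv CSV with columns `trial_id`, `arm`, `time`,
#'   `n_at_risk`.
#' @param meta_csv optional CSV with columns `trial_id`, `arm`,
#'   `total_events`.
#' @return named list of [km_curve()]s, one per `trial_id:arm`.
#' @export
read_km_curves <- function(points_csv, risk_csv, meta_csv = NULL) {
  pts <- read.csv(points_csv, stringsAsFactors = FALSE)
  rsk <- read.csv(risk_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "arm", "time", "survival") %in% names(pts)),
            all(c("trial_id", "arm", "time", "n_at_risk") %in% names(rsk)))
  meta <- if (!is.null(meta_csv)) read.csv(meta_csv,
                                           stringsAsFactors = FALSE)
  keys <- unique(paste(pts$trial_id, pts$arm, sep = ":"))
  out <- lapply(keys, function(k) {
    p <- pts[paste(pts$trial_id, pts$arm, sep = ":") == k, ]
    r <- rsk[paste(rsk$trial_id, rsk$arm, sep = ":") == k, ]
    if (nrow(r) < 2L) stop("risk table for ", k, " needs >= 2 rows")
    te <- NULL
    if (!is.null(meta)) {
      m <- meta[paste(meta$trial_id, meta$arm, sep = ":") == k, ]
      if (nrow(m) == 1L) te <- m$total_events
    }
    km_curve(p$time, p$survival, r$time, r$n_at_risk, total_events = te)
  })
  names(out) <- keys
  out
}

#' Evaluate a KM curve at arbitrary times (right-continuous step function)
#' @param curve a [km_curve()].
#' @param at times at which to evaluate.
#' @return survival probabilities.
#' @export
km_surv_at <- function(curve, at) {
  idx <- findInterval(at, curve$times)
  c(1, curve$surv)[idx + 1L]
}
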