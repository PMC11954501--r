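#' Two-group Cox proportional-hazards estimate from pseudo-IPD
#'
#' Maximizes the two-group partial likelihood with Efron handling of tied
#' event times by Newton-Raphson (convergence when the step falls below
#' 1e-8, at most 50 iterations). The standard error comes from the inverse
#' observed information at the maximum. With a monotone likelihood (all
#' events drifting to one arm, so the MLE diverges), the fit falls back to
#' the Firth-penalized likelihood and warns.
#'
#' @param arm_a,arm_b data.frames with columns `time` and `status`
#'   (1 = event, 0 = censored), e.g. from [reconstruct_ipd()].
#' @return list with `log_hr` (log hazard of `arm_a` relative to `arm_b`),
#'   `se`, `iterations`, `converged` and `penalized` (TRUE when the Firth
#'   fallback was used).
#' @export
cox_loghr <- function(arm_a, arm_b) {
  stopifnot(all(c("time", "status") %in% names(arm_a)),
            all(c("time", "status") %in% names(arm_b)))
  time <- c(arm_a$time, arm_b$time)
  status <- c(arm_a$status, arm_b$status)
  z <- c(rep(1L, nrow(arm_a)), rep(0L, nrow(arm_b)))
  if (sum(status) < 1L) stop("no events in either arm")

  ev_times <- sort(unique(time[status == 1L]))
  n1 <- vapply(ev_times, function(u) sum(time >= u & z == 1L), numeric(1L))
  n0 <- vapply(ev_times, function(u) sum(time >= u & z == 0L), numeric(1L))
  d1 <- vapply(ev_times, function(u)
    sum(time == u & status == 1L & z == 1L), numeric(1L))
  d0 <- vapply(ev_times, function(u)
    sum(time == u & status == 1L & z == 0L), numeric(1L))
  d <- d1 + d0

  # Efron partial log-likelihood, score and information for binary z
  derivs <- function(beta) {
    eb <- exp(beta)
    ll <- sum(d1) * beta
    U <- sum(d1)
    I <- 0
    for (j in seq_along(ev_times)) {
      l <- seq_len(d[j]) - 1
      den <- (n0[j] + n1[j] * eb) - (l / d[j]) * (d0[j] + d1[j] * eb)
      num <- n1[j] * eb - (l / d[j]) * d1[j] * eb
      A <- num / den
      ll <- ll - sum(log(den))
      U <- U - sum(A)
      I <- I + sum(A * (1 - A))
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- 0; converged <- FALSE; iter <- 0L
  monotone <- FALSE
  while (iter < 50L) {
    iter <- iter + 1L
    dv <- derivs(beta)
    if (!is.finite(dv$U) || dv$I < 1e-12) { monotone <- TRUE; break }
    step <- dv$U / dv$I
    beta <- beta + step
    if (abs(beta) > 15) { monotone <- TRUE; break }
    if (abs(step) < 1e-8) { converged <- TRUE; break }
  }

  penalized <- FALSE
  if (monotone || !converged) {
    # monotone or ill-behaved likelihood: Firth/Jeffreys penalty keeps the
    # estimate finite
    penalized <- TRUE
    warning("monotone or non-converged partial likelihood; ",
            "returning Firth-penalized estimate")
    pll <- function(b) {
      dv <- derivs(b)
      dv$ll + 0.5 * log(max(dv$I, 1e-300))
    }
    opt <- stats::optimize(pll, interval = c(-20, 20), maximum = TRUE,
                           tol = 1e-9)
    beta <- opt$maximum
  }
  info <- derivs(beta)$I
  list(log_hr = beta, se = sqrt(1 / info), iterations = iter,
       converged = converged || penalized, penalized = penalized)
}
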