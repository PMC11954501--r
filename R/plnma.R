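#' Penalized-likelihood fixed-effect NMA for rare adverse events
#'
#' Arm-level adverse-event counts are modelled binomially with a
#' complementary log-log link and a log follow-up offset,
#' `cloglog(p_ik) = ln(f_i) + mu_i + (d_k - d_b)`, so the treatment
#' effects are discrete hazard ratios that account for unequal trial
#' follow-up. Estimation is Newton-Raphson (Fisher scoring) on the
#' log-likelihood, optionally augmented by the Firth/Jeffreys penalty
#' `0.5 * ln det I(theta)` which removes the leading-order bias of the MLE
#' and keeps estimates finite when arms have zero events. Fixed-effect
#' only: trial intercepts mu_i are profile parameters, one per trial.
#'
#' @param network an `evidence_network` built from arm-level records.
#' @param ae_records optional data.frame of arm records with columns
#'   `trial_id`, `treatment`, `events`, `n`, `follow_up` (months);
#'   defaults to the network's records. Missing follow-up is imputed with
#'   the median across trials (with a logged warning).
#' @param penalty `"firth"` (default) or `"none"`.
#' @param tol convergence tolerance on the (penalized) score norm.
#' @param max_iter maximum Newton iterations.
#' @return list of class `pl_fit` with `d_hat` (named, log discrete-hazard
#'   scale), `cov` (variance-covariance of d_hat), `mu_hat`, `converged`,
#'   `iterations`, `treatments`, `reference` and `penalty`.
#' @export
fit_pl_cloglog <- function(network, ae_records = NULL,
                           penalty = c("firth", "none"),
                           tol = 1e-8, max_iter = 100L) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(network, "evidence_network"))
  cr <- component_records(network)
  rec <- ae_records %||% cr$records
  if (!.is_arm_records(rec)) {
    stop("fit_pl_cloglog requires arm-level records")
  }
  rec <- rec[rec$treatment %in% cr$component, , drop = FALSE]
  if (!("follow_up" %in% names(rec))) rec$follow_up <- NA_real_
  if (any(is.na(rec$follow_up))) {
    med <- median(rec$follow_up, na.rm = TRUE)
    if (!is.finite(med)) stop("no follow-up information to impute from")
    log_msg("WARN", "pl_nma",
            sprintf("imputing median follow-up (%.1f months) for %d arm(s)",
                    med, sum(is.na(rec$follow_up))))
    rec$follow_up[is.na(rec$follow_up)] <- med
  }
  if (any(rec$follow_up <= 0)) stop("non-positive follow-up")
  if (any(is.na(rec$events))) stop("arm records must carry event counts")

  reference <- network$reference
  treatments <- c(reference, sort(setdiff(cr$component, reference)))
  trial_ids <- sort(unique(rec$trial_id))
  rec <- rec[order(rec$trial_id, rec$treatment), , drop = FALSE]
  trial_idx <- match(rec$trial_id, trial_ids)
  # within-trial baseline arm: the reference when present, else first arm
  is_base <- logical(nrow(rec))
  for (tid in trial_ids) {
    rows <- which(rec$trial_id == tid)
    base <- if (reference %in% rec$treatment[rows]) {
      rows[rec$treatment[rows] == reference][1L]
    } else rows[1L]
    is_base[base] <- TRUE
  }
  Tn <- length(trial_ids)
  cols <- setdiff(treatments, reference)
  K <- length(cols)
  # full design: columns = mu_1..mu_T, d_[cols]; contrast vs trial baseline
  X <- matrix(0, nrow(rec), Tn + K,
              dimnames = list(NULL, c(paste0("mu[", trial_ids, "]"),
                                      paste0("d[", cols, "]"))))
  X[cbind(seq_len(nrow(rec)), trial_idx)] <- 1
  for (i in which(!is_base)) {
    bt <- rec$treatment[is_base & trial_idx == trial_idx[i]]
    t <- rec$treatment[i]
    if (t != reference) X[i, paste0("d[", t, "]")] <- 1
    if (bt != reference) X[i, paste0("d[", bt, "]")] <- -1
  }
  y <- rec$events; n <- rec$n
  off <- log(rec$follow_up)

  # cloglog binomial pieces: p = 1 - exp(-exp(eta)), u = exp(eta)
  pieces <- function(theta) {
    eta <- drop(X %*% theta) + off
    eta <- pmin(eta, 30)                     # overflow guard
    u <- exp(eta)
    p <- -expm1(-u)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    q <- 1 - p
    s <- (y - n * p) * u / p                 # score residual per arm
    w <- n * u^2 * q / p                     # Fisher weight
    ll <- sum(y * log(p) + (n - y) * log(q))
    list(eta = eta, u = u, p = p, q = q, s = s, w = w, ll = ll)
  }

  theta <- numeric(Tn + K)
  # crude start: per-trial cloglog of pooled event rate
  for (ti in seq_len(Tn)) {
    rows <- which(trial_idx == ti)
    ph <- (sum(y[rows]) + 0.5) / (sum(n[rows]) + 1)
    theta[ti] <- log(-log(1 - ph)) - mean(off[rows])
  }

  converged <- FALSE
  iter <- 0L
  score_mod <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    pc <- pieces(theta)
    I_mat <- crossprod(X * pc$w, X)
    U <- drop(crossprod(X, pc$s))
    if (penalty == "firth") {
      ch <- tryCatch(chol(I_mat), error = function(e) NULL)
      if (is.null(ch)) break
      # leverages of the weighted design: h_i = w_i x_i' I^{-1} x_i
      XtI <- backsolve(ch, forwardsolve(t(ch), t(X)))
      h <- pc$w * colSums(t(X) * XtI)
      # d log w / d eta for the cloglog-binomial weight
      dlogw <- 2 - pc$u - pc$u * pc$q / pc$p
      U <- U + 0.5 * drop(crossprod(X, h * dlogw))
    }
    step <- tryCatch(solve(I_mat, U), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps (rare-event likelihoods can be flat)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    theta <- theta + step
    if (sqrt(sum(U^2)) < tol) { converged <- TRUE; break }
  }
  pc <- pieces(theta)
  I_mat <- crossprod(X * pc$w, X)
  cov_all <- tryCatch(solve(I_mat), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  d_idx <- Tn + seq_len(K)
  if (!converged) {
    log_msg("WARN", "pl_nma",
            sprintf("PL-NMA did not converge in %d iterations (|U| = %.2e)",
                    iter, sqrt(sum(drop(crossprod(X, pc$s))^2))))
  }
  structure(list(d_hat = setNames(theta[d_idx], cols),
                 cov = matrix(cov_all[d_idx, d_idx], K, K,
                              dimnames = list(cols, cols)),
                 mu_hat = setNames(theta[seq_len(Tn)], trial_ids),
                 converged = converged, iterations = iter,
                 loglik = pc$ll,
                 treatments = treatments, reference = reference,
                 penalty = penalty),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf("Penalized-likelihood cloglog NMA (%s penalty)\n", x$penalty))
  se <- sqrt(diag(x$cov))
  df <- data.frame(treatment = names(x$d_hat),
                   log_dhr = round(x$d_hat, 3), se = round(se, 3),
                   dhr = round(exp(x$d_hat), 3))
  rownames(df) <- NULL
  print(df)
  cat(sprintf("converged: %s after %d iterations\n", x$converged,
              x$iterations))
  invisible(x)
}

#' Pairwise discrete hazard ratios with Wald 95% CIs
#'
#' Exponentiated contrasts of the penalized-likelihood estimates; interval
#' from the delta-method variance of the contrast.
#'
#' @param fit a `pl_fit`.
#' @param comparator optional treatment id to restrict comparisons to.
#' @return data.frame with `treatment`, `comparator`, `dhr`, `lo95`,
#'   `hi95`, `significant`.
#' @export
relative_discrete_hazards <- function(fit, comparator = NULL) {
  stopifnot(inherits(fit, "pl_fit"))
  trt <- fit$treatments
  d_full <- c(setNames(0, fit$reference), fit$d_hat)[trt]
  cv <- matrix(0, length(trt), length(trt), dimnames = list(trt, trt))
  nr <- names(fit$d_hat)
  cv[nr, nr] <- fit$cov
  comps <- comparator %||% trt
  out <- list()
  for (k in comps) {
    for (j in trt) {
      est <- d_full[j] - d_full[k]
      v <- cv[j, j] + cv[k, k] - 2 * cv[j, k]
      se <- sqrt(max(v, 0))
      lo <- exp(est - 1.96 * se); hi <- exp(est + 1.96 * se)
      out[[length(out) + 1L]] <- data.frame(
        treatment = j, comparator = k, dhr = exp(est),
        lo95 = lo, hi95 = hi,
        significant = j != k & (lo > 1 | hi < 1))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
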