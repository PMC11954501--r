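#' Prior settings for Bayesian NMA models
#'
#' Treatment effects (and trial baselines in the binomial model) get vague
#' normal priors; the between-trial variance gets the informative
#' log-normal prior for pharmacological comparisons on mortality/major
#' morbidity outcomes, tau^2 ~ LogNormal(-3.95, 1.79^2).
#'
#' @param d_sd prior SD of basic treatment effects (log scale).
#' @param mu_sd prior SD of trial baselines (binomial model).
#' @param tau2_lognormal length-2 vector: mean and SD of log(tau^2).
#' @return list of class `nma_priors`.
#' @export
nma_priors <- function(d_sd = 100, mu_sd = 100,
                       tau2_lognormal = c(-3.95, 1.79)) {
  stopifnot(d_sd > 0, mu_sd > 0, length(tau2_lognormal) == 2L,
            tau2_lognormal[2L] > 0)
  structure(list(d_sd = d_sd, mu_sd = mu_sd,
                 tau2_lognormal = tau2_lognormal),
            class = "nma_priors")
}

#' MCMC schedule
#'
#' The full-scale default follows the analysis plan: burn-in and sampling
#' phases of 60 000 iterations each. Four chains with dispersed starting
#' values are run by default; chain seeds are derived deterministically
#' from `seed`.
#'
#' @param burn burn-in iterations per chain.
#' @param sample sampling iterations per chain.
#' @param chains number of chains (>= 2).
#' @param seed master seed.
#' @param thin thinning interval.
#' @return list of class `nma_mcmc`.
#' @export
nma_mcmc <- function(burn = 60000, sample = 60000, chains = 4, seed = 1,
                     thin = 1) {
  stopifnot(burn >= 1, sample >= 1, chains >= 2, thin >= 1)
  structure(list(burn = as.integer(burn), sample = as.integer(sample),
                 chains = as.integer(chains), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "nma_mcmc")
}

# ---- design construction ---------------------------------------------------

# contrast design: one row per contrast, columns = non-reference treatments
# in the connected component (+ optional split parameter "omega" for the
# direct effect of `split_pair`)
.contrast_design <- function(records, component, reference,
                             split_pair = NULL) {
  treatments <- c(reference, sort(setdiff(component, reference)))
  K <- length(treatments) - 1L
  cols <- setdiff(treatments, reference)
  n <- nrow(records)
  X <- matrix(0, n, K + as.integer(!is.null(split_pair)),
              dimnames = list(NULL, c(paste0("d[", cols, "]"),
                                      if (!is.null(split_pair)) "omega")))
  direct <- rep(FALSE, n)
  if (!is.null(split_pair)) {
    direct <- .is_direct_row(records, split_pair)
  }
  for (i in seq_len(n)) {
    if (direct[i]) {
      sgn <- if (records$treatment[i] == split_pair[2L]) 1 else -1
      X[i, "omega"] <- sgn
      next
    }
    t <- records$treatment[i]; b <- records$baseline_treatment[i]
    if (t != reference) X[i, paste0("d[", t, "]")] <- 1
    if (b != reference) X[i, paste0("d[", b, "]")] <- -1
  }
  blocks <- split(seq_len(n), records$trial_id)
  list(X = X, y = records$log_effect, se = records$se, blocks = blocks,
       treatments = treatments, direct = direct)
}

.is_direct_row <- function(records, pair) {
  two_arm <- records$trial_id %in%
    names(which(table(records$trial_id) == 1L))
  same <- (records$baseline_treatment == pair[1L] &
             records$treatment == pair[2L]) |
    (records$baseline_treatment == pair[2L] & records$treatment == pair[1L])
  two_arm & same
}

# correlation structure of random effects within a multi-arm trial:
# var tau^2, covariance tau^2/2
.block_pinv <- function(m) {
  P <- matrix(0.5, m, m); diag(P) <- 1
  solve(P)
}

# ---- normal-likelihood sampler --------------------------------------------

# Blocked Gibbs for the contrast-level model. Fixed effect: the posterior
# of theta is exactly multivariate normal, so draws are independent.
# Random effects: conjugate updates for the trial-specific effects delta
# and for theta, adaptive Metropolis on phi = log tau^2 (step size frozen
# after burn-in).
.normal_gibbs <- function(design, model, priors, mcmc) {
  X <- design$X; y <- design$y; se <- design$se
  n <- length(y); K <- ncol(X)
  w <- if (n) 1 / se^2 else numeric(0L)
  prior_prec <- 1 / priors$d_sd^2
  m0 <- priors$tau2_lognormal[1L]; s0 <- priors$tau2_lognormal[2L]
  n_keep <- mcmc$sample %/% mcmc$thin
  pars <- c(colnames(X), if (model == "random") "tau")
  samples <- array(NA_real_, dim = c(n_keep, mcmc$chains, length(pars)),
                   dimnames = list(NULL, paste0("chain", seq_len(mcmc$chains)),
                                   pars))
  dev_draws <- matrix(NA_real_, n_keep, mcmc$chains)
  fitted_sum <- numeric(n)

  if (model == "fixed") {
    Lam <- crossprod(X * sqrt(w)) + diag(prior_prec, K)
    ch <- chol(Lam)
    mean_theta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * y)))
    for (c_i in seq_len(mcmc$chains)) {
      set.seed(substream_seed(mcmc$seed, paste0("normal-fixed-", c_i)))
      Z <- matrix(rnorm(n_keep * K), K, n_keep)
      Th <- drop(mean_theta) + backsolve(ch, Z)      # K x n_keep
      samples[, c_i, seq_len(K)] <- t(Th)
      if (n) {
        R <- y - X %*% Th
        dev_draws[, c_i] <- colSums(w * R^2)
        fitted_sum <- fitted_sum + rowSums(X %*% Th)
      } else dev_draws[, c_i] <- 0
    }
    fitted_mean <- if (n) fitted_sum / (n_keep * mcmc$chains) else numeric(0L)
  } else {
    blocks <- design$blocks
    msize <- vapply(blocks, length, integer(1L))
    two <- unlist(blocks[msize == 1L], use.names = FALSE)
    multi <- blocks[msize > 1L]
    if (length(multi) > 0L) {
      log_msg("INFO", "bayes_nma",
              sprintf("%d multi-arm trial(s): random-effects correlation tau^2/2 via conditional-normal blocks; likelihood contrasts treated independent",
                      length(multi)))
    }
    pinv <- lapply(multi, function(ix) .block_pinv(length(ix)))
    A <- matrix(0, K, K)
    if (length(two) > 0L) A <- A + crossprod(X[two, , drop = FALSE])
    for (j in seq_along(multi)) {
      Xi <- X[multi[[j]], , drop = FALSE]
      A <- A + t(Xi) %*% pinv[[j]] %*% Xi
    }
    eg <- eigen(A, symmetric = TRUE)
    V <- eg$vectors; avals <- pmax(eg$values, 0)

    for (c_i in seq_len(mcmc$chains)) {
      set.seed(substream_seed(mcmc$seed, paste0("normal-random-", c_i)))
      theta <- rnorm(K, 0, 1)                       # dispersed start
      phi <- max(-8, min(1, rnorm(1L, m0, s0)))
      delta <- if (n) drop(X %*% theta) + rnorm(n, 0, 0.1) else numeric(0L)
      step <- 0.8; acc <- 0L; kept <- 0L
      total <- mcmc$burn + mcmc$sample
      for (it in seq_len(total)) {
        tau2 <- exp(phi)
        prior_mean <- if (n) drop(X %*% theta) else numeric(0L)
        # delta | theta, tau, y
        if (length(two) > 0L) {
          prec <- w[two] + 1 / tau2
          mu_d <- (w[two] * y[two] + prior_mean[two] / tau2) / prec
          delta[two] <- mu_d + rnorm(length(two)) / sqrt(prec)
        }
        for (j in seq_along(multi)) {
          ix <- multi[[j]]
          Q <- diag(w[ix], length(ix)) + pinv[[j]] / tau2
          bvec <- w[ix] * y[ix] + (pinv[[j]] %*% prior_mean[ix]) / tau2
          chq <- chol(Q)
          mu_b <- backsolve(chq, forwardsolve(t(chq), bvec))
          delta[ix] <- drop(mu_b) + backsolve(chq, rnorm(length(ix)))
        }
        # theta | delta, tau
        v <- delta
        for (j in seq_along(multi)) {
          ix <- multi[[j]]
          v[ix] <- drop(pinv[[j]] %*% delta[ix])
        }
        b <- if (n) drop(crossprod(X, v)) / tau2 else numeric(K)
        lam <- avals / tau2 + prior_prec
        tb <- drop(crossprod(V, b))
        theta <- drop(V %*% (tb / lam + rnorm(K) / sqrt(lam)))
        # phi | delta, theta  (adaptive random-walk Metropolis)
        prior_mean <- if (n) drop(X %*% theta) else numeric(0L)
        r <- delta - prior_mean
        qsum <- 0
        if (length(two) > 0L) qsum <- qsum + sum(r[two]^2)
        for (j in seq_along(multi)) {
          ix <- multi[[j]]
          qsum <- qsum + drop(t(r[ix]) %*% pinv[[j]] %*% r[ix])
        }
        lp <- function(p) {
          -0.5 * (n * p + qsum * exp(-p)) + dnorm(p, m0, s0, log = TRUE)
        }
        phi_new <- phi + step * rnorm(1L)
        if (log(runif(1L)) < lp(phi_new) - lp(phi)) {
          phi <- phi_new; acc <- acc + 1L
        }
        if (it <= mcmc$burn && it %% 50L == 0L) {
          rate <- acc / 50; acc <- 0L
          step <- step * exp(0.6 * (rate - 0.44))
        }
        if (it > mcmc$burn && (it - mcmc$burn) %% mcmc$thin == 0L) {
          kept <- kept + 1L
          samples[kept, c_i, seq_len(K)] <- theta
          samples[kept, c_i, K + 1L] <- sqrt(exp(phi))
          dev_draws[kept, c_i] <- if (n) sum(w * (y - delta)^2) else 0
          if (n) fitted_sum <- fitted_sum + delta
        }
      }
    }
    fitted_mean <- if (n) fitted_sum / (n_keep * mcmc$chains) else numeric(0L)
  }

  dbar <- mean(dev_draws)
  dhat <- if (n) sum(w * (y - fitted_mean)^2) else 0
  list(samples = samples, dev_draws = dev_draws,
       fit = list(resdev = dbar, pd = dbar - dhat, dic = dbar + (dbar - dhat),
                  n_datapoints = n))
}

# ---- binomial-likelihood sampler ------------------------------------------

# arm-level logit model: r_ik ~ Binomial(p_ik, n_ik),
# logit(p_ik) = mu_i + delta_ik (0 for the baseline arm).
.binom_loglik <- function(eta, r, n) r * eta - n * log1p(exp(eta))

.binom_gibbs <- function(arms, design, model, priors, mcmc) {
  # arms: data.frame with trial (factor index), r, n, is_base, X rows for
  # non-baseline arms (design$X, one row per non-baseline arm)
  X <- design$X
  K <- ncol(X)
  trial_ids <- design$trial_ids
  Tn <- length(trial_ids)
  tr_idx <- arms$trial_idx
  nonbase <- which(!arms$is_base)
  nb_trial <- tr_idx[nonbase]
  r <- arms$events; n <- arms$n
  prior_prec_d <- 1 / priors$d_sd^2
  prior_prec_mu <- 1 / priors$mu_sd^2
  m0 <- priors$tau2_lognormal[1L]; s0 <- priors$tau2_lognormal[2L]

  blocks <- split(seq_along(nonbase), nb_trial)   # positions within nonbase
  msize <- vapply(blocks, length, integer(1L))
  two <- unlist(blocks[msize == 1L], use.names = FALSE)
  multi <- blocks[msize > 1L]
  pinv <- lapply(multi, function(ix) .block_pinv(length(ix)))
  random <- model == "random"
  if (random) {
    A <- matrix(0, K, K)
    if (length(two) > 0L) A <- A + crossprod(X[two, , drop = FALSE])
    for (j in seq_along(multi)) {
      Xi <- X[multi[[j]], , drop = FALSE]
      A <- A + t(Xi) %*% pinv[[j]] %*% Xi
    }
    eg <- eigen(A, symmetric = TRUE)
    V <- eg$vectors; avals <- pmax(eg$values, 0)
  }

  n_keep <- mcmc$sample %/% mcmc$thin
  pars <- c(colnames(X), paste0("mu[", trial_ids, "]"),
            if (random) "tau")
  samples <- array(NA_real_, dim = c(n_keep, mcmc$chains, length(pars)),
                   dimnames = list(NULL, paste0("chain", seq_len(mcmc$chains)),
                                   pars))
  dev_draws <- matrix(NA_real_, n_keep, mcmc$chains)
  p_sum <- numeric(length(r))

  arm_eta <- function(mu, delta_nb) {
    eta <- mu[tr_idx]
    eta[nonbase] <- eta[nonbase] + delta_nb
    eta
  }
  resdev <- function(p) {
    t1 <- ifelse(r > 0, r * log(r / (n * p)), 0)
    t2 <- ifelse(n - r > 0, (n - r) * log((n - r) / (n - n * p)), 0)
    2 * sum(t1 + t2)
  }

  for (c_i in seq_len(mcmc$chains)) {
    set.seed(substream_seed(mcmc$seed, paste0("binom-", model, "-", c_i)))
    base_rows <- which(arms$is_base)
    mu <- qlogis((r[base_rows] + 0.5) / (n[base_rows] + 1))[
      order(tr_idx[base_rows])] + rnorm(Tn, 0, 0.3)
    theta <- rnorm(K, 0, 1)
    delta_nb <- drop(X %*% theta) + if (random) rnorm(length(nonbase), 0, 0.1) else 0
    phi <- max(-8, min(1, rnorm(1L, m0, s0)))
    s_mu <- rep(0.3, Tn); s_de <- rep(0.3, length(nonbase))
    s_d <- rep(0.3, K); s_phi <- 0.8
    a_mu <- numeric(Tn); a_de <- numeric(length(nonbase))
    a_d <- numeric(K); a_phi <- 0
    kept <- 0L
    total <- mcmc$burn + mcmc$sample
    for (it in seq_len(total)) {
      tau2 <- exp(phi)
      # mu update: conditionally independent across trials
      eta <- arm_eta(mu, delta_nb)
      ll_arm <- .binom_loglik(eta, r, n)
      ll_tr <- rowsum(ll_arm, tr_idx, reorder = TRUE)
      mu_new <- mu + s_mu * rnorm(Tn)
      eta_new <- arm_eta(mu_new, delta_nb)
      ll_tr_new <- rowsum(.binom_loglik(eta_new, r, n), tr_idx,
                          reorder = TRUE)
      lacc <- drop(ll_tr_new - ll_tr) +
        prior_prec_mu / 2 * (mu^2 - mu_new^2)
      take <- log(runif(Tn)) < lacc
      mu[take] <- mu_new[take]
      a_mu <- a_mu + take

      if (random) {
        # delta update for two-arm trials: vectorized independent MH
        prior_mean <- drop(X %*% theta)
        eta <- arm_eta(mu, delta_nb)
        if (length(two) > 0L) {
          rows <- nonbase[two]
          d_new <- delta_nb
          d_new[two] <- delta_nb[two] + s_de[two] * rnorm(length(two))
          ll_old <- .binom_loglik(eta[rows], r[rows], n[rows])
          ll_new <- .binom_loglik(mu[tr_idx[rows]] + d_new[two],
                                  r[rows], n[rows])
          lacc <- ll_new - ll_old +
            ((delta_nb[two] - prior_mean[two])^2 -
               (d_new[two] - prior_mean[two])^2) / (2 * tau2)
          take <- log(runif(length(two))) < lacc
          delta_nb[two][take] <- d_new[two][take]
          a_de[two] <- a_de[two] + take
        }
        for (j in seq_along(multi)) {        # per-component MH with
          ix <- multi[[j]]                   # conditional normal prior
          Pj <- pinv[[j]]
          for (u in seq_along(ix)) {
            pos <- ix[u]; row <- nonbase[pos]
            others <- ix[-u]
            # conditional prior of delta_pos | others from precision Pj/tau2
            prec_u <- Pj[u, u] / tau2
            mean_u <- prior_mean[pos] -
              drop(Pj[u, -u, drop = FALSE] %*%
                     (delta_nb[others] - prior_mean[others])) / Pj[u, u]
            d_new <- delta_nb[pos] + s_de[pos] * rnorm(1L)
            ll_old <- .binom_loglik(mu[tr_idx[row]] + delta_nb[pos],
                                    r[row], n[row])
            ll_new <- .binom_loglik(mu[tr_idx[row]] + d_new, r[row], n[row])
            lacc <- ll_new - ll_old +
              prec_u / 2 * ((delta_nb[pos] - mean_u)^2 - (d_new - mean_u)^2)
            if (log(runif(1L)) < lacc) {
              delta_nb[pos] <- d_new; a_de[pos] <- a_de[pos] + 1
            }
          }
        }
        # theta | delta, tau: conjugate
        v <- delta_nb
        for (j in seq_along(multi)) {
          ix <- multi[[j]]
          v[ix] <- drop(pinv[[j]] %*% delta_nb[ix])
        }
        b <- drop(crossprod(X, v)) / tau2
        lam <- avals / tau2 + prior_prec_d
        tb <- drop(crossprod(V, b))
        theta <- drop(V %*% (tb / lam + rnorm(K) / sqrt(lam)))
        # phi
        rres <- delta_nb - drop(X %*% theta)
        qsum <- 0
        if (length(two) > 0L) qsum <- qsum + sum(rres[two]^2)
        for (j in seq_along(multi)) {
          ix <- multi[[j]]
          qsum <- qsum + drop(t(rres[ix]) %*% pinv[[j]] %*% rres[ix])
        }
        nn <- length(nonbase)
        lp <- function(p) -0.5 * (nn * p + qsum * exp(-p)) +
          dnorm(p, m0, s0, log = TRUE)
        phi_new <- phi + s_phi * rnorm(1L)
        if (log(runif(1L)) < lp(phi_new) - lp(phi)) {
          phi <- phi_new; a_phi <- a_phi + 1
        }
      } else {
        # fixed effect: delta == X theta; coordinate-wise MH on theta
        for (k in seq_len(K)) {
          touch <- which(X[, k] != 0)
          if (length(touch) == 0L) next
          rows <- nonbase[touch]
          th_new <- theta
          th_new[k] <- theta[k] + s_d[k] * rnorm(1L)
          eta_old <- mu[tr_idx[rows]] + drop(X[touch, , drop = FALSE] %*% theta)
          eta_new <- mu[tr_idx[rows]] + drop(X[touch, , drop = FALSE] %*% th_new)
          lacc <- sum(.binom_loglik(eta_new, r[rows], n[rows]) -
                        .binom_loglik(eta_old, r[rows], n[rows])) +
            prior_prec_d / 2 * (theta[k]^2 - th_new[k]^2)
          if (log(runif(1L)) < lacc) {
            theta <- th_new; a_d[k] <- a_d[k] + 1
          }
        }
        delta_nb <- drop(X %*% theta)
      }

      if (it <= mcmc$burn && it %% 50L == 0L) {
        adj <- function(s, a) s * exp(0.6 * (a / 50 - 0.44))
        s_mu <- adj(s_mu, a_mu); a_mu[] <- 0
        if (random) {
          s_de <- adj(s_de, a_de); a_de[] <- 0
          s_phi <- adj(s_phi, a_phi); a_phi <- 0
        } else {
          s_d <- adj(s_d, a_d); a_d[] <- 0
        }
      }
      if (it > mcmc$burn && (it - mcmc$burn) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        samples[kept, c_i, seq_len(K)] <- theta
        samples[kept, c_i, K + seq_len(Tn)] <- mu
        if (random) samples[kept, c_i, K + Tn + 1L] <- sqrt(exp(phi))
        p <- plogis(arm_eta(mu, delta_nb))
        dev_draws[kept, c_i] <- resdev(p)
        p_sum <- p_sum + p
      }
    }
  }
  p_mean <- p_sum / (n_keep * mcmc$chains)
  dbar <- mean(dev_draws)
  dhat <- resdev(p_mean)
  list(samples = samples, dev_draws = dev_draws,
       fit = list(resdev = dbar, pd = dbar - dhat, dic = dbar + (dbar - dhat),
                  n_datapoints = length(r)))
}

# ---- result assembly -------------------------------------------------------

.posterior_result <- function(raw, model, scale, treatments, reference,
                              mcmc, priors) {
  pars <- dimnames(raw$samples)[[3L]]
  flat <- apply(raw$samples, 3L, identity)      # (draws*chains) x params
  summaries <- do.call(rbind, lapply(seq_along(pars), function(p) {
    s <- summarise_draws_vec(flat[, p])
    data.frame(parameter = pars[p], mean = s["mean"], median = s["median"],
               lo95 = s["lo95"], hi95 = s["hi95"], row.names = NULL)
  }))
  diag <- mcmc_diagnostics(raw$samples)
  converged <- all(diag$pass, na.rm = TRUE)
  if (!converged) {
    log_msg("WARN", "bayes_nma",
            "convergence gate failed (R-hat >= 1.05 or ESS <= 400)")
  }
  structure(list(samples = raw$samples,
                 summaries = cbind(summaries,
                                   diag[match(summaries$parameter,
                                              diag$parameter),
                                        c("rhat", "ess_bulk", "ess_tail")]),
                 diagnostics = diag,
                 fit = raw$fit,
                 dev_draws = raw$dev_draws,
                 model = model, scale = scale,
                 treatments = treatments, reference = reference,
                 mcmc = mcmc, priors = priors,
                 converged = converged),
            class = "nma_posterior")
}

#' @export
print.nma_posterior <- function(x, ...) {
  cat(sprintf("Bayesian NMA posterior (%s-effect, %s scale)\n",
              x$model, x$scale))
  cat(sprintf("  %d treatments (reference %s); %d chains x %d draws\n",
              length(x$treatments), x$reference,
              dim(x$samples)[2L], dim(x$samples)[1L]))
  cat(sprintf("  ResDev %.1f on %d data points; DIC %.1f; converged: %s\n",
              x$fit$resdev, x$fit$n_datapoints, x$fit$dic, x$converged))
  invisible(x)
}

#' Fit a contrast-level Bayesian NMA (normal likelihood, identity link)
#'
#' Relative treatment effects are modelled on the log hazard ratio scale:
#' each observed contrast `y_ik` is normal around the trial-specific effect
#' with its reported squared standard error. Under the fixed-effect model
#' the trial-specific effect equals the difference of basic parameters
#' `d_k - d_b`; under random effects it is drawn from a normal distribution
#' around that difference with between-trial SD tau, and contrasts from a
#' multi-arm trial share the standard tau^2/2 correlation. Records outside
#' the connected component of the reference are excluded with a warning.
#'
#' @param network an `evidence_network` built from contrast records.
#' @param contrasts optional data.frame of contrast records; defaults to
#'   the network's own records.
#' @param model `"random"` (primary) or `"fixed"`.
#' @param priors a [nma_priors()].
#' @param mcmc a [nma_mcmc()].
#' @return an `nma_posterior` with samples, summaries, diagnostics and
#'   deviance-based fit statistics.
#' @export
fit_contrast_nma <- function(network, contrasts = NULL,
                             model = c("random", "fixed"),
                             priors = nma_priors(), mcmc = nma_mcmc()) {
  model <- match.arg(model)
  stopifnot(inherits(network, "evidence_network"))
  cr <- component_records(network)
  records <- contrasts %||% cr$records
  if (!.is_contrast_records(records)) {
    stop("fit_contrast_nma requires contrast-level records")
  }
  ok <- records$treatment %in% cr$component &
    records$baseline_treatment %in% cr$component
  records <- records[ok, , drop = FALSE]
  design <- .contrast_design(records, cr$component, network$reference)
  raw <- .normal_gibbs(design, model, priors, mcmc)
  .posterior_result(raw, model, "log_hr", design$treatments,
                    network$reference, mcmc, priors)
}

#' Fit an arm-level Bayesian NMA (binomial likelihood, logit link)
#'
#' Response counts are modelled binomially with trial baselines mu_i on the
#' logit scale and relative effects as log odds ratios versus each trial's
#' baseline arm (the network reference arm when present in the trial, else
#' the first arm).
#'
#' @inheritParams fit_contrast_nma
#' @param arms optional data.frame of arm records (`trial_id`, `treatment`,
#'   `events`, `n`); defaults to the network's records.
#' @return an `nma_posterior` on the log odds ratio scale.
#' @export
fit_binary_nma <- function(network, arms = NULL,
                           model = c("random", "fixed"),
                           priors = nma_priors(), mcmc = nma_mcmc()) {
  model <- match.arg(model)
  stopifnot(inherits(network, "evidence_network"))
  cr <- component_records(network)
  records <- arms %||% cr$records
  if (!.is_arm_records(records)) {
    stop("fit_binary_nma requires arm-level records with events and n")
  }
  records <- records[records$treatment %in% cr$component, , drop = FALSE]
  if (any(is.na(records$events))) stop("arm records must carry event counts")
  reference <- network$reference
  treatments <- c(reference, sort(setdiff(cr$component, reference)))

  trial_ids <- sort(unique(records$trial_id))
  records <- records[order(records$trial_id, records$treatment), ,
                     drop = FALSE]
  trial_idx <- match(records$trial_id, trial_ids)
  is_base <- logical(nrow(records))
  for (tid in trial_ids) {
    rows <- which(records$trial_id == tid)
    base <- if (reference %in% records$treatment[rows]) {
      rows[records$treatment[rows] == reference][1L]
    } else rows[1L]
    is_base[base] <- TRUE
  }
  nonbase <- which(!is_base)
  cols <- setdiff(treatments, reference)
  X <- matrix(0, length(nonbase), length(cols),
              dimnames = list(NULL, paste0("d[", cols, "]")))
  for (u in seq_along(nonbase)) {
    i <- nonbase[u]
    bt <- records$treatment[is_base & trial_idx == trial_idx[i]]
    t <- records$treatment[i]
    if (t != reference) X[u, paste0("d[", t, "]")] <- 1
    if (bt != reference) X[u, paste0("d[", bt, "]")] <- -1
  }
  arms_df <- data.frame(trial_idx = trial_idx, events = records$events,
                        n = records$n, is_base = is_base)
  design <- list(X = X, trial_ids = trial_ids)
  raw <- .binom_gibbs(arms_df, design, model, priors, mcmc)
  .posterior_result(raw, model, "log_or", treatments, reference, mcmc,
                    priors)
}

# draws x treatments matrix of basic parameters, reference column = 0
.d_draws <- function(posterior) {
  pars <- dimnames(posterior$samples)[[3L]]
  trt <- posterior$treatments
  out <- matrix(0, prod(dim(posterior$samples)[1:2]), length(trt),
                dimnames = list(NULL, trt))
  for (t in setdiff(trt, posterior$reference)) {
    out[, t] <- as.vector(posterior$samples[, , paste0("d[", t, "]")])
  }
  out
}

#' All pairwise relative effects from a posterior
#'
#' For each ordered treatment pair (j, k) the posterior of
#' `exp(d_j - d_k)` is summarized by its median and equal-tailed 95%
#' credible interval; a comparison is flagged significant when the interval
#' excludes 1.
#'
#' @param posterior an `nma_posterior`.
#' @param comparator optional single treatment id; when given only pairs
#'   versus this comparator are returned.
#' @return data.frame with columns `treatment`, `comparator`, `median`,
#'   `lo95`, `hi95`, `significant`.
#' @export
relative_effects <- function(posterior, comparator = NULL) {
  stopifnot(inherits(posterior, "nma_posterior"))
  D <- .d_draws(posterior)
  trt <- colnames(D)
  comps <- comparator %||% trt
  out <- list()
  for (k in comps) {
    for (j in trt) {
      # summarize on the log scale so reciprocal pairs are exact
      lr <- D[, j] - D[, k]
      s <- exp(c(median(lr), quantile(lr, c(0.025, 0.975))))
      out[[length(out) + 1L]] <- data.frame(
        treatment = j, comparator = k,
        median = s[1L], lo95 = s[2L], hi95 = s[3L],
        significant = s[2L] > 1 | s[3L] < 1)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deviance-based model fit statistics
#'
#' Returns the posterior mean residual deviance (to be compared with the
#' number of unconstrained data points for absolute fit), the effective
#' number of parameters pD and the deviance information criterion.
#'
#' @param posterior an `nma_posterior`.
#' @return list with `resdev`, `pd`, `dic`, `n_datapoints`.
#' @export
model_fit <- function(posterior) {
  stopifnot(inherits(posterior, "nma_posterior"))
  posterior$fit
}
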