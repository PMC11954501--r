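#' MCMC convergence diagnostics
#'
#' Rank-normalized split R-hat and bulk/tail effective sample sizes,
#' following current practice for Markov chain Monte Carlo quality control:
#' chains are split in half, draws are rank-normalized through the inverse
#' normal transform, R-hat is the larger of the bulk and fold (median
#' absolute deviation) statistics, bulk ESS is computed on the
#' rank-normalized draws and tail ESS is the smaller of the effective
#' sample sizes of the 5% and 95% quantile indicators. A fit passes the
#' convergence gate when every parameter has R-hat < 1.05 and both ESS
#' measures exceed 400.
#'
#' @name diagnostics
NULL

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  lower <- mat[seq_len(half), , drop = FALSE]
  upper <- mat[seq.int(n - half + 1L, n), , drop = FALSE]
  cbind(lower, upper)
}

z_scale <- function(mat) {
  r <- rank(mat, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(mat) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2L) return(NA_real_)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2L, var)
  W <- mean(chain_vars)
  B <- n * var(chain_means)
  if (W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# autocovariance by FFT, biased (divided by n), per column
autocov_fft <- function(mat) {
  n <- nrow(mat)
  m2 <- 2L * 2L^ceiling(log2(n))
  centred <- sweep(mat, 2L, colMeans(mat))
  padded <- rbind(centred, matrix(0, m2 - n, ncol(mat)))
  f <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(n), ,
                                                      drop = FALSE]
  ac / (m2 * n)
}

ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  chain_vars <- apply(mat, 2L, var)
  W <- mean(chain_vars)
  if (W < 1e-300) return(NA_real_)   # constant draws: ESS undefined
  B <- if (m > 1L) n * var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + B / n
  ac <- autocov_fft(mat) * n / (n - 1)
  rho <- 1 - (W - rowMeans(ac)) / var_plus    # rho[1] is lag 0
  # Geyer initial monotone positive sequence on paired sums
  tau <- -1
  pair_prev <- Inf
  t <- 1L
  while (t <= n) {
    pair <- rho[t] + if (t + 1L <= n) rho[t + 1L] else 0
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, pair_prev)     # enforce monotone decrease
    pair_prev <- pair
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  ess <- n * m / max(tau, 1e-12)
  min(ess, n * m * log10(n * m))     # cap for antithetic chains
}

ess_tail_mat <- function(mat) {
  q <- quantile(mat, c(0.05, 0.95))
  e1 <- ess_basic((mat <= q[1L]) + 0)
  e2 <- ess_basic((mat <= q[2L]) + 0)
  min(e1, e2, na.rm = TRUE)
}

#' Per-parameter convergence diagnostics from raw chains
#'
#' @param samples a draws x chains x parameters array (or a draws x chains
#'   matrix for a single parameter).
#' @return data.frame with one row per parameter: `rhat`, `ess_bulk`,
#'   `ess_tail` and `pass` (R-hat < 1.05, both ESS > 400).
#' @export
mcmc_diagnostics <- function(samples) {
  if (is.matrix(samples)) {
    samples <- array(samples, dim = c(dim(samples), 1L),
                     dimnames = list(NULL, NULL, "parameter"))
  }
  stopifnot(length(dim(samples)) == 3L)
  if (dim(samples)[2L] < 2L) stop("diagnostics require at least 2 chains")
  pars <- dimnames(samples)[[3L]] %||% paste0("par", seq_len(dim(samples)[3L]))
  out <- do.call(rbind, lapply(seq_along(pars), function(p) {
    mat <- samples[, , p]
    if (sd(mat) < 1e-300) {     # constant parameter (e.g. reference d)
      return(data.frame(parameter = pars[p], rhat = NA_real_,
                        ess_bulk = NA_real_, ess_tail = NA_real_,
                        pass = TRUE))
    }
    sp <- split_chains(mat)
    rhat <- max(rhat_basic(z_scale(sp)),
                rhat_basic(z_scale(abs(sp - median(sp)))),
                na.rm = TRUE)
    data.frame(parameter = pars[p],
               rhat = rhat,
               ess_bulk = ess_basic(z_scale(sp)),
               ess_tail = ess_tail_mat(sp),
               pass = NA)
  }))
  out$pass <- ifelse(is.na(out$rhat), out$pass,
                     out$rhat < 1.05 & out$ess_bulk > 400 & out$ess_tail > 400)
  rownames(out) <- NULL
  out
}
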