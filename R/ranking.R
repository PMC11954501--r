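#' Rank probabilities from posterior samples of treatment effects
#'
#' For each posterior draw, treatments are ordered in the declared benefit
#' direction (`lower_better` for hazard-type outcomes, `higher_better` for
#' response odds); ties are broken by a seeded uniform random permutation.
#' The rank matrix collects the empirical frequency of each treatment
#' occupying each rank and is doubly stochastic by construction.
#'
#' @param d_draws draws x treatments matrix of basic parameters (reference
#'   column identically 0), e.g. from a fitted `nma_posterior`.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @param tie_seed seed for tie-breaking permutations.
#' @return treatments x ranks probability matrix.
#' @export
rank_probabilities <- function(d_draws,
                               direction = c("lower_better",
                                             "higher_better"),
                               tie_seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(d_draws), ncol(d_draws) >= 2L)
  a <- ncol(d_draws)
  n <- nrow(d_draws)
  eff <- if (direction == "lower_better") d_draws else -d_draws
  # uniform tie-break noise, far below any real effect difference
  set.seed(tie_seed)
  eff <- eff + matrix(runif(n * a, 0, 1e-12), n, a)
  rk <- matrix(1L, n, a)
  for (j in 2L:a) {
    for (i in seq_len(j - 1L)) {
      smaller <- eff[, i] < eff[, j]
      rk[, j] <- rk[, j] + smaller
      rk[, i] <- rk[, i] + !smaller
    }
  }
  counts <- vapply(seq_len(a), function(k) tabulate(rk[, k], nbins = a),
                   numeric(a))
  out <- t(counts) / n
  dimnames(out) <- list(colnames(d_draws), paste0("rank", seq_len(a)))
  out
}

#' SUCRA: surface under the cumulative ranking curve
#'
#' `SUCRA_k = sum_{j=1}^{a-1} P(rank_k <= j) / (a - 1)`: 1 for a treatment
#' certainly ranked best, 0 for one certainly ranked worst. The values sum
#' to a/2 across treatments.
#'
#' @param rank_matrix treatments x ranks probability matrix from
#'   [rank_probabilities()].
#' @return named vector of SUCRA values in [0, 1].
#' @export
sucra <- function(rank_matrix) {
  a <- ncol(rank_matrix)
  if (a < 2L) stop("SUCRA is undefined for a single treatment")
  cum <- t(apply(rank_matrix, 1L, cumsum))
  out <- rowSums(cum[, seq_len(a - 1L), drop = FALSE]) / (a - 1L)
  setNames(as.numeric(out), rownames(rank_matrix))
}

#' Treatment ranking summary
#'
#' @param posterior an `nma_posterior`.
#' @param direction benefit direction for the outcome.
#' @param tie_seed seed for tie-breaking.
#' @return list of class `nma_ranking` with `rank_matrix`, `p_best`,
#'   `sucra`, `mean_rank` and `direction`.
#' @export
treatment_ranks <- function(posterior,
                            direction = c("lower_better", "higher_better"),
                            tie_seed = 1L) {
  direction <- match.arg(direction)
  D <- .d_draws(posterior)
  rm <- rank_probabilities(D, direction, tie_seed)
  structure(list(rank_matrix = rm,
                 p_best = rm[, 1L],
                 sucra = sucra(rm),
                 mean_rank = drop(rm %*% seq_len(ncol(rm))),
                 direction = direction),
            class = "nma_ranking")
}

#' @export
print.nma_ranking <- function(x, ...) {
  ord <- order(-x$sucra)
  df <- data.frame(treatment = names(x$sucra)[ord],
                   p_best = round(x$p_best[ord], 3),
                   sucra = round(x$sucra[ord], 3),
                   mean_rank = round(x$mean_rank[ord], 2))
  rownames(df) <- NULL
  cat(sprintf("Treatment ranking (%s)\n", x$direction))
  print(df)
  invisible(x)
}

#' League table of all pairwise relative effects
#'
#' Treatments are ordered by descending SUCRA; cell (row, col) holds the
#' posterior median ratio of column versus row with its 95% credible
#' interval. A ratio below 1 on a lower-is-better outcome favours the
#' column treatment. The parallel `significant` matrix flags intervals
#' excluding 1.
#'
#' @param posterior an `nma_posterior`.
#' @param direction benefit direction used for the SUCRA ordering.
#' @param tie_seed tie-break seed passed to the ranking.
#' @return list of class `nma_league` with matrices `median`, `lo95`,
#'   `hi95`, `significant`, `cells` (formatted strings) and the treatment
#'   `order`.
#' @export
league_table <- function(posterior,
                         direction = c("lower_better", "higher_better"),
                         tie_seed = 1L) {
  direction <- match.arg(direction)
  rk <- treatment_ranks(posterior, direction, tie_seed)
  ord <- names(sort(rk$sucra, decreasing = TRUE))
  D <- .d_draws(posterior)[, ord, drop = FALSE]
  a <- length(ord)
  med <- lo <- hi <- matrix(NA_real_, a, a, dimnames = list(ord, ord))
  for (i in seq_len(a)) {
    for (j in seq_len(a)) {
      if (i == j) next
      lr <- D[, j] - D[, i]           # column j vs row i, log scale so
      med[i, j] <- exp(median(lr))    # reciprocal pairs are exact
      qs <- exp(quantile(lr, c(0.025, 0.975)))
      lo[i, j] <- qs[1L]; hi[i, j] <- qs[2L]
    }
  }
  sig <- lo > 1 | hi < 1
  cells <- matrix(sprintf("%.2f (%.2f, %.2f)", med, lo, hi), a, a,
                  dimnames = list(ord, ord))
  diag(cells) <- ord
  structure(list(median = med, lo95 = lo, hi95 = hi, significant = sig,
                 cells = cells, order = ord, direction = direction),
            class = "nma_league")
}

#' @export
print.nma_league <- function(x, ...) {
  cat(sprintf("League table (%s; cell = column vs row)\n", x$direction))
  print(x$cells, quote = FALSE)
  invisible(x)
}
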