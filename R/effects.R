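#' Derive a log hazard ratio and its standard error from an HR with 95% CI
#'
#' The point estimate is the natural log of the reported hazard ratio; the
#' standard error is the width of the log CI divided by 2 x 1.96, i.e.
#' `(ln(ci_high) - ln(ci_low)) / 3.92`.
#'
#' @param hr hazard ratio point estimate.
#' @param ci_low,ci_high 95% confidence limits.
#' @return list with `log_effect` and `se`.
#' @examples
#' loghr_from_hr_ci(1.4, 1.1, 1.8)
#' @export
loghr_from_hr_ci <- function(hr, ci_low, ci_high) {
  if (any(c(hr, ci_low, ci_high) <= 0)) {
    stop("hazard ratio and CI limits must be positive")
  }
  if (ci_low >= ci_high) stop("confidence interval is zero-width or inverted")
  if (hr < ci_low || hr > ci_high) {
    stop("point estimate lies outside its confidence interval")
  }
  list(log_effect = log(hr), se = (log(ci_high) - log(ci_low)) / (2 * 1.96))
}

#' Log odds ratio from a 2x2 contingency table
#'
#' Computes the log odds ratio of arm 1 versus arm 2 with the Woolf
#' standard error (square root of the sum of reciprocal cell counts). When
#' any cell of the table is zero, 0.5 is added to all four cells before
#' computation (Gart continuity correction).
#'
#' @param r1,n1 responders and sample size in arm 1 (treatment).
#' @param r2,n2 responders and sample size in arm 2 (baseline).
#' @return list with `log_effect`, `se` and `corrected` (logical; whether
#'   the continuity correction was applied).
#' @export
or_from_counts <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, r1 >= 0, r2 >= 0, r1 <= n1, r2 <= n2)
  cells <- c(r1, n1 - r1, r2, n2 - r2)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(log_effect = log(cells[1L] * cells[4L] / (cells[2L] * cells[3L])),
       se = sqrt(sum(1 / cells)),
       corrected = corrected)
}

#' Event count from a reported percentage
#'
#' Rounds `pct * n / 100` to the nearest integer, halves away from zero
#' (so 10.5 events in 2 of 40 at 26.25% become 11, not banker's 10).
#'
#' @param pct percentage in [0, 100].
#' @param n arm sample size.
#' @return integer count in [0, n].
#' @export
counts_from_percent <- function(pct, n) {
  stopifnot(pct >= 0, pct <= 100, n >= 1)
  x <- pct * n / 100
  as.integer(min(n, floor(x + 0.5)))   # half away from zero (x >= 0 here)
}

#' Read contrast-level records from CSV
#'
#' The schema accepts either reported hazard ratios with 95% CI columns
#' (`hr`, `ci_low`, `ci_high`) or precomputed log effects (`log_hr`, `se`);
#' a row filling both groups is ambiguous and rejected. HR rows are
#' converted with [loghr_from_hr_ci()].
#'
#' @param path CSV file with columns `trial_id`, `outcome`, `treatment`,
#'   `baseline_treatment` plus one effect column group.
#' @param effect_scale scale tag recorded on the output, `"log_hr"` or
#'   `"log_or"`.
#' @return data.frame of contrast records with `log_effect` and `se`.
#' @export
read_contrasts <- function(path, effect_scale = "log_hr") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "outcome", "treatment", "baseline_treatment")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  if ("log_effect" %in% names(df) && !("log_hr" %in% names(df))) {
    df$log_hr <- df$log_effect
  }
  has_hr <- all(c("hr", "ci_low", "ci_high") %in% names(df))
  has_log <- all(c("log_hr", "se") %in% names(df))
  if (!has_hr && !has_log) {
    stop("need either hr/ci_low/ci_high or log_hr/se columns")
  }
  hr_filled <- if (has_hr) !is.na(df$hr) else rep(FALSE, nrow(df))
  log_filled <- if (has_log) !is.na(df$log_hr) else rep(FALSE, nrow(df))
  if (any(hr_filled & log_filled)) {
    stop("row(s) with both hr and log_hr filled (ambiguous): rows ",
         paste(which(hr_filled & log_filled), collapse = ", "))
  }
  if (any(!hr_filled & !log_filled)) {
    stop("row(s) with no effect estimate: rows ",
         paste(which(!hr_filled & !log_filled), collapse = ", "))
  }
  out <- df[need]
  out$log_effect <- NA_real_
  out$se <- NA_real_
  if (any(hr_filled)) {
    conv <- lapply(which(hr_filled), function(i) {
      loghr_from_hr_ci(df$hr[i], df$ci_low[i], df$ci_high[i])
    })
    out$log_effect[hr_filled] <- vapply(conv, `[[`, numeric(1L), "log_effect")
    out$se[hr_filled] <- vapply(conv, `[[`, numeric(1L), "se")
  }
  if (any(log_filled)) {
    out$log_effect[log_filled] <- df$log_hr[log_filled]
    out$se[log_filled] <- df$se[log_filled]
  }
  if (any(out$se <= 0)) stop("non-positive standard error in input")
  out$effect_scale <- effect_scale
  out
}

#' Read arm-level records from CSV
#'
#' @param path CSV with columns `trial_id`, `outcome`, `treatment`, `n` and
#'   optionally `events` and `follow_up_months`.
#' @return data.frame of arm records (column `follow_up` in months).
#' @export
read_arms <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "outcome", "treatment", "n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  if ("follow_up_months" %in% names(df)) {
    df$follow_up <- df$follow_up_months
    df$follow_up_months <- NULL
  }
  if (any(df$n < 1)) stop("arm sample size < 1")
  if ("events" %in% names(df)) {
    bad <- !is.na(df$events) & (df$events < 0 | df$events > df$n)
    if (any(bad)) stop("events outside [0, n] at rows ",
                       paste(which(bad), collapse = ", "))
  }
  if ("follow_up" %in% names(df) &&
      any(!is.na(df$follow_up) & df$follow_up <= 0)) {
    stop("non-positive follow-up")
  }
  df
}
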