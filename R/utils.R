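#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm median pnorm qnorm quantile rbinom rexp rnorm
#'   runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' Each generator component draws from its own substream so that adding a
#' new component never perturbs the draws of existing ones. The substream
#' seed is a deterministic 31-bit hash of the master seed and a component
#' label.
#'
#' @param seed master integer seed.
#' @param component character label of the component.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(component)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

log_msg <- function(level, component, msg) {
  line <- sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, component, msg)
  message(line)
  invisible(line)
}

#' Equal-tailed interval and point summaries of a sample
#' @noRd
summarise_draws_vec <- function(x) {
  c(mean = mean(x), median = median(x),
    lo95 = unname(quantile(x, 0.025)), hi95 = unname(quantile(x, 0.975)))
}
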