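#' Load a run configuration
#'
#' Configurations are YAML (or equivalent lists) declaring input files,
#' outcomes with their likelihood kind and benefit direction, node merges,
#' model settings, sensitivity exclusions and the output directory.
#'
#' @param path YAML file path.
#' @return list of class `nma_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_nma_config(cfg, dir = dirname(path))
}

#' Coerce a list to a run configuration
#'
#' @param cfg named list; see the package vignette for the schema.
#' @param dir base directory against which relative data paths resolve.
#' @return list of class `nma_config`.
#' @export
as_nma_config <- function(cfg, dir = ".") {
  stopifnot(is.list(cfg))
  if (is.null(cfg$outcomes) || length(cfg$outcomes) == 0L) {
    stop("config declares no outcomes")
  }
  for (i in seq_along(cfg$outcomes)) {
    oc <- cfg$outcomes[[i]]
    if (is.null(oc$name)) stop("outcome ", i, " has no name")
    if (is.null(oc$kind) ||
        !(oc$kind %in% c("contrast", "binary", "ae"))) {
      stop("outcome '", oc$name,
           "' needs kind: contrast, binary or ae")
    }
    if (is.null(oc$direction) ||
        !(oc$direction %in% c("lower_better", "higher_better"))) {
      stop("outcome '", oc$name, "' needs a declared benefit direction")
    }
    if (is.null(oc$data)) stop("outcome '", oc$name, "' has no data file")
    if (!grepl("^(/|[A-Za-z]:)", oc$data)) {
      cfg$outcomes[[i]]$data <- file.path(dir, oc$data)
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "nma_output"
  cfg$mcmc <- do.call(nma_mcmc, c(cfg$mcmc %||% list(),
                                  if (is.null(cfg$mcmc$seed)) list(seed = cfg$seed)))
  pr <- cfg$priors %||% list()
  if (!is.null(pr$tau2_lognormal)) {
    pr$tau2_lognormal <- as.numeric(unlist(pr$tau2_lognormal))
  }
  cfg$priors <- do.call(nma_priors, pr)
  structure(cfg, class = c("nma_config", "list"))
}

.merge_map_from_config <- function(cfg) {
  mm <- character(0L)
  for (m in cfg$merges %||% list()) {
    mm[unlist(m$from)] <- m$to
  }
  mm
}

#' Validate pipeline inputs
#'
#' Schema checks, per-record invariant checks and cross-file referential
#' integrity for every outcome in the configuration. Violations are
#' collected, not thrown, so a report can list all of them at once.
#'
#' @param config an `nma_config` (or path to one).
#' @return data.frame of class `nma_validation` with columns `outcome`,
#'   `file`, `row`, `message`; zero rows when the bundle is clean.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "nma_config"))
  viol <- list()
  note <- function(outcome, file, row, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(
      outcome = outcome, file = file, row = row, message = msg,
      stringsAsFactors = FALSE)
  }
  for (oc in config$outcomes) {
    if (!file.exists(oc$data)) {
      note(oc$name, oc$data, NA_integer_, "file does not exist")
      next
    }
    df <- tryCatch(read.csv(oc$data, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) {
      note(oc$name, oc$data, NA_integer_, "unreadable CSV")
      next
    }
    if ("outcome" %in% names(df)) {
      bad <- which(df$outcome != oc$name)
      for (r in bad) note(oc$name, oc$data, r, paste0(
        "row labelled outcome '", df$outcome[r], "', expected '",
        oc$name, "'"))
    }
    if (oc$kind == "contrast") {
      has_hr <- all(c("hr", "ci_low", "ci_high") %in% names(df))
      has_log <- all(c("log_hr", "se") %in% names(df)) ||
        all(c("log_effect", "se") %in% names(df))
      if (!has_hr && !has_log) {
        note(oc$name, oc$data, NA_integer_,
             "neither hr/ci_low/ci_high nor log_hr/se columns present")
        next
      }
      if (has_hr && ("log_hr" %in% names(df))) {
        both <- which(!is.na(df$hr) & !is.na(df$log_hr))
        for (r in both) note(oc$name, oc$data, r,
                             "both hr and log_hr filled (ambiguous)")
      }
      secol <- if ("se" %in% names(df)) df$se else NULL
      if (!is.null(secol)) {
        for (r in which(!is.na(secol) & secol <= 0)) {
          note(oc$name, oc$data, r, "non-positive standard error")
        }
      }
    } else {
      need <- c("trial_id", "treatment", "n", "events")
      miss <- setdiff(need, names(df))
      if (length(miss) > 0L) {
        note(oc$name, oc$data, NA_integer_,
             paste("missing columns:", paste(miss, collapse = ", ")))
        next
      }
      for (r in which(df$events > df$n)) {
        note(oc$name, oc$data, r,
             sprintf("trial '%s': events (%s) exceed n (%s)",
                     df$trial_id[r], df$events[r], df$n[r]))
      }
      for (r in which(df$n < 1)) {
        note(oc$name, oc$data, r, "sample size below 1")
      }
      if (oc$kind == "ae" &&
          ("follow_up_months" %in% names(df) || "follow_up" %in% names(df))) {
        fu <- df$follow_up_months %||% df$follow_up
        for (r in which(!is.na(fu) & fu <= 0)) {
          note(oc$name, oc$data, r, "non-positive follow-up")
        }
      }
      arm_count <- table(df$trial_id)
      for (tid in names(arm_count)[arm_count < 2L]) {
        note(oc$name, oc$data, NA_integer_,
             sprintf("trial '%s' contributes a single arm", tid))
      }
    }
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(outcome = character(0L), file = character(0L),
               row = integer(0L), message = character(0L))
  class(out) <- c("nma_validation", "data.frame")
  out
}

.load_outcome_records <- function(oc) {
  if (oc$kind == "contrast") {
    read_contrasts(oc$data)
  } else {
    read_arms(oc$data)
  }
}

.write_posterior_outputs <- function(post, dir, prefix, direction,
                                     tie_seed) {
  write.csv(post$summaries,
            file.path(dir, paste0(prefix, "_posterior_summary.csv")),
            row.names = FALSE)
  jsonlite::write_json(post$fit,
                       file.path(dir, paste0(prefix, "_fit.json")),
                       auto_unbox = TRUE, digits = NA)
  rk <- treatment_ranks(post, direction, tie_seed)
  write.csv(data.frame(treatment = names(rk$sucra),
                       p_best = unname(rk$p_best),
                       sucra = unname(rk$sucra),
                       mean_rank = unname(rk$mean_rank)),
            file.path(dir, paste0(prefix, "_rankings.csv")),
            row.names = FALSE)
  lt <- league_table(post, direction, tie_seed)
  write.csv(lt$cells, file.path(dir, paste0(prefix, "_league.csv")))
  write.csv(lt$significant,
            file.path(dir, paste0(prefix, "_league_significant.csv")))
  invisible(rk)
}

.run_one_outcome <- function(oc, config, out_dir, exclude = character(0L)) {
  records <- .load_outcome_records(oc)
  if (length(exclude) > 0L) {
    records <- records[!(records$trial_id %in% exclude), , drop = FALSE]
  }
  net <- build_network(records, oc$name, reference = oc$reference %||%
                         config$reference %||% NULL)
  mm <- .merge_map_from_config(config)
  mm <- mm[names(mm) %in% net$treatments$id]
  if (length(mm) > 0L) net <- merge_nodes(net, mm)
  network_to_dot(net, file.path(out_dir, paste0(oc$name, "_network.dot")))

  status <- "ok"
  if (oc$kind == "ae") {
    fit <- fit_pl_cloglog(net)
    se <- sqrt(diag(fit$cov))
    write.csv(data.frame(treatment = names(fit$d_hat),
                         log_dhr = unname(fit$d_hat), se = se,
                         dhr = exp(unname(fit$d_hat)),
                         lo95 = exp(unname(fit$d_hat) - 1.96 * se),
                         hi95 = exp(unname(fit$d_hat) + 1.96 * se)),
              file.path(out_dir, paste0(oc$name, "_pl_summary.csv")),
              row.names = FALSE)
    write.csv(relative_discrete_hazards(fit),
              file.path(out_dir, paste0(oc$name, "_league_pl.csv")),
              row.names = FALSE)
    if (!fit$converged) status <- "failed-diagnostics"
    return(list(network = net, fits = list(pl = fit), status = status))
  }

  fitter <- if (oc$kind == "contrast") fit_contrast_nma else fit_binary_nma
  mcmc <- config$mcmc
  mcmc$seed <- substream_seed(config$seed, paste0("fit-", oc$name))
  post_re <- fitter(net, model = "random", priors = config$priors,
                    mcmc = mcmc)
  post_fe <- fitter(net, model = "fixed", priors = config$priors,
                    mcmc = mcmc)
  tie_seed <- substream_seed(config$seed, paste0("ranks-", oc$name))
  .write_posterior_outputs(post_re, out_dir, paste0(oc$name, "_random"),
                           oc$direction, tie_seed)
  .write_posterior_outputs(post_fe, out_dir, paste0(oc$name, "_fixed"),
                           oc$direction, tie_seed)
  cons <- NULL
  if (oc$kind == "contrast") {
    cons <- consistency_checks(net, model = "fixed",
                               priors = config$priors, mcmc = mcmc)
    write.csv(cons, file.path(out_dir, paste0(oc$name, "_consistency.csv")),
              row.names = FALSE)
  }
  if (!post_re$converged || !post_fe$converged) status <- "failed-diagnostics"
  list(network = net, fits = list(random = post_re, fixed = post_fe),
       consistency = cons, status = status)
}

#' Run the full analysis pipeline for a configuration
#'
#' For every declared outcome: validate, build the network (with configured
#' node merges), fit the designated models — random-effects primary plus
#' fixed-effect secondary Bayesian NMA for efficacy outcomes, fixed-effect
#' penalized-likelihood cloglog NMA for safety outcomes — and write
#' rankings, league tables, consistency checks, network diagrams and a
#' machine-readable manifest to the output directory. Sensitivity re-runs
#' repeat configured outcomes with listed trials removed.
#'
#' @param config an `nma_config`, a list coercible to one, or a YAML path.
#' @param strict error (rather than warn) on validation violations.
#' @return invisible list of per-outcome results plus the manifest.
#' @export
run_pipeline <- function(config, strict = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "nma_config")) config <- as_nma_config(config)
  report <- validate_inputs(config)
  if (nrow(report) > 0L) {
    msg <- paste0(nrow(report), " validation violation(s); first: ",
                  report$message[1L])
    if (strict) stop(msg) else log_msg("WARN", "pipeline", msg)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  statuses <- list()
  for (oc in config$outcomes) {
    log_msg("INFO", "pipeline", paste("fitting outcome", oc$name))
    res <- .run_one_outcome(oc, config, out_dir)
    results[[oc$name]] <- res
    statuses[[oc$name]] <- res$status
  }
  sens <- config$sensitivity %||% list()
  if (length(sens$exclude_trials %||% character(0L)) > 0L) {
    for (nm in (sens$outcomes %||%
                vapply(config$outcomes, `[[`, "", "name"))) {
      oc <- config$outcomes[[which(vapply(config$outcomes, `[[`, "",
                                          "name") == nm)]]
      key <- paste0(nm, "_sensitivity")
      log_msg("INFO", "pipeline", paste("sensitivity re-run for", nm))
      sdir <- file.path(out_dir, "sensitivity")
      dir.create(sdir, showWarnings = FALSE)
      res <- .run_one_outcome(oc, config, sdir,
                              exclude = unlist(sens$exclude_trials))
      results[[key]] <- res
      statuses[[key]] <- res$status
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nmakit")),
    seed = config$seed,
    mcmc = unclass(config$mcmc),
    priors = unclass(config$priors),
    outcomes = statuses,
    sensitivity_excluded = sens$exclude_trials %||% character(0L),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
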