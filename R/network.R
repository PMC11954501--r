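#' Evidence networks for network meta-analysis
#'
#' An evidence network represents treatments as nodes and randomized trials
#' as (multi-)edges for a single outcome. Networks are built from either
#' contrast-level records (one relative effect per treatment pair and trial)
#' or arm-level records (one row per trial arm). The network carries its
#' records so downstream model fits always see data consistent with the
#' declared structure.
#'
#' @name evidence_network
NULL

.is_contrast_records <- function(records) {
  all(c("trial_id", "treatment", "baseline_treatment") %in% names(records))
}

.is_arm_records <- function(records) {
  all(c("trial_id", "treatment", "n") %in% names(records)) &&
    !("baseline_treatment" %in% names(records))
}

#' Build an evidence network from trial records
#'
#' @param records data.frame of contrast-level records (columns `trial_id`,
#'   `outcome`, `treatment`, `baseline_treatment`, `log_effect`, `se`) or
#'   arm-level records (columns `trial_id`, `outcome`, `treatment`, `n`,
#'   optionally `events`, `follow_up`).
#' @param outcome outcome label; all records must share it.
#' @param reference reference treatment id. Defaults to a merged
#'   placebo/best-supportive-care style node when one is present (ids
#'   matching `pbo`, `placebo` or `bsc`), else the lexicographically first
#'   treatment.
#' @param labels optional named character vector mapping treatment ids to
#'   human-readable regimen labels.
#' @return an object of class `evidence_network` with elements `outcome`,
#'   `reference`, `treatments` (data.frame id/label), `trials` (list of arm
#'   vectors), `edges` (data.frame trial_id/t1/t2) and `records`.
#' @export
build_network <- function(records, outcome, reference = NULL, labels = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if ("outcome" %in% names(records)) {
    if (!all(records$outcome == outcome)) {
      stop("all records must share the outcome '", outcome, "'")
    }
  }
  records$trial_id <- as.character(records$trial_id)
  records$treatment <- as.character(records$treatment)

  if (.is_contrast_records(records)) {
    records$baseline_treatment <- as.character(records$baseline_treatment)
    if (any(records$treatment == records$baseline_treatment)) {
      stop("contrast with identical treatment and baseline")
    }
    if (!("se" %in% names(records)) || any(!is.finite(records$se)) ||
        any(records$se <= 0)) {
      stop("contrast records require finite positive standard errors")
    }
    key <- paste(records$trial_id,
                 pmin(records$treatment, records$baseline_treatment),
                 pmax(records$treatment, records$baseline_treatment))
    if (anyDuplicated(key)) {
      dup <- records$trial_id[duplicated(key)][1L]
      stop("duplicate (trial, treatment pair) rows in trial '", dup, "'")
    }
    trials <- lapply(split(records, records$trial_id), function(df) {
      base <- unique(df$baseline_treatment)
      if (length(base) != 1L) {
        stop("trial '", df$trial_id[1L],
             "' has contrasts against multiple baselines")
      }
      c(base, df$treatment)
    })
    edges <- data.frame(trial_id = records$trial_id,
                        t1 = records$baseline_treatment,
                        t2 = records$treatment,
                        stringsAsFactors = FALSE)
    kind <- "contrast"
  } else if (.is_arm_records(records)) {
    if (any(records$n < 1)) stop("arm sample sizes must be >= 1")
    if ("events" %in% names(records)) {
      bad <- !is.na(records$events) &
        (records$events < 0 | records$events > records$n)
      if (any(bad)) {
        stop("events outside [0, n] in trial '",
             records$trial_id[bad][1L], "'")
      }
    }
    key <- paste(records$trial_id, records$treatment)
    if (anyDuplicated(key)) {
      dup <- records$trial_id[duplicated(key)][1L]
      stop("duplicate (trial, treatment) arm rows in trial '", dup, "'")
    }
    trials <- lapply(split(records, records$trial_id), function(df) df$treatment)
    edges <- do.call(rbind, lapply(names(trials), function(tid) {
      arms <- trials[[tid]]
      if (length(arms) < 2L) return(NULL)
      pr <- utils::combn(arms, 2L)
      data.frame(trial_id = tid, t1 = pr[1L, ], t2 = pr[2L, ],
                 stringsAsFactors = FALSE)
    }))
    kind <- "arm"
  } else {
    stop("records are neither contrast-level nor arm-level ",
         "(see ?build_network for the required columns)")
  }

  single <- names(trials)[vapply(trials, function(a) length(unique(a)) < 2L,
                                 logical(1L))]
  if (length(single) > 0L) {
    stop("trial(s) with a single arm: ", paste(single, collapse = ", "))
  }

  ids <- sort(unique(unlist(trials, use.names = FALSE)))
  if (is.null(reference)) {
    pref <- ids[grepl("^(pbo|placebo|bsc)", ids, ignore.case = TRUE)]
    reference <- if (length(pref) > 0L) pref[1L] else ids[1L]
  }
  if (!(reference %in% ids)) {
    stop("reference treatment '", reference, "' is not in the network")
  }
  lab <- if (is.null(labels)) setNames(ids, ids) else {
    out <- ifelse(ids %in% names(labels), labels[ids], ids)
    setNames(out, ids)
  }
  if (any(!nzchar(lab))) stop("treatment labels must be non-empty")

  structure(list(outcome = outcome,
                 reference = reference,
                 treatments = data.frame(id = ids, label = unname(lab[ids]),
                                         stringsAsFactors = FALSE),
                 trials = trials,
                 edges = edges,
                 records = records,
                 kind = kind),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat(sprintf("Evidence network for outcome '%s'\n", x$outcome))
  cat(sprintf("  %d treatments, %d trials, %d edges (reference: %s)\n",
              nrow(x$treatments), length(x$trials), nrow(x$edges),
              x$reference))
  invisible(x)
}

#' Merge treatment nodes
#'
#' Relabels arms according to `merge_map` (e.g. pooling all
#' placebo/corticosteroid arms into one node regardless of route of
#' administration) and rebuilds the network. A trial whose arms all collapse
#' onto a single node no longer carries a contrast; it is dropped with a
#' warning rather than silently.
#'
#' @param network an `evidence_network`.
#' @param merge_map named character vector, `old id -> merged id`.
#' @return a rebuilt `evidence_network`.
#' @export
merge_nodes <- function(network, merge_map) {
  stopifnot(inherits(network, "evidence_network"))
  if (length(merge_map) == 0L) return(network)
  unknown <- setdiff(names(merge_map), network$treatments$id)
  if (length(unknown) > 0L) {
    stop("merge_map keys not in network: ", paste(unknown, collapse = ", "))
  }
  relabel <- function(x) ifelse(x %in% names(merge_map), merge_map[x], x)

  rec <- network$records
  rec$treatment <- unname(relabel(rec$treatment))
  if (network$kind == "contrast") {
    rec$baseline_treatment <- unname(relabel(rec$baseline_treatment))
    degenerate <- rec$treatment == rec$baseline_treatment
    drop_trials <- unique(rec$trial_id[degenerate])
    rec <- rec[!degenerate, , drop = FALSE]
    # a multi-arm trial may keep other contrasts; only fully-collapsed
    # trials disappear
    gone <- setdiff(drop_trials, rec$trial_id)
  } else {
    # merged arms within a trial are pooled
    key <- paste(rec$trial_id, rec$treatment)
    if (anyDuplicated(key)) {
      agg_cols <- intersect(c("n", "events"), names(rec))
      pooled <- lapply(split(rec, key), function(df) {
        out <- df[1L, , drop = FALSE]
        for (cc in agg_cols) out[[cc]] <- sum(df[[cc]])
        if ("follow_up" %in% names(df)) {
          out$follow_up <- sum(df$follow_up * df$n) / sum(df$n)
        }
        out
      })
      rec <- do.call(rbind, pooled)
      rownames(rec) <- NULL
    }
    n_arms <- table(rec$trial_id)
    gone <- names(n_arms)[n_arms < 2L]
    rec <- rec[!(rec$trial_id %in% gone), , drop = FALSE]
  }
  if (length(gone) > 0L) {
    warning("merge collapsed all arms of trial(s) ",
            paste(gone, collapse = ", "), "; dropped from the network")
  }
  if (nrow(rec) == 0L) stop("merge removed every trial from the network")
  ref <- unname(relabel(network$reference))
  build_network(rec, network$outcome, reference = ref)
}

#' Treatments reachable from the reference
#'
#' Breadth-first closure over trial edges. Treatments outside the component
#' cannot be compared with the reference and their trials are excluded from
#' model fitting.
#'
#' @param network an `evidence_network`.
#' @return list with `component` (reachable treatment ids, including the
#'   reference) and `excluded` (unreachable ids).
#' @export
connected_component <- function(network) {
  stopifnot(inherits(network, "evidence_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("t1", "t2")], directed = FALSE,
    vertices = network$treatments$id)
  comp <- igraph::components(g)
  ref_comp <- comp$membership[network$reference]
  inside <- names(comp$membership)[comp$membership == ref_comp]
  if (length(inside) < 2L) {
    stop("reference treatment '", network$reference,
         "' is isolated in the network")
  }
  list(component = sort(inside),
       excluded = sort(setdiff(network$treatments$id, inside)))
}

#' Remove a trial (sensitivity analysis)
#'
#' Drops one trial's records and rebuilds the network, reporting treatments
#' that become disconnected from the reference as a consequence.
#'
#' @param network an `evidence_network`.
#' @param trial_id trial to remove.
#' @return the rebuilt `evidence_network`, with attribute `"orphaned"`
#'   listing treatments newly disconnected from the reference.
#' @export
remove_trial <- function(network, trial_id) {
  stopifnot(inherits(network, "evidence_network"))
  if (!(trial_id %in% names(network$trials))) {
    stop("unknown trial '", trial_id, "'")
  }
  rec <- network$records[network$records$trial_id != trial_id, , drop = FALSE]
  if (nrow(rec) == 0L) stop("removing trial '", trial_id,
                            "' empties the network")
  out <- build_network(rec, network$outcome, reference = network$reference)
  before <- connected_component(network)$component
  after <- connected_component(out)$component
  # newly unreachable, whether still present as disconnected nodes or gone
  orphaned <- sort(setdiff(before, after))
  if (length(orphaned) > 0L) {
    log_msg("WARN", "network",
            sprintf("removing trial '%s' orphans treatment(s): %s",
                    trial_id, paste(orphaned, collapse = ", ")))
  }
  attr(out, "orphaned") <- orphaned
  out
}

trial_arms <- function(network, trial_id) {
  unique(network$trials[[trial_id]])
}

#' Restrict a network's records to the reference component
#' @noRd
component_records <- function(network) {
  cc <- connected_component(network)
  rec <- network$records
  if (length(cc$excluded) > 0L) {
    if (network$kind == "contrast") {
      keep <- rec$treatment %in% cc$component &
        rec$baseline_treatment %in% cc$component
    } else {
      keep <- rec$treatment %in% cc$component
    }
    dropped <- unique(rec$trial_id[!keep])
    log_msg("WARN", "network",
            sprintf("excluding disconnected trial(s): %s",
                    paste(dropped, collapse = ", ")))
    rec <- rec[keep, , drop = FALSE]
  }
  list(records = rec, component = cc$component)
}

#' Export a network as a DOT graph
#'
#' One node per treatment, one edge per trial-pair, edge labelled with the
#' trial id.
#'
#' @param network an `evidence_network`.
#' @param file optional path; when given the DOT text is written there.
#' @return the DOT source as a character scalar, invisibly when `file` is
#'   given.
#' @export
network_to_dot <- function(network, file = NULL) {
  stopifnot(inherits(network, "evidence_network"))
  quote_id <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  nodes <- sprintf("  %s [label=%s];",
                   quote_id(network$treatments$id),
                   quote_id(network$treatments$label))
  edges <- sprintf("  %s -- %s [label=%s];",
                   quote_id(network$edges$t1), quote_id(network$edges$t2),
                   quote_id(network$edges$trial_id))
  dot <- paste(c(sprintf("graph %s {", quote_id(network$outcome)),
                 nodes, edges, "}"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
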