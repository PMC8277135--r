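#' Mining scenarios and stressor ranking
#'
#' A scenario is a combination of decision-variable states describing one
#' mining operation (plus optional evidence on random variables, e.g. known
#' contaminant release). Scenario queries report the posterior total and
#' indirect mortality distributions for each benthic functional group;
#' stressor ranking sweeps one pressure at a time and measures the change in
#' class-midpoint expected mortality between its extreme states.
#'
#' @name scenario-engine
NULL

#' Construct a mining scenario
#'
#' @param name Scenario name.
#' @param decisions Named list of decision-variable states.
#' @param evidence Named list of observed random-variable states.
#' @return Object of class `mining_scenario`.
#' @export
scenario <- function(name, decisions = list(), evidence = list()) {
  structure(list(name = as.character(name),
                 decisions = lapply(decisions, as.character),
                 evidence = lapply(evidence, as.character)),
            class = "mining_scenario")
}

#' @export
print.mining_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s\n", x$name,
              paste(c(sprintf("%s=%s", names(x$decisions), unlist(x$decisions)),
                      sprintf("%s=%s (evidence)", names(x$evidence),
                              unlist(x$evidence))), collapse = ", ")))
  invisible(x)
}

scenario_fingerprint <- function(sc) {
  a <- c(unlist(sc$decisions), unlist(sc$evidence))
  a <- a[order(names(a))]
  paste(sprintf("%s=%s", names(a), a), collapse = ";")
}

mortality_targets <- function(network) {
  if (is.null(network$groups)) {
    stop("network has no functional-group metadata; pass targets explicitly")
  }
  out <- list()
  for (g in names(network$groups)) {
    out[[length(out) + 1L]] <- list(group = g, kind = "total",
                                    node = network$groups[[g]]$total)
    out[[length(out) + 1L]] <- list(group = g, kind = "indirect",
                                    node = network$groups[[g]]$indirect)
  }
  out
}

#' Evaluate one mining scenario
#'
#' Computes the posterior total- and indirect-mortality distribution of each
#' benthic functional group under the scenario's decision assignments and
#' evidence. Decision variables not set by the scenario are resolved by the
#' policy (a message notes each defaulted variable).
#'
#' @param network A `bn_network` with group metadata (see [build_network]).
#' @param sc A [scenario].
#' @param policy Policy for unset decision variables (default `"uniform"`,
#'   logged).
#' @param scheme A [mortality_scheme] used for expected-mortality summaries.
#' @return Object of class `scenario_result`: list with `name`, `table`
#'   (long data frame: scenario, group, kind, state, probability),
#'   `posteriors`, `most_probable`, `fingerprint`.
#' @export
run_scenario <- function(network, sc, policy = "uniform",
                         scheme = mortality_scheme()) {
  stopifnot(inherits(sc, "mining_scenario"))
  evidence <- c(sc$decisions, sc$evidence)
  targets <- mortality_targets(network)
  unset <- setdiff(network_variables(network, "decision"), names(evidence))
  if (length(unset)) {
    message("scenario '", sc$name, "': decision variable(s) ",
            paste(unset, collapse = ", "), " resolved by policy")
  }
  posteriors <- list(); rows <- list(); mps <- list()
  for (tg in targets) {
    po <- bn_posterior(network, tg$node, evidence, policy = policy)
    key <- paste(tg$group, tg$kind, sep = ".")
    posteriors[[key]] <- po
    mps[[key]] <- most_probable_state(po)
    rows[[key]] <- data.frame(
      scenario = sc$name, group = tg$group, kind = tg$kind,
      state = names(po$prob), probability = unname(po$prob),
      stringsAsFactors = FALSE)
  }
  structure(list(name = sc$name,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 posteriors = posteriors, most_probable = mps,
                 fingerprint = scenario_fingerprint(sc)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%s)\n", x$name, x$fingerprint))
  for (k in names(x$most_probable)) {
    m <- x$most_probable[[k]]
    cat(sprintf("  %-28s most probable %s (p=%.3f)%s\n", k, m$state,
                m$probability, if (m$tie) " [tie]" else ""))
  }
  invisible(x)
}

#' Compare several scenarios
#'
#' @param network A `bn_network` with group metadata.
#' @param scenarios List of [scenario] objects with unique names.
#' @param policy,scheme Passed to [run_scenario].
#' @return Long data frame keyed by (scenario, group, kind, state) with a
#'   probability column; probabilities sum to 1 within each
#'   (scenario, group, kind).
#' @export
compare_scenarios <- function(network, scenarios, policy = "uniform",
                              scheme = mortality_scheme()) {
  nms <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate scenario names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  do.call(rbind, lapply(scenarios, function(sc) {
    run_scenario(network, sc, policy, scheme)$table
  }))
}

#' Rank stressors by their effect on a mortality node
#'
#' Each stressor is swept over its states while everything else is held at
#' the baseline scenario; the effect size is the difference in class-midpoint
#' expected mortality between the extreme (most vs least harmful) states.
#' The total-variation distance between the two extreme posteriors is
#' reported alongside. Stressors that are not ancestors of the target get a
#' warning and effect 0.
#'
#' @param network A `bn_network`.
#' @param target A mortality node (5-class state space).
#' @param stressors Character vector of variables to sweep.
#' @param baseline A [scenario] providing the held-fixed context.
#' @param policy Policy for unset decision variables.
#' @param sweep If `TRUE`, also compute the full factorial sweep over all
#'   stressor-state combinations (returned as `$sweep`).
#' @param scheme A [mortality_scheme].
#' @return Object of class `stressor_report`: `ranking` data frame (stressor,
#'   effect_size, tv_distance, best_state, worst_state) sorted by descending
#'   effect, `details` per-state expectations, and optionally `sweep`.
#' @export
rank_stressors <- function(network, target, stressors, baseline,
                           policy = "uniform", sweep = FALSE,
                           scheme = mortality_scheme()) {
  stopifnot(inherits(baseline, "mining_scenario"))
  base_ev <- c(baseline$decisions, baseline$evidence)
  anc <- names(igraph::subcomponent(network$graph, target, mode = "in"))
  rows <- list(); details <- list()
  for (s in stressors) {
    states <- network$specs[[s]]$states
    if (!s %in% anc || s == target) {
      warning("stressor '", s, "' is not an ancestor of ", target,
              "; effect size 0")
      rows[[s]] <- data.frame(stressor = s, effect_size = 0, tv_distance = 0,
                              best_state = NA_character_,
                              worst_state = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    ev <- lapply(states, function(st) {
      e <- base_ev; e[[s]] <- st
      bn_posterior(network, target, e, policy = policy)$prob
    })
    em <- vapply(ev, expected_mortality, numeric(1), scheme = scheme)
    hi <- which.max(em); lo <- which.min(em)
    rows[[s]] <- data.frame(
      stressor = s, effect_size = em[hi] - em[lo],
      tv_distance = 0.5 * sum(abs(ev[[hi]] - ev[[lo]])),
      best_state = states[lo], worst_state = states[hi],
      stringsAsFactors = FALSE)
    details[[s]] <- data.frame(stressor = s, state = states,
                               expected_mortality = em,
                               stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ranking <- ranking[order(-ranking$effect_size, ranking$stressor), ]
  rownames(ranking) <- NULL
  out <- list(ranking = ranking,
              details = if (length(details)) do.call(rbind, c(details, list(make.row.names = FALSE))) else NULL,
              target = target, baseline = baseline$name)
  if (sweep) {
    swept <- stressors[stressors %in% anc & stressors != target]
    grid <- combo_grid(stats::setNames(
      lapply(swept, function(s) network$specs[[s]]$states), swept))
    grid$expected_mortality <- vapply(seq_len(nrow(grid)), function(i) {
      e <- base_ev
      for (s in swept) e[[s]] <- grid[i, s]
      expected_mortality(bn_posterior(network, target, e, policy = policy)$prob,
                         scheme)
    }, numeric(1))
    out$sweep <- grid
  }
  structure(out, class = "stressor_report")
}

#' @export
print.stressor_report <- function(x, ...) {
  cat(sprintf("<stressor_report> target %s (baseline %s)\n", x$target, x$baseline))
  print(x$ranking)
  invisible(x)
}

#' Read a scenario file
#'
#' Structured text: each scenario starts with `scenario <name>`, followed by
#' indented `set <decision> = <state>` and `evidence <variable> = <state>`
#' lines.
#'
#' @param path Input path.
#' @return Named list of [scenario] objects.
#' @export
read_scenario_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list(); cur <- NULL
  flush <- function() {
    if (!is.null(cur)) out[[cur$name]] <<- scenario(cur$name, cur$dec, cur$ev)
  }
  for (ln in lines) {
    if (grepl("^scenario ", ln)) {
      flush()
      cur <- list(name = trimws(sub("^scenario ", "", ln)),
                  dec = list(), ev = list())
    } else if (grepl("^\\s+(set|evidence) ", ln)) {
      if (is.null(cur)) stop("assignment before any 'scenario' line: ", ln)
      body <- trimws(ln)
      kv <- regmatches(body, regexec("^(set|evidence) (\\S+) = (.+)$", body))[[1]]
      if (length(kv) != 4) stop("malformed scenario line: ", ln)
      if (kv[2] == "set") cur$dec[[kv[3]]] <- trimws(kv[4])
      else cur$ev[[kv[3]]] <- trimws(kv[4])
    } else stop("unrecognized scenario line: ", ln)
  }
  flush()
  if (!length(out)) stop("no scenarios in ", path)
  out
}

#' Write scenarios to a scenario file
#' @param scenarios List of [scenario] objects.
#' @param path Output path.
#' @export
write_scenario_file <- function(scenarios, path) {
  out <- character()
  for (sc in scenarios) {
    out <- c(out, paste0("scenario ", sc$name),
             sprintf("  set %s = %s", names(sc$decisions), unlist(sc$decisions)),
             if (length(sc$evidence))
               sprintf("  evidence %s = %s", names(sc$evidence), unlist(sc$evidence)))
  }
  writeLines(out, path)
  invisible(path)
}
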