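#' Discrete Bayesian networks with decision and random nodes
#'
#' The quantitative risk model is a discrete Bayesian network. Random
#' variables carry conditional probability tables (CPTs); decision variables
#' (mining intensity, extraction depth, processing return technique) carry no
#' prior and must be fixed by a scenario or covered by an explicit policy at
#' query time. Inference is exact, by variable elimination.
#'
#' @name bn-core
NULL

#' Declare a network variable
#'
#' @param name Variable name.
#' @param states Ordered character vector of >= 2 unique state labels. Order
#'   is meaningful for ordinal variables such as the five relative-mortality
#'   classes.
#' @param kind `"random"` or `"decision"`.
#' @param category Free-text category tag (e.g. "extraction technique").
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, states, kind = c("random", "decision"),
                          category = NA_character_) {
  kind <- match.arg(kind)
  states <- as.character(states)
  if (length(states) < 2) stop("variable ", name, " needs >= 2 states")
  if (anyDuplicated(states)) stop("duplicate states for variable ", name)
  structure(list(name = as.character(name), states = states, kind = kind,
                 category = as.character(category)),
            class = "variable_spec")
}

# canonical parent-combination keys: first parent varies fastest
combo_grid <- function(parent_states) {
  if (!length(parent_states)) return(data.frame(row.names = "1"))
  g <- expand.grid(parent_states, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- names(parent_states)
  g
}

combo_keys <- function(parent_states) {
  g <- combo_grid(parent_states)
  if (!ncol(g)) return("")
  do.call(paste, c(unname(g), sep = "|"))
}

#' Construct a conditional probability table
#'
#' Rows are indexed by parent-state combinations in canonical order (first
#' parent varying fastest); columns by the child's states. Every row must sum
#' to 1 within 1e-9. A root variable has a single row (its prior).
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (may be empty).
#' @param child_states Ordered states of the child.
#' @param parent_states Named list of parent state vectors, in `parents` order.
#' @param table Numeric matrix (rows = parent combinations, cols = child
#'   states) or a vector for a root prior.
#' @param tol Row-sum tolerance, default 1e-9.
#' @return Object of class `cpt`.
#' @export
cpt <- function(child, parents = character(), child_states, parent_states = list(),
                table, tol = 1e-9) {
  parents <- as.character(parents)
  if (!identical(names(parent_states), parents) && length(parents)) {
    parent_states <- parent_states[parents]
  }
  keys <- combo_keys(parent_states)
  if (is.vector(table) && !is.matrix(table)) table <- matrix(table, nrow = 1)
  table <- as.matrix(table)
  if (nrow(table) != length(keys)) {
    stop(sprintf("CPT for %s: %d rows but %d parent combinations",
                 child, nrow(table), length(keys)))
  }
  if (ncol(table) != length(child_states)) {
    stop(sprintf("CPT for %s: %d columns but %d child states",
                 child, ncol(table), length(child_states)))
  }
  if (any(table < 0)) stop("CPT for ", child, ": negative entries")
  rs <- rowSums(table)
  if (any(abs(rs - 1) > tol)) {
    i <- which(abs(rs - 1) > tol)[1]
    stop(sprintf("CPT for %s: row '%s' sums to %.12g (tolerance %g)",
                 child, keys[i], rs[i], tol))
  }
  dimnames(table) <- list(keys, child_states)
  structure(list(child = as.character(child), parents = parents,
                 child_states = as.character(child_states),
                 parent_states = parent_states, table = table),
            class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("<cpt> %s | %s  (%d rows x %d states)\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = ", ") else "(root)",
              nrow(x$table), ncol(x$table)))
  invisible(x)
}

#' Look up one CPT row by parent assignment
#' @param x A [cpt].
#' @param assignment Named list/vector of parent states.
#' @return Named probability vector over child states.
#' @export
cpt_row <- function(x, assignment = list()) {
  stopifnot(inherits(x, "cpt"))
  if (!length(x$parents)) return(x$table[1, ])
  key <- paste(vapply(x$parents, function(p) as.character(assignment[[p]]),
                      character(1)), collapse = "|")
  if (!key %in% rownames(x$table)) {
    stop(sprintf("CPT for %s: no row for parent combination '%s'", x$child, key))
  }
  x$table[key, ]
}

#' Assemble and validate a Bayesian network
#'
#' Checks that every CPT parent is declared, that the implied graph is
#' acyclic (any cycle is named in the error), that every random variable has
#' exactly one CPT with complete rows, and that decision variables have none.
#'
#' @param specs List of [variable_spec] objects.
#' @param cpts List of [cpt] objects, one per random variable.
#' @param groups Optional named list tagging benthic functional groups with
#'   their direct/indirect/total mortality node names (used by the scenario
#'   engine); each element is `list(direct=, indirect=, total=)`.
#' @return Object of class `bn_network`.
#' @export
build_network <- function(specs, cpts, groups = NULL) {
  stopifnot(all(vapply(specs, inherits, logical(1), "variable_spec")),
            all(vapply(cpts, inherits, logical(1), "cpt")))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  names(cpts) <- vapply(cpts, `[[`, character(1), "child")
  if (anyDuplicated(names(specs))) stop("duplicate variable names")
  for (ct in cpts) {
    if (!ct$child %in% names(specs)) stop("CPT child not declared: ", ct$child)
    sp <- specs[[ct$child]]
    if (sp$kind == "decision") stop("decision variable has a CPT: ", ct$child)
    if (!identical(ct$child_states, sp$states)) {
      stop("CPT states disagree with spec for ", ct$child)
    }
    for (p in ct$parents) {
      if (!p %in% names(specs)) stop("CPT parent not declared: ", p,
                                     " (child ", ct$child, ")")
      if (!identical(ct$parent_states[[p]], specs[[p]]$states)) {
        stop("CPT parent states disagree with spec: ", p, " (child ", ct$child, ")")
      }
    }
  }
  rand <- names(specs)[vapply(specs, function(s) s$kind == "random", logical(1))]
  missing_cpt <- setdiff(rand, names(cpts))
  if (length(missing_cpt)) stop("random variable(s) without CPT: ",
                                paste(missing_cpt, collapse = ", "))
  edges <- do.call(rbind, lapply(cpts, function(ct) {
    if (!length(ct$parents)) return(NULL)
    cbind(ct$parents, ct$child)
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(names(specs))
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc)
    stop("network is cyclic; e.g. removing edge ",
         ends[1, 1], " -> ", ends[1, 2], " would break a cycle")
  }
  structure(list(specs = specs, cpts = cpts, graph = g, groups = groups),
            class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  nd <- sum(vapply(x$specs, function(s) s$kind == "decision", logical(1)))
  cat(sprintf("<bn_network> %d variables (%d decision, %d random), %d edges\n",
              length(x$specs), nd, length(x$specs) - nd,
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Variables of a network
#' @param network A `bn_network`.
#' @param kind Optional filter, `"random"` or `"decision"`.
#' @return Character vector of variable names.
#' @export
network_variables <- function(network, kind = NULL) {
  v <- names(network$specs)
  if (is.null(kind)) return(v)
  v[vapply(network$specs, function(s) s$kind == kind, logical(1))]
}

resolve_policy <- function(network, evidence, policy) {
  dec <- network_variables(network, "decision")
  uncovered <- setdiff(dec, names(evidence))
  out <- list()
  for (v in uncovered) {
    states <- network$specs[[v]]$states
    p <- NULL
    if (is.character(policy) && identical(policy, "uniform")) {
      p <- rep(1 / length(states), length(states))
      names(p) <- states
    } else if (is.list(policy) && v %in% names(policy)) {
      pv <- policy[[v]]
      if (is.character(pv)) {
        if (!pv %in% states) stop("policy state '", pv, "' invalid for ", v)
        p <- as.numeric(states == pv); names(p) <- states
      } else {
        p <- as.numeric(pv)
        if (length(p) != length(states) || abs(sum(p) - 1) > 1e-9) {
          stop("policy distribution for ", v, " invalid")
        }
        names(p) <- states
      }
    }
    if (is.null(p)) {
      stop("decision variable '", v,
           "' is neither in evidence nor covered by the policy")
    }
    out[[v]] <- p
  }
  out
}

check_evidence <- function(network, evidence) {
  for (v in names(evidence)) {
    if (!v %in% names(network$specs)) stop("evidence variable not declared: ", v)
    st <- as.character(evidence[[v]])
    if (!st %in% network$specs[[v]]$states) {
      stop(sprintf("evidence state '%s' invalid for variable %s", st, v))
    }
  }
  lapply(evidence, as.character)
}

# ---- factor algebra on data frames -----------------------------------------

cpt_factor <- function(ct) {
  g <- combo_grid(ct$parent_states)
  k <- length(ct$child_states)
  df <- g[rep(seq_len(max(1L, nrow(g))), each = k), , drop = FALSE]
  df[[ct$child]] <- rep(ct$child_states, times = max(1L, nrow(g)))
  df$p <- as.vector(t(ct$table))
  rownames(df) <- NULL
  df
}

prior_factor <- function(var, dist) {
  data.frame(stats::setNames(list(names(dist)), var), p = as.numeric(dist),
             stringsAsFactors = FALSE)
}

factor_vars <- function(f) setdiff(names(f), "p")

factor_reduce <- function(f, evidence) {
  for (v in intersect(factor_vars(f), names(evidence))) {
    f <- f[f[[v]] == evidence[[v]], setdiff(names(f), v), drop = FALSE]
  }
  f
}

factor_product <- function(f1, f2) {
  common <- intersect(factor_vars(f1), factor_vars(f2))
  if (length(common)) {
    m <- merge(f1, f2, by = common)
  } else {
    m <- merge(f1, f2, by = NULL)  # cartesian
  }
  m$p <- m$p.x * m$p.y
  m[, c(setdiff(names(m), c("p.x", "p.y", "p")), "p"), drop = FALSE]
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(factor_vars(f), var)
  if (!length(keep)) {
    return(data.frame(p = sum(f$p)))
  }
  agg <- stats::aggregate(f["p"], f[keep], sum)
  agg
}

# ---- inference -------------------------------------------------------------

#' Joint probability of a full assignment
#'
#' Chain-rule product of CPT entries, times the policy mass of each decision
#' variable (fixed states contribute an indicator, distributions their mass;
#' with `policy = NULL` an assigned decision variable contributes 1).
#'
#' @param network A `bn_network`.
#' @param assignment Named list covering every variable.
#' @param policy `NULL`, `"uniform"`, or a named list of fixed states /
#'   probability vectors for decision variables.
#' @return Probability in \[0, 1\].
#' @export
joint_probability <- function(network, assignment, policy = NULL) {
  missing <- setdiff(names(network$specs), names(assignment))
  if (length(missing)) stop("incomplete assignment; missing: ",
                            paste(missing, collapse = ", "))
  assignment <- check_evidence(network, assignment)
  p <- 1
  for (ct in network$cpts) {
    row <- cpt_row(ct, assignment)
    p <- p * unname(row[assignment[[ct$child]]])
  }
  for (v in network_variables(network, "decision")) {
    states <- network$specs[[v]]$states
    mass <- 1
    if (is.character(policy) && identical(policy, "uniform")) {
      mass <- 1 / length(states)
    } else if (is.list(policy) && v %in% names(policy)) {
      pv <- policy[[v]]
      mass <- if (is.character(pv)) as.numeric(pv == assignment[[v]])
              else as.numeric(pv[match(assignment[[v]], states)])
    }
    p <- p * mass
  }
  p
}

#' Exact posterior of a variable by variable elimination
#'
#' @param network A `bn_network`.
#' @param query Variable name to query.
#' @param evidence Named list of observed/assigned states (decision
#'   assignments go here too).
#' @param policy Policy for decision variables not in evidence: `NULL`
#'   (error if any uncovered), `"uniform"`, or a named list of fixed states
#'   or probability vectors.
#' @param elim_order Optional explicit elimination order (character vector);
#'   the posterior is invariant to it.
#' @return Object of class `bn_posterior`: list with `variable`, `prob`
#'   (named vector over states), `evidence`, `policy_note`.
#' @export
bn_posterior <- function(network, query, evidence = list(), policy = NULL,
                         elim_order = NULL) {
  if (!query %in% names(network$specs)) stop("unknown query variable: ", query)
  evidence <- check_evidence(network, evidence)
  pol <- resolve_policy(network, evidence, policy)
  states <- network$specs[[query]]$states
  if (query %in% names(evidence)) {
    pr <- as.numeric(states == evidence[[query]])
    names(pr) <- states
    return(structure(list(variable = query, prob = pr, evidence = evidence,
                          policy_note = names(pol)), class = "bn_posterior"))
  }
  factors <- lapply(unname(network$cpts), cpt_factor)
  for (v in names(pol)) factors <- c(factors, list(prior_factor(v, pol[[v]])))
  factors <- lapply(factors, factor_reduce, evidence = evidence)
  factors <- Filter(function(f) length(factor_vars(f)) > 0 || nrow(f) > 0, factors)
  todo <- setdiff(unique(unlist(lapply(factors, factor_vars))), query)
  if (!is.null(elim_order)) {
    if (!setequal(intersect(elim_order, todo), todo)) {
      stop("elim_order must cover all non-query, non-evidence variables")
    }
    order_fun <- function(remaining) intersect(elim_order, remaining)[1]
  } else {
    order_fun <- function(remaining) {
      # greedy: eliminate the variable whose combined factor is smallest
      cost <- vapply(remaining, function(v) {
        sc <- unique(unlist(lapply(factors, function(f)
          if (v %in% factor_vars(f)) factor_vars(f) else NULL)))
        prod(vapply(sc, function(u) length(network$specs[[u]]$states), numeric(1)))
      }, numeric(1))
      remaining[which.min(cost)]
    }
  }
  while (length(todo)) {
    v <- order_fun(todo)
    todo <- setdiff(todo, v)
    has <- vapply(factors, function(f) v %in% factor_vars(f), logical(1))
    if (!any(has)) next
    prod_f <- Reduce(factor_product, factors[has])
    factors <- c(factors[!has], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  res <- factor_marginalize(res, setdiff(factor_vars(res), query))
  pr <- stats::setNames(rep(0, length(states)), states)
  pr[res[[query]]] <- res$p
  z <- sum(pr)
  if (z <= 0) stop("contradictory evidence: zero marginal likelihood")
  pr <- pr / z
  structure(list(variable = query, prob = pr, evidence = evidence,
                 policy_note = names(pol)), class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, ...) {
  cat(sprintf("<posterior> %s\n", x$variable))
  print(round(x$prob, 4))
  if (length(x$policy_note)) {
    cat("policy applied to:", paste(x$policy_note, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Most probable state of a posterior
#'
#' Ties are broken toward the earlier-ordered (lower-severity) state and
#' flagged.
#'
#' @param posterior A `bn_posterior` or a named probability vector.
#' @param tol Tie tolerance, default 1e-12.
#' @return List with `state`, `probability`, `tie` (logical).
#' @export
most_probable_state <- function(posterior, tol = 1e-12) {
  p <- if (inherits(posterior, "bn_posterior")) posterior$prob else posterior
  i <- which.max(p)  # first maximum = earliest-ordered state
  tie <- sum(p >= p[i] - tol) > 1
  list(state = names(p)[i], probability = unname(p[i]), tie = tie)
}

#' Write posteriors as a delimited long table
#'
#' @param posteriors List of `bn_posterior` objects.
#' @param path Output path.
#' @param sep Field separator.
#' @return The table, invisibly.
#' @export
write_posteriors <- function(posteriors, path, sep = ",") {
  rows <- do.call(rbind, lapply(posteriors, function(po) {
    fp <- paste(sprintf("%s=%s", names(po$evidence), unlist(po$evidence)),
                collapse = ";")
    data.frame(variable = po$variable, state = names(po$prob),
               probability = unname(po$prob), evidence = fp,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(rows)
}
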