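#' CPT elicitation from ranked parent influences
#'
#' Direct elicitation of full conditional probability tables is labour
#' intensive; instead, an expert ranks the direction (+/-) and magnitude
#' (nonnegative weight) of each parent's influence on the child, and the
#' table is initialized by a scoring algorithm. The scoring scheme used here
#' is a documented reimplementation choice (the original elicitation tool's
#' internals are not public): each parent combination gets a signed weighted
#' score, which is rescaled to \[0, 1\] over its attainable range and used as
#' the centre of a truncated-normal kernel over the child state indices.
#' Explicitly adjusted rows always take precedence over initialized ones.
#'
#' @name cpt-elicitation
NULL

#' Declare an influence ranking for one child variable
#'
#' @param child Child variable name.
#' @param influences Named list, one element per parent. Each element is
#'   either `list(direction = +1 or -1, weight = w)` for an ordinal parent
#'   (higher parent state pushes the child toward higher/lower states), or
#'   `list(offsets = c(...), weight = w)` for a nominal parent, giving a
#'   per-state score offset instead of a direction.
#' @param baseline Probability vector over child states used when the
#'   ranking carries no influence at all (zero weight range); `NULL` means
#'   no fallback and such rankings are an error.
#' @param spread Kernel standard deviation in child-state-index units. The
#'   default 1.0 keeps a neutral score spread over >= 3 states with mass
#'   >= 0.05 for a 5-state child, avoiding false certainty.
#' @return Object of class `influence_ranking`.
#' @export
influence_ranking <- function(child, influences, baseline = NULL, spread = 1.0) {
  stopifnot(is.list(influences), !is.null(names(influences)))
  for (nm in names(influences)) {
    inf <- influences[[nm]]
    w <- inf$weight %||% 1
    if (w < 0) stop("negative weight for parent ", nm)
    if (is.null(inf$offsets) && is.null(inf$direction)) {
      stop("influence for ", nm, " needs a direction or per-state offsets")
    }
    if (!is.null(inf$direction) && !inf$direction %in% c(-1, 1)) {
      stop("direction for ", nm, " must be +1 or -1")
    }
    # canonical field order so rankings compare equal after file round trips
    influences[[nm]] <- if (is.null(inf$offsets)) {
      list(weight = w, direction = inf$direction)
    } else {
      list(weight = w, offsets = inf$offsets)
    }
  }
  if (!is.null(baseline)) {
    if (any(baseline < 0) || abs(sum(baseline) - 1) > 1e-9) {
      stop("baseline must be a probability vector")
    }
  }
  if (spread <= 0) stop("spread must be positive")
  structure(list(child = child, influences = influences, baseline = baseline,
                 spread = spread), class = "influence_ranking")
}

# evenly map ordinal state index to [0,1]
rank01 <- function(i, k) if (k == 1) 0.5 else (i - 1) / (k - 1)

# discretized truncated-normal kernel over state indices 0..k-1
score_kernel <- function(center01, k, spread) {
  mu <- center01 * (k - 1)
  w <- exp(-0.5 * ((seq_len(k) - 1 - mu) / spread)^2)
  w / sum(w)
}

#' Initialize a CPT from an influence ranking
#'
#' For each parent-state combination the signed score
#' `s = sum_p weight_p * direction_p * rank01(state_p)` (nominal parents
#' contribute `weight_p * offset_p[state]`) is rescaled over its attainable
#' range to \[0, 1\] and mapped to a discretized unimodal distribution over
#' the child states, centred at `s01 * (K - 1)` with dispersion `spread`.
#' If the ranking carries no influence (zero score range), every row equals
#' the baseline.
#'
#' @param child_spec [variable_spec] of the child.
#' @param parent_specs List of [variable_spec] for the parents, in order.
#' @param ranking An [influence_ranking] covering exactly those parents.
#' @param spread Overrides the ranking's spread when given.
#' @return A [cpt] with one row per parent combination.
#' @export
initialize_cpt <- function(child_spec, parent_specs, ranking, spread = NULL) {
  stopifnot(inherits(ranking, "influence_ranking"))
  spread <- spread %||% ranking$spread
  parents <- vapply(parent_specs, `[[`, character(1), "name")
  if (!setequal(parents, names(ranking$influences))) {
    stop("ranking parents disagree with parent_specs")
  }
  pstates <- stats::setNames(lapply(parent_specs, `[[`, "states"), parents)
  k <- length(child_spec$states)
  grid <- combo_grid(pstates)
  # per-parent score contribution for every state
  contrib <- lapply(parents, function(p) {
    inf <- ranking$influences[[p]]
    w <- inf$weight %||% 1
    np <- length(pstates[[p]])
    if (!is.null(inf$offsets)) {
      if (length(inf$offsets) != np) stop("offsets length mismatch for ", p)
      stats::setNames(w * inf$offsets, pstates[[p]])
    } else {
      stats::setNames(w * inf$direction * rank01(seq_len(np), np), pstates[[p]])
    }
  })
  names(contrib) <- parents
  lo <- sum(vapply(contrib, min, numeric(1)))
  hi <- sum(vapply(contrib, max, numeric(1)))
  n <- max(1L, nrow(grid))
  tab <- matrix(NA_real_, n, k)
  if (hi - lo <= 1e-12) {
    if (is.null(ranking$baseline)) {
      stop("ranking has zero influence range and no baseline")
    }
    tab <- matrix(rep(ranking$baseline, each = n), n, k)
  } else {
    for (i in seq_len(n)) {
      s <- sum(vapply(parents, function(p) contrib[[p]][[grid[i, p]]], numeric(1)))
      tab[i, ] <- score_kernel((s - lo) / (hi - lo), k, spread)
    }
  }
  cpt(child_spec$name, parents, child_spec$states, pstates, tab)
}

#' Replace specific CPT rows with expert-adjusted distributions
#'
#' Mirrors the second elicitation session: initialized rows are reviewed and
#' selected rows replaced verbatim. An audit log of changed rows is attached
#' as the `audit` attribute (row key, old and new vectors).
#'
#' @param x A [cpt].
#' @param overrides List of `list(combo = named parent states, p = vector)`.
#' @return The adjusted [cpt].
#' @export
adjust_cpt <- function(x, overrides) {
  stopifnot(inherits(x, "cpt"))
  audit <- list()
  for (ov in overrides) {
    key <- if (length(x$parents)) {
      paste(vapply(x$parents, function(p) as.character(ov$combo[[p]]),
                   character(1)), collapse = "|")
    } else rownames(x$table)[1]
    if (!key %in% rownames(x$table)) {
      stop("unknown parent combination: ", key)
    }
    p <- as.numeric(ov$p)
    if (length(p) != ncol(x$table) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("override for '", key, "' is not a valid distribution")
    }
    audit[[length(audit) + 1L]] <- data.frame(
      row = key, old = paste(fmt_p(x$table[key, ]), collapse = " "),
      new = paste(fmt_p(p), collapse = " "), stringsAsFactors = FALSE)
    x$table[key, ] <- p
  }
  attr(x, "audit") <- if (length(audit)) do.call(rbind, audit) else NULL
  x
}

#' Write a CPT adjustment audit log
#' @param x A [cpt] returned by [adjust_cpt].
#' @param path Output path.
#' @param session Session tag recorded on every row.
#' @export
write_cpt_audit <- function(x, path, session = "session-2") {
  audit <- attr(x, "audit")
  if (is.null(audit)) audit <- data.frame(row = character(), old = character(),
                                          new = character())
  audit$session <- rep(session, nrow(audit))
  utils::write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a random CPT (test fixture generator)
#'
#' Rows are drawn from a symmetric Dirichlet. With `monotone = TRUE`, rows
#' are reordered so that parent combinations with higher total ordinal score
#' receive first-order stochastically larger child distributions: the CDF
#' columns are sorted across score-ordered rows, which preserves row-wise
#' monotonicity (order statistics of pointwise-ordered sequences) and yields
#' a full pairwise dominance chain.
#'
#' @param child_spec [variable_spec] of the child.
#' @param parent_specs List of parent [variable_spec]s (may be empty for a
#'   root prior).
#' @param seed Integer seed; same seed gives an identical CPT.
#' @param concentration Dirichlet concentration; large values approach
#'   uniform rows.
#' @param monotone Enforce stochastic monotonicity in the parents.
#' @return A [cpt].
#' @export
random_cpt <- function(child_spec, parent_specs = list(), seed = 1,
                       concentration = 1, monotone = FALSE) {
  parents <- vapply(parent_specs, `[[`, character(1), "name")
  pstates <- stats::setNames(lapply(parent_specs, `[[`, "states"), parents)
  k <- length(child_spec$states)
  grid <- combo_grid(pstates)
  n <- max(1L, nrow(grid))
  tab <- withr_seed(seed, {
    g <- matrix(stats::rgamma(n * k, shape = concentration), n, k)
    g / rowSums(g)
  })
  if (monotone && length(parents)) {
    score <- rowSums(vapply(parents, function(p) {
      np <- length(pstates[[p]])
      rank01(match(grid[[p]], pstates[[p]]), np)
    }, numeric(n)))
    ord <- order(score)  # stable; ties keep canonical order
    cdf <- t(apply(tab, 1, cumsum))
    cdf <- apply(cdf, 2, function(col) sort(col, decreasing = TRUE))
    cdf <- matrix(cdf, n, k)
    rows <- cbind(cdf[, 1, drop = FALSE],
                  cdf[, -1, drop = FALSE] - cdf[, -k, drop = FALSE])
    rows[rows < 0] <- 0
    rows <- rows / rowSums(rows)
    tab[ord, ] <- rows
  }
  cpt(child_spec$name, parents, child_spec$states, pstates, tab)
}

# run code under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write an influence ranking to a structured text file
#' @param ranking An [influence_ranking].
#' @param path Output path.
#' @export
write_ranking_file <- function(ranking, path) {
  out <- c(paste0("child ", ranking$child),
           paste0("  spread: ", fmt_p(ranking$spread)))
  if (!is.null(ranking$baseline)) {
    out <- c(out, paste0("  baseline: ",
                         paste(fmt_p(ranking$baseline), collapse = " ")))
  }
  for (nm in names(ranking$influences)) {
    inf <- ranking$influences[[nm]]
    w <- inf$weight %||% 1
    if (!is.null(inf$offsets)) {
      out <- c(out, sprintf("  parent %s weight %s offsets %s", nm, fmt_p(w),
                            paste(fmt_p(inf$offsets), collapse = " ")))
    } else {
      out <- c(out, sprintf("  parent %s weight %s direction %+d", nm,
                            fmt_p(w), inf$direction))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an influence ranking file written by [write_ranking_file]
#' @param path Input path.
#' @return An [influence_ranking].
#' @export
read_ranking_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  child <- trimws(sub("^child ", "", lines[1]))
  spread <- 1.0; baseline <- NULL; influences <- list()
  for (ln in lines[-1]) {
    body <- trimws(ln)
    if (grepl("^spread:", body)) {
      spread <- as.numeric(sub("^spread:", "", body))
    } else if (grepl("^baseline:", body)) {
      baseline <- as.numeric(strsplit(trimws(sub("^baseline:", "", body)),
                                      "\\s+")[[1]])
    } else if (grepl("^parent ", body)) {
      m <- regmatches(body, regexec(
        "^parent (\\S+) weight (\\S+) (direction|offsets) (.*)$", body))[[1]]
      if (length(m) != 5) stop("malformed parent line: ", body)
      inf <- list(weight = as.numeric(m[3]))
      if (m[4] == "direction") {
        inf$direction <- as.integer(m[5])
      } else {
        inf$offsets <- as.numeric(strsplit(trimws(m[5]), "\\s+")[[1]])
      }
      influences[[m[2]]] <- inf
    } else stop("unrecognized ranking line: ", body)
  }
  influence_ranking(child, influences, baseline = baseline, spread = spread)
}
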