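#' Direct, indirect, and total mortality on the 1% grid
#'
#' Relative mortality of a benthic functional group is discretized into five
#' ordered classes (0-10 / 11-30 / 31-60 / 61-80 / 81-100%). Total mortality
#' combines the direct mortality from substrate extraction with the indirect
#' mortality of the remaining fauna exposed to pressures:
#' `total = direct + indirect * (1 - direct)`. The combination is computed by
#' numerical approximation at 1% accuracy: class distributions are expanded
#' to the integer-percent grid 0..100 (uniform within each class), combined
#' pairwise, and re-binned into classes.
#'
#' @name mortality
NULL

#' The five relative-mortality classes
#'
#' @param breaks Not configurable by default; the standard scheme covers
#'   0..100 with intervals 0-10, 11-30, 31-60, 61-80, 81-100.
#' @return Object of class `mortality_scheme`: data frame with `label`,
#'   `lo`, `hi` (integer percent bounds, inclusive).
#' @export
mortality_scheme <- function(breaks = c(10L, 30L, 60L, 80L, 100L)) {
  breaks <- as.integer(breaks)
  stopifnot(!is.unsorted(breaks, strictly = TRUE), breaks[length(breaks)] == 100L)
  lo <- c(0L, utils::head(breaks, -1) + 1L)
  hi <- breaks
  structure(data.frame(label = sprintf("%d-%d%%", lo, hi), lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("mortality_scheme", "data.frame"))
}

#' Class midpoints of a mortality scheme
#' @param scheme A [mortality_scheme].
#' @return Numeric vector of interval midpoints in percent (default scheme:
#'   5, 20.5, 45.5, 70.5, 90.5).
#' @export
scheme_midpoints <- function(scheme = mortality_scheme()) {
  (scheme$lo + scheme$hi) / 2
}

check_dist <- function(p, n, what, tol = 1e-9) {
  if (length(p) != n) stop(what, ": expected length ", n, ", got ", length(p))
  if (any(p < 0)) stop(what, ": negative probabilities")
  if (abs(sum(p) - 1) > tol) stop(what, ": probabilities sum to ", sum(p))
  p
}

#' Expand a class distribution to the 1% grid
#'
#' Each class's mass is spread uniformly over the integer percents inside
#' its interval (the within-class distribution is not dictated by the class
#' scheme; uniform is the documented default and is swappable by expanding
#' manually).
#'
#' @param class_dist Probability vector over the scheme's classes.
#' @param scheme A [mortality_scheme].
#' @return Probability vector of length 101 over 0..100 percent, named by
#'   grid value.
#' @export
class_to_grid <- function(class_dist, scheme = mortality_scheme()) {
  class_dist <- check_dist(class_dist, nrow(scheme), "class distribution")
  g <- stats::setNames(rep(0, 101), 0:100)
  for (i in seq_len(nrow(scheme))) {
    idx <- (scheme$lo[i]:scheme$hi[i]) + 1L
    g[idx] <- g[idx] + class_dist[i] / length(idx)
  }
  g
}

#' Re-bin a 1% grid distribution into mortality classes
#'
#' @param grid_dist Probability vector of length 101 over 0..100 percent.
#' @param scheme A [mortality_scheme].
#' @return Probability vector over the classes, named by class label.
#' @export
grid_to_class <- function(grid_dist, scheme = mortality_scheme()) {
  grid_dist <- check_dist(grid_dist, 101, "grid distribution")
  out <- stats::setNames(numeric(nrow(scheme)), scheme$label)
  for (i in seq_len(nrow(scheme))) {
    out[i] <- sum(grid_dist[(scheme$lo[i]:scheme$hi[i]) + 1L])
  }
  out
}

# round half-up to nearest integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Combine direct and indirect mortality on the 1% grid
#'
#' For every pair of grid values (d, i), the total is
#' `t = d + i * (100 - d) / 100`, rounded half-up to the nearest integer
#' percent; the joint mass `p(d) * p(i)` accumulates at t. Direct and
#' indirect mortality are treated as independent given their parents.
#'
#' @param direct,indirect Grid distributions (length 101 over 0..100).
#' @return Grid distribution of total mortality.
#' @export
combine_mortality <- function(direct, indirect) {
  direct <- check_dist(direct, 101, "direct")
  indirect <- check_dist(indirect, 101, "indirect")
  d <- 0:100
  out <- numeric(101)
  for (j in which(indirect > 0)) {
    i <- j - 1L
    t_idx <- round_half_up(d + i * (100 - d) / 100) + 1L
    contrib <- direct * indirect[j]
    for (u in unique(t_idx)) out[u] <- out[u] + sum(contrib[t_idx == u])
  }
  out <- out / sum(out)
  stats::setNames(out, 0:100)
}

#' Direct mortality implied by mining intensity
#'
#' Direct mortality is proportionate to the mined area: intensity x% removed
#' gives a point mass at x. An optional dispersion widens the distribution
#' symmetrically (truncated-normal weights over a symmetric window around x,
#' so the expected mortality always equals the stated intensity; near the
#' grid boundaries the window shrinks to preserve symmetry).
#'
#' @param intensity One of 50, 75, 100 (percent of concretions removed), or
#'   any integer percent.
#' @param dispersion Nonnegative kernel width in percent; 0 gives the point
#'   mass.
#' @return Grid [0..100] probability vector.
#' @export
direct_mortality_from_intensity <- function(intensity, dispersion = 0) {
  intensity <- suppressWarnings(as.numeric(intensity))
  if (is.na(intensity) || intensity < 0 || intensity > 100 ||
      intensity != round(intensity)) {
    stop("unknown mining intensity state; expected an integer percent in 0..100")
  }
  g <- stats::setNames(numeric(101), 0:100)
  if (dispersion <= 0) {
    g[intensity + 1L] <- 1
    return(g)
  }
  half <- min(floor(3 * dispersion), intensity, 100 - intensity)
  off <- -half:half
  w <- exp(-0.5 * (off / dispersion)^2)
  g[intensity + off + 1L] <- w / sum(w)
  g
}

#' Deterministic CPT for the total-mortality node
#'
#' For each (direct class, indirect class) pair, both classes are expanded
#' to the 1% grid, combined with [combine_mortality], and re-binned; the 25
#' resulting rows form the CPT of total mortality given direct and indirect
#' mortality.
#'
#' @param direct_node,indirect_node Names of the parent variables (both must
#'   use the 5-class mortality state space).
#' @param total_node Name of the child; default `"total_mortality"`.
#' @param scheme A [mortality_scheme].
#' @return A [cpt] with 25 rows.
#' @export
build_total_mortality_cpt <- function(direct_node, indirect_node,
                                      total_node = "total_mortality",
                                      scheme = mortality_scheme()) {
  k <- nrow(scheme)
  pstates <- stats::setNames(list(scheme$label, scheme$label),
                             c(direct_node, indirect_node))
  grid <- combo_grid(pstates)
  tab <- matrix(NA_real_, nrow(grid), k)
  point <- function(i) { p <- numeric(k); p[i] <- 1; p }
  for (r in seq_len(nrow(grid))) {
    di <- match(grid[[direct_node]][r], scheme$label)
    ii <- match(grid[[indirect_node]][r], scheme$label)
    total <- combine_mortality(class_to_grid(point(di), scheme),
                               class_to_grid(point(ii), scheme))
    tab[r, ] <- grid_to_class(total, scheme)
  }
  cpt(total_node, c(direct_node, indirect_node), scheme$label, pstates, tab)
}

#' Expected mortality of a class distribution
#'
#' Class-midpoint expectation in percent; the summary statistic used for
#' stressor ranking.
#'
#' @param class_dist Probability vector over the scheme's classes.
#' @param scheme A [mortality_scheme].
#' @return Expected mortality in percent.
#' @export
expected_mortality <- function(class_dist, scheme = mortality_scheme()) {
  class_dist <- check_dist(class_dist, nrow(scheme), "class distribution")
  sum(class_dist * scheme_midpoints(scheme))
}
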