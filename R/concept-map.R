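#' Expert concept maps and their combination
#'
#' A concept map is one expert's directed causal graph over named variables,
#' optionally with link strengths on a 1-3 scale (3 strongest). Individual
#' maps are harmonized against a synonym table (so that, e.g., "worms" and
#' "polychaetes" collapse onto one canonical label) and merged into a single
#' combined causal network that keeps per-expert provenance on every edge.
#'
#' @name concept-maps
NULL

#' Construct a concept map
#'
#' @param expert_id Opaque identifier of the expert.
#' @param links Data frame with columns `source`, `target` and optionally
#'   `strength` (integer 1-3 or `NA`).
#' @param nodes Optional character vector of node labels; defaults to the
#'   union of link endpoints. Extra isolated nodes are allowed.
#' @return An object of class `concept_map`.
#' @export
concept_map <- function(expert_id, links, nodes = NULL) {
  stopifnot(is.data.frame(links))
  if (!all(c("source", "target") %in% names(links))) {
    stop("links must have columns 'source' and 'target'")
  }
  links$source <- as.character(links$source)
  links$target <- as.character(links$target)
  if (is.null(links$strength)) links$strength <- NA_integer_
  links$strength <- as.integer(links$strength)
  bad <- !is.na(links$strength) & !(links$strength %in% 1:3)
  if (any(bad)) {
    stop(sprintf("link strength outside 1-3 for %s -> %s",
                 links$source[bad][1], links$target[bad][1]))
  }
  loops <- links$source == links$target
  if (any(loops)) {
    stop(sprintf("self-loop not allowed: %s -> %s (expert %s)",
                 links$source[loops][1], links$target[loops][1], expert_id))
  }
  endpoints <- unique(c(links$source, links$target))
  nodes <- sort(unique(c(endpoints, as.character(nodes))))
  links <- links[order(links$source, links$target), c("source", "target", "strength")]
  rownames(links) <- NULL
  structure(list(expert_id = as.character(expert_id),
                 nodes = nodes, links = links),
            class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  cat(sprintf("<concept_map> expert %s: %d nodes, %d links\n",
              x$expert_id, length(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Read concept maps from a delimited edge list
#'
#' Each non-comment line is `expert_id,source,target[,strength]`. Lines
#' starting with `#` and blank lines are ignored. A header line starting with
#' `expert_id` is skipped. Malformed strengths and self-loops are rejected
#' with the offending line number.
#'
#' @param path Path to the edge-list file.
#' @param sep Field separator, default comma.
#' @return A named list of [concept_map] objects, one per expert, in order
#'   of first appearance.
#' @export
read_concept_maps <- function(path, sep = ",") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- list()
  for (i in idx) {
    f <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    if (i == idx[1] && identical(tolower(f[1]), "expert_id")) next
    if (length(f) < 3 || length(f) > 4) {
      stop(sprintf("line %d: expected 3 or 4 fields, got %d", i, length(f)))
    }
    strength <- NA_integer_
    if (length(f) == 4 && nzchar(f[4])) {
      s <- suppressWarnings(as.integer(f[4]))
      if (is.na(s) || !(s %in% 1:3) || as.character(s) != f[4]) {
        stop(sprintf("line %d: strength '%s' not an integer in 1-3", i, f[4]))
      }
      strength <- s
    }
    if (f[2] == f[3]) {
      stop(sprintf("line %d: self-loop %s -> %s", i, f[2], f[3]))
    }
    recs[[length(recs) + 1L]] <- data.frame(
      expert_id = f[1], source = f[2], target = f[3],
      strength = strength, stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("no records in ", path)
  recs <- do.call(rbind, recs)
  ids <- unique(recs$expert_id)
  maps <- lapply(ids, function(id) {
    concept_map(id, recs[recs$expert_id == id, c("source", "target", "strength")])
  })
  names(maps) <- ids
  maps
}

#' Read a synonym table
#'
#' Two-column delimited text mapping raw labels to canonical labels. The
#' table must be closed after one application: canonical labels may not be
#' mapped onward.
#'
#' @param path Path to the file.
#' @param sep Field separator, default comma.
#' @return Named character vector `raw -> canonical` of class `synonym_table`.
#' @export
read_synonym_table <- function(path, sep = ",") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  raw <- character(); canon <- character()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    if (i == 1L && identical(tolower(f[1]), "raw")) next
    if (length(f) != 2) stop("synonym table line has ", length(f), " fields: ", lines[i])
    raw <- c(raw, f[1]); canon <- c(canon, f[2])
  }
  synonym_table(stats::setNames(canon, raw))
}

#' Construct a synonym table
#'
#' @param mapping Named character vector, names are raw labels, values the
#'   canonical labels they are grouped under.
#' @return The validated mapping, class `synonym_table`.
#' @export
synonym_table <- function(mapping) {
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop("synonym mapping must be named (raw -> canonical)")
  }
  onward <- intersect(mapping, names(mapping))
  onward <- onward[mapping[onward] != onward]
  if (length(onward)) {
    stop("synonym table not closed after one application: canonical label(s) ",
         paste(onward, collapse = ", "), " are mapped onward")
  }
  structure(mapping, class = "synonym_table")
}

apply_synonyms <- function(labels, synonyms) {
  if (is.null(synonyms) || !length(synonyms)) return(labels)
  hit <- labels %in% names(synonyms)
  labels[hit] <- unname(unclass(synonyms)[labels[hit]])
  labels
}

#' Harmonize a concept map against a synonym table
#'
#' Replaces raw labels by their canonical forms. Links made parallel by the
#' relabeling are collapsed keeping the maximum strength (missing strengths
#' lose to any stated strength). Links collapsed onto a self-loop are dropped
#' and recorded in the `dropped_self_loops` attribute.
#'
#' @param map A [concept_map].
#' @param synonyms A [synonym_table] (may be empty or `NULL`).
#' @return The harmonized [concept_map]. Idempotent: harmonizing twice
#'   changes nothing.
#' @export
harmonize <- function(map, synonyms = NULL) {
  stopifnot(inherits(map, "concept_map"))
  if (!is.null(synonyms) && !inherits(synonyms, "synonym_table")) {
    synonyms <- synonym_table(synonyms)
  }
  links <- map$links
  links$source <- apply_synonyms(links$source, synonyms)
  links$target <- apply_synonyms(links$target, synonyms)
  loops <- links$source == links$target
  dropped <- links[loops, , drop = FALSE]
  links <- links[!loops, , drop = FALSE]
  if (nrow(links)) {
    key <- paste(links$source, links$target, sep = "\r")
    strength <- tapply(links$strength, key, function(s) {
      if (all(is.na(s))) NA_integer_ else max(s, na.rm = TRUE)
    })
    first <- !duplicated(key)
    links <- links[first, , drop = FALSE]
    links$strength <- as.integer(strength[paste(links$source, links$target, sep = "\r")])
  }
  nodes <- unique(apply_synonyms(map$nodes, synonyms))
  out <- concept_map(map$expert_id, links, nodes = nodes)
  if (nrow(dropped)) {
    attr(out, "dropped_self_loops") <- dropped
    message(sprintf("harmonize: dropped %d self-loop(s) created by relabeling (expert %s)",
                    nrow(dropped), map$expert_id))
  }
  out
}

#' Merge harmonized concept maps into a combined causal network
#'
#' The combined network is the non-redundant union of all nodes and links.
#' Every edge keeps the full set of per-expert strength records and a
#' supporting-expert count. Cycles are permitted at this stage; acyclicity
#' is only enforced when a subnetwork is promoted to a Bayesian network.
#'
#' @param maps List of [concept_map] objects (already harmonized).
#' @param categories Optional named character vector tagging node labels with
#'   a category (e.g. pressure, biological component).
#' @return An object of class `combined_network` with elements `nodes`
#'   (data frame: label, category), `edges` (data frame: source, target,
#'   n_experts, max_strength) and `records` (per-expert edge records).
#' @export
merge_concept_maps <- function(maps, categories = NULL) {
  if (!length(maps)) stop("merge_concept_maps: empty list of maps")
  stopifnot(all(vapply(maps, inherits, logical(1), "concept_map")))
  recs <- do.call(rbind, lapply(maps, function(m) {
    if (!nrow(m$links)) return(NULL)
    cbind(expert_id = m$expert_id, m$links, stringsAsFactors = FALSE)
  }))
  nodes <- sort(unique(unlist(lapply(maps, `[[`, "nodes"))))
  if (is.null(recs)) recs <- data.frame(expert_id = character(), source = character(),
                                        target = character(), strength = integer())
  recs <- recs[order(recs$source, recs$target, recs$expert_id), , drop = FALSE]
  rownames(recs) <- NULL
  key <- paste(recs$source, recs$target, sep = "\r")
  ukey <- unique(key)
  edges <- data.frame(
    source = sub("\r.*$", "", ukey),
    target = sub("^.*\r", "", ukey),
    n_experts = as.integer(tapply(recs$expert_id, key, length)[ukey]),
    max_strength = as.integer(tapply(recs$strength, key, function(s) {
      if (all(is.na(s))) NA_integer_ else max(s, na.rm = TRUE)
    })[ukey]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  cat_col <- rep(NA_character_, length(nodes))
  if (!is.null(categories)) cat_col <- unname(categories[nodes])
  structure(list(
    nodes = data.frame(label = nodes, category = cat_col, stringsAsFactors = FALSE),
    edges = edges, records = recs),
    class = "combined_network")
}

#' @export
print.combined_network <- function(x, ...) {
  cat(sprintf("<combined_network> %d nodes, %d edges (%d expert records)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$records)))
  invisible(x)
}

#' Adjacency matrix of a combined network
#'
#' @param network A `combined_network`.
#' @param weight_rule One of `"none"` (0/1 indicator), `"support_count"`
#'   (number of supporting experts) or `"max_strength"` (maximum elicited
#'   strength; edges with no elicited strength get 1).
#' @return Square numeric matrix with lexicographically ordered row/column
#'   labels; entry (i, j) nonzero iff edge i -> j exists.
#' @export
network_adjacency <- function(network, weight_rule = c("none", "support_count", "max_strength")) {
  stopifnot(inherits(network, "combined_network"))
  weight_rule <- match.arg(weight_rule)
  labs <- sort(network$nodes$label)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  e <- network$edges
  w <- switch(weight_rule,
              none = rep(1, nrow(e)),
              support_count = e$n_experts,
              max_strength = ifelse(is.na(e$max_strength), 1L, e$max_strength))
  m[cbind(match(e$source, labs), match(e$target, labs))] <- w
  m
}

#' Rebuild a combined network from an adjacency matrix
#'
#' Inverse of [network_adjacency] at the topology level: nonzero entries
#' become edges. Support counts are taken from the entries when the matrix
#' was written with `weight_rule = "support_count"`, otherwise set to 1.
#'
#' @param mat Square matrix with identical row and column labels.
#' @param weight_rule How the entries should be interpreted.
#' @return A `combined_network` (records carry a single pseudo-expert).
#' @export
adjacency_to_network <- function(mat, weight_rule = c("none", "support_count", "max_strength")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            identical(rownames(mat), colnames(mat)))
  nz <- which(mat != 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(mat)[nz[, 1]],
                      target = colnames(mat)[nz[, 2]],
                      w = mat[nz], stringsAsFactors = FALSE)
  links <- data.frame(source = edges$source, target = edges$target,
                      strength = if (weight_rule == "max_strength")
                        as.integer(edges$w) else NA_integer_,
                      stringsAsFactors = FALSE)
  net <- merge_concept_maps(list(concept_map("adjacency", links, nodes = rownames(mat))))
  if (weight_rule == "support_count") {
    key <- paste(net$edges$source, net$edges$target, sep = "\r")
    ekey <- paste(edges$source, edges$target, sep = "\r")
    net$edges$n_experts <- as.integer(edges$w[match(key, ekey)])
  }
  net
}

#' Write an adjacency matrix as delimited text
#'
#' @param mat Matrix from [network_adjacency].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_adjacency <- function(mat, path, sep = ",") {
  utils::write.table(mat, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read an adjacency matrix written by [write_adjacency]
#' @param path Input path.
#' @param sep Field separator.
#' @return Numeric matrix with row/column labels.
#' @export
read_adjacency <- function(path, sep = ",") {
  as.matrix(utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Summary counts of a combined network
#'
#' @param network A `combined_network`.
#' @return List with `n_nodes`, `n_edges`, `by_category` (named counts) and
#'   `degrees` (data frame: label, out_degree, in_degree).
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "combined_network"))
  labs <- network$nodes$label
  outd <- table(factor(network$edges$source, levels = labs))
  ind <- table(factor(network$edges$target, levels = labs))
  list(n_nodes = nrow(network$nodes),
       n_edges = nrow(network$edges),
       by_category = table(network$nodes$category, useNA = "ifany"),
       degrees = data.frame(label = labs,
                            out_degree = as.integer(outd),
                            in_degree = as.integer(ind),
                            stringsAsFactors = FALSE))
}

combined_to_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")],
    directed = TRUE,
    vertices = network$nodes[, "label", drop = FALSE])
  igraph::V(g)$category <- ifelse(is.na(network$nodes$category), "",
                                  network$nodes$category)
  igraph::E(g)$support <- network$edges$n_experts
  igraph::E(g)$max_strength <- ifelse(is.na(network$edges$max_strength), 0L,
                                      network$edges$max_strength)
  g
}

#' Export a combined network to GraphML
#' @param network A `combined_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(combined_to_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a combined network to Graphviz DOT
#' @param network A `combined_network`.
#' @param path Output path.
#' @export
write_network_dot <- function(network, path) {
  igraph::write_graph(combined_to_igraph(network), path, format = "dot")
  invisible(path)
}
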