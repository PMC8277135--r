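# Independent oracles and tiny fixture builders. These deliberately avoid the
# package's inference/combination code paths: posteriors are computed by full
# enumeration of the joint, mortality combination by a naive double loop.

# enumerate all assignments and sum joint mass consistent with evidence
enum_posterior <- function(network, query, evidence = list(), policy = NULL) {
  vars <- names(network$specs)
  states <- lapply(network$specs, `[[`, "states")
  grid <- expand.grid(states, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (ct in network$cpts) {
    key <- if (length(ct$parents)) {
      do.call(paste, c(grid[ct$parents], sep = "|"))
    } else rep(rownames(ct$table)[1], nrow(grid))
    p <- p * ct$table[cbind(match(key, rownames(ct$table)),
                            match(grid[[ct$child]], colnames(ct$table)))]
  }
  for (v in vars[vapply(network$specs, function(s) s$kind == "decision", logical(1))]) {
    if (v %in% names(evidence)) next
    st <- network$specs[[v]]$states
    mass <- if (is.character(policy) && identical(policy, "uniform")) {
      rep(1 / length(st), length(st))[match(grid[[v]], st)]
    } else if (is.list(policy) && v %in% names(policy)) {
      pv <- policy[[v]]
      if (is.character(pv)) as.numeric(grid[[v]] == pv)
      else as.numeric(pv)[match(grid[[v]], st)]
    } else stop("decision variable uncovered in oracle: ", v)
    p <- p * mass
  }
  for (v in names(evidence)) p[grid[[v]] != evidence[[v]]] <- 0
  qs <- network$specs[[query]]$states
  post <- vapply(qs, function(s) sum(p[grid[[query]] == s]), numeric(1))
  post / sum(post)
}

# naive double-loop grid combination oracle
combine_oracle <- function(direct, indirect) {
  out <- numeric(101)
  for (di in 0:100) {
    for (ii in 0:100) {
      m <- direct[di + 1] * indirect[ii + 1]
      if (m == 0) next
      t <- floor(di + ii * (100 - di) / 100 + 0.5)
      out[t + 1] <- out[t + 1] + m
    }
  }
  out / sum(out)
}

# random discrete BN for property tests: n nodes, DAG over a fixed order
random_test_network <- function(seed, max_nodes = 8, max_states = 3,
                                with_decision = FALSE) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  nm <- sprintf("V%d", seq_len(n))
  kinds <- rep("random", n)
  if (with_decision) kinds[sample(n, 1)] <- "decision"
  specs <- lapply(seq_len(n), function(i) {
    variable_spec(nm[i], paste0("s", seq_len(sample(2:max_states, 1))),
                  kind = kinds[i])
  })
  names(specs) <- nm
  cpts <- list()
  for (i in seq_len(n)) {
    if (kinds[i] == "decision") next
    pool <- which(seq_len(n) < i)
    pa <- nm[pool[runif(length(pool)) < 0.5]]
    pstates <- setNames(lapply(pa, function(p) specs[[p]]$states), pa)
    k <- length(specs[[nm[i]]]$states)
    rows <- max(1L, prod(lengths(pstates)))
    tab <- matrix(rgamma(rows * k, 1), rows, k)
    tab <- tab / rowSums(tab)
    cpts[[nm[i]]] <- cpt(nm[i], pa, specs[[nm[i]]]$states, pstates, tab)
  }
  build_network(unname(specs), unname(cpts))
}

random_evidence <- function(network, seed, n_max = 2, exclude = character()) {
  set.seed(seed)
  pool <- setdiff(names(network$specs), exclude)
  pick <- sample(pool, min(length(pool), sample(0:n_max, 1)))
  ev <- lapply(pick, function(v) sample(network$specs[[v]]$states, 1))
  names(ev) <- pick
  ev
}

# a small hand-specified 3-node chain A -> B -> C (binary)
chain3_network <- function() {
  sA <- variable_spec("A", c("a0", "a1"))
  sB <- variable_spec("B", c("b0", "b1"))
  sC <- variable_spec("C", c("c0", "c1"))
  cA <- cpt("A", character(), c("a0", "a1"), list(), c(0.3, 0.7))
  cB <- cpt("B", "A", c("b0", "b1"), list(A = c("a0", "a1")),
            rbind(c(0.9, 0.1), c(0.2, 0.8)))
  cC <- cpt("C", "B", c("c0", "c1"), list(B = c("b0", "b1")),
            rbind(c(0.6, 0.4), c(0.25, 0.75)))
  build_network(list(sA, sB, sC), list(cA, cB, cC))
}

fixture_path <- function(f) {
  p <- system.file("extdata", f, package = "seabedrisk")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}
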