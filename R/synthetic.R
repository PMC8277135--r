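#' Synthetic expert maps, networks, and scenario suites
#'
#' Generators reproducing the statistical structure the analysis assumes, so
#' the whole pipeline is testable without any external download: 11 expert
#' maps with 8-24 variables each drawn from a hidden consensus graph of 53
#' variables and 96 causal connections, monotone pressure-to-mortality CPTs
#' over the five mortality classes, and a full factorial scenario suite over
#' the decision variables. Everything is reproducible from a single seed.
#'
#' These artifacts are synthetic stand-ins: the consensus graph encodes the
#' category structure (pressures, operational factors, environmental
#' conditions, biological components) at the elicited scale, not the actual
#' elicited connections, which live in the original model repository.
#'
#' @name synthetic-data
NULL

#' Synthetic generator configuration
#'
#' Defaults encode the elicited structure: 11 experts, map sizes 8-24,
#' strengths on a 1-3 scale with roughly a third missing (only the strongest
#' connections were rated by everyone), no noise links, monotone CPTs.
#'
#' @param seed Master seed.
#' @param n_experts Number of expert maps.
#' @param size_range Per-map node-count range (inclusive).
#' @param link_noise Probability of adding a non-consensus link per map.
#' @param strength_dist Probabilities of strengths 1, 2, 3.
#' @param missing_strength_rate Fraction of links left unrated.
#' @param alias_rate Probability that an expert uses a raw synonym (e.g.
#'   "worms") instead of the canonical label.
#' @param cpt_concentration Dirichlet concentration for random CPTs.
#' @param monotone Enforce stochastic monotonicity of generated CPTs.
#' @param dispersion Spread (percent) of direct mortality around the
#'   intensity value; 0 = exactly proportionate.
#' @param ensure_coverage Guarantee that the union of the maps recovers the
#'   full consensus graph (gives the merge stage a recoverable ground truth).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_experts = 11, size_range = c(8L, 24L),
                             link_noise = 0, strength_dist = c(0.2, 0.45, 0.35),
                             missing_strength_rate = 0.35, alias_rate = 0.25,
                             cpt_concentration = 1, monotone = TRUE,
                             dispersion = 0, ensure_coverage = TRUE) {
  stopifnot(n_experts >= 1, size_range[1] >= 2, size_range[1] <= size_range[2],
            link_noise >= 0, link_noise <= 1,
            abs(sum(strength_dist) - 1) < 1e-9,
            missing_strength_rate >= 0, missing_strength_rate <= 1,
            cpt_concentration > 0)
  structure(list(seed = as.integer(seed), n_experts = as.integer(n_experts),
                 size_range = as.integer(size_range), link_noise = link_noise,
                 strength_dist = strength_dist,
                 missing_strength_rate = missing_strength_rate,
                 alias_rate = alias_rate,
                 cpt_concentration = cpt_concentration, monotone = monotone,
                 dispersion = dispersion, ensure_coverage = ensure_coverage),
            class = "synthetic_config")
}

#' Canonical variable vocabulary (53 variables, 4 categories)
#'
#' Pressures used as the causal-mapping starting point, operational factors
#' of the extraction technique, environmental conditions, and biological
#' components named by functional traits.
#'
#' @return Data frame with `label` and `category`.
#' @export
default_vocabulary <- function() {
  v <- list(
    `operational factor` = c(
      "mining intensity", "depth of extracted sediment",
      "processing return technique", "volume of extraction",
      "water depth at extraction site", "duration of operation",
      "mining vessel operation", "extraction pattern"),
    pressure = c(
      "nodule removal", "modification of seafloor substrate type",
      "modification of seafloor topography",
      "sediment dispersal in the water column",
      "sediment dispersal near seafloor",
      "release of nutrients from the sediment",
      "release of toxic substances from the sediment", "underwater noise"),
    `environmental condition` = c(
      "sediment type", "contaminants in sediment", "grain size",
      "organic matter content", "oxygen conditions", "near-bottom currents",
      "water column stratification", "salinity", "temperature",
      "background turbidity", "nutrient status", "sediment compaction",
      "pore water composition", "light availability"),
    `biological component` = c(
      "sessile epifauna", "mobile epifauna", "mobile infauna",
      "burrowing infauna", "filter feeders", "deposit feeders",
      "predatory invertebrates", "meiofauna", "bacterial communities",
      "phytoplankton", "zooplankton", "macrophytes", "demersal fish",
      "pelagic fish", "fish eggs and larvae", "marine mammals", "seabirds",
      "benthic food availability", "primary production",
      "benthic habitat structure", "species richness", "community biomass",
      "reproductive success"))
  data.frame(label = unlist(v, use.names = FALSE),
             category = rep(names(v), lengths(v)),
             stringsAsFactors = FALSE)
}

#' Raw-label synonyms used by individual experts
#' @return A [synonym_table] mapping raw labels to canonical vocabulary.
#' @export
default_synonyms <- function() {
  synonym_table(c(
    polychaetes = "mobile infauna", worms = "mobile infauna",
    annelids = "mobile infauna", bivalves = "burrowing infauna",
    clams = "burrowing infauna", mussels = "sessile epifauna",
    crustaceans = "mobile epifauna", microbes = "bacterial communities",
    turbidity = "background turbidity",
    `suspended solids` = "sediment dispersal in the water column",
    `toxic substances` = "contaminants in sediment",
    `seafloor morphology` = "modification of seafloor topography"))
}

#' The hidden consensus graph (53 nodes, 96 directed edges)
#'
#' Deterministic construction from the vocabulary's category structure:
#' operational factors drive pressures, environmental conditions modulate
#' pressures and biota, pressures affect biological components, and a few
#' food-web links connect biological components. No randomness is involved.
#'
#' @return A `combined_network` with category-tagged nodes.
#' @export
synthetic_consensus <- function() {
  voc <- default_vocabulary()
  lab <- function(cat) voc$label[voc$category == cat]
  op <- lab("operational factor"); pr <- lab("pressure")
  cond <- lab("environmental condition"); bio <- lab("biological component")
  e <- list()
  add <- function(s, t) e[[length(e) + 1L]] <<- c(s, t)
  for (j in seq_along(pr)) {           # each pressure: 2 operational parents
    add(op[((2 * j - 2) %% 8) + 1], pr[j])
    add(op[((2 * j - 1) %% 8) + 1], pr[j])
  }
  for (j in seq_along(pr)) add(cond[j], pr[j])   # 1 condition parent each
  for (i in seq_along(bio)) {          # each biological: 2 pressure parents
    add(pr[(i %% 8) + 1], bio[i])
    add(pr[((i + 2) %% 8) + 1], bio[i])
  }
  for (j in seq_along(cond)) add(cond[j], bio[j])  # conditions modulate biota
  for (i in 1:8) add(bio[i], bio[i + 8])           # food-web links
  add(op[1], op[4]); add(op[2], op[4])             # intensity/depth -> volume
  add(op[5], op[6]); add(op[8], op[7])
  edges <- do.call(rbind, e)
  links <- data.frame(source = edges[, 1], target = edges[, 2],
                      strength = NA_integer_, stringsAsFactors = FALSE)
  merge_concept_maps(list(concept_map("consensus", links, nodes = voc$label)),
                     categories = stats::setNames(voc$category, voc$label))
}

#' Generate synthetic expert concept maps
#'
#' Each map samples its node count from the configured range and grows a
#' connected edge subset of the hidden consensus graph, optionally plus noise
#' links; some canonical labels are swapped for raw synonyms to exercise
#' harmonization. With `ensure_coverage`, every consensus edge is assigned to
#' at least one expert, so harmonize + merge recovers the consensus exactly.
#'
#' @param config A [synthetic_config].
#' @return List with `maps` (raw-label [concept_map]s), `synonyms` (the
#'   [synonym_table] needed to harmonize them), and `consensus`.
#' @export
generate_expert_maps <- function(config = synthetic_config()) {
  consensus <- synthetic_consensus()
  edges <- consensus$edges[, c("source", "target")]
  syn <- default_synonyms()
  alias_of <- split(names(syn), unname(unclass(syn)))
  withr_seed(config$seed, {
    chosen <- vector("list", config$n_experts)
    for (ex in seq_len(config$n_experts)) {
      n_target <- sample(config$size_range[1]:config$size_range[2], 1)
      sel <- sample(nrow(edges), 1)
      nodes <- unique(unlist(edges[sel, ]))
      while (length(nodes) < n_target) {
        remaining <- setdiff(seq_len(nrow(edges)), sel)
        if (!length(remaining)) break
        adj <- remaining[edges$source[remaining] %in% nodes |
                         edges$target[remaining] %in% nodes]
        if (length(adj)) {
          pick <- adj[sample.int(length(adj), 1)]
        } else {
          pick <- remaining[sample.int(length(remaining), 1)]
          if (length(nodes) + 2 > config$size_range[2]) break
        }
        sel <- c(sel, pick)
        nodes <- unique(c(nodes, unlist(edges[pick, ])))
      }
      chosen[[ex]] <- sel
    }
    if (config$ensure_coverage) {
      covered <- unique(unlist(chosen))
      for (miss in setdiff(seq_len(nrow(edges)), covered)) {
        ends <- unlist(edges[miss, ])
        gain <- vapply(chosen, function(s) {
          length(setdiff(ends, unique(unlist(edges[s, ]))))
        }, numeric(1))
        size <- vapply(chosen, function(s) length(unique(unlist(edges[s, ]))),
                       numeric(1))
        ok <- which(size + gain <= config$size_range[2])
        if (!length(ok)) stop("cannot cover consensus edge within size range")
        tgt <- ok[order(gain[ok], size[ok])][1]
        chosen[[tgt]] <- c(chosen[[tgt]], miss)
      }
    }
    maps <- vector("list", config$n_experts)
    for (ex in seq_len(config$n_experts)) {
      sel <- sort(unique(chosen[[ex]]))
      links <- edges[sel, , drop = FALSE]
      nodes <- unique(unlist(links))
      if (config$link_noise > 0 && stats::runif(1) < config$link_noise &&
          length(nodes) >= 2) {
        pair <- sample(nodes, 2)
        key <- paste(edges$source, edges$target)
        if (!paste(pair[1], pair[2]) %in%
            c(key, paste(links$source, links$target))) {
          links <- rbind(links, data.frame(source = pair[1], target = pair[2],
                                           stringsAsFactors = FALSE))
        }
      }
      n <- nrow(links)
      links$strength <- ifelse(
        stats::runif(n) < config$missing_strength_rate, NA_integer_,
        sample(1:3, n, replace = TRUE, prob = config$strength_dist))
      # expert-specific raw labels: swap a canonical label for a synonym
      relabel <- character()
      for (canon in intersect(names(alias_of), unique(unlist(links[, 1:2])))) {
        if (stats::runif(1) < config$alias_rate) {
          relabel[canon] <- sample(alias_of[[canon]], 1)
        }
      }
      if (length(relabel)) {
        hit_s <- links$source %in% names(relabel)
        hit_t <- links$target %in% names(relabel)
        links$source[hit_s] <- relabel[links$source[hit_s]]
        links$target[hit_t] <- relabel[links$target[hit_t]]
      }
      maps[[ex]] <- concept_map(sprintf("E%02d", ex), links)
    }
    names(maps) <- vapply(maps, `[[`, character(1), "expert_id")
    list(maps = maps, synonyms = syn, consensus = consensus)
  })
}

#' Generate a synthetic 18-node Bayesian network
#'
#' Default wiring from [default_bn_structure]; priors and pressure CPTs are
#' Dirichlet-random (monotone if configured), direct mortality is
#' proportionate to mining intensity, and total mortality is the
#' deterministic 1%-grid combination.
#'
#' @param config A [synthetic_config].
#' @param scheme A [mortality_scheme].
#' @return A validated `bn_network` with group metadata.
#' @export
generate_network <- function(config = synthetic_config(),
                             scheme = mortality_scheme()) {
  st <- default_bn_structure(scheme)
  base <- (config$seed %% 200000L) * 10000L
  cpts <- list(); i <- 0L
  subseed <- function() { i <<- i + 1L; base + i }
  for (nm in names(st$parents)) {
    sp <- st$specs[[nm]]
    psp <- lapply(st$parents[[nm]], function(p) st$specs[[p]])
    if (grepl("^direct_mortality_", nm)) {
      cpts[[nm]] <- build_direct_mortality_cpt(nm, config$dispersion, scheme)
    } else if (grepl("^total_mortality_", nm)) {
      cpts[[nm]] <- build_total_mortality_cpt(st$parents[[nm]][1],
                                              st$parents[[nm]][2], nm, scheme)
    } else {
      cpts[[nm]] <- random_cpt(sp, psp, seed = subseed(),
                               concentration = config$cpt_concentration,
                               monotone = config$monotone)
    }
  }
  build_network(unname(st$specs), unname(cpts), groups = st$groups)
}

#' Generate the full factorial scenario suite
#'
#' One scenario per combination of decision-variable states (3 intensities x
#' 3 extraction depths x 2 return techniques = 18 with the default model).
#'
#' @param network A `bn_network`.
#' @param fixed Optional named list pinning some decision variables.
#' @return Named list of [scenario] objects.
#' @export
generate_scenarios <- function(network, fixed = list()) {
  dec <- network_variables(network, "decision")
  free <- setdiff(dec, names(fixed))
  grid <- combo_grid(stats::setNames(
    lapply(free, function(v) network$specs[[v]]$states), free))
  out <- list()
  for (i in seq_len(max(1L, nrow(grid)))) {
    dc <- fixed
    for (v in free) dc[[v]] <- grid[i, v]
    nm <- sprintf("S%02d", i)
    out[[nm]] <- scenario(nm, decisions = dc)
  }
  out
}

#' The two headline mining scenarios
#'
#' Scenario A: mining 75% of a discrete block with 11-30 cm sediment
#' extracted. Scenario B: mining 50% with 11-30 cm extracted and known
#' release of harmful substances from the sediment. Neither fixes the
#' processing return technique; it is resolved by the query policy.
#'
#' @return A [scenario].
#' @export
scenario_A <- function() {
  scenario("A", decisions = list(mining_intensity = "75% removed",
                                 depth_of_extracted_sediment = "11-30 cm"))
}

#' @rdname scenario_A
#' @export
scenario_B <- function() {
  scenario("B", decisions = list(mining_intensity = "50% removed",
                                 depth_of_extracted_sediment = "11-30 cm"),
           evidence = list(contaminant_release = "significant"))
}

#' Materialize a complete synthetic test workspace
#'
#' Writes raw expert edge lists, the synonym table, node categories, a model
#' file, and a scenario file in the formats the pipeline reads.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synthetic_config].
#' @return Named list of file paths.
#' @export
make_fixtures <- function(dir, config = synthetic_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_expert_maps(config)
  paths <- list(
    maps = file.path(dir, "expert_maps_synthetic.csv"),
    synonyms = file.path(dir, "synonyms_synthetic.csv"),
    categories = file.path(dir, "categories_synthetic.csv"),
    model = file.path(dir, "model_synthetic.txt"),
    scenarios = file.path(dir, "scenarios_synthetic.txt"))
  lines <- c("expert_id,source,target,strength")
  for (m in gen$maps) {
    s <- ifelse(is.na(m$links$strength), "", m$links$strength)
    lines <- c(lines, sprintf("%s,%s,%s,%s", m$expert_id, m$links$source,
                              m$links$target, s))
  }
  writeLines(lines, paths$maps)
  writeLines(c("raw,canonical",
               sprintf("%s,%s", names(gen$synonyms), unname(unclass(gen$synonyms)))),
             paths$synonyms)
  voc <- default_vocabulary()
  writeLines(c("label,category", sprintf("%s,%s", voc$label, voc$category)),
             paths$categories)
  net <- generate_network(config)
  write_model_file(net, paths$model)
  write_scenario_file(c(list(scenario_A(), scenario_B()),
                        unname(generate_scenarios(net))), paths$scenarios)
  paths
}
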