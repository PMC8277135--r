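#' Pipeline orchestration and command-line entry points
#'
#' The three-step workflow — expert maps to combined causal network,
#' combined network to quantitative Bayesian network, scenario queries — as
#' one reproducible run. Every defaulted choice (policy, dropped self-loops,
#' strength reconciliation) is logged, and the run manifest records inputs,
#' checksums and applied defaults so a run can be reproduced exactly.
#'
#' @name cli-pipeline
NULL

#' Validate a model-definition file
#'
#' Lists all violations found: parse/structure errors (cycles, missing CPT
#' rows, decision nodes with CPTs, undeclared parents) and unnormalized CPT
#' rows. An empty report means the file is valid.
#'
#' @param path Model file path.
#' @param tol Row-sum tolerance.
#' @return Data frame with columns `kind` and `detail` (zero rows if valid).
#' @export
validate_model_file <- function(path, tol = 1e-9) {
  viol <- list()
  net <- tryCatch(read_model_file(path, tol = Inf), error = function(e) {
    viol[[1]] <<- data.frame(kind = "structure", detail = conditionMessage(e),
                             stringsAsFactors = FALSE)
    NULL
  })
  if (!is.null(net)) {
    for (ct in net$cpts) {
      rs <- rowSums(ct$table)
      bad <- which(abs(rs - 1) > tol)
      for (b in bad) {
        viol[[length(viol) + 1L]] <- data.frame(
          kind = "row_sum",
          detail = sprintf("CPT %s row '%s' sums to %.12g", ct$child,
                           rownames(ct$table)[b], rs[b]),
          stringsAsFactors = FALSE)
      }
      if (any(ct$table < 0)) {
        viol[[length(viol) + 1L]] <- data.frame(
          kind = "negative", detail = paste("CPT", ct$child, "has negative entries"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(kind = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Assemble a pipeline configuration
#'
#' @param maps Path to the expert edge-list file.
#' @param synonyms Path to the synonym table (optional).
#' @param categories Path to a node-category table (optional; columns
#'   label, category).
#' @param model Path to the model-definition file.
#' @param scenarios Path to the scenario file.
#' @param out_dir Output directory.
#' @param policy Policy for unset decision variables (default uniform,
#'   logged).
#' @param seed Seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(maps, model, scenarios, out_dir,
                            synonyms = NULL, categories = NULL,
                            policy = "uniform", seed = 1L) {
  structure(list(maps = maps, synonyms = synonyms, categories = categories,
                 model = model, scenarios = scenarios, out_dir = out_dir,
                 policy = policy, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' merge maps -> summarize -> validate/build BN -> run scenarios -> reports.
#' Any stage error aborts naming the stage. The manifest (also written as
#' JSON) lists artifact paths, md5 checksums, the seed, and every defaulted
#' decision applied.
#'
#' @param config A [pipeline_config].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$maps, config$model, config$scenarios)) {
    if (!file.exists(p)) stop("pipeline stage 'inputs' failed: missing file ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- character()
  maps <- stage("read-maps", read_concept_maps(config$maps))
  syn <- NULL
  if (!is.null(config$synonyms)) {
    syn <- stage("read-synonyms", read_synonym_table(config$synonyms))
  }
  maps <- stage("harmonize", lapply(maps, harmonize, synonyms = syn))
  categories <- NULL
  if (!is.null(config$categories)) {
    cv <- utils::read.table(config$categories, sep = ",", header = TRUE,
                            stringsAsFactors = FALSE)
    categories <- stats::setNames(cv$category, cv$label)
  }
  combined <- stage("merge", merge_concept_maps(maps, categories = categories))
  sm <- summarize_network(combined)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.table(
    data.frame(metric = c("n_nodes", "n_edges"),
               value = c(sm$n_nodes, sm$n_edges)),
    out("combined_summary.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(sm$degrees, out("combined_degrees.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  write_network_graphml(combined, out("combined.graphml"))
  write_network_dot(combined, out("combined.dot"))
  write_adjacency(network_adjacency(combined, "support_count"),
                  out("combined_adjacency.csv"))
  report <- stage("validate-model", validate_model_file(config$model))
  if (nrow(report)) {
    stop("pipeline stage 'validate-model' failed: ", report$detail[1])
  }
  network <- stage("build-bn", read_model_file(config$model))
  scenarios <- stage("read-scenarios", read_scenario_file(config$scenarios))
  unset <- lapply(scenarios, function(sc) {
    setdiff(network_variables(network, "decision"), names(sc$decisions))
  })
  for (nm in names(scenarios)) {
    if (length(unset[[nm]])) {
      defaults <- c(defaults, sprintf(
        "scenario %s: policy '%s' applied to %s", nm, config$policy,
        paste(unset[[nm]], collapse = ", ")))
    }
  }
  tab <- stage("scenarios", suppressMessages(
    compare_scenarios(network, unname(scenarios), policy = config$policy)))
  utils::write.table(tab, out("scenario_posteriors.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  artifacts <- c("combined_summary.csv", "combined_degrees.csv",
                 "combined.graphml", "combined.dot", "combined_adjacency.csv",
                 "scenario_posteriors.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("seabedrisk")),
    seed = config$seed, policy = config$policy,
    inputs = lapply(Filter(Negate(is.null),
                           config[c("maps", "synonyms", "categories",
                                    "model", "scenarios")]),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    combined_map = list(n_nodes = sm$n_nodes, n_edges = sm$n_edges),
    model = list(n_variables = length(network$specs)),
    n_scenarios = length(scenarios),
    defaults = as.list(defaults),
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f) {
      list(path = out(f), md5 = unname(tools::md5sum(out(f))))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (grepl("^--", args[i])) {
      key <- sub("^--", "", args[i])
      if (i + 1L <= length(args) && !grepl("^--", args[i + 1L])) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `merge-maps`, `build-bn` (validate + summarize a model
#' file), `run-scenario`, `compare-scenarios`, `rank-stressors`,
#' `validate-model`, `make-fixtures`, `pipeline`. Flags are `--key value`
#' pairs: `--maps`, `--synonyms`, `--categories`, `--model`, `--scenarios`,
#' `--scenario <name>`, `--target`, `--stressors a,b,c`, `--baseline <name>`,
#' `--policy`, `--seed`, `--out`. Returns (invisibly) an exit status:
#' 0 success, 2 validation failure, 1 computation failure.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
seabedrisk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: seabedrisk <merge-maps|build-bn|run-scenario|compare-scenarios|",
        "rank-stressors|validate-model|make-fixtures|pipeline> [--flags]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  out_dir <- opt$out %||% "."
  policy <- opt$policy %||% "uniform"
  seed <- as.integer(opt$seed %||% 1L)
  status <- tryCatch({
    switch(cmd,
      "merge-maps" = {
        maps <- read_concept_maps(opt$maps)
        syn <- if (!is.null(opt$synonyms)) read_synonym_table(opt$synonyms)
        maps <- lapply(maps, harmonize, synonyms = syn)
        net <- merge_concept_maps(maps)
        sm <- summarize_network(net)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_network_graphml(net, file.path(out_dir, "combined.graphml"))
        write_adjacency(network_adjacency(net, "support_count"),
                        file.path(out_dir, "combined_adjacency.csv"))
        cat(sprintf("combined network: %d nodes, %d edges\n",
                    sm$n_nodes, sm$n_edges))
        0L
      },
      "validate-model" = ,
      "build-bn" = {
        report <- validate_model_file(opt$model)
        if (nrow(report)) {
          utils::write.table(report, stdout(), sep = "\t", quote = FALSE,
                             row.names = FALSE)
          2L
        } else {
          net <- read_model_file(opt$model)
          cat(sprintf("valid model: %d variables, %d edges\n",
                      length(net$specs), igraph::ecount(net$graph)))
          0L
        }
      },
      "run-scenario" = {
        net <- read_model_file(opt$model)
        scs <- read_scenario_file(opt$scenarios)
        nm <- opt$scenario %||% names(scs)[1]
        if (!nm %in% names(scs)) stop("scenario not in file: ", nm)
        res <- run_scenario(net, scs[[nm]], policy = policy)
        print(res)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(res$table,
                           file.path(out_dir, paste0("scenario_", nm, ".csv")),
                           sep = ",", quote = FALSE, row.names = FALSE)
        0L
      },
      "compare-scenarios" = {
        net <- read_model_file(opt$model)
        scs <- read_scenario_file(opt$scenarios)
        tab <- compare_scenarios(net, unname(scs), policy = policy)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(tab, file.path(out_dir, "scenario_posteriors.csv"),
                           sep = ",", quote = FALSE, row.names = FALSE)
        cat(sprintf("wrote %d posterior rows for %d scenarios\n",
                    nrow(tab), length(scs)))
        0L
      },
      "rank-stressors" = {
        net <- read_model_file(opt$model)
        scs <- read_scenario_file(opt$scenarios)
        nm <- opt$baseline %||% names(scs)[1]
        stressors <- strsplit(opt$stressors, ",", fixed = TRUE)[[1]]
        rep <- rank_stressors(net, opt$target, stressors, scs[[nm]],
                              policy = policy)
        print(rep)
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(rep$ranking,
                           file.path(out_dir, "stressor_ranking.csv"),
                           sep = ",", quote = FALSE, row.names = FALSE)
        0L
      },
      "make-fixtures" = {
        paths <- make_fixtures(out_dir, synthetic_config(seed = seed))
        cat("fixtures written to", out_dir, "\n")
        0L
      },
      "pipeline" = {
        cfg <- pipeline_config(maps = opt$maps, model = opt$model,
                               scenarios = opt$scenarios, out_dir = out_dir,
                               synonyms = opt$synonyms,
                               categories = opt$categories,
                               policy = policy, seed = seed)
        run_pipeline(cfg)
        cat("pipeline complete; manifest at",
            file.path(out_dir, "manifest.json"), "\n")
        0L
      },
      { cat("unknown subcommand:", cmd, "\n"); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("validate|valid model|row_sum|cycle", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
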