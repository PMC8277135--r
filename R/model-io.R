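#' Model-definition file I/O
#'
#' A human-editable structured text format declaring variables (kind,
#' category, ordered states, parents) and CPT rows. Probabilities are written
#' with 17 significant digits so that read -> write -> read is an identical
#' round trip. State labels may not contain the pipe character, which
#' separates states in rows and keys.
#'
#' @name model-io
NULL

fmt_p <- function(x) sprintf("%.17g", x)

#' Write a network to a model-definition file
#' @param network A `bn_network`.
#' @param path Output path.
#' @export
write_model_file <- function(network, path) {
  out <- c("# seabedrisk model file v1")
  for (sp in network$specs) {
    out <- c(out, paste0("variable ", sp$name),
             paste0("  category: ", ifelse(is.na(sp$category), "-", sp$category)),
             paste0("  kind: ", sp$kind),
             paste0("  states: ", paste(sp$states, collapse = " | ")))
    ct <- network$cpts[[sp$name]]
    if (!is.null(ct) && length(ct$parents)) {
      out <- c(out, paste0("  parents: ", paste(ct$parents, collapse = " | ")))
    }
  }
  if (!is.null(network$groups)) {
    for (g in names(network$groups)) {
      gr <- network$groups[[g]]
      out <- c(out, paste0("group ", g),
               paste0("  direct: ", gr$direct),
               paste0("  indirect: ", gr$indirect),
               paste0("  total: ", gr$total))
    }
  }
  for (sp in network$specs) {
    ct <- network$cpts[[sp$name]]
    if (is.null(ct)) next
    out <- c(out, paste0("cpt ", sp$name))
    keys <- rownames(ct$table)
    for (i in seq_len(nrow(ct$table))) {
      key <- if (length(ct$parents)) keys[i] else "-"
      out <- c(out, paste0("  ", key, " : ",
                           paste(fmt_p(ct$table[i, ]), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

split_pipe <- function(x) trimws(strsplit(x, "|", fixed = TRUE)[[1]])

#' Read a model-definition file
#' @param path Path written by [write_model_file] (or hand-edited).
#' @param tol CPT row-sum tolerance.
#' @return A validated `bn_network`.
#' @export
read_model_file <- function(path, tol = 1e-9) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  specs <- list(); parents <- list(); cpt_rows <- list(); groups <- list()
  cur <- NULL; mode <- ""
  flush_var <- function(v) {
    if (is.null(v)) return()
    specs[[v$name]] <<- variable_spec(v$name, v$states, v$kind, v$category)
    if (length(v$parents)) parents[[v$name]] <<- v$parents
  }
  for (ln in lines) {
    if (grepl("^variable ", ln)) {
      flush_var(cur)
      cur <- list(name = trimws(sub("^variable ", "", ln)),
                  category = NA_character_, kind = "random",
                  states = character(), parents = character())
      mode <- "var"
    } else if (grepl("^cpt ", ln)) {
      flush_var(cur); cur <- NULL
      mode <- paste0("cpt:", trimws(sub("^cpt ", "", ln)))
      cpt_rows[[sub("^cpt:", "", mode)]] <- list()
    } else if (grepl("^group ", ln)) {
      flush_var(cur); cur <- NULL
      mode <- paste0("grp:", trimws(sub("^group ", "", ln)))
      groups[[sub("^grp:", "", mode)]] <- list()
    } else if (grepl("^\\s", ln)) {
      body <- trimws(ln)
      if (mode == "var") {
        if (grepl("^category:", body)) {
          v <- trimws(sub("^category:", "", body))
          cur$category <- if (v == "-") NA_character_ else v
        } else if (grepl("^kind:", body)) {
          cur$kind <- trimws(sub("^kind:", "", body))
        } else if (grepl("^states:", body)) {
          cur$states <- split_pipe(sub("^states:", "", body))
        } else if (grepl("^parents:", body)) {
          cur$parents <- split_pipe(sub("^parents:", "", body))
        } else stop("unrecognized variable field: ", body)
      } else if (grepl("^cpt:", mode)) {
        nm <- sub("^cpt:", "", mode)
        parts <- strsplit(body, " : ", fixed = TRUE)[[1]]
        if (length(parts) != 2) stop("malformed CPT row: ", body)
        p <- as.numeric(strsplit(trimws(parts[2]), "\\s+")[[1]])
        cpt_rows[[nm]][[trimws(parts[1])]] <- p
      } else if (grepl("^grp:", mode)) {
        nm <- sub("^grp:", "", mode)
        kv <- strsplit(body, ":", fixed = TRUE)[[1]]
        groups[[nm]][[trimws(kv[1])]] <- trimws(kv[2])
      } else stop("unexpected indented line: ", body)
    } else stop("unrecognized line: ", ln)
  }
  flush_var(cur)
  cpts <- list()
  for (nm in names(cpt_rows)) {
    if (!nm %in% names(specs)) stop("CPT for undeclared variable: ", nm)
    pv <- parents[[nm]] %||% character()
    pstates <- stats::setNames(lapply(pv, function(p) {
      if (!p %in% names(specs)) stop("undeclared parent '", p, "' of ", nm)
      specs[[p]]$states
    }), pv)
    keys <- if (length(pv)) combo_keys(pstates) else "-"
    rows <- cpt_rows[[nm]]
    missing <- setdiff(keys, names(rows))
    if (length(missing)) {
      stop(sprintf("CPT for %s: missing row for parent combination '%s'",
                   nm, missing[1]))
    }
    tab <- do.call(rbind, rows[keys])
    cpts[[nm]] <- cpt(nm, pv, specs[[nm]]$states, pstates, tab, tol = tol)
  }
  build_network(unname(specs), unname(cpts),
                groups = if (length(groups)) groups else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import a CPT from a delimited table
#'
#' Accommodates CPTs stored one row per parent combination: the first
#' columns name the parent states (headers = parent names), the remaining
#' columns the probability of each child state (headers = state labels).
#' Root priors use a single probability-only row.
#'
#' @param path Delimited text file.
#' @param child Child variable name.
#' @param child_states Ordered child states (defaults to the probability
#'   column headers in file order).
#' @param parent_states Named list of parent state vectors; parents are the
#'   columns of `path` matching these names.
#' @param sep Field separator.
#' @param tol Row-sum tolerance.
#' @return A [cpt].
#' @export
read_cpt_table <- function(path, child, child_states = NULL,
                           parent_states = list(), sep = ",", tol = 1e-9) {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  parents <- intersect(names(df), names(parent_states))
  pcols <- df[, parents, drop = FALSE]
  prob <- as.matrix(df[, setdiff(names(df), parents), drop = FALSE])
  if (is.null(child_states)) child_states <- colnames(prob)
  pstates <- parent_states[parents]
  keys <- combo_keys(pstates)
  if (length(parents)) {
    have <- do.call(paste, c(unname(lapply(pcols, as.character)), sep = "|"))
    tab <- prob[match(keys, have), , drop = FALSE]
    if (anyNA(tab)) {
      stop(sprintf("CPT table %s: missing row for parent combination '%s'",
                   path, keys[which(is.na(tab[, 1]))[1]]))
    }
  } else tab <- prob
  cpt(child, parents, child_states, pstates, tab, tol = tol)
}
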