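#' Default quantitative model structure
#'
#' The quantitative risk model covers the acute impacts of nodule extraction
#' on three benthic functional groups (sessile epifauna, mobile epifauna,
#' burrowing infauna) within a discrete mining block. Each group is expanded
#' into three nodes — direct, indirect, and total mortality — which together
#' with three decision variables (mining intensity, depth of extracted
#' sediment, processing return technique) and six environmental/pressure
#' variables gives an 18-node network. The full wiring of the published
#' model is not printed in its source; this default structure is a
#' documented reconstruction and is overridable through the model file.
#'
#' @name model-structure
NULL

#' Benthic functional groups of the default model
#' @return Character vector of group identifiers.
#' @export
benthic_groups <- function() c("sessile_epifauna", "mobile_epifauna", "infauna")

#' Mining-intensity state labels and their percent values
#' @return Named integer vector (label -> percent removed).
#' @export
intensity_levels <- function() {
  c("50% removed" = 50L, "75% removed" = 75L, "100% removed" = 100L)
}

#' Variable specifications and default wiring of the 18-node model
#'
#' @param scheme A [mortality_scheme] for the nine mortality nodes.
#' @return List with `specs` (list of [variable_spec]), `parents` (named
#'   list of parent vectors for every random variable) and `groups` (per
#'   functional group, its direct/indirect/total node names).
#' @export
default_bn_structure <- function(scheme = mortality_scheme()) {
  mort <- scheme$label
  specs <- list(
    variable_spec("mining_intensity", names(intensity_levels()),
                  "decision", "extraction technique"),
    variable_spec("depth_of_extracted_sediment", c("<10 cm", "11-30 cm", ">30 cm"),
                  "decision", "extraction technique"),
    variable_spec("processing_return_technique", c("at the surface", "at the bottom"),
                  "decision", "extraction technique"),
    variable_spec("sediment_type", c("soft", "hard", "rocks"),
                  "random", "environmental condition"),
    variable_spec("contaminants_in_sediment", c("low", "medium", "high"),
                  "random", "environmental condition"),
    variable_spec("volume_of_extraction", c("low", "medium", "high"),
                  "random", "extraction technique"),
    variable_spec("suspended_sediment", c("low", "medium", "high"),
                  "random", "environmental change"),
    variable_spec("contaminant_release", c("low", "significant"),
                  "random", "environmental change"),
    variable_spec("sediment_deposition", c("low", "medium", "high"),
                  "random", "environmental change"))
  parents <- list(
    sediment_type = character(),
    contaminants_in_sediment = character(),
    volume_of_extraction = c("mining_intensity", "depth_of_extracted_sediment"),
    suspended_sediment = c("volume_of_extraction", "sediment_type",
                           "processing_return_technique"),
    sediment_deposition = c("volume_of_extraction", "sediment_type",
                            "processing_return_technique"),
    contaminant_release = c("contaminants_in_sediment", "suspended_sediment"))
  groups <- list()
  for (g in benthic_groups()) {
    d <- paste0("direct_mortality_", g)
    i <- paste0("indirect_mortality_", g)
    t <- paste0("total_mortality_", g)
    specs <- c(specs,
               list(variable_spec(d, mort, "random", "affected functional group"),
                    variable_spec(i, mort, "random", "affected functional group"),
                    variable_spec(t, mort, "random", "affected functional group")))
    parents[[d]] <- "mining_intensity"
    parents[[i]] <- c("suspended_sediment", "sediment_deposition",
                      "contaminant_release")
    parents[[t]] <- c(d, i)
    groups[[g]] <- list(direct = d, indirect = i, total = t)
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  list(specs = specs, parents = parents, groups = groups)
}

#' CPT of direct mortality given mining intensity
#'
#' Direct mortality is proportionate to the mined area: each intensity state
#' maps to a grid distribution centred at its percent value (a point mass by
#' default), re-binned into the mortality classes.
#'
#' @param node Name of the direct-mortality node.
#' @param dispersion Optional symmetric spread in percent around the
#'   intensity value (mean preserved).
#' @param scheme A [mortality_scheme].
#' @return A [cpt] with one row per intensity state.
#' @export
build_direct_mortality_cpt <- function(node, dispersion = 0,
                                       scheme = mortality_scheme()) {
  lv <- intensity_levels()
  tab <- t(vapply(lv, function(pct) {
    grid_to_class(direct_mortality_from_intensity(pct, dispersion), scheme)
  }, numeric(nrow(scheme))))
  cpt(node, "mining_intensity", scheme$label,
      list(mining_intensity = names(lv)), tab)
}
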