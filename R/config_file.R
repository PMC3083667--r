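#' Read a simulation configuration from a YAML or JSON file
#'
#' The file mirrors the arguments of [simulation_config()]; any field can be
#' omitted to accept the package default, and `overrides` (a named list using
#' the same keys) takes precedence over the file. The `climate` block either
#' names a CSV table (`path:`) or parameterizes the synthetic generator
#' (`start_year`, `end_year`, `seed`, and an optional `variables` list of
#' per-variable records). Weight-table entries are overridable with flat
#' keys, e.g. `weights: {w_p: {O.alpha: 1.0}, w_k: {gamma.alpha: 0.0}}`
#' (age class or recipient first, type or provider second).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param overrides Named list overriding top-level fields.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw[names(overrides)] <- overrides

  climate <- if (!is.null(raw$climate$path)) {
    load_climate_table(raw$climate$path)
  } else {
    cl <- raw$climate %||% list()
    vars <- default_climate_variables()
    if (!is.null(cl$variables)) {
      user <- tibble::as_tibble(cl$variables)
      for (col in setdiff(names(user), "variable")) {
        vars[[col]][match(user$variable, vars$variable)] <- user[[col]]
      }
    }
    climate_gen_config(
      variables = vars,
      start_year = cl$start_year %||% 1960,
      end_year = cl$end_year %||% 2090,
      seed = cl$seed %||% 1L
    )
  }

  cm <- raw$community %||% list()
  if (is.null(cm$population_size)) {
    abort("configuration is missing community population_size")
  }
  community <- community_config(
    population_size = cm$population_size,
    type_proportions = unlist(cm$type_proportions) %||%
      c(alpha = 0.35, beta = 0.45, gamma = 0.20),
    age_class_proportions = unlist(cm$age_class_proportions) %||%
      c(Y = 0.45, M = 0.35, O = 0.20),
    max_initial_age = cm$max_initial_age %||% 80,
    min_initial_age = cm$min_initial_age %||% 18,
    mortality_exponent = cm$mortality_exponent %||% exp(1),
    mortality_enabled = cm$mortality_enabled %||% TRUE
  )

  weights <- default_weights()
  if (!is.null(raw$weights)) {
    apply_flat <- function(tab, flat, key_cols) {
      for (key in names(flat)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        if (length(parts) != 2) abort(paste0("bad weight key: ", key))
        hit <- tab[[key_cols[1]]] == parts[1] & tab[[key_cols[2]]] == parts[2]
        if (!any(hit)) abort(paste0("unknown weight key: ", key))
        tab$weight[hit] <- flat[[key]]
      }
      tab
    }
    if (!is.null(raw$weights$w_p)) {
      weights$w_p <- apply_flat(weights$w_p, raw$weights$w_p,
                                c("age_class", "type"))
    }
    if (!is.null(raw$weights$w_k)) {
      weights$w_k <- apply_flat(weights$w_k, raw$weights$w_k,
                                c("recipient", "provider"))
    }
  }

  simulation_config(
    climate = climate,
    community = community,
    scenario = raw$scenario %||% "A",
    lk_enabled = raw$lk %||% raw$lk_enabled %||% TRUE,
    sim_start_year = raw$sim_start_year %||% 2010,
    sim_end_year = raw$sim_end_year %||% 2090,
    history_start_year = raw$history_start_year %||% 1960,
    replicates = raw$replicates %||% 30,
    base_seed = raw$base_seed %||% 1,
    freeze_climate = raw$freeze_climate %||% TRUE,
    weights = weights,
    lk_eligibility = raw$lk_eligibility %||% "cardinality",
    gate_current_observation = raw$gate_current_observation %||% FALSE
  )
}
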