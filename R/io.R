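#' Write and read simulation results
#'
#' Results are stored as a long-format CSV (one row per year, month and
#' variable) alongside a JSON metadata sidecar (same path with a `.json`
#' extension) recording the scenario, the seeds used, a configuration echo
#' and the package version, so a result file is self-describing.
#'
#' @param result A `tied_run` or `tied_avg` tibble.
#' @param path Output CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the result tibble with the sidecar (if present) re-attached as
#'   the `meta` attribute.
#' @export
write_results <- function(result, path) {
  if (!(inherits(result, "tied_run") || inherits(result, "tied_avg"))) {
    abort("result must come from run_simulation() or run_replicates()")
  }
  meta <- attr(result, "meta")
  ok <- tryCatch({
    readr::write_csv(tibble::as_tibble(result), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("failed to write results to '", path, "': ", conditionMessage(ok)))
  }
  sidecar <- list(
    kind = if (inherits(result, "tied_run")) "run" else "averaged",
    scenario = meta$scenario,
    lk_enabled = meta$lk_enabled,
    seeds = if (!is.null(meta$seeds)) meta$seeds else meta$seed,
    package_version = as.character(utils::packageVersion("tiedsim")),
    config = config_as_list(meta$config)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sp <- sidecar_path(path)
  meta <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
  cls <- if (!is.null(meta) && identical(meta$kind, "averaged")) "tied_avg" else
    if ("P_c" %in% names(out)) "tied_run" else "tied_avg"
  tibble::new_tibble(out, meta = meta, class = cls)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

# Flatten a simulation_config into JSON-serializable lists.
config_as_list <- function(config) {
  if (is.null(config)) return(NULL)
  list(
    climate = if (is.data.frame(config$climate)) {
      list(source = "table",
           start_year = min(config$climate$year),
           end_year = max(config$climate$year))
    } else {
      list(source = "synthetic",
           start_year = config$climate$start_year,
           end_year = config$climate$end_year,
           seed = config$climate$seed,
           variables = as.data.frame(config$climate$variables))
    },
    community = list(
      population_size = config$community$population_size,
      type_proportions = as.list(config$community$type_proportions),
      age_class_proportions = as.list(config$community$age_class_proportions),
      max_initial_age = config$community$max_initial_age,
      mortality_exponent = config$community$mortality_exponent,
      mortality_enabled = config$community$mortality_enabled
    ),
    scenario = as.data.frame(config$scenario),
    lk_enabled = config$lk_enabled,
    sim_start_year = config$sim_start_year,
    sim_end_year = config$sim_end_year,
    history_start_year = config$history_start_year,
    replicates = config$replicates,
    base_seed = config$base_seed,
    freeze_climate = config$freeze_climate,
    lk_eligibility = config$lk_eligibility,
    gate_current_observation = config$gate_current_observation,
    weights = list(w_p = as.data.frame(config$weights$w_p),
                   w_k = as.data.frame(config$weights$w_k))
  )
}
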