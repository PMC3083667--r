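#' Simulation configuration
#'
#' Bundles everything one run needs: the climate forcing (a generator
#' configuration or a ready-made monthly table), the community, the scenario
#' of declining traditional resource use, whether local-knowledge transfer is
#' active, the simulated window, and replication settings.
#'
#' The simulation steps monthly from January of `sim_start_year` to December
#' of `sim_end_year`; agents draw on the climate record back to
#' `history_start_year`. Demographic turnover, engagement decline and
#' known-history growth fire at each January step; the first simulated
#' January initializes histories before any perception is computed.
#'
#' @param climate A [climate_gen_config()] or a climate series data frame
#'   covering `history_start_year` through `sim_end_year`.
#' @param community A [community_config()].
#' @param scenario Scenario id (`"A"`..`"F"`) or a custom scenario tibble.
#' @param lk_enabled Should local-knowledge transfer operate?
#' @param sim_start_year,sim_end_year Simulated window (inclusive).
#' @param history_start_year First year of climate record agents may know.
#' @param replicates Number of replicate runs for [run_replicates()].
#' @param base_seed Seed of the first replicate; replicate `r` uses
#'   `base_seed + r - 1`.
#' @param freeze_climate When the forcing is generated, should all replicates
#'   share one climate realization (generated from the climate config's own
#'   seed)? If `FALSE` each replicate generates its own realization from its
#'   replicate seed, so replicate spread mixes climate and social noise.
#' @param weights Perception/transfer weight tables ([default_weights()]).
#' @param lk_eligibility Passed to [select_lk_provider()].
#' @param gate_current_observation If `TRUE`, even the current month's
#'   observation requires an engagement draw to succeed (off by default:
#'   all agents observe the present).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(climate = climate_gen_config(),
                              community = community_config(),
                              scenario = "A",
                              lk_enabled = TRUE,
                              sim_start_year = 2010,
                              sim_end_year = 2090,
                              history_start_year = 1960,
                              replicates = 30,
                              base_seed = 1,
                              freeze_climate = TRUE,
                              weights = default_weights(),
                              lk_eligibility = c("cardinality", "span"),
                              gate_current_observation = FALSE) {
  if (!(history_start_year <= sim_start_year && sim_start_year < sim_end_year)) {
    abort("need history_start_year <= sim_start_year < sim_end_year")
  }
  if (replicates < 1) abort("replicates must be >= 1")
  if (is.data.frame(climate)) {
    climate <- validate_climate_series(climate)
  } else if (!inherits(climate, "climate_gen_config")) {
    abort("climate must be a climate_gen_config or a climate series data frame")
  }
  structure(
    list(climate = climate,
         community = community,
         scenario = scenario(scenario),
         lk_enabled = isTRUE(lk_enabled),
         sim_start_year = as.integer(sim_start_year),
         sim_end_year = as.integer(sim_end_year),
         history_start_year = as.integer(history_start_year),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         freeze_climate = isTRUE(freeze_climate),
         weights = weights,
         lk_eligibility = match.arg(lk_eligibility),
         gate_current_observation = isTRUE(gate_current_observation)),
    class = "simulation_config"
  )
}

# Resolve the forcing for one replicate and check it covers the window.
resolve_climate <- function(config, seed) {
  series <- if (is.data.frame(config$climate)) {
    config$climate
  } else {
    gen_cfg <- config$climate
    if (!config$freeze_climate) gen_cfg$seed <- as.integer(seed)
    generate_synthetic_climate(gen_cfg)
  }
  if (min(series$year) > config$history_start_year ||
      max(series$year) < config$sim_end_year) {
    abort(sprintf("climate series must cover %d-%d",
                  config$history_start_year, config$sim_end_year))
  }
  series
}

#' Run one simulation replicate
#'
#' Steps the community month by month over the simulated window. At each
#' January the population turns over (aging, engagement decline, mortality,
#' replacement) and known histories grow by the newly completed year; at
#' every monthly step each variable's recorded change, the community's
#' weighted consensus perception — after local-knowledge transfer when
#' enabled — and the resulting vulnerability are computed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for this replicate (default `config$base_seed`).
#'   Fixes every random draw: community initialization, history admission,
#'   mortality, and (unless frozen) the generated climate.
#' @return A tibble of class `tied_run` with one row per (year, month,
#'   variable): columns `scenario`, `lk`, `year`, `month`, `variable`, `q`,
#'   `P_c`, `v`, `v_abs`. Run metadata (seed, config) is attached as the
#'   `meta` attribute.
#' @examples
#' \donttest{
#' cfg <- simulation_config(scenario = "B", sim_end_year = 2020)
#' run <- run_simulation(cfg, seed = 1)
#' glance(run)
#' }
#' @export
run_simulation <- function(config, seed = config$base_seed) {
  stopifnot(inherits(config, "simulation_config"))
  series <- resolve_climate(config, seed)
  records <- withr::with_seed(as.integer(seed), engine_run(config, series))
  meta <- list(seed = as.integer(seed),
               scenario = config$scenario$scenario[1],
               lk_enabled = config$lk_enabled,
               config = config)
  tibble::new_tibble(records, meta = meta, class = "tied_run")
}

# Core monthly-stepping engine. Operates on plain vectors and a logical
# year-membership matrix for speed; the per-operation exported functions
# define the semantics and are cross-checked against this path in the tests.
engine_run <- function(config, series) {
  sc <- config$scenario
  cfg <- config$community
  hs <- config$history_start_year
  y0 <- config$sim_start_year
  y1 <- config$sim_end_year
  n_hist_years <- y1 - hs          # candidate years hs .. y1-1
  all_years <- hs:y1

  # climate values as val[year_index, month, variable]
  series <- arrange(filter(series, .data$year >= hs, .data$year <= y1),
                    .data$year, .data$month)
  val <- array(0, dim = c(length(all_years), 12, 3))
  for (v in 1:3) {
    val[, , v] <- matrix(series[[CLIMATE_VARIABLES[v]]], ncol = 12, byrow = TRUE)
  }
  # cumulative year-sums per (month, variable) for the growing q baseline
  cval <- array(0, dim = dim(val))
  for (v in 1:3) cval[, , v] <- apply(val[, , v], 2, cumsum)

  pop <- initialize_community(cfg, sc)
  n <- nrow(pop)
  n_steps <- (y1 - y0 + 1L) * 12L
  q_out <- matrix(0, n_steps, 3)
  pc_out <- matrix(0, n_steps, 3)

  H <- matrix(FALSE, n, n_hist_years)
  wp <- numeric(n)
  prov <- integer(n)
  wk <- numeric(n)

  refresh_annual_state <- function() {
    H[,] <<- FALSE
    for (i in seq_len(n)) {
      h <- pop$known_history[[i]]
      if (length(h) > 0) H[i, h - hs + 1L] <<- TRUE
    }
    wp <<- perception_weight(pop, config$weights)
  }

  step <- 0L
  for (y in y0:y1) {
    yi <- y - hs + 1L
    # annual events at the January step: turnover, own experience, then
    # local-knowledge transfer (provider selection on pre-transfer histories)
    if (y == y0) {
      pop <- build_known_history(pop, y, hs)
    } else {
      pop <- annual_demographic_update(pop, cfg, sc, years_elapsed = y - y0)
      pop <- extend_known_history(pop, y)
    }
    if (config$lk_enabled) {
      sel <- select_lk_provider(pop, config$lk_eligibility)
      prov <- match(sel$provider_id, pop$id)   # NA when none
      has <- !is.na(prov)
      wk[] <- 0
      wk[has] <- knowledge_transfer_weight(pop$type[has],
                                           pop$type[prov[has]],
                                           config$weights)
      pop <- acquire_knowledge(pop, sel, config$weights)
    }
    refresh_annual_state()
    hist_size <- rowSums(H)
    has_hist <- hist_size > 0

    for (m in 1:12) {
      step <- step + 1L
      # recorded change: baseline = all years hs..y-1
      nb <- yi - 1L
      q <- val[yi, m, ] - cval[yi - 1L, m, ] / nb
      # individual perceptions: current value minus known-history mean
      hist_mean <- (H %*% val[seq_len(n_hist_years), m, ]) / hist_size
      p <- matrix(rep(val[yi, m, ], each = n), n, 3) - hist_mean
      p[!has_hist, ] <- NA_real_
      if (config$gate_current_observation) {
        observes <- pop$t_tru > runif(n)
        p[!observes, ] <- NA_real_
      }
      if (config$lk_enabled) {
        has <- !is.na(prov)
        pp <- p
        own_def <- !is.na(p)
        for (v in 1:3) {
          pv <- p[, v]
          prov_p <- pv[prov[has]]
          blended <- ifelse(own_def[has, v],
                            wk[has] * prov_p + (1 - wk[has]) * pv[has],
                            wk[has] * prov_p)
          blended[is.na(prov_p)] <- pv[has][is.na(prov_p)]
          blended[!own_def[has, v] & (wk[has] == 0 | is.na(prov_p))] <- NA_real_
          pp[has, v] <- blended
        }
        p <- pp
      }
      for (v in 1:3) {
        pc_out[step, v] <- as.numeric(community_perception(p[, v], wp))
      }
      q_out[step, ] <- q
    }
  }

  years_rep <- rep(y0:y1, each = 12)
  months_rep <- rep(1:12, times = y1 - y0 + 1L)
  tibble::tibble(
    scenario = sc$scenario[1],
    lk = config$lk_enabled,
    year = rep(years_rep, times = 3),
    month = rep(months_rep, times = 3),
    variable = rep(CLIMATE_VARIABLES, each = n_steps),
    q = as.vector(q_out),
    P_c = as.vector(pc_out),
    v = as.vector(q_out - pc_out),
    v_abs = abs(as.vector(q_out - pc_out))
  )
}

#' Run replicates and average the vulnerability trajectories
#'
#' Runs `config$replicates` simulations with seeds `base_seed`,
#' `base_seed + 1`, ... and averages the signed vulnerability and its
#' magnitude pointwise across replicates.
#'
#' @param config A [simulation_config()].
#' @return A tibble of class `tied_avg` with one row per (year, month,
#'   variable): `mean_q`, `mean_v`, `sd_v`, `mean_v_abs`, `sd_v_abs`,
#'   `n_replicates`. The seeds used are recorded in the `meta` attribute.
#' @export
run_replicates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- config$base_seed + seq_len(config$replicates) - 1L
  runs <- lapply(seeds, function(s) run_simulation(config, seed = s))
  v_mat <- vapply(runs, function(r) r$v, numeric(nrow(runs[[1]])))
  q_mat <- vapply(runs, function(r) r$q, numeric(nrow(runs[[1]])))
  v_mat <- matrix(v_mat, nrow = nrow(runs[[1]]))
  q_mat <- matrix(q_mat, nrow = nrow(runs[[1]]))
  sd0 <- function(m) if (ncol(m) > 1) apply(m, 1, sd) else rep(0, nrow(m))
  base <- runs[[1]][, c("scenario", "lk", "year", "month", "variable")]
  out <- mutate(base,
                mean_q = rowMeans(q_mat),
                mean_v = rowMeans(v_mat),
                sd_v = sd0(v_mat),
                mean_v_abs = rowMeans(abs(v_mat)),
                sd_v_abs = sd0(abs(v_mat)),
                n_replicates = config$replicates)
  meta <- list(seeds = seeds,
               scenario = config$scenario$scenario[1],
               lk_enabled = config$lk_enabled,
               config = config)
  tibble::new_tibble(out, meta = meta, class = "tied_avg")
}
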