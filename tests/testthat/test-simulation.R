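short_config <- function(...) {
  simulation_config(community = community_config(population_size = 40),
                    sim_end_year = 2020, replicates = 2, ...)
}

test_that("a run covers the simulated window densely, one record per variable", {
  run <- run_simulation(short_config(scenario = "B", lk_enabled = FALSE), seed = 1)
  expect_s3_class(run, "tied_run")
  expect_equal(nrow(run), 11 * 12 * 3)
  expect_equal(sort(unique(run$year)), 2010:2020)
  expect_equal(unique(table(run$year, run$month)), 3L)
  expect_equal(run$v, run$q - run$P_c)
  expect_equal(run$v_abs, abs(run$v))
  # default window: 81 years x 12 months x 3 variables
  full <- simulation_config()
  n_steps <- (full$sim_end_year - full$sim_start_year + 1) * 12
  expect_equal(n_steps, 972)
})

test_that("runs are deterministic under the seed and vary across seeds", {
  cfg <- short_config(scenario = "C", lk_enabled = TRUE)
  r1 <- run_simulation(cfg, seed = 7)
  r2 <- run_simulation(cfg, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_simulation(cfg, seed = 8)
  expect_false(identical(r1$v, r3$v))
})

test_that("a fully knowledgeable immortal community has zero vulnerability", {
  for (lk in c(FALSE, TRUE)) {
    cfg <- simulation_config(community = elder_community(10), scenario = "A",
                             lk_enabled = lk, sim_end_year = 2030)
    run <- run_simulation(cfg, seed = 3)
    expect_lt(max(run$v_abs), 1e-9)
  }
  # a single immortal agent with full history is already sufficient
  cfg1 <- simulation_config(community = elder_community(1), scenario = "A",
                            lk_enabled = TRUE, sim_end_year = 2020)
  expect_lt(max(run_simulation(cfg1, seed = 4)$v_abs), 1e-9)
})

test_that("local knowledge is inert in an all-gamma community", {
  gamma_cfg <- community_config(population_size = 30,
                                type_proportions = c(alpha = 0, beta = 0, gamma = 1))
  on_ <- run_simulation(simulation_config(community = gamma_cfg, scenario = "B",
                                          lk_enabled = TRUE, sim_end_year = 2020),
                        seed = 5)
  off <- run_simulation(simulation_config(community = gamma_cfg, scenario = "B",
                                          lk_enabled = FALSE, sim_end_year = 2020),
                        seed = 5)
  expect_identical(on_$v, off$v)
})

test_that("replicate averaging reduces to the single run at n = 1 and is bounded", {
  cfg <- short_config(scenario = "B", lk_enabled = FALSE)
  cfg$replicates <- 1L
  avg1 <- run_replicates(cfg)
  single <- run_simulation(cfg, seed = cfg$base_seed)
  expect_equal(avg1$mean_v, single$v)
  expect_equal(avg1$mean_v_abs, single$v_abs)
  expect_equal(avg1$sd_v, rep(0, nrow(avg1)))

  cfg$replicates <- 3L
  avg <- run_replicates(cfg)
  runs <- lapply(cfg$base_seed + 0:2, function(s) run_simulation(cfg, seed = s))
  vs <- sapply(runs, function(r) r$v)
  expect_true(all(avg$mean_v >= apply(vs, 1, min) - 1e-12))
  expect_true(all(avg$mean_v <= apply(vs, 1, max) + 1e-12))
  expect_equal(attr(avg, "meta")$seeds, cfg$base_seed + 0:2)
})

test_that("results round-trip through CSV with a seed-recording sidecar", {
  cfg <- short_config(scenario = "D", lk_enabled = TRUE)
  avg <- run_replicates(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(avg, path)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
  back <- read_results(path)
  expect_equal(back$mean_v, avg$mean_v, tolerance = 1e-12)
  meta <- attr(back, "meta")
  expect_equal(unlist(meta$seeds), cfg$base_seed + 0:1)
  expect_equal(meta$scenario, "D")

  run <- run_simulation(cfg, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_results(run, path2)
  expect_equal(nrow(read_results(path2)), nrow(run))
})

test_that("longer engagement never shrinks histories and lowers misperception", {
  # coupled draws: same seed, higher engagement => superset history
  pop <- make_population(c(60, 45), t_tru = 0.3)
  lo <- withr::with_seed(11, build_known_history(pop, 2010, 1980))
  pop$t_tru <- c(0.9, 0.9)
  hi <- withr::with_seed(11, build_known_history(pop, 2010, 1980))
  for (i in 1:2) {
    expect_true(all(lo$known_history[[i]] %in% hi$known_history[[i]]))
  }
  # statistically, a near-fully distanced community misperceives more than an
  # engaged one (LK off); above moderate engagement the relation flattens out
  # because sparser histories are unbiased subsamples of the same age window
  sc_lo <- scenario(data.frame(scenario = "lo", age_class = c("Y", "M", "O"),
                               initial_tru = 0.05, annual_change = 0))
  sc_hi <- scenario(data.frame(scenario = "hi", age_class = c("Y", "M", "O"),
                               initial_tru = 0.8, annual_change = 0))
  mean_abs_v <- function(sc) {
    cfg <- simulation_config(community = community_config(population_size = 60),
                             scenario = sc, lk_enabled = FALSE,
                             sim_end_year = 2050, replicates = 8, base_seed = 1)
    mean(run_replicates(cfg)$mean_v_abs)
  }
  expect_lt(mean_abs_v(sc_hi), mean_abs_v(sc_lo))
})

test_that("configuration files parse with overrides and validate", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario: C",
    "lk: false",
    "sim_end_year: 2030",
    "replicates: 4",
    "base_seed: 42",
    "community:",
    "  population_size: 55",
    "  mortality_enabled: false",
    "climate:",
    "  seed: 3",
    "weights:",
    "  w_p:",
    "    O.alpha: 0.9",
    "  w_k:",
    "    alpha.gamma: 0.25"
  ), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$scenario$scenario[1], "C")
  expect_false(cfg$lk_enabled)
  expect_equal(cfg$community$population_size, 55L)
  expect_false(cfg$community$mortality_enabled)
  expect_equal(cfg$base_seed, 42L)
  wp <- cfg$weights$w_p
  expect_equal(wp$weight[wp$age_class == "O" & wp$type == "alpha"], 0.9)
  wk <- cfg$weights$w_k
  expect_equal(wk$weight[wk$recipient == "alpha" & wk$provider == "gamma"], 0.25)

  over <- read_simulation_config(path, overrides = list(scenario = "F", lk = TRUE))
  expect_equal(over$scenario$scenario[1], "F")
  expect_true(over$lk_enabled)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("scenario: A", bad)
  expect_error(read_simulation_config(bad), "population_size")
})

test_that("runs reject climate series that do not cover the window", {
  small <- generate_synthetic_climate(
    climate_gen_config(start_year = 1990, end_year = 2050, seed = 1))
  expect_error(
    run_simulation(simulation_config(climate = small, sim_end_year = 2020), seed = 1),
    "must cover")
})

test_that("tidiers and plots expose the result surface", {
  run <- run_simulation(short_config(scenario = "B", lk_enabled = FALSE), seed = 1)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  g <- glance(run)
  expect_equal(g$scenario, "B")
  expect_equal(g$n_steps, 132)
  fd <- final_decade_summary(run)
  expect_equal(sort(fd$variable), sort(c("temperature", "precipitation", "runoff")))
  expect_s3_class(ggplot2::autoplot(run), "ggplot")
  cfg <- short_config(scenario = "B", lk_enabled = FALSE)
  avg <- run_replicates(cfg)
  expect_s3_class(ggplot2::autoplot(avg), "ggplot")
  expect_equal(glance(avg)$n_replicates, 2)
  expect_s3_class(plot_climate(generate_synthetic_climate(
    climate_gen_config(start_year = 2000, end_year = 2010, seed = 1))), "ggplot")
})
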