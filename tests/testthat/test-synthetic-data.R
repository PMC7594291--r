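test_that("gen_trajectory produces the configured fix schedule", {
  # 10-day single-month span at 1 h spacing: 241 fixes
  spec <- population_spec(n_individuals = 2, months = 6,
                          days_per_month = 10, rng_seed = 1)
  tr <- gen_trajectory(spec, "deer_01")
  expect_equal(nrow(tr), 241)
  expect_false(is.unsorted(tr$timestamp, strictly = TRUE))
  expect_true(all(format(tr$timestamp[-nrow(tr)], "%m") == "06"))

  expect_error(gen_trajectory(spec, "deer_99"), "unknown animal_id")
})

test_that("a zero step scale yields a stationary trajectory", {
  spec <- population_spec(n_individuals = 1, months = 5,
                          days_per_month = 3,
                          step_scale = c(deer_01 = 0), rng_seed = 2)
  tr <- gen_trajectory(spec, "deer_01")
  expect_equal(length(unique(tr$easting)), 1)
  expect_equal(length(unique(tr$northing)), 1)
  expect_equal(length(unique(tr$elevation)), 1)
})

test_that("realized mean step length matches the step scale within 5%", {
  # > 10,000 steps: full May-December at 30-minute fixes
  spec <- population_spec(n_individuals = 1, fix_interval_h = 0.5,
                          step_scale = c(deer_01 = 150), rng_seed = 3)
  tr <- gen_trajectory(spec, "deer_01")
  expect_gt(nrow(tr), 10000)
  steps <- sqrt(diff(tr$easting)^2 + diff(tr$northing)^2)
  expect_lt(abs(mean(steps) - 150) / 150, 0.05)
})

test_that("elevation equals the deterministic terrain at every fix", {
  spec <- population_spec(n_individuals = 1, months = 7,
                          days_per_month = 5, rng_seed = 4)
  tr <- gen_trajectory(spec, "deer_01")
  expect_identical(tr$elevation,
                   terrain_elevation(tr$easting, tr$northing, spec))
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  spec <- population_spec(n_individuals = 3, months = 5:6,
                          days_per_month = 2, rng_seed = 11)
  a <- gen_population(spec)
  b <- gen_population(spec)
  expect_identical(a, b)
  # different individuals follow different paths
  expect_false(identical(a[[1]]$easting, a[[2]]$easting))
})

test_that("gen_seed_data realises the documented log-linear mean function", {
  pop <- population_spec(n_individuals = 6, months = 5:8,
                         days_per_month = 2, rng_seed = 5)
  mob <- stats::setNames(seq(50, 300, length.out = 6), pop$ids)
  spec <- seed_load_spec(n_species = 8, samples_per_cell = 2,
                         mobility_coupling = 0, rng_seed = 6)
  out <- gen_seed_data(spec, pop, mob)
  expect_equal(nrow(out$dung), 6 * 4 * 2)
  expect_true(all(out$seedlings$count >= 0))
  expect_true(all(out$seedlings$count == floor(out$seedlings$count)))

  # analytic mean function: recompute one cell by hand from the params
  pr <- out$params
  lam <- expected_seed_count(pr, "deer_03", "Jun", "species_02", 20)
  manual <- 20 * pr$base_rates[["species_02"]] *
    pr$month_profiles["species_02", "Jun"] * 4 *
    pr$individual_multipliers["species_02", "deer_03"]
  expect_equal(lam, manual, tolerance = 1e-12)

  # month profiles are distributions
  expect_equal(unname(rowSums(pr$month_profiles)), rep(1, 8),
               tolerance = 1e-9)

  # reproducibility
  out2 <- gen_seed_data(spec, pop, mob)
  expect_identical(out$dung, out2$dung)
  expect_identical(out$seedlings, out2$seedlings)

  # samples_per_cell = 0: no samples at all
  none <- gen_seed_data(seed_load_spec(samples_per_cell = 0, rng_seed = 6),
                        pop, mob)
  expect_equal(nrow(none$dung), 0)
})

test_that("mobility coupling orders expected loads by mobility", {
  pop <- population_spec(n_individuals = 10, months = 5:6,
                         days_per_month = 1, rng_seed = 7)
  mob <- stats::setNames(seq(60, 240, length.out = 10), pop$ids)
  # with coupling and no individual noise the generator's mean function is
  # strictly increasing in mobility
  spec <- seed_load_spec(n_species = 2, individual_effect_sd = 0,
                         mobility_coupling = 1, samples_per_cell = 1,
                         rng_seed = 8)
  pr <- gen_seed_data(spec, pop, mob)$params
  for (sp in pr$species) {
    mult <- pr$individual_multipliers[sp, pop$ids]
    expect_equal(cor(mult, mob, method = "spearman"), 1)
  }

  # with coupling = 0 the multipliers ignore mobility entirely
  spec0 <- seed_load_spec(n_species = 2, individual_effect_sd = 0,
                          mobility_coupling = 0, samples_per_cell = 1,
                          rng_seed = 8)
  pr0 <- gen_seed_data(spec0, pop, mob)$params
  expect_equal(as.vector(pr0$individual_multipliers), rep(1, 20))
})

test_that("contaminants appear in at least three control trays", {
  pop <- population_spec(n_individuals = 3, months = 5,
                         days_per_month = 1, rng_seed = 9)
  mob <- stats::setNames(rep(100, 3), pop$ids)
  spec <- seed_load_spec(n_species = 3, n_contaminants = 2,
                         n_control_trays = 6, rng_seed = 10)
  out <- gen_seed_data(spec, pop, mob)
  trays_per <- tapply(out$control$tray_id, out$control$species,
                      function(x) length(unique(x)))
  expect_true(all(trays_per >= 3))
  expect_setequal(names(trays_per), c("contaminant_1", "contaminant_2"))
})

test_that("gen_passage_table emits normalized cells whose mean grows with skew", {
  m <- gen_passage_table(skew = 0.5, rng_seed = 12)
  expect_equal(nrow(m$cell_probs), 36)
  expect_equal(unname(rowSums(m$cell_probs)), rep(1, 36), tolerance = 1e-9)

  mid <- (c(0, m$interval_upper_bounds[-14]) + m$interval_upper_bounds) / 2
  implied_mean <- function(mod) mean(as.vector(mod$cell_probs %*% mid))
  m_lo <- gen_passage_table(skew = 0.1, rng_seed = 12)
  m_hi <- gen_passage_table(skew = 0.9, rng_seed = 12)
  expect_lt(implied_mean(m_lo), implied_mean(m_hi))

  # degenerate point-mass table confines the sampler to one interval
  pm <- gen_passage_table(n_trials = 1, n_species = 1,
                          point_mass_interval = 10)
  set.seed(13)
  x <- sample_passage_times(pm, 2000)
  expect_true(all(x > 24 & x <= 30))
})

test_that("write_synthetic_study emits readable CSVs in the core dialects", {
  dir <- file.path(tempdir(), "synthstudy")
  pop <- population_spec(n_individuals = 2, months = 5:6,
                         days_per_month = 2, rng_seed = 14)
  seeds <- seed_load_spec(n_species = 4, samples_per_cell = 1,
                          rng_seed = 14)
  paths <- write_synthetic_study(dir, pop, seeds)
  fx <- read_gps_fixes(paths$fixes)
  expect_equal(length(unique(fx$animal_id)), 2)
  trajs <- suppressMessages(filter_and_split(fx))
  expect_length(trajs, 2)
  expect_s3_class(read_dung_samples(paths$dung)$collection_date, "Date")
  expect_gt(nrow(read_seedling_counts(paths$seedlings)), 0)
  m <- build_passage_model(read_passage_rows(paths$passage))
  expect_equal(nrow(m$cell_probs), 36)
})
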