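#' Specification of a synthetic deer population
#'
#' Describes the synthetic telemetry study the generator emulates: by
#' default 21 collared individuals tracked at hourly fixes from May to
#' December, each moving as a correlated random walk with an
#' individual-specific mean hourly step length (the mobility axis), mild
#' attraction to an individual home-range centre, over a smooth sinusoidal
#' terrain that supplies elevations.
#'
#' @param n_individuals Number of deer (default 21).
#' @param months Integer calendar months covered (default 5:12, May to
#'   December).
#' @param year Calendar year of the fixes (default 2018).
#' @param days_per_month Days simulated at the start of each month; `NULL`
#'   (default) simulates full months. Smaller values scale the study down
#'   while preserving its month structure.
#' @param fix_interval_h Hours between fixes (default 1).
#' @param step_scale Named numeric vector of mean hourly step lengths in
#'   metres, one per individual; the default spans a 4-fold range
#'   (70–280 m/h) on a log scale across individuals.
#' @param turn_concentration Persistence of the correlated random walk;
#'   turning angles are drawn from a wrapped normal with
#'   `sd = pi / (1 + turn_concentration)` radians, so larger values give
#'   straighter paths.
#' @param terrain_amplitude Half-range of the sinusoidal terrain in metres.
#' @param terrain_wavelength Terrain wavelength in metres.
#' @param terrain_base Base elevation in metres above sea level.
#' @param home_range_attraction Dimensionless >= 0; per-step angular pull of
#'   the heading toward the individual's home-range centre.
#' @param rng_seed Optional integer seed; trajectories are bit-reproducible
#'   given the spec and seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 21,
                            months = 5:12,
                            year = 2018,
                            days_per_month = NULL,
                            fix_interval_h = 1,
                            step_scale = NULL,
                            turn_concentration = 2,
                            terrain_amplitude = 200,
                            terrain_wavelength = 3000,
                            terrain_base = 900,
                            home_range_attraction = 0.1,
                            rng_seed = NULL) {
  stopifnot(n_individuals >= 1, length(months) >= 1,
            all(months %in% 1:12), fix_interval_h > 0,
            turn_concentration >= 0, terrain_wavelength > 0,
            terrain_amplitude >= 0, home_range_attraction >= 0)
  ids <- sprintf("deer_%02d", seq_len(n_individuals))
  if (is.null(step_scale)) {
    step_scale <- stats::setNames(
      exp(seq(log(70), log(280), length.out = n_individuals)), ids)
  } else {
    stopifnot(!is.null(names(step_scale)), all(step_scale >= 0))
    ids <- names(step_scale)
    n_individuals <- length(ids)
  }
  # Home-range centres on a coarse grid, ~2 km apart, deterministic in the
  # individual index.
  gx <- (seq_len(n_individuals) - 1L) %% 5L
  gy <- (seq_len(n_individuals) - 1L) %/% 5L
  centres <- data.frame(animal_id = ids,
                        easting = 650000 + gx * 2000,
                        northing = 5400000 + gy * 2000)
  structure(list(
    n_individuals = n_individuals, ids = ids, months = sort(months),
    year = year, days_per_month = days_per_month,
    fix_interval_h = fix_interval_h, step_scale = step_scale,
    turn_concentration = turn_concentration,
    terrain_amplitude = terrain_amplitude,
    terrain_wavelength = terrain_wavelength,
    terrain_base = terrain_base,
    home_range_attraction = home_range_attraction,
    centres = centres, rng_seed = rng_seed
  ), class = "population_spec")
}

#' Deterministic synthetic terrain
#'
#' Smooth sinusoidal elevation surface used by the trajectory generator:
#' `base + amplitude/2 * (sin(2*pi*e/wl) + cos(2*pi*n/wl))`. Being an exact
#' closed form, it provides an oracle for vertical displacements.
#'
#' @param easting,northing Planar coordinates in metres.
#' @param spec A [population_spec()].
#' @return Elevation in metres.
#' @export
terrain_elevation <- function(easting, northing, spec) {
  wl <- spec$terrain_wavelength
  spec$terrain_base + spec$terrain_amplitude / 2 *
    (sin(2 * pi * easting / wl) + cos(2 * pi * northing / wl))
}

synth_timestamps <- function(spec) {
  out <- list()
  for (i in seq_along(spec$months)) {
    m <- spec$months[i]
    start <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", spec$year, m),
                        tz = "UTC")
    next_m <- if (m == 12L) {
      as.POSIXct(sprintf("%d-01-01 00:00:00", spec$year + 1L), tz = "UTC")
    } else {
      as.POSIXct(sprintf("%d-%02d-01 00:00:00", spec$year, m + 1L),
                 tz = "UTC")
    }
    days_in <- as.numeric(difftime(next_m, start, units = "days"))
    days <- if (is.null(spec$days_per_month)) days_in else
      min(spec$days_per_month, days_in)
    n_fix <- floor(days * 24 / spec$fix_interval_h)
    out[[i]] <- start + (seq_len(n_fix) - 1L) * spec$fix_interval_h * 3600
  }
  ts <- do.call(c, out)
  # terminal fix closing the last interval, so a d-day single-month span at
  # 1 h spacing has 24*d + 1 fixes
  c(ts, ts[length(ts)] + spec$fix_interval_h * 3600)
}

animal_seed <- function(base, idx, offset = 0L) {
  if (is.null(base)) return(NULL)
  (as.integer(base) + 7919L * as.integer(idx) + as.integer(offset)) %% 2147483629L
}

#' Generate one synthetic trajectory
#'
#' Correlated random walk for one individual: hourly step lengths are
#' gamma-distributed with mean `step_scale[animal_id]` (shape 2), headings
#' persist with wrapped-normal turning noise and are nudged toward the
#' individual's home-range centre; elevations are read exactly from
#' [terrain_elevation()] at every fix. A zero step scale yields a
#' stationary trajectory with constant elevation.
#'
#' @param spec A [population_spec()].
#' @param animal_id One of `spec$ids`.
#' @return A `deer_trajectory` (see [filter_and_split()]).
#' @export
gen_trajectory <- function(spec, animal_id) {
  idx <- match(animal_id, spec$ids)
  if (is.na(idx)) stop("unknown animal_id: ", animal_id)
  seed <- animal_seed(spec$rng_seed, idx)
  if (!is.null(seed)) set.seed(seed)
  ts <- synth_timestamps(spec)
  n <- length(ts)
  scale <- spec$step_scale[[animal_id]]
  centre <- spec$centres[idx, ]
  e <- no <- numeric(n)
  e[1] <- centre$easting
  no[1] <- centre$northing
  heading <- stats::runif(1, 0, 2 * pi)
  turn_sd <- pi / (1 + spec$turn_concentration)
  if (scale > 0) {
    steps <- stats::rgamma(n - 1L, shape = 2, scale = scale / 2)
    turns <- stats::rnorm(n - 1L, 0, turn_sd)
    for (i in seq_len(n - 1L)) {
      heading <- heading + turns[i]
      if (spec$home_range_attraction > 0) {
        bearing <- atan2(centre$northing - no[i], centre$easting - e[i])
        delta <- atan2(sin(bearing - heading), cos(bearing - heading))
        heading <- heading + spec$home_range_attraction * delta
      }
      e[i + 1L] <- e[i] + steps[i] * cos(heading)
      no[i + 1L] <- no[i] + steps[i] * sin(heading)
    }
  } else {
    e[] <- e[1]
    no[] <- no[1]
  }
  traj <- data.frame(timestamp = ts, easting = e, northing = no,
                     elevation = terrain_elevation(e, no, spec))
  attr(traj, "animal_id") <- animal_id
  class(traj) <- c("deer_trajectory", "data.frame")
  traj
}

#' Generate all trajectories of a synthetic population
#'
#' @param spec A [population_spec()].
#' @return Named list of `deer_trajectory` objects, one per individual.
#' @export
gen_population <- function(spec) {
  stats::setNames(lapply(spec$ids, gen_trajectory, spec = spec), spec$ids)
}

#' Realized mean hourly step length per individual
#'
#' The mobility scalar used when coupling seed loads to movement: the mean
#' Euclidean distance between consecutive fixes.
#'
#' @param trajectories Named list of `deer_trajectory` objects.
#' @return Named numeric vector, metres per fix interval.
#' @export
realized_mobility <- function(trajectories) {
  vapply(trajectories, function(tr) {
    mean(sqrt(diff(tr$easting)^2 + diff(tr$northing)^2))
  }, numeric(1))
}

#' Specification of synthetic dung seed loads
#'
#' Describes how species x individual x month seedling counts are
#' generated. Expected counts follow a log-linear mean function
#' `lambda = dry_mass_g * base_rate[s] * month_profile[s, m] * n_months *
#' exp(individual_effect_sd * z[s, a] + mobility_coupling * zmob_a)`, where
#' `z[s, a]` is a standard-normal species-by-individual effect (plant
#' species differ in how their load distributes across deer) and `zmob_a`
#' the standardized mobility of individual `a`; realized counts are
#' Poisson.
#' With `mobility_coupling = 0` loads are independent of movement by
#' construction; positive coupling concentrates seed load on the more
#' mobile individuals.
#'
#' @param n_species Number of plant species (default 62, of which the
#'   commonest species end up dispersed by many individuals and the rare
#'   tail by few).
#' @param individual_effect_sd Log-scale SD of the per-animal load
#'   multiplier.
#' @param mobility_coupling Log-linear coefficient of standardized mobility
#'   in the mean function (0 = independence).
#' @param samples_per_cell Dung samples collected per individual x month
#'   (default 3).
#' @param mean_volume_ml Mean pellet-group volume (default 172.3 ml).
#' @param sd_volume_ml SD of pellet-group volume (default 25 ml,
#'   truncated at 20 ml).
#' @param n_contaminants Weedy contaminant species injected into control
#'   trays and samples (default 3).
#' @param n_control_trays Number of dung-free control trays (default 6).
#' @param seasonal If `TRUE` (default) each species fruits in a seeded
#'   seasonal window (Gaussian month profile); if `FALSE` profiles are flat,
#'   which together with `individual_effect_sd = 0` makes loads
#'   exchangeable across cells — the regime in which the cell-level
#'   permutation null is exactly calibrated.
#' @param rng_seed Optional integer seed.
#' @return Object of class `seed_load_spec`.
#' @export
seed_load_spec <- function(n_species = 62,
                           individual_effect_sd = 1,
                           mobility_coupling = 0,
                           samples_per_cell = 3,
                           mean_volume_ml = 172.3,
                           sd_volume_ml = 25,
                           n_contaminants = 3,
                           n_control_trays = 6,
                           seasonal = TRUE,
                           rng_seed = NULL) {
  stopifnot(n_species >= 1, individual_effect_sd >= 0,
            samples_per_cell >= 0, mean_volume_ml > 0, sd_volume_ml >= 0,
            n_contaminants >= 0, n_control_trays >= 0)
  structure(list(
    n_species = as.integer(n_species),
    individual_effect_sd = individual_effect_sd,
    mobility_coupling = mobility_coupling,
    samples_per_cell = as.integer(samples_per_cell),
    mean_volume_ml = mean_volume_ml, sd_volume_ml = sd_volume_ml,
    n_contaminants = as.integer(n_contaminants),
    n_control_trays = as.integer(n_control_trays),
    seasonal = isTRUE(seasonal),
    rng_seed = rng_seed
  ), class = "seed_load_spec")
}

# Deterministic per-species ingredients of the seed-load mean function:
# base rates follow a steep abundance series (few common, many rare
# species); month profiles are normalized Gaussian bumps over the month
# sequence with seeded centres and widths.
seed_load_params <- function(spec, pop, mobility) {
  if (!is.null(spec$rng_seed)) set.seed(as.integer(spec$rng_seed))
  n_sp <- spec$n_species
  species <- sprintf("species_%02d", seq_len(n_sp))
  # steep abundance series: dung seed loads are dominated by a few common
  # species, with a long rare tail that the minimum-individuals filter
  # removes from the species-level analyses
  base_rates <- stats::setNames(
    exp(seq(log(2), log(1e-4), length.out = max(n_sp, 2L)))[seq_len(n_sp)],
    species)
  n_m <- length(pop$months)
  centres <- stats::runif(n_sp, 1, n_m)
  widths <- stats::runif(n_sp, 1, n_m)
  prof <- matrix(0, n_sp, n_m,
                 dimnames = list(species, month.abb[pop$months]))
  for (s in seq_len(n_sp)) {
    if (isTRUE(spec$seasonal)) {
      w <- exp(-((seq_len(n_m) - centres[s])^2) / (2 * widths[s]^2))
      prof[s, ] <- w / sum(w)
    } else {
      prof[s, ] <- 1 / n_m
    }
  }
  # species-specific individual effects: plant species differ in how their
  # load distributes across individuals (diet composition), on top of a
  # shared mobility coupling
  z <- matrix(stats::rnorm(n_sp * length(pop$ids)), n_sp,
              dimnames = list(species, pop$ids))
  mob <- mobility[pop$ids]
  zmob <- if (stats::sd(mob) > 0) (mob - mean(mob)) / stats::sd(mob) else
    rep(0, length(mob))
  ind_mult <- exp(spec$individual_effect_sd * z +
                    rep(spec$mobility_coupling * zmob, each = n_sp))
  list(species = species, base_rates = base_rates, month_profiles = prof,
       individual_multipliers = ind_mult, n_months = n_m)
}

#' Expected seedling count of the generator's mean function
#'
#' Evaluates the documented mean function analytically, for checking the
#' generator against its own contract.
#'
#' @param params The `params` element returned by [gen_seed_data()].
#' @param animal_id,month_name,species Cell identifiers (`month_name` is a
#'   three-letter month label).
#' @param dry_mass_g Sample dry mass in grams.
#' @return Expected Poisson count.
#' @export
expected_seed_count <- function(params, animal_id, month_name, species,
                                dry_mass_g) {
  dry_mass_g * params$base_rates[[species]] *
    params$month_profiles[species, month_name] * params$n_months *
    params$individual_multipliers[species, animal_id]
}

#' Generate synthetic dung samples, seedling counts and control trays
#'
#' Emits, per individual x month, `samples_per_cell` dung samples with
#' volumes drawn around `mean_volume_ml`, Poisson seedling counts per
#' species following the mean function documented in [seed_load_spec()],
#' and a control-tray table in which each contaminant species appears in at
#' least three distinct trays (so the contamination filter excludes exactly
#' those species). Contaminant seedlings are also injected into the dung
#' samples.
#'
#' @param spec A [seed_load_spec()].
#' @param pop The [population_spec()] the samples refer to.
#' @param mobility Named mobility scalar per individual, e.g. from
#'   [realized_mobility()].
#' @return List with `dung`, `seedlings`, `control` (data frames in the
#'   package's CSV dialects) and `params` (the mean-function ingredients,
#'   for analytic checks).
#' @export
gen_seed_data <- function(spec, pop, mobility) {
  stopifnot(inherits(spec, "seed_load_spec"),
            inherits(pop, "population_spec"),
            all(pop$ids %in% names(mobility)))
  params <- seed_load_params(spec, pop, mobility)
  month_names <- month.abb[pop$months]
  dung <- list()
  seedl <- list()
  k <- 0L
  if (spec$samples_per_cell > 0L) {
    for (a in pop$ids) {
      for (mi in seq_along(pop$months)) {
        m <- pop$months[mi]
        for (r in seq_len(spec$samples_per_cell)) {
          k <- k + 1L
          vol <- max(20, stats::rnorm(1, spec$mean_volume_ml,
                                      spec$sd_volume_ml))
          day <- sample(1:28, 1)
          sid <- sprintf("s_%s_%02d_%d", a, m, r)
          dung[[k]] <- data.frame(
            sample_id = sid, animal_id = a,
            collection_date = as.Date(sprintf("%d-%02d-%02d", pop$year, m,
                                              day)),
            volume_ml = round(vol, 1))
          mass <- dung[[k]]$volume_ml * 0.13
          lam <- vapply(params$species, function(s) {
            expected_seed_count(params, a, month_names[mi], s, mass)
          }, numeric(1))
          counts <- stats::rpois(length(lam), lam)
          if (spec$n_contaminants > 0L) {
            csp <- sprintf("contaminant_%d", seq_len(spec$n_contaminants))
            ccounts <- stats::rpois(spec$n_contaminants, 0.5)
            counts <- c(counts, ccounts)
            names(counts) <- c(params$species, csp)
          } else {
            names(counts) <- params$species
          }
          pos <- counts > 0
          if (any(pos)) {
            seedl[[k]] <- data.frame(sample_id = sid,
                                     species = names(counts)[pos],
                                     count = as.integer(counts[pos]))
          }
        }
      }
    }
  }
  dung <- if (k > 0L) do.call(rbind, dung) else
    data.frame(sample_id = character(), animal_id = character(),
               collection_date = as.Date(character()),
               volume_ml = numeric())
  seedl <- if (length(seedl)) {
    do.call(rbind, c(seedl, list(make.row.names = FALSE)))
  } else {
    data.frame(sample_id = character(), species = character(),
               count = integer())
  }
  control <- if (spec$n_contaminants > 0L && spec$n_control_trays >= 3L) {
    rows <- list()
    for (ci in seq_len(spec$n_contaminants)) {
      n_tr <- sample(3:spec$n_control_trays, 1)
      trays <- sample(spec$n_control_trays, n_tr)
      rows[[ci]] <- data.frame(
        tray_id = sprintf("tray_%d", sort(trays)),
        species = sprintf("contaminant_%d", ci))
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(tray_id = character(), species = character())
  }
  rownames(dung) <- NULL
  list(dung = dung, seedlings = seedl, control = control, params = params)
}

#' Generate a synthetic gut-passage probability table
#'
#' Produces unimodal excretion-probability vectors over the 14 retention
#' intervals for each (trial, species) cell: interval weights follow a
#' log-normal density over interval midpoints whose median retention is
#' `12 + 24 * skew` hours, with mild seeded cell-to-cell jitter, so larger
#' `skew` shifts mass toward long retention and increases the implied mean
#' passage time.
#'
#' @param skew Dimensionless in \[0, 1\]; 0 concentrates excretion early,
#'   1 late.
#' @param n_trials,n_species Grid size (default 6 x 6, giving 36 cells).
#' @param rng_seed Optional integer seed for the cell jitter.
#' @param point_mass_interval Optional interval index (1–14); if given, all
#'   cells put probability 1 on that interval (degenerate model for exact
#'   tests).
#' @return A `passage_model` (see [build_passage_model()]).
#' @export
gen_passage_table <- function(skew = 0.5, n_trials = 6, n_species = 6,
                              rng_seed = NULL,
                              point_mass_interval = NULL) {
  stopifnot(n_trials >= 1, n_species >= 1, skew >= 0, skew <= 1)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  bounds <- PASSAGE_BOUNDS
  lower <- c(0, bounds[-length(bounds)])
  mid <- (lower + bounds) / 2
  width <- bounds - lower
  rows <- list()
  k <- 0L
  for (tr in seq_len(n_trials)) {
    for (sp in seq_len(n_species)) {
      k <- k + 1L
      if (!is.null(point_mass_interval)) {
        p <- rep(0, length(bounds))
        p[point_mass_interval] <- 1
      } else {
        jitter <- if (is.null(rng_seed)) 1 else exp(stats::rnorm(1, 0, 0.1))
        med <- (12 + 24 * skew) * jitter
        w <- stats::dlnorm(mid, meanlog = log(med), sdlog = 0.5) * width
        p <- w / sum(w)
      }
      rows[[k]] <- data.frame(trial = sprintf("trial_%d", tr),
                              species = sprintf("pspecies_%d", sp),
                              interval_upper_h = bounds, prob = p)
    }
  }
  build_passage_model(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write a complete synthetic study directory
#'
#' Generates trajectories, dung samples, seedling counts, control trays and
#' a passage table, and writes them in the package's CSV dialects
#' (`fixes.csv`, `dung.csv`, `seedlings.csv`, `control.csv`,
#' `passage.csv`).
#'
#' @param dir Output directory (created if needed).
#' @param pop A [population_spec()].
#' @param seeds A [seed_load_spec()].
#' @param passage_skew Skew passed to [gen_passage_table()].
#' @return Invisibly, a named list of the written file paths.
#' @export
write_synthetic_study <- function(dir, pop = population_spec(),
                                  seeds = seed_load_spec(),
                                  passage_skew = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trajs <- gen_population(pop)
  fixes <- do.call(rbind, lapply(names(trajs), function(id) {
    tr <- trajs[[id]]
    data.frame(animal_id = id,
               timestamp = format(tr$timestamp, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               easting_m = tr$easting, northing_m = tr$northing,
               elevation_m = tr$elevation, quality_ok = TRUE)
  }))
  sdat <- gen_seed_data(seeds, pop, realized_mobility(trajs))
  pm <- gen_passage_table(passage_skew, rng_seed = seeds$rng_seed)
  passage_rows <- do.call(rbind, lapply(rownames(pm$cell_probs), function(rn) {
    parts <- strsplit(rn, "/", fixed = TRUE)[[1]]
    data.frame(trial = parts[1], species = parts[2],
               interval_upper_h = pm$interval_upper_bounds,
               prob = as.vector(pm$cell_probs[rn, ]))
  }))
  paths <- list(
    fixes = file.path(dir, "fixes.csv"),
    dung = file.path(dir, "dung.csv"),
    seedlings = file.path(dir, "seedlings.csv"),
    control = file.path(dir, "control.csv"),
    passage = file.path(dir, "passage.csv")
  )
  utils::write.csv(fixes, paths$fixes, row.names = FALSE)
  write_table(sdat$dung, paths$dung)
  write_table(sdat$seedlings, paths$seedlings)
  write_table(sdat$control, paths$control)
  write_table(passage_rows, paths$passage)
  invisible(paths)
}
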