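# Replicated mini-studies used by the calibration and pattern checks.
# Problem sizes are scaled-down versions of the full design (fewer days per
# month and fewer draws) so hundreds of replicates stay cheap; seeds are
# passed in so every replicate is reproducible.

# one fixed small population + its horizontal LDD probabilities per cell
fixed_ldd_cells <- function(seed = 777, n_individuals = 10, months = 5:8,
                            days_per_month = 2, n_draws = 800) {
  pop <- population_spec(n_individuals = n_individuals, months = months,
                         days_per_month = days_per_month, rng_seed = seed)
  trajs <- gen_population(pop)
  pm <- gen_passage_table(skew = 0.5, rng_seed = seed)
  set.seed(seed)
  p_samples <- sample_passage_times(pm, 300)
  cfg <- dispersal_config(n_endpoint_draws = n_draws)
  set.seed(seed + 1)
  ev <- simulate_all_events(trajs, p_samples, cfg)
  ldd <- ldd_probability_table(ev, cfg)
  list(pop = pop, trajs = trajs, ldd = ldd, cfg = cfg,
       mobility = realized_mobility(trajs))
}

# one replicate of the null-coverage experiment: loads drawn independently
# of the (fixed) LDD probabilities, exchangeable across cells
coverage_replicate <- function(base, rep_seed, n_perm = 1000) {
  seeds <- seed_load_spec(n_species = 1, individual_effect_sd = 0,
                          mobility_coupling = 0, seasonal = FALSE,
                          samples_per_cell = 1, n_contaminants = 0,
                          rng_seed = rep_seed)
  sdat <- gen_seed_data(seeds, base$pop, base$mobility)
  tab <- build_seed_load_table(sdat$dung, sdat$seedlings, base$cfg)
  lv <- species_load_vector(tab, "species_01")
  lt <- base$ldd[base$ldd$orientation == "horizontal", ]
  m <- match(paste(lv$animal_id, as.character(lv$month)),
             paste(lt$animal_id, as.character(lt$month)))
  loads <- lv$q[!is.na(m)]
  probs <- lt$prob[m[!is.na(m)]]
  if (sum(loads) == 0 || length(unique(loads)) < 2) return(NA)
  obs <- weighted_potential(loads, probs)
  set.seed(rep_seed + 500000L)
  nul <- permutation_null(loads, probs, n_perm)
  obs >= nul$null_low && obs <= nul$null_high
}

# one replicate of the individual-vs-month variance-partitioning pattern:
# 21 individuals with 4-fold step-scale heterogeneity, no month effect
recovery_replicate <- function(rep_seed, p_samples,
                               n_draws = 1000) {
  pop <- population_spec(n_individuals = 21, months = 5:8,
                         days_per_month = 2, rng_seed = rep_seed)
  trajs <- gen_population(pop)
  cfg <- dispersal_config(n_endpoint_draws = n_draws)
  set.seed(rep_seed + 600000L)
  ev <- simulate_all_events(trajs, p_samples, cfg)
  ldd <- ldd_probability_table(ev, cfg)
  lt <- ldd[ldd$orientation == "horizontal", ]
  r_ind <- one_way_partition(lt$prob, lt$animal_id)$r_squared
  r_mon <- one_way_partition(lt$prob, as.character(lt$month))$r_squared
  c(individual = r_ind, month = r_mon)
}

# one replicate of the directional-detection experiment: the potential scan
# on a population whose seed loads are (or are not) coupled to mobility
direction_replicate <- function(base, rep_seed, coupling, n_perm = 500) {
  seeds <- seed_load_spec(n_species = 5, individual_effect_sd = 0,
                          mobility_coupling = coupling, seasonal = FALSE,
                          samples_per_cell = 1, n_contaminants = 0,
                          rng_seed = rep_seed)
  sdat <- gen_seed_data(seeds, base$pop, base$mobility)
  cfg <- dispersal_config(n_endpoint_draws = base$cfg$n_endpoint_draws,
                          n_permutations = n_perm)
  tab <- build_seed_load_table(sdat$dung, sdat$seedlings, cfg)
  set.seed(rep_seed + 700000L)
  scan <- tryCatch(
    suppressWarnings(species_potential_scan(tab, base$ldd, cfg)),
    error = function(e) NULL)
  if (is.null(scan)) return(NULL)
  c(direction_of_deviation(scan)[c("increased", "decreased")],
    n_tests = nrow(scan))
}
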