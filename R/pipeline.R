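# Stage seeds are derived from the master seed by fixed offsets so any
# stage can be rerun in isolation and still match the full run.
stage_seeds <- function(master) {
  if (is.null(master)) {
    return(list(synth = NULL, passage = NULL, simulate = NULL,
                permute = NULL))
  }
  m <- as.integer(master)
  list(synth = (m + 1001L) %% 2147483629L,
       passage = (m + 2002L) %% 2147483629L,
       simulate = (m + 3003L) %% 2147483629L,
       permute = (m + 4004L) %% 2147483629L)
}

#' Run the full dispersal pipeline
#'
#' Orchestrates the end-to-end analysis: (optionally) generate a synthetic
#' study, read and screen the GPS fixes, build the gut-passage model and
#' sample passage times, simulate dispersal events and per-cell LDD
#' probabilities, compute dung seed loads with contamination filtering, run
#' the variance partitioning and regression analyses, and scan
#' species-level LDD potentials against their permutation nulls with the
#' across-species binomial meta-test. All stage outputs, a JSON run
#' manifest, and a Markdown report are written to `out_dir`. With a fixed
#' `cfg$rng_seed` the run is fully reproducible: per-stage seeds are
#' derived from the master seed by fixed offsets.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [dispersal_config()].
#' @param inputs Either `NULL` (generate a synthetic study from `pop` and
#'   `seeds`) or a named list of paths `fixes`, `dung`, `seedlings`,
#'   `control`, `passage`.
#' @param pop A [population_spec()] for synthetic generation.
#' @param seeds A [seed_load_spec()] for synthetic generation.
#' @param passage_skew Skew of the synthetic passage table.
#' @param write_events Also write the (potentially large) per-event table
#'   as `events.csv`?
#' @param figures Draw report figures (requires ggplot2)?
#' @return Invisibly, a named list of all stage results.
#' @export
run_pipeline <- function(out_dir, cfg = dispersal_config(), inputs = NULL,
                         pop = population_spec(),
                         seeds = seed_load_spec(),
                         passage_skew = 0.5, write_events = FALSE,
                         figures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seeds(cfg$rng_seed)
  manifest <- list(tool = "deerseed",
                   version = as.character(utils::packageVersion("deerseed")),
                   r_version = R.version.string,
                   config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                   stage_seeds = sseed, stages = list())
  fail <- function(stage, err) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(err)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }

  if (is.null(inputs)) {
    res <- tryCatch({
      if (!is.null(sseed$synth)) {
        pop$rng_seed <- sseed$synth
        seeds$rng_seed <- sseed$synth
      }
      write_synthetic_study(file.path(out_dir, "inputs"), pop, seeds,
                            passage_skew)
    }, error = function(e) fail("synth", e))
    inputs <- res
    manifest$stages$synth <- list(generated = TRUE)
  }
  manifest$input_digests <- as.list(tools::md5sum(unlist(inputs)))

  # movement -------------------------------------------------------------
  fixes <- tryCatch(read_gps_fixes(inputs$fixes),
                    error = function(e) fail("read_fixes", e))
  trajs <- tryCatch(suppressMessages(filter_and_split(fixes)),
                    error = function(e) fail("filter_fixes", e))
  manifest$stages$movement <- list(n_fixes = nrow(fixes),
                                   n_individuals = length(trajs))

  # passage time ---------------------------------------------------------
  p_samples <- tryCatch({
    model <- build_passage_model(read_passage_rows(inputs$passage))
    if (!is.null(sseed$passage)) set.seed(sseed$passage)
    sample_passage_times(model, cfg$n_passage_draws_per_cell)
  }, error = function(e) fail("passage", e))
  manifest$stages$passage <- list(
    n_samples = length(p_samples),
    quantiles = as.list(stats::setNames(
      empirical_quantiles(p_samples, c(0.025, 0.5, 0.975)),
      c("q025_h", "q50_h", "q975_h"))))

  # dispersal simulation -------------------------------------------------
  sim <- tryCatch({
    if (!is.null(sseed$simulate)) set.seed(sseed$simulate)
    events <- simulate_all_events(trajs, p_samples, cfg)
    list(events = events,
         ldd = ldd_probability_table(events, cfg),
         kernel = kernel_summary(events, cfg))
  }, error = function(e) fail("simulate", e))
  manifest$stages$simulate <- list(
    n_events = nrow(sim$events),
    dropped_fractions = as.list(attr(sim$events, "dropped_fractions")))
  write_table(sim$ldd, file.path(out_dir, "ldd_table.csv"))
  if (write_events) {
    write_table(sim$events, file.path(out_dir, "events.csv"))
  }
  write_run_metadata(sim$kernel, file.path(out_dir, "kernel_summary.json"))

  # seed load ------------------------------------------------------------
  load_res <- tryCatch({
    dung <- read_dung_samples(inputs$dung)
    seedl <- read_seedling_counts(inputs$seedlings)
    control <- read_control_trays(inputs$control)
    filt <- exclude_contaminants(seedl, control, cfg)
    table <- build_seed_load_table(dung, filt$seedlings, cfg)
    counts <- species_individual_counts(table, cfg)
    list(table = table, excluded = filt$excluded, counts = counts)
  }, error = function(e) fail("seedload", e))
  manifest$stages$seedload <- list(
    n_samples = nrow(load_res$table$samples),
    n_species = length(load_res$table$species),
    excluded_contaminants = load_res$excluded,
    n_filtered_species = length(load_res$counts$filtered))
  write_table(load_res$table$cells, file.path(out_dir, "seedload.csv"))
  write_table(load_res$table$totals, file.path(out_dir,
                                               "seedload_totals.csv"))

  # inference (Questions 1-4) --------------------------------------------
  infer <- tryCatch({
    run_inference(sim$ldd, load_res$table, cfg)
  }, error = function(e) fail("inference", e))
  write_table(infer$anova, file.path(out_dir, "anova.csv"))
  write_table(infer$regression, file.path(out_dir, "regression.csv"))
  write_table(infer$interaction, file.path(out_dir, "interaction.csv"))
  manifest$stages$inference <- list(n_cells = infer$n_cells,
                                    n_samples = infer$n_samples)

  # species potential (Question 5) ---------------------------------------
  pot <- tryCatch({
    if (cfg$n_permutations < 1000L) {
      warning("n_permutations = ", cfg$n_permutations,
              " gives unstable 2.5/97.5 percentiles; consider >= 1000")
    }
    if (!is.null(sseed$permute)) set.seed(sseed$permute)
    scan <- species_potential_scan(load_res$table, sim$ldd, cfg)
    list(scan = scan, meta = deviation_scan(scan),
         direction = direction_of_deviation(scan))
  }, error = function(e) fail("potential", e))
  write_table(pot$scan, file.path(out_dir, "potential.csv"))
  write_run_metadata(c(unclass(pot$meta), pot$direction),
                     file.path(out_dir, "meta.json"))
  manifest$stages$potential <- list(n_tests = nrow(pot$scan),
                                    n_deviations = pot$meta$n_deviations)

  write_run_metadata(manifest, file.path(out_dir, "manifest.json"))
  results <- list(trajectories = trajs, p_samples = p_samples,
                  events = sim$events, ldd = sim$ldd, kernel = sim$kernel,
                  seed_load = load_res, inference = infer, potential = pot,
                  manifest = manifest)
  make_report(results, file.path(out_dir, "report.md"), cfg = cfg,
              figures = figures)
  invisible(results)
}

# Questions 1-4 on pipeline outputs: one-way partitions at the grains the
# study reports (LDD at the individual x month cell grain, seed load at the
# sample grain), the load-vs-LDD regression per orientation at the
# individual grain, and the species x LDD interaction test.
run_inference <- function(ldd, seed_table, cfg = dispersal_config()) {
  anova_rows <- list()
  for (orient in c("horizontal", "upward", "downward")) {
    lt <- ldd[ldd$orientation == orient, , drop = FALSE]
    for (fac in c("individual", "month")) {
      labels <- if (fac == "individual") lt$animal_id else
        as.character(lt$month)
      res <- one_way_partition(lt$prob, labels, fac)
      res$response <- paste0(orient, "_ldd_probability")
      anova_rows[[paste(orient, fac)]] <- res
    }
  }
  samp <- seed_table$samples
  log_q <- transform_values(samp$q_total, "log")
  anova_rows[["load individual"]] <- cbind(
    one_way_partition(log_q, samp$animal_id, "individual"),
    response = "log_seed_load")
  anova_rows[["load month"]] <- cbind(
    one_way_partition(log_q, as.character(samp$month), "month"),
    response = "log_seed_load")
  anova <- do.call(rbind, c(anova_rows, list(make.row.names = FALSE)))

  totals <- seed_table$totals
  animal_load <- tapply(totals$total_q, totals$animal_id, sum)
  reg_rows <- list()
  for (orient in c("horizontal", "upward", "downward")) {
    lt <- ldd[ldd$orientation == orient, , drop = FALSE]
    num <- tapply(lt$prob * lt$n_events, lt$animal_id, sum)
    den <- tapply(lt$n_events, lt$animal_id, sum)
    prob_a <- num / den
    shared <- intersect(names(animal_load), names(prob_a))
    if (length(shared) >= 3L) {
      reg_rows[[orient]] <- regress_load_on_ldd(
        as.vector(animal_load[shared]), as.vector(prob_a[shared]),
        orientation = orient, n_events = as.vector(den[shared]))
    }
  }
  regression <- do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))

  filtered <- species_individual_counts(seed_table, cfg)$filtered
  inter_rows <- list()
  if (length(filtered) >= 2L) {
    cells <- seed_table$cells[seed_table$cells$species %in% filtered, ,
                              drop = FALSE]
    for (orient in c("horizontal", "upward", "downward")) {
      inter_rows[[orient]] <- tryCatch(
        suppressWarnings(species_interaction_model(cells, ldd, orient)),
        error = function(e) NULL)
    }
  }
  interaction <- if (length(inter_rows)) {
    do.call(rbind, c(inter_rows, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  # better-specified joint (individual + month) fits alongside the
  # one-way partitions
  joint <- list()
  for (orient in c("horizontal", "upward", "downward")) {
    lt <- ldd[ldd$orientation == orient, , drop = FALSE]
    joint[[paste0(orient, "_ldd")]] <- tryCatch(
      joint_partition(lt$prob, lt$animal_id, as.character(lt$month),
                      c("individual", "month")),
      error = function(e) NULL)
  }
  joint$log_seed_load <- tryCatch(
    joint_partition(log_q, samp$animal_id, as.character(samp$month),
                    c("individual", "month")),
    error = function(e) NULL)

  list(anova = anova, regression = regression, interaction = interaction,
       joint = joint,
       n_cells = nrow(ldd[ldd$orientation == "horizontal", ]),
       n_samples = nrow(samp))
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")

md_table <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0L) return("*(unavailable)*")
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]], digits)
    else df[[nm]] <- as.character(df[[nm]])
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Write a Markdown run report
#'
#' Summarises a pipeline run in the structure of the study's five
#' questions: the pooled dispersal-kernel summary, the variance
#' partitioning of LDD probability and seed load across individuals and
#' months, the load-versus-LDD regressions, the species x LDD interaction
#' test, and the species LDD potentials with their permutation nulls and
#' the across-species meta-test. Missing stage outputs are marked
#' unavailable rather than failing. Regenerating the report from the same
#' results is idempotent.
#'
#' @param results Result list from [run_pipeline()] (any subset of its
#'   elements).
#' @param path Output `.md` path.
#' @param cfg The [dispersal_config()] used (echoed in the header).
#' @param figures If `TRUE` and ggplot2 is installed, PNG figures are
#'   written next to the report.
#' @return Invisibly, `path`.
#' @export
make_report <- function(results, path, cfg = dispersal_config(),
                        figures = FALSE) {
  L <- character()
  add <- function(...) L <<- c(L, ...)
  add("# Red deer seed-dispersal run report", "")
  add(sprintf("Thresholds: horizontal LDD > %g m; vertical LDD > %g m.",
              cfg$horizontal_threshold, cfg$vertical_threshold), "")

  add("## Dispersal kernel", "")
  if (!is.null(results$kernel)) {
    k <- results$kernel
    add(sprintf(paste0("Across %d simulated events: mean horizontal ",
                       "displacement %s m; %s%% beyond %g m; %s%% upward ",
                       "and %s%% downward beyond %g m; 1/99%% horizontal ",
                       "quantiles %s / %s m; 1/99%% vertical quantiles ",
                       "%s / %s m."),
                k$n_events, fmt_num(k$mean_horizontal_m),
                fmt_num(100 * k$frac_horizontal_ldd),
                cfg$horizontal_threshold,
                fmt_num(100 * k$frac_upward_ldd),
                fmt_num(100 * k$frac_downward_ldd), cfg$vertical_threshold,
                fmt_num(k$q01_horizontal_m), fmt_num(k$q99_horizontal_m),
                fmt_num(k$q01_vertical_m), fmt_num(k$q99_vertical_m)), "")
  } else add("*(unavailable)*", "")

  add("## Questions 1-2: variance across individuals and months", "")
  add(md_table(results$inference$anova), "")
  add("## Question 3: seed load vs LDD probability", "")
  add(md_table(results$inference$regression), "")
  add("## Question 4: species x LDD interaction", "")
  add(md_table(results$inference$interaction), "")

  add("## Question 5: species LDD potential vs permutation null", "")
  if (!is.null(results$potential)) {
    add(md_table(results$potential$scan), "")
    meta <- results$potential$meta
    dir <- results$potential$direction
    add(sprintf(paste0("%d of %d species x orientation tests deviate from ",
                       "their 95%% null interval (%d increased, %d ",
                       "decreased LDD potential); across-species binomial ",
                       "p = %s (n per test: see table)."),
                meta$n_deviations, meta$n_tests, dir$increased,
                dir$decreased, fmt_num(meta$p_value)), "")
  } else add("*(unavailable)*", "")

  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    try(report_figures(results, dirname(path), cfg), silent = TRUE)
    add("Figures written alongside this report: kernel_horizontal.png,",
        "kernel_vertical.png, ldd_by_individual.png, load_vs_ldd.png,",
        "potential_intervals.png", "")
  }
  writeLines(L, path)
  invisible(path)
}

report_figures <- function(results, dir, cfg) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  ev <- results$events
  if (!is.null(ev)) {
    p1 <- gg(ev, aes(x = d_horiz_m, colour = animal_id)) +
      ggplot2::geom_density() + ggplot2::scale_y_sqrt() +
      ggplot2::geom_vline(xintercept = cfg$horizontal_threshold,
                          linetype = 2) +
      ggplot2::labs(x = "horizontal displacement (m)", y = "density") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
    ggplot2::ggsave(file.path(dir, "kernel_horizontal.png"), p1,
                    width = 6, height = 4, dpi = 120)
    p2 <- gg(ev, aes(x = d_vert_m, colour = animal_id)) +
      ggplot2::geom_density() +
      ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$vertical_threshold,
                          linetype = 2) +
      ggplot2::labs(x = "vertical displacement (m)", y = "density") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
    ggplot2::ggsave(file.path(dir, "kernel_vertical.png"), p2,
                    width = 6, height = 4, dpi = 120)
  }
  if (!is.null(results$ldd)) {
    p3 <- gg(results$ldd, aes(x = animal_id, y = prob, colour = month)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~orientation, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "per-seed LDD probability") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
    ggplot2::ggsave(file.path(dir, "ldd_by_individual.png"), p3,
                    width = 8, height = 4, dpi = 120)
  }
  if (!is.null(results$seed_load) && !is.null(results$ldd)) {
    tot <- results$seed_load$table$totals
    lt <- results$ldd[results$ldd$orientation == "horizontal", ]
    m <- match(paste(tot$animal_id, as.character(tot$month)),
               paste(lt$animal_id, as.character(lt$month)))
    d <- data.frame(load = tot$total_q, prob = lt$prob[m])
    d <- d[!is.na(d$prob) & d$load > 0, ]
    p4 <- gg(d, aes(x = log(prob / (1 - prob)), y = log(load))) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
      ggplot2::labs(x = "logit horizontal LDD probability",
                    y = "log total seed load") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "load_vs_ldd.png"), p4,
                    width = 6, height = 4, dpi = 120)
  }
  if (!is.null(results$potential)) {
    sc <- results$potential$scan
    p5 <- gg(sc, aes(x = species, y = observed, colour = deviates)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(aes(ymin = null_low, ymax = null_high),
                             width = 0.2, colour = "grey40") +
      ggplot2::facet_wrap(~orientation) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "LDD potential") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "potential_intervals.png"), p5,
                    width = 8, height = 6, dpi = 120)
  }
  invisible(NULL)
}
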