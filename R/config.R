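#' Analysis configuration for the dispersal pipeline
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults reproduce the field-study settings: long-distance dispersal (LDD)
#' thresholds of 1000 m horizontal and 50 m vertical, 100,000 endpoint draws
#' per individual, 100,000 passage-time draws per retention-model cell,
#' 100,000 permutations for the species-potential null, a minimum of five
#' deer individuals per analysed plant species, contamination exclusion at
#' three control trays, and a dung dry-mass conversion of 0.13 g/ml.
#'
#' @param horizontal_threshold Horizontal LDD threshold in metres (> 0).
#' @param vertical_threshold Vertical LDD threshold in metres (> 0); applied
#'   symmetrically for upward (> threshold) and downward (< -threshold)
#'   displacement.
#' @param n_endpoint_draws Number of random deposition endpoints simulated
#'   per individual.
#' @param n_passage_draws_per_cell Passage-time draws per (trial, species)
#'   cell of the retention model.
#' @param n_permutations Permutations for the species-potential null model.
#' @param min_individuals_per_species Minimum number of distinct deer
#'   individuals that must disperse a plant species for it to enter the
#'   species-level analyses.
#' @param contamination_tray_min Minimum number of distinct control trays in
#'   which a species must appear to be excluded as a greenhouse contaminant.
#' @param dry_mass_per_ml Dung dry mass per unit volume, in g/ml.
#' @param rng_seed Optional integer seed recorded in run metadata and used by
#'   [run_pipeline()] to derive per-stage seeds.
#' @param max_redraws Maximum number of redraws of an (endpoint, passage
#'   time) pair whose implied start time falls before the trajectory begins,
#'   before the event is dropped.
#' @param start_rule How the dispersal start position is placed on the
#'   trajectory: `"interpolate"` (linear interpolation between bracketing
#'   fixes, the default) or `"nearest"` (snap to the nearest fix in time).
#' @param q_formula Seed-load arithmetic: `"per_gram"` (the default) divides
#'   seedling counts by dung dry mass (volume times `dry_mass_per_ml`),
#'   yielding seedlings per gram; `"literal"` divides by volume and then
#'   multiplies by `dry_mass_per_ml`, an alternative reading retained for
#'   auditing (its units are not seedlings per gram).
#' @param cell_aggregation How per-sample seed loads are aggregated to the
#'   (individual, month) cell: `"mean"` (default), `"sum"`, or `"pooled"`
#'   (total seedlings over total dry mass).
#' @param permute_positive_only If `TRUE`, the permutation null shuffles a
#'   species' loads only across cells where that species had positive load;
#'   the default `FALSE` permutes across all sampled cells.
#'
#' @return An object of class `dispersal_config`: a named list of the
#'   validated settings.
#' @examples
#' cfg <- dispersal_config(n_endpoint_draws = 1000)
#' cfg$horizontal_threshold
#' @export
dispersal_config <- function(horizontal_threshold = 1000,
                             vertical_threshold = 50,
                             n_endpoint_draws = 100000,
                             n_passage_draws_per_cell = 100000,
                             n_permutations = 100000,
                             min_individuals_per_species = 5,
                             contamination_tray_min = 3,
                             dry_mass_per_ml = 0.13,
                             rng_seed = NULL,
                             max_redraws = 100,
                             start_rule = c("interpolate", "nearest"),
                             q_formula = c("per_gram", "literal"),
                             cell_aggregation = c("mean", "sum", "pooled"),
                             permute_positive_only = FALSE) {
  start_rule <- match.arg(start_rule)
  q_formula <- match.arg(q_formula)
  cell_aggregation <- match.arg(cell_aggregation)
  stopifnot(
    is.numeric(horizontal_threshold), horizontal_threshold > 0,
    is.numeric(vertical_threshold), vertical_threshold > 0,
    n_endpoint_draws >= 1, n_passage_draws_per_cell >= 1,
    n_permutations >= 1, min_individuals_per_species >= 1,
    contamination_tray_min >= 1, dry_mass_per_ml > 0, max_redraws >= 0,
    is.logical(permute_positive_only), length(permute_positive_only) == 1L
  )
  if (!is.null(rng_seed)) {
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L,
              rng_seed == floor(rng_seed))
    rng_seed <- as.integer(rng_seed)
  }
  structure(list(
    horizontal_threshold = horizontal_threshold,
    vertical_threshold = vertical_threshold,
    n_endpoint_draws = as.integer(n_endpoint_draws),
    n_passage_draws_per_cell = as.integer(n_passage_draws_per_cell),
    n_permutations = as.integer(n_permutations),
    min_individuals_per_species = as.integer(min_individuals_per_species),
    contamination_tray_min = as.integer(contamination_tray_min),
    dry_mass_per_ml = dry_mass_per_ml,
    rng_seed = rng_seed,
    max_redraws = as.integer(max_redraws),
    start_rule = start_rule,
    q_formula = q_formula,
    cell_aggregation = cell_aggregation,
    permute_positive_only = permute_positive_only
  ), class = "dispersal_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file holds a flat key-value mapping whose keys mirror the arguments of
#' [dispersal_config()]; missing keys take the defaults, unknown keys are an
#' error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `dispersal_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(dispersal_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(dispersal_config, vals)
}

#' @export
print.dispersal_config <- function(x, ...) {
  cat("<dispersal_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
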