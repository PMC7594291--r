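#' Convert dung volume to dry mass
#'
#' Applies the study-calibrated dry-weight-to-volume ratio (default
#' 0.13 g/ml) to pellet-group volumes.
#'
#' @param volume_ml Numeric vector of volumes in ml (> 0).
#' @param cfg A [dispersal_config()].
#' @return Dry mass in grams.
#' @export
volume_to_dry_mass <- function(volume_ml, cfg = dispersal_config()) {
  if (any(!is.finite(volume_ml) | volume_ml <= 0)) {
    stop("volume_ml must be finite and > 0")
  }
  volume_ml * cfg$dry_mass_per_ml
}

#' Remove greenhouse contaminant species
#'
#' Species that emerge in at least `cfg$contamination_tray_min` distinct
#' dung-free control trays (default 3) are treated as substrate or airborne
#' contaminants and removed from every sample's seedling counts.
#'
#' @param seedlings Long seedling-count data frame
#'   (`sample_id`, `species`, `count`).
#' @param control_rows Control-tray data frame (`tray_id`, `species`).
#' @param cfg A [dispersal_config()].
#' @return List with `seedlings` (filtered data frame) and `excluded`
#'   (character vector of excluded species, possibly empty).
#' @export
exclude_contaminants <- function(seedlings, control_rows,
                                 cfg = dispersal_config()) {
  stopifnot(is.data.frame(seedlings), is.data.frame(control_rows))
  if (nrow(control_rows) == 0L) {
    return(list(seedlings = seedlings, excluded = character()))
  }
  u <- unique(control_rows[c("tray_id", "species")])
  tray_counts <- table(u$species)
  excluded <- sort(names(tray_counts)[tray_counts >= cfg$contamination_tray_min])
  out <- seedlings[!(seedlings$species %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  list(seedlings = out, excluded = excluded)
}

#' Build the seed-load table Q
#'
#' Computes the vector seed load Q — seedlings per gram of dung dry mass —
#' for every sample and species, and aggregates it to the (individual,
#' month) cell grain. Per sample, `q = count / (volume_ml * dry_mass_per_ml)`
#' (a literal count/volume*ratio variant is available via
#' `cfg$q_formula = "literal"` for auditing). Cell values are, by default,
#' the mean of per-sample q across the cell's samples, with samples lacking
#' a species contributing 0; `cfg$cell_aggregation` selects `"sum"` or
#' `"pooled"` (total seedlings / total dry mass) instead. Months come from
#' the sample collection date.
#'
#' @param dung Dung-sample data frame
#'   (`sample_id`, `animal_id`, `collection_date`, `volume_ml`).
#' @param seedlings Long, contaminant-filtered seedling-count data frame.
#' @param cfg A [dispersal_config()].
#' @return Object of class `seed_load_table`: list with
#'   \describe{
#'     \item{cells}{data frame `animal_id`, `month`, `species`, `q` — one
#'       row per species observed in a cell;}
#'     \item{totals}{data frame `animal_id`, `month`, `total_q`,
#'       `n_samples` — one row per sampled cell, including zero-load cells;}
#'     \item{samples}{per-sample data frame with `q_total`;}
#'     \item{species}{character vector of all species in the table.}
#'   }
#' @export
build_seed_load_table <- function(dung, seedlings, cfg = dispersal_config()) {
  stopifnot(is.data.frame(dung), is.data.frame(seedlings))
  unknown <- setdiff(seedlings$sample_id, dung$sample_id)
  if (length(unknown)) {
    stop("seedling counts reference unknown sample_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  dung <- dung[order(dung$sample_id), , drop = FALSE]
  dung$month <- month_label(dung$collection_date)
  dung$dry_mass_g <- volume_to_dry_mass(dung$volume_ml, cfg)

  sl <- seedlings
  m <- match(sl$sample_id, dung$sample_id)
  sl$animal_id <- dung$animal_id[m]
  sl$month <- dung$month[m]
  sl$q <- if (cfg$q_formula == "per_gram") {
    sl$count / dung$dry_mass_g[m]
  } else {
    sl$count / dung$volume_ml[m] * cfg$dry_mass_per_ml
  }
  sl$mass <- dung$dry_mass_g[m]

  cell_of <- function(a, mo) paste(a, as.character(mo), sep = "\r")
  dung$cell <- cell_of(dung$animal_id, dung$month)
  sl$cell <- cell_of(sl$animal_id, sl$month)
  n_samples <- tapply(dung$sample_id, dung$cell,
                      function(x) length(unique(x)))
  cell_mass <- tapply(dung$dry_mass_g, dung$cell, sum)

  if (nrow(sl)) {
    key <- interaction(sl$cell, sl$species, drop = TRUE, sep = "\n")
    q_sum <- tapply(sl$q, key, sum)
    count_sum <- tapply(sl$count, key, sum)
    cell_of_level <- vapply(strsplit(names(q_sum), "\n", fixed = TRUE),
                            `[`, character(1), 1L)
    q_cell <- switch(cfg$cell_aggregation,
      mean = q_sum / as.vector(n_samples[cell_of_level]),
      sum = q_sum,
      pooled = count_sum / as.vector(cell_mass[cell_of_level])
    )
    kparts <- strsplit(names(q_sum), "\n", fixed = TRUE)
    cell_id <- vapply(kparts, `[`, character(1), 1L)
    species <- vapply(kparts, `[`, character(1), 2L)
    aparts <- strsplit(cell_id, "\r", fixed = TRUE)
    cells <- data.frame(
      animal_id = vapply(aparts, `[`, character(1), 1L),
      month = factor(vapply(aparts, `[`, character(1), 2L),
                     levels = MONTH_LEVELS, ordered = TRUE),
      species = species,
      q = as.vector(q_cell)
    )
    cells <- cells[order(cells$species, cells$animal_id, cells$month), ]
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(animal_id = character(),
                        month = factor(character(), levels = MONTH_LEVELS,
                                       ordered = TRUE),
                        species = character(), q = numeric())
  }

  tot_parts <- strsplit(names(n_samples), "\r", fixed = TRUE)
  totals <- data.frame(
    animal_id = vapply(tot_parts, `[`, character(1), 1L),
    month = factor(vapply(tot_parts, `[`, character(1), 2L),
                   levels = MONTH_LEVELS, ordered = TRUE),
    n_samples = as.integer(n_samples)
  )
  tot_q <- tapply(cells$q, cell_of(cells$animal_id, cells$month), sum)
  totals$total_q <- as.vector(tot_q[match(names(n_samples), names(tot_q))])
  totals$total_q[is.na(totals$total_q)] <- 0
  totals <- totals[order(totals$animal_id, totals$month),
                   c("animal_id", "month", "total_q", "n_samples")]
  rownames(totals) <- NULL

  samples <- dung[c("sample_id", "animal_id", "month", "volume_ml",
                    "dry_mass_g")]
  st <- tapply(sl$q, sl$sample_id, sum)
  samples$q_total <- as.vector(st[match(samples$sample_id, names(st))])
  samples$q_total[is.na(samples$q_total)] <- 0
  rownames(samples) <- NULL

  structure(list(cells = cells, totals = totals, samples = samples,
                 species = sort(unique(cells$species))),
            class = "seed_load_table")
}

#' @export
print.seed_load_table <- function(x, ...) {
  cat(sprintf(paste0("<seed_load_table> %d species, %d sampled ",
                     "(individual, month) cells, %d samples\n"),
              length(x$species), nrow(x$totals), nrow(x$samples)))
  invisible(x)
}

#' Count dispersing individuals per species and apply the species filter
#'
#' For each plant species, counts the distinct deer individuals with any
#' positive seed load, and returns the subset of species dispersed by at
#' least `cfg$min_individuals_per_species` individuals (default 5) — the
#' species admitted to the species-level analyses.
#'
#' @param table A `seed_load_table`.
#' @param cfg A [dispersal_config()].
#' @return List with `counts` (named integer vector per species) and
#'   `filtered` (character vector of retained species).
#' @export
species_individual_counts <- function(table, cfg = dispersal_config()) {
  stopifnot(inherits(table, "seed_load_table"))
  pos <- table$cells[table$cells$q > 0, , drop = FALSE]
  if (nrow(pos) == 0L) {
    return(list(counts = integer(0), filtered = character(0)))
  }
  counts <- tapply(pos$animal_id, pos$species,
                   function(x) length(unique(x)))
  counts <- vapply(counts, as.integer, integer(1))
  list(counts = counts,
       filtered = sort(names(counts)[counts >=
                                       cfg$min_individuals_per_species]))
}

#' Seed loads of one species over all sampled cells
#'
#' Returns the species' load in every sampled (individual, month) cell,
#' zero-filled for cells where the species did not emerge — the support over
#' which the permutation null shuffles loads.
#'
#' @param table A `seed_load_table`.
#' @param species Species name.
#' @return Data frame `animal_id`, `month`, `q` covering every sampled cell.
#' @export
species_load_vector <- function(table, species) {
  stopifnot(inherits(table, "seed_load_table"))
  out <- table$totals[c("animal_id", "month")]
  sp <- table$cells[table$cells$species == species, , drop = FALSE]
  key_all <- paste(out$animal_id, as.character(out$month), sep = "\r")
  key_sp <- paste(sp$animal_id, as.character(sp$month), sep = "\r")
  out$q <- sp$q[match(key_all, key_sp)]
  out$q[is.na(out$q)] <- 0
  out
}
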