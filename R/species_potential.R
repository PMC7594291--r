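#' Seed-load-weighted LDD potential
#'
#' The LDD potential of a plant species in one orientation: the mean of the
#' per-seed LDD probabilities over (individual, month) cells, weighted by
#' the species' seed load in each cell —
#' `sum(q_c * ldd_c) / sum(q_c)` over shared cells.
#'
#' @param loads Seed loads q per cell (non-negative).
#' @param probs Per-cell LDD probabilities, same length and cell order.
#' @return The weighted potential in \[0, 1\], or `NA` if all loads are zero
#'   (undefined potential).
#' @export
weighted_potential <- function(loads, probs) {
  stopifnot(length(loads) == length(probs), all(loads >= 0))
  s <- sum(loads)
  if (s == 0) {
    warning("all seed loads are zero; potential undefined")
    return(NA_real_)
  }
  sum(loads * probs) / s
}

#' Permutation null for the weighted LDD potential
#'
#' Generates the null distribution of the weighted potential under random
#' association of seed load and LDD probability: each permutation shuffles
#' the species' load vector uniformly at random across the sampled cells
#' and recomputes the weighted potential. Returns the 2.5% and 97.5%
#' percentiles of the permutation distribution as a 95% interval. With
#' fewer than two distinct load values every permutation returns the same
#' potential; the interval collapses to the observed value and is flagged
#' degenerate.
#'
#' @param loads Seed loads per sampled cell.
#' @param probs Per-cell LDD probabilities, same cell order.
#' @param n_perm Number of permutations.
#' @return List with `null_low`, `null_high`, `degenerate`, `n_perm`,
#'   `null_mean`.
#' @export
permutation_null <- function(loads, probs, n_perm = 100000) {
  stopifnot(length(loads) == length(probs), length(loads) >= 2L,
            n_perm >= 1)
  s <- sum(loads)
  if (s == 0) stop("all loads zero; null undefined")
  if (length(unique(loads)) < 2L) {
    obs <- weighted_potential(loads, probs)
    return(list(null_low = obs, null_high = obs, degenerate = TRUE,
                n_perm = as.integer(n_perm), null_mean = obs))
  }
  n <- length(loads)
  vals <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    vals[i] <- sum(loads[sample.int(n)] * probs)
  }
  vals <- vals / s
  q <- empirical_quantiles(vals, c(0.025, 0.975))
  list(null_low = q[1], null_high = q[2], degenerate = FALSE,
       n_perm = as.integer(n_perm), null_mean = mean(vals))
}

#' Species-level LDD potential scan
#'
#' For every admitted plant species (dispersed by at least
#' `cfg$min_individuals_per_species` individuals) and every orientation,
#' computes the observed seed-load-weighted LDD potential, its permutation
#' null interval, and whether the observed value deviates from the
#' interval. Loads are taken over all sampled (individual, month) cells
#' (zero-load cells included) unless `cfg$permute_positive_only` restricts
#' the support to positive-load cells; cells without a simulated LDD value
#' are dropped.
#'
#' @param table A `seed_load_table`.
#' @param ldd An `ldd_table`.
#' @param cfg A [dispersal_config()]; `cfg$n_permutations` sets the null
#'   size.
#' @param species Optional character vector of species to scan; the default
#'   applies the minimum-individuals filter.
#' @return Data frame (class `potential_result`) with columns `species`,
#'   `orientation`, `observed`, `null_low`, `null_high`, `deviates`,
#'   `degenerate`, `n_permutations`, `n_cells`.
#' @export
species_potential_scan <- function(table, ldd, cfg = dispersal_config(),
                                   species = NULL) {
  stopifnot(inherits(table, "seed_load_table"))
  if (is.null(species)) {
    species <- species_individual_counts(table, cfg)$filtered
  }
  if (!length(species)) stop("no species pass the individual filter")
  orientations <- c("horizontal", "upward", "downward")
  rows <- vector("list", length(species) * length(orientations))
  k <- 0L
  for (sp in species) {
    lv <- species_load_vector(table, sp)
    key_l <- paste(lv$animal_id, as.character(lv$month))
    for (orient in orientations) {
      lt <- ldd[ldd$orientation == orient, , drop = FALSE]
      m <- match(key_l, paste(lt$animal_id, as.character(lt$month)))
      ok <- !is.na(m)
      loads <- lv$q[ok]
      probs <- lt$prob[m[ok]]
      if (cfg$permute_positive_only) {
        pos <- loads > 0
        loads <- loads[pos]
        probs <- probs[pos]
      }
      if (sum(loads) == 0 || length(loads) < 2L) {
        warning("species ", sp, " (", orient,
                "): no usable cells; skipped")
        next
      }
      obs <- weighted_potential(loads, probs)
      nul <- permutation_null(loads, probs, cfg$n_permutations)
      k <- k + 1L
      rows[[k]] <- data.frame(
        species = sp, orientation = orient, observed = obs,
        null_low = nul$null_low, null_high = nul$null_high,
        deviates = (obs < nul$null_low || obs > nul$null_high),
        degenerate = nul$degenerate,
        n_permutations = nul$n_perm, n_cells = length(loads)
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  class(out) <- c("potential_result", "data.frame")
  out
}

#' Binomial across-species meta-test
#'
#' Upper-tail binomial probability of observing at least `n_deviations`
#' deviations from 95% null intervals in `n_tests` independent species x
#' orientation tests, each with deviation probability `null_rate` under the
#' null: `P(X >= n_deviations)` with `X ~ Binomial(n_tests, null_rate)`.
#'
#' @param n_deviations Observed number of deviations.
#' @param n_tests Number of species x orientation tests.
#' @param null_rate Per-test deviation probability under the null
#'   (default 0.05 for 95% intervals).
#' @return List (class `meta_test_result`) with `n_deviations`, `n_tests`,
#'   `null_rate`, `p_value` (full precision) and `p_value_rounded` (3
#'   decimals).
#' @export
binomial_meta_test <- function(n_deviations, n_tests, null_rate = 0.05) {
  stopifnot(n_deviations >= 0, n_tests >= 1, n_deviations <= n_tests,
            null_rate > 0, null_rate < 1)
  p <- stats::pbinom(n_deviations - 1, n_tests, null_rate,
                     lower.tail = FALSE)
  structure(list(n_deviations = as.integer(n_deviations),
                 n_tests = as.integer(n_tests),
                 null_rate = null_rate,
                 p_value = p,
                 p_value_rounded = round(p, 3)),
            class = "meta_test_result")
}

#' @export
print.meta_test_result <- function(x, ...) {
  cat(sprintf(paste0("<meta_test_result> %d deviation(s) in %d tests ",
                     "(null rate %.3g): p = %.6g\n"),
              x$n_deviations, x$n_tests, x$null_rate, x$p_value))
  invisible(x)
}

#' Count deviations across a potential scan and run the meta-test
#'
#' Counts the species x orientation tests whose observed potential falls
#' outside the 95% permutation interval (ties with the bounds count as
#' non-deviations) and computes the across-species binomial p-value.
#'
#' @param potentials A `potential_result` from [species_potential_scan()].
#' @param null_rate Per-test deviation probability under the null.
#' @return A `meta_test_result` (see [binomial_meta_test()]).
#' @export
deviation_scan <- function(potentials, null_rate = 0.05) {
  stopifnot(is.data.frame(potentials),
            all(c("observed", "null_low", "null_high") %in%
                  names(potentials)))
  dev <- potentials$observed < potentials$null_low |
    potentials$observed > potentials$null_high
  binomial_meta_test(sum(dev), nrow(potentials), null_rate)
}

#' Direction of potential deviations
#'
#' Splits the deviations of a potential scan into those where the
#' non-random load/LDD association increased the LDD potential (observed
#' above the null interval) versus decreased it (below).
#'
#' @param potentials A `potential_result`.
#' @return List with `increased`, `decreased`, `n_deviations`.
#' @export
direction_of_deviation <- function(potentials) {
  up <- sum(potentials$observed > potentials$null_high)
  dn <- sum(potentials$observed < potentials$null_low)
  list(increased = up, decreased = dn, n_deviations = up + dn)
}
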