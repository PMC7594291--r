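# Interval upper bounds (hours) of the 14-interval gut-retention model for
# red deer; the first interval spans [0, 1) h.
PASSAGE_BOUNDS <- c(1, 3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54)

#' Build a gut-passage time model from interval probabilities
#'
#' Assembles the per-(trial, species) excretion probabilities over the
#' retention experiment's time intervals into a validated model of seed
#' passage time p. Each cell's probability vector must cover every interval
#' and sum to 1; sums deviating by at most `tol` are renormalised, larger
#' deviations are an error naming the cell.
#'
#' @param rows Data frame with columns `trial`, `species`,
#'   `interval_upper_h`, `prob`, as read by [read_passage_rows()].
#' @param bounds Ordered interval upper bounds in hours; defaults to the
#'   14-interval retention model (1, 3, 6, ..., 48, 54 h).
#' @param tol Tolerance on the per-cell probability sum (default 1e-6).
#' @return An object of class `passage_model`: a list with
#'   `interval_upper_bounds` and `cell_probs`, a cells-by-intervals matrix
#'   with rownames `"trial/species"`.
#' @export
build_passage_model <- function(rows, bounds = PASSAGE_BOUNDS, tol = 1e-6) {
  stopifnot(is.data.frame(rows),
            all(c("trial", "species", "interval_upper_h", "prob") %in%
                  names(rows)))
  if (is.unsorted(bounds, strictly = TRUE) || any(bounds <= 0)) {
    stop("interval bounds must be positive and strictly increasing")
  }
  cells <- unique(rows[c("trial", "species")])
  k <- length(bounds)
  probs <- matrix(NA_real_, nrow = nrow(cells), ncol = k,
                  dimnames = list(paste(cells$trial, cells$species, sep = "/"),
                                  paste0("upto_", bounds, "h")))
  for (i in seq_len(nrow(cells))) {
    cell <- rows[rows$trial == cells$trial[i] &
                   rows$species == cells$species[i], , drop = FALSE]
    idx <- match(bounds, cell$interval_upper_h)
    if (anyNA(idx)) {
      stop("cell (", cells$trial[i], ", ", cells$species[i],
           ") is missing interval(s): ",
           paste(bounds[is.na(idx)], collapse = ", "))
    }
    p <- cell$prob[idx]
    s <- sum(p)
    if (abs(s - 1) > tol) {
      stop("probabilities for cell (", cells$trial[i], ", ",
           cells$species[i], ") sum to ", format(s), ", not 1")
    }
    probs[i, ] <- p / s
  }
  structure(list(interval_upper_bounds = bounds, cell_probs = probs),
            class = "passage_model")
}

#' @export
print.passage_model <- function(x, ...) {
  cat(sprintf("<passage_model> %d cell(s) x %d intervals, support [0, %g] h\n",
              nrow(x$cell_probs), length(x$interval_upper_bounds),
              max(x$interval_upper_bounds)))
  invisible(x)
}

#' Simulate seed passage times from a retention model
#'
#' For every (trial, species) cell, draws `n_per_cell` passage times: an
#' excretion interval is drawn from the cell's probability vector, then a
#' time uniformly within that interval (the first interval spans from 0 to
#' the first bound). All cells are pooled with equal weight into one
#' empirical distribution of p, so the result has length
#' `n_per_cell * n_cells`. With the study's 6 trials x 6 species and 100,000
#' draws per cell this yields 3,600,000 values of p.
#'
#' @param model A `passage_model`.
#' @param n_per_cell Draws per cell (>= 1).
#' @param cell_weights Optional non-negative weights over cells for
#'   sensitivity analyses; the default pools all cells equally. Weights
#'   rescale each cell's share of the total draw budget
#'   (`n_per_cell * n_cells` draws overall).
#' @return Numeric vector of passage times in hours, pooled across cells.
#' @export
sample_passage_times <- function(model, n_per_cell, cell_weights = NULL) {
  stopifnot(inherits(model, "passage_model"), n_per_cell >= 1)
  bounds <- model$interval_upper_bounds
  lower <- c(0, bounds[-length(bounds)])
  n_cells <- nrow(model$cell_probs)
  if (is.null(cell_weights)) {
    per_cell <- rep(as.integer(n_per_cell), n_cells)
  } else {
    stopifnot(length(cell_weights) == n_cells, all(cell_weights >= 0),
              sum(cell_weights) > 0)
    w <- cell_weights / sum(cell_weights)
    per_cell <- round(w * n_per_cell * n_cells)
  }
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (per_cell[i] == 0L) {
      out[[i]] <- numeric(0)
      next
    }
    iv <- sample.int(length(bounds), per_cell[i], replace = TRUE,
                     prob = model$cell_probs[i, ])
    out[[i]] <- stats::runif(per_cell[i], lower[iv], bounds[iv])
  }
  unlist(out, use.names = FALSE)
}

#' Empirical quantiles of a passage-time (or any) sample
#'
#' Linear-interpolation (type 7) quantiles, monotone in the requested
#' probabilities.
#'
#' @param samples Non-empty numeric vector.
#' @param qs Probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, one per element of `qs`.
#' @export
empirical_quantiles <- function(samples, qs) {
  if (length(samples) == 0L) stop("samples must be non-empty")
  stopifnot(all(qs >= 0 & qs <= 1))
  unname(stats::quantile(samples, probs = qs, type = 7, names = FALSE))
}

# Mean of the distribution a passage model implies under uniform
# within-interval placement: mixture of interval midpoints.
passage_model_mean <- function(model, cell_weights = NULL) {
  bounds <- model$interval_upper_bounds
  mid <- (c(0, bounds[-length(bounds)]) + bounds) / 2
  cell_means <- as.vector(model$cell_probs %*% mid)
  if (is.null(cell_weights)) {
    mean(cell_means)
  } else {
    sum(cell_means * cell_weights) / sum(cell_weights)
  }
}
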