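#' Logit / log transforms with boundary smoothing
#'
#' Prepares probabilities and seed loads for linear modelling. The logit is
#' undefined at 0 and 1, which occur at finite simulation draws, so boundary
#' values are smoothed empirically before transforming:
#' `p' = (p * (n - 1) + 0.5) / n`, with `n` the number of events behind each
#' probability. The log transform handles zero loads by adding half the
#' smallest positive value in the vector. Optionally the transformed values
#' are z-standardised (mean 0, sd 1).
#'
#' @param values Numeric vector: probabilities in \[0, 1\] for `"logit"`,
#'   non-negative loads for `"log"`.
#' @param kind `"logit"` or `"log"`.
#' @param standardize Z-score the transformed values?
#' @param n For `"logit"`: events per cell (scalar or vector), required if
#'   any value is exactly 0 or 1.
#' @return Transformed numeric vector.
#' @export
transform_values <- function(values, kind = c("logit", "log"),
                             standardize = FALSE, n = NULL) {
  kind <- match.arg(kind)
  x <- values
  if (kind == "logit") {
    stopifnot(all(x >= 0 & x <= 1))
    at_edge <- x == 0 | x == 1
    if (any(at_edge)) {
      if (is.null(n)) {
        stop("probabilities of exactly 0 or 1 require n (events per cell) ",
             "for boundary smoothing")
      }
      nn <- rep_len(n, length(x))
      x[at_edge] <- (x[at_edge] * (nn[at_edge] - 1) + 0.5) / nn[at_edge]
    }
    out <- log(x / (1 - x))
  } else {
    stopifnot(all(x >= 0))
    if (any(x == 0)) {
      pos <- x[x > 0]
      if (!length(pos)) stop("cannot log-transform an all-zero vector")
      x <- x + min(pos) / 2
    }
    out <- log(x)
  }
  if (standardize) {
    s <- stats::sd(out)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize values with zero variance")
    }
    out <- (out - mean(out)) / s
  }
  out
}

#' One-way variance partitioning
#'
#' Ordinary least-squares one-way ANOVA of a response on a single grouping
#' factor (deer individual or sampling month): the fraction of variance the
#' factor explains (R^2 = SS_factor / SS_total), the F statistic and its
#' degrees of freedom, and the p-value from the F distribution. Factor
#' levels with no observations are dropped with a warning.
#'
#' @param response Numeric vector of per-cell (or per-sample) values.
#' @param factor_labels Grouping labels, same length as `response`.
#' @param factor_name Label for the output (e.g. `"individual"`, `"month"`).
#' @return One-row data frame (class `anova_partition`) with `factor`,
#'   `r_squared`, `f_statistic`, `df_factor`, `df_residual`, `p_value`, `n`.
#' @export
one_way_partition <- function(response, factor_labels,
                              factor_name = "factor") {
  stopifnot(length(response) == length(factor_labels))
  f <- factor(factor_labels)
  if (any(table(f) == 0L)) {
    warning("dropping empty factor level(s)")
    f <- droplevels(f)
  }
  if (nlevels(f) < 2L) stop("need at least 2 factor levels")
  if (length(response) - nlevels(f) < 1L) stop("no residual degrees of freedom")
  fit <- stats::lm(response ~ f)
  a <- stats::anova(fit)
  ss_f <- a$`Sum Sq`[1]
  ss_r <- a$`Sum Sq`[2]
  out <- data.frame(
    factor = factor_name,
    r_squared = ss_f / (ss_f + ss_r),
    f_statistic = a$`F value`[1],
    df_factor = a$Df[1],
    df_residual = a$Df[2],
    p_value = a$`Pr(>F)`[1],
    n = length(response)
  )
  class(out) <- c("anova_partition", "data.frame")
  out
}

#' Two-factor additive variance partitioning
#'
#' Additive two-factor least-squares fit (`response ~ A + B`), reporting the
#' combined R^2 and the per-factor sequential sums-of-squares shares in both
#' fitting orders (in unbalanced designs the shares depend on the order, so
#' both are reported). Perfectly confounded factors are an error.
#'
#' @param response Numeric vector.
#' @param factor_a,factor_b Grouping labels.
#' @param names_ab Length-2 character: names for the two factors.
#' @return List with `combined_r_squared`, `n`, and `shares`, a data frame
#'   with the sequential R^2 share of each factor in each order.
#' @export
joint_partition <- function(response, factor_a, factor_b,
                            names_ab = c("A", "B")) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(response) == length(fa), length(fa) == length(fb),
            nlevels(fa) >= 2L, nlevels(fb) >= 2L)
  fit <- stats::lm(response ~ fa + fb)
  if (anyNA(stats::coef(fit))) {
    stop("factors ", names_ab[1], " and ", names_ab[2],
         " are aliased (confounded); joint fit is not identifiable")
  }
  ss_total <- sum((response - mean(response))^2)
  seq_shares <- function(first, second) {
    a <- stats::anova(stats::lm(response ~ first + second))
    a$`Sum Sq`[1:2] / ss_total
  }
  ab <- seq_shares(fa, fb)
  ba <- seq_shares(fb, fa)
  shares <- data.frame(
    order = c("a_first", "a_first", "b_first", "b_first"),
    factor = c(names_ab, rev(names_ab)),
    r_squared_share = c(ab, ba)
  )
  list(combined_r_squared = sum(ab), n = length(response), shares = shares)
}

#' Regress seed load on LDD probability
#'
#' Simple least-squares regression of log-transformed (and z-standardised)
#' seed load on logit-transformed (and z-standardised) LDD probability —
#' the test of whether more mobile individuals carry systematically larger
#' or smaller seed loads.
#'
#' @param loads Seed loads (response; log-transformed internally).
#' @param ldd_probs LDD probabilities (predictor; logit-transformed
#'   internally).
#' @param orientation Label recorded in the result.
#' @param n_events Events behind each probability, for boundary smoothing.
#' @return One-row data frame (class `ldd_regression`) with `orientation`,
#'   `slope`, `intercept`, `f_statistic`, `df_model`, `df_residual`,
#'   `p_value`, `r_squared`, `n`.
#' @export
regress_load_on_ldd <- function(loads, ldd_probs,
                                orientation = "horizontal",
                                n_events = NULL) {
  stopifnot(length(loads) == length(ldd_probs), length(loads) >= 3L)
  # constant response is legitimate (slope 0); constant predictor is not
  y <- transform_values(loads, "log")
  sy <- stats::sd(y)
  y <- if (sy > 0) (y - mean(y)) / sy else y - mean(y)
  x <- transform_values(ldd_probs, "logit", standardize = TRUE,
                        n = n_events)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  fstat <- s$fstatistic
  if (is.null(fstat)) fstat <- c(0, 1, fit$df.residual)
  out <- data.frame(
    orientation = orientation,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    f_statistic = unname(fstat[1]),
    df_model = unname(fstat[2]),
    df_residual = unname(fstat[3]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    r_squared = if (is.finite(s$r.squared)) s$r.squared else 0,
    n = length(y)
  )
  class(out) <- c("ldd_regression", "data.frame")
  out
}

#' Species-by-LDD interaction test
#'
#' Tests whether the relationship between seed load and LDD probability
#' differs between plant species: a full linear model
#' `log(load) ~ species + logit(LDD) + species:logit(LDD)` is compared to
#' the additive reduced model by an F test on the interaction term, and the
#' interaction's partial R^2, `(SS_reduced - SS_full) / SS_reduced` on
#' residual sums of squares, is reported. Species with fewer than two cells
#' are dropped with a warning. A saturated full model (zero residual sum of
#' squares) yields an infinite F sentinel.
#'
#' @param load_cells Data frame `animal_id`, `month`, `species`, `q` —
#'   per-cell loads of the analysed species (see [build_seed_load_table()]).
#' @param ldd An `ldd_table` from [ldd_probability_table()].
#' @param orientation `"horizontal"`, `"upward"` or `"downward"`.
#' @return One-row data frame with `orientation`, `partial_r_squared`,
#'   `f_statistic`, `df_interaction`, `df_residual`, `p_value`, `n_species`,
#'   `n`.
#' @export
species_interaction_model <- function(load_cells, ldd,
                                      orientation = "horizontal") {
  stopifnot(is.data.frame(load_cells),
            all(c("animal_id", "month", "species", "q") %in%
                  names(load_cells)))
  lt <- ldd[ldd$orientation == orientation, , drop = FALSE]
  key_l <- paste(load_cells$animal_id, as.character(load_cells$month))
  key_p <- paste(lt$animal_id, as.character(lt$month))
  m <- match(key_l, key_p)
  d <- load_cells[!is.na(m), , drop = FALSE]
  d$prob <- lt$prob[m[!is.na(m)]]
  d$n_events <- lt$n_events[m[!is.na(m)]]
  tab <- table(d$species)
  thin <- names(tab)[tab < 2L]
  if (length(thin)) {
    warning("dropping species with < 2 cells: ", paste(thin, collapse = ", "))
    d <- d[!(d$species %in% thin), , drop = FALSE]
  }
  if (length(unique(d$species)) < 2L) {
    stop("need at least 2 species with >= 2 cells each")
  }
  d$y <- transform_values(d$q, "log", standardize = TRUE)
  d$x <- transform_values(d$prob, "logit", standardize = TRUE,
                          n = d$n_events)
  sp <- factor(d$species)
  full <- stats::lm(y ~ sp + x + sp:x, data = d)
  reduced <- stats::lm(y ~ sp + x, data = d)
  ss_full <- sum(stats::resid(full)^2)
  ss_red <- sum(stats::resid(reduced)^2)
  df_int <- reduced$df.residual - full$df.residual
  df_res <- full$df.residual
  if (ss_full <= .Machine$double.eps * ss_red || df_res == 0L) {
    fstat <- Inf
    p <- 0
  } else {
    fstat <- ((ss_red - ss_full) / df_int) / (ss_full / df_res)
    p <- stats::pf(fstat, df_int, df_res, lower.tail = FALSE)
  }
  data.frame(
    orientation = orientation,
    partial_r_squared = if (ss_red > 0) (ss_red - ss_full) / ss_red else 0,
    f_statistic = fstat,
    df_interaction = df_int,
    df_residual = df_res,
    p_value = p,
    n_species = length(unique(d$species)),
    n = nrow(d)
  )
}
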