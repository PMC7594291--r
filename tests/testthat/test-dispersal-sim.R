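test_that("sample_endpoints draws uniformly with replacement from the fixes", {
  tr <- make_linear_traj(10)
  set.seed(1)
  ep <- sample_endpoints(tr, 20000)
  # support check: every endpoint is one of the fixes
  expect_true(all(ep$easting %in% tr$easting))
  # uniformity over the 10 fixes: chi-squared GOF not rejected at 0.01
  counts <- table(factor(ep$easting, levels = tr$easting))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)

  # seeded single draw is reproducible
  set.seed(9)
  a <- sample_endpoints(tr, 1)
  set.seed(9)
  b <- sample_endpoints(tr, 1)
  expect_identical(a, b)

  expect_error(sample_endpoints(make_linear_traj(1), 5), "at least 2")
})

test_that("locate_start interpolates linearly and flags unresolved times", {
  # fixes at t=0h (0,0,600) and t=1h (1000,0,700)
  tr <- make_traj(c(0, 1), c(0, 1000), c(0, 0), c(600, 700))
  mid <- locate_start(tr, t0_utc + 0.5 * 3600)
  expect_equal(mid$easting, 500)
  expect_equal(mid$northing, 0)
  expect_equal(mid$elevation, 650)
  expect_true(mid$resolved)

  # exact fix hit returns the fix
  hit <- locate_start(tr, tr$timestamp[2])
  expect_equal(hit$easting, 1000)
  expect_equal(hit$elevation, 700)

  # before the first fix: unresolved, not an error
  early <- locate_start(tr, t0_utc - 3600)
  expect_false(early$resolved)
  expect_true(is.na(early$easting))

  # nearest-fix rule snaps to the closer fix in time
  near <- locate_start(tr, t0_utc + 0.8 * 3600, rule = "nearest")
  expect_equal(near$easting, 1000)
  near2 <- locate_start(tr, t0_utc + 0.2 * 3600, rule = "nearest")
  expect_equal(near2$easting, 0)
})

test_that("simulate_events reproduces the d = v * p closed form", {
  cfg <- dispersal_config(n_endpoint_draws = 2000, max_redraws = 50)

  # stationary trajectory: all displacements zero
  tr0 <- make_traj(0:20, rep(5, 21), rep(7, 21), rep(640, 21))
  set.seed(2)
  ev0 <- simulate_events(tr0, p_samples = c(1, 2, 3), cfg)
  expect_true(all(ev0$d_horiz_m == 0))
  expect_true(all(ev0$d_vert_m == 0))

  # straight east-bound walk at 1000 m/h, degenerate p = 2 h
  tr <- make_linear_traj(50, speed = 1000)
  set.seed(3)
  ev <- simulate_events(tr, p_samples = 2, cfg)
  expect_true(all(ev$d_horiz_m == 2000))
  expect_true(all(ev$passage_h == 2))

  # constant climb 10 m/h with p = 6 h: every vertical displacement +60 m
  trc <- make_linear_traj(50, speed = 100, climb = 10)
  set.seed(4)
  evc <- simulate_events(trc, p_samples = 6, cfg)
  expect_true(all(abs(evc$d_vert_m - 60) < 1e-9))

  # passage time longer than the whole trajectory: nothing resolvable
  short <- make_linear_traj(3)
  expect_error(
    suppressWarnings(simulate_events(short, p_samples = 100, cfg)),
    "dropped")
})

test_that("dropped events are redrawn and the dropped fraction is reported", {
  tr <- make_linear_traj(6, speed = 1000)
  cfg <- dispersal_config(n_endpoint_draws = 500, max_redraws = 0)
  set.seed(5)
  # p = 3 h resolves only endpoints at t >= 3 h (3 of 6 fixes)
  ev <- simulate_events(tr, p_samples = 3, cfg)
  expect_gt(attr(ev, "dropped_fraction"), 0.2)
  expect_equal(attr(ev, "n_attempted"), 500)
  # with redraws allowed, everything resolves
  cfg2 <- dispersal_config(n_endpoint_draws = 500, max_redraws = 100)
  set.seed(5)
  ev2 <- simulate_events(tr, p_samples = 3, cfg2)
  expect_equal(attr(ev2, "dropped_fraction"), 0)
  expect_equal(nrow(ev2), 500)
})

test_that("ldd_probability_table computes per-cell threshold fractions", {
  ev <- data.frame(animal_id = "a", month = factor("Jun", month.abb),
                   d_horiz_m = c(500, 1500, 800, 2000),
                   d_vert_m = c(0, 10, -20, 30))
  cfg <- dispersal_config()
  tab <- ldd_probability_table(ev, cfg)
  expect_equal(tab$prob[tab$orientation == "horizontal"], 0.5)
  # all vertical displacements within (-50, 50): upward = downward = 0
  expect_equal(tab$prob[tab$orientation == "upward"], 0)
  expect_equal(tab$prob[tab$orientation == "downward"], 0)
  expect_equal(unique(tab$n_events), 4)

  # threshold ~0 with all positive horizontal displacements: probability 1
  cfg0 <- dispersal_config(horizontal_threshold = 1e-9)
  tab0 <- ldd_probability_table(ev[ev$d_horiz_m > 0, ], cfg0)
  expect_equal(tab0$prob[tab0$orientation == "horizontal"], 1)
})

test_that("LDD probability is non-increasing in the threshold", {
  tr <- make_linear_traj(80, speed = 400, climb = 5, id = "mono")
  set.seed(6)
  ev <- simulate_events(tr, p_samples = runif(200, 0, 10),
                        dispersal_config(n_endpoint_draws = 3000))
  probs <- vapply(c(200, 500, 1000, 2000, 4000), function(th) {
    tab <- ldd_probability_table(ev, dispersal_config(
      horizontal_threshold = th))
    mean(tab$prob[tab$orientation == "horizontal"])
  }, numeric(1))
  expect_false(is.unsorted(rev(probs)))

  # upward + downward probabilities never exceed 1 per cell
  tab <- ldd_probability_table(ev, dispersal_config(vertical_threshold = 10))
  wide <- split(tab$prob, tab$orientation)
  expect_true(all(wide$upward + wide$downward <= 1))
})

test_that("exhaustive simulation equals brute-force endpoint x p enumeration", {
  set.seed(7)
  n_fix <- 40
  h <- 0:(n_fix - 1)
  tr <- make_traj(h, easting = cumsum(rnorm(n_fix, 0, 400)),
                  northing = cumsum(rnorm(n_fix, 0, 400)),
                  elevation = 700 + cumsum(rnorm(n_fix, 0, 30)),
                  id = "oracle")
  p_set <- c(0.5, 2, 7.25, 13, 20)
  cfg <- dispersal_config(horizontal_threshold = 600,
                          vertical_threshold = 25)

  # independent brute force: loop over every (fix, p) pair, interpolate the
  # start with stats::approx, drop pairs starting before the trajectory
  d_h <- d_v <- c()
  for (i in seq_len(n_fix)) {
    for (p in p_set) {
      t_start <- h[i] - p
      if (t_start < 0) next
      se <- approx(h, tr$easting, xout = t_start)$y
      sn <- approx(h, tr$northing, xout = t_start)$y
      sz <- approx(h, tr$elevation, xout = t_start)$y
      d_h <- c(d_h, sqrt((tr$easting[i] - se)^2 + (tr$northing[i] - sn)^2))
      d_v <- c(d_v, tr$elevation[i] - sz)
    }
  }
  brute <- c(horizontal = mean(d_h > cfg$horizontal_threshold),
             upward = mean(d_v > cfg$vertical_threshold),
             downward = mean(d_v < -cfg$vertical_threshold))

  ev <- simulate_events(tr, p_samples = p_set, cfg, exhaustive = TRUE)
  expect_equal(nrow(ev), length(d_h))
  tab <- ldd_probability_table(ev, cfg)
  sim <- vapply(c("horizontal", "upward", "downward"), function(o) {
    sub <- tab[tab$orientation == o, ]
    sum(sub$prob * sub$n_events) / sum(sub$n_events)
  }, numeric(1))
  expect_identical(unname(sim), unname(brute))
})

test_that("kernel_summary pools events and reports quantiles", {
  ev1 <- data.frame(animal_id = "a", month = factor("Jul", month.abb),
                    d_horiz_m = 737, d_vert_m = -3)
  k1 <- kernel_summary(ev1)
  expect_equal(k1$mean_horizontal_m, 737)
  expect_equal(k1$q01_horizontal_m, 737)
  expect_equal(k1$q99_horizontal_m, 737)

  ev2 <- data.frame(animal_id = "a", month = factor("Jul", month.abb),
                    d_horiz_m = c(0, 2000), d_vert_m = c(0, 0))
  expect_equal(kernel_summary(ev2)$frac_horizontal_ldd, 0.5)
  expect_error(kernel_summary(ev2[0, ]), "non-empty")
})
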