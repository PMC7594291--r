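# Shared in-code fixtures: toy trajectories and passage tables small enough
# to check against closed forms or brute-force enumeration.

t0_utc <- as.POSIXct("2018-06-01 00:00:00", tz = "UTC")

make_traj <- function(times_h, easting, northing, elevation,
                      id = "deer_toy") {
  traj <- data.frame(timestamp = t0_utc + times_h * 3600,
                     easting = easting, northing = northing,
                     elevation = elevation)
  attr(traj, "animal_id") <- id
  class(traj) <- c("deer_trajectory", "data.frame")
  traj
}

# straight east-bound walk at `speed` m/h with constant climb rate m/h
make_linear_traj <- function(n_fixes, speed = 1000, climb = 0,
                             id = "deer_lin") {
  h <- seq_len(n_fixes) - 1
  make_traj(h, easting = speed * h, northing = rep(0, n_fixes),
            elevation = 600 + climb * h, id = id)
}

passage_rows <- function(probs, trial = "t1", species = "sp1",
                         bounds = c(1, 3, 6, 9, 12, 15, 18, 21, 24, 30,
                                    36, 42, 48, 54)) {
  data.frame(trial = trial, species = species, interval_upper_h = bounds,
             prob = probs)
}

point_mass_rows <- function(interval_idx, ...) {
  p <- rep(0, 14)
  p[interval_idx] <- 1
  passage_rows(p, ...)
}

write_fixes_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# minimal valid fixes data frame in the file dialect
fixes_dialect <- function(n = 3, animal = "a1", quality = TRUE) {
  data.frame(animal_id = rep_len(animal, n),
             timestamp = format(t0_utc + (seq_len(n) - 1) * 3600,
                                "%Y-%m-%dT%H:%M:%S"),
             easting_m = 1000 + seq_len(n), northing_m = 2000 + seq_len(n),
             elevation_m = 600 + seq_len(n),
             quality_ok = rep_len(quality, n))
}
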