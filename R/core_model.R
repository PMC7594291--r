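#' @keywords internal
"_PACKAGE"

# Month labels are calendar months in UTC, kept as an ordered factor so that
# tables and figures sort May before December rather than alphabetically.
MONTH_LEVELS <- month.abb

month_label <- function(t) {
  if (inherits(t, "Date")) {
    m <- as.POSIXlt(t)$mon + 1L
  } else {
    m <- as.POSIXlt(t, tz = "UTC")$mon + 1L
  }
  factor(month.abb[m], levels = MONTH_LEVELS, ordered = TRUE)
}

# NA-safe ISO-8601 parsing: unparseable entries become NA for per-row
# error reporting instead of aborting the whole read
parse_utc <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  res <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in formats) {
    need <- which(is.na(res))
    if (!length(need)) break
    res[need] <- as.POSIXct(strptime(x[need], f, tz = "UTC"))
  }
  res
}

#' Read a GPS fix table
#'
#' Reads the fixes CSV dialect
#' (`animal_id,timestamp,easting_m,northing_m,elevation_m,quality_ok`) into a
#' validated data frame. Coordinates must already be planar metres (UTM-style
#' easting/northing); no geodetic reprojection is performed. Timestamps are
#' parsed as UTC instants. Rows with unparseable timestamps or non-finite
#' coordinates abort with an error naming the offending file lines.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `animal_id` (character), `timestamp`
#'   (POSIXct, UTC), `easting`, `northing`, `elevation` (numeric metres) and
#'   `quality_ok` (logical).
#' @export
read_gps_fixes <- function(path) {
  need <- c("animal_id", "timestamp", "easting_m", "northing_m",
            "elevation_m", "quality_ok")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("fixes file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("fixes file ", path, " contains a header only; returning 0 fixes")
    return(data.frame(animal_id = character(), timestamp = parse_utc(character()),
                      easting = numeric(), northing = numeric(),
                      elevation = numeric(), quality_ok = logical()))
  }
  lines <- seq_len(nrow(raw)) + 1L  # file line numbers (header is line 1)
  ts <- suppressWarnings(parse_utc(raw$timestamp))
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop("unparseable timestamp in ", path, " at line(s) ",
         paste(lines[bad_ts], collapse = ", "))
  }
  num <- lapply(raw[c("easting_m", "northing_m", "elevation_m")],
                function(x) suppressWarnings(as.numeric(x)))
  bad_num <- which(!is.finite(num$easting_m) | !is.finite(num$northing_m) |
                     !is.finite(num$elevation_m))
  if (length(bad_num)) {
    stop("non-finite coordinate/elevation in ", path, " at line(s) ",
         paste(lines[bad_num], collapse = ", "))
  }
  q <- tolower(trimws(raw$quality_ok)) %in% c("true", "t", "1", "yes")
  data.frame(animal_id = raw$animal_id, timestamp = ts,
             easting = num$easting_m, northing = num$northing_m,
             elevation = num$elevation_m, quality_ok = q)
}

#' Build per-animal trajectories from a fix table
#'
#' Applies the fix-quality screen (only fixes flagged `quality_ok`, i.e.
#' accuracy of 5 m or less / 3D validated, are kept), splits the table by
#' individual, time-sorts each trajectory, collapses duplicate timestamps to
#' their first occurrence, and drops individuals with fewer than two
#' surviving fixes. Degraded inputs produce warnings, never errors.
#'
#' @param fixes A fix table as returned by [read_gps_fixes()].
#' @return A named list of trajectories, one per surviving individual; each
#'   is a data frame (class `deer_trajectory`) with columns `timestamp`,
#'   `easting`, `northing`, `elevation`, strictly increasing in time, and an
#'   `animal_id` attribute.
#' @export
filter_and_split <- function(fixes) {
  stopifnot(is.data.frame(fixes))
  keep <- fixes[fixes$quality_ok, , drop = FALSE]
  n_drop <- nrow(fixes) - nrow(keep)
  if (n_drop > 0L) {
    message(n_drop, " fix(es) removed by the quality screen")
  }
  if (nrow(keep) == 0L) {
    warning("no fixes survive the quality screen")
    return(structure(list(), names = character()))
  }
  out <- list()
  for (id in unique(keep$animal_id)) {
    tr <- keep[keep$animal_id == id, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    dup <- duplicated(tr$timestamp)
    if (any(dup)) {
      message(sum(dup), " duplicate timestamp(s) collapsed for animal ", id)
      tr <- tr[!dup, , drop = FALSE]
    }
    if (nrow(tr) < 2L) {
      warning("animal ", id, " has fewer than 2 usable fixes; excluded")
      next
    }
    traj <- tr[c("timestamp", "easting", "northing", "elevation")]
    rownames(traj) <- NULL
    attr(traj, "animal_id") <- id
    class(traj) <- c("deer_trajectory", "data.frame")
    out[[id]] <- traj
  }
  out
}

#' @export
print.deer_trajectory <- function(x, ...) {
  cat(sprintf("<deer_trajectory> animal %s: %d fixes, %s .. %s\n",
              attr(x, "animal_id"), nrow(x),
              format(x$timestamp[1], tz = "UTC"),
              format(x$timestamp[nrow(x)], tz = "UTC")))
  invisible(x)
}

#' Write a result table to CSV
#'
#' Writes any of the pipeline's tabular results (fix tables, dispersal
#' events, LDD tables, seed-load tables, potential results) with a
#' deterministic column order and no row names, so that writing and reading
#' back yields an identical table (text fields bit-exact, numerics to full
#' double precision).
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- format(out[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    } else if (is.factor(out[[nm]])) {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a dung-sample table
#'
#' CSV dialect: `sample_id,animal_id,collection_date,volume_ml`. Volumes must
#' be strictly positive.
#'
#' @param path CSV path.
#' @return Data frame with `sample_id`, `animal_id` (character),
#'   `collection_date` (Date) and `volume_ml` (numeric).
#' @export
read_dung_samples <- function(path) {
  need <- c("sample_id", "animal_id", "collection_date", "volume_ml")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("dung file missing column(s): ", paste(missing, collapse = ", "))
  }
  d$sample_id <- as.character(d$sample_id)
  d$animal_id <- as.character(d$animal_id)
  d$collection_date <- as.Date(d$collection_date)
  if (anyNA(d$collection_date)) stop("unparseable collection_date in ", path)
  if (any(!is.finite(d$volume_ml) | d$volume_ml <= 0)) {
    stop("volume_ml must be finite and > 0 in ", path)
  }
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in ", path)
  d
}

#' Read a seedling-count table
#'
#' Long CSV dialect: `sample_id,species,count`, one row per species emerging
#' from a sample; counts are non-negative integers.
#'
#' @param path CSV path.
#' @return Data frame with `sample_id`, `species` (character), `count`
#'   (integer).
#' @export
read_seedling_counts <- function(path) {
  need <- c("sample_id", "species", "count")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("seedling file missing column(s): ", paste(missing, collapse = ", "))
  }
  d$sample_id <- as.character(d$sample_id)
  d$species <- as.character(d$species)
  if (any(!is.finite(d$count) | d$count < 0 | d$count != floor(d$count))) {
    stop("seedling counts must be non-negative integers in ", path)
  }
  d$count <- as.integer(d$count)
  d
}

#' Read a control-tray species list
#'
#' CSV dialect: `tray_id,species`, one row per species observed in a
#' dung-free control tray; used by the contamination filter.
#'
#' @param path CSV path.
#' @return Data frame with `tray_id`, `species` (character).
#' @export
read_control_trays <- function(path) {
  need <- c("tray_id", "species")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("control file missing column(s): ", paste(missing, collapse = ", "))
  }
  d$tray_id <- as.character(d$tray_id)
  d$species <- as.character(d$species)
  d
}

#' Read a gut-passage interval-probability table
#'
#' CSV dialect: `trial,species,interval_upper_h,prob` — for each (trial,
#' species) cell of the retention experiment, the probability that a seed is
#' excreted in each time interval, identified by the interval's upper bound
#' in hours.
#'
#' @param path CSV path.
#' @return Data frame with `trial`, `species` (character),
#'   `interval_upper_h`, `prob` (numeric).
#' @export
read_passage_rows <- function(path) {
  need <- c("trial", "species", "interval_upper_h", "prob")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("passage file missing column(s): ", paste(missing, collapse = ", "))
  }
  d$trial <- as.character(d$trial)
  d$species <- as.character(d$species)
  if (any(!is.finite(d$interval_upper_h) | d$interval_upper_h <= 0)) {
    stop("interval_upper_h must be finite and > 0 in ", path)
  }
  if (any(!is.finite(d$prob) | d$prob < 0)) {
    stop("prob must be finite and >= 0 in ", path)
  }
  d
}

#' Write a JSON run-metadata sidecar
#'
#' @param meta A named list (config echo, seeds, row counts, versions, ...).
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
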