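#' Read a Geolife-style PLT trajectory file
#'
#' Parses one PLT file into a tibble of track points. The PLT dialect is the
#' public Geolife release: six header lines, then one comma-separated record
#' per line with fields latitude, longitude, a constant `0`, altitude in feet
#' (`-777` when missing), fractional days since 1899-12-30, a date string and
#' a time string. The timestamp is taken from the date and time strings,
#' interpreted as UTC. Malformed lines (wrong field count, non-numeric or
#' out-of-range coordinates, unparseable clock strings) are skipped and the
#' skip count reported via a message.
#'
#' @param path Path to a `.plt` file.
#' @param user_id,file_id Identifiers attached to every point; default to the
#'   grandparent directory name (the Geolife user folder) and the file name.
#' @param quiet If `TRUE`, suppress the skipped-line message.
#'
#' @return A tibble with columns `user_id`, `file_id`, `latitude`,
#'   `longitude`, `altitude` (metres, `NA` when the sentinel `-777` was
#'   recorded) and `timestamp` (POSIXct, UTC), ordered chronologically.
#' @export
#' @examples
#' plan <- itinerary_plan(n_staypoints = 2)
#' traj <- generate_trajectory(plan, seed = 1)$trajectory
#' f <- tempfile(fileext = ".plt")
#' write_plt(traj, f)
#' read_plt(f, user_id = "u1", file_id = "demo")
read_plt <- function(path, user_id = NULL, file_id = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("PLT file does not exist: ", path), class = "mobiscale_io_error")
  }
  if (is.null(user_id)) user_id <- basename(dirname(dirname(path)))
  if (is.null(file_id)) file_id <- basename(path)

  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 6L) lines <- lines[-(1:6)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]

  fields <- strsplit(lines, ",", fixed = TRUE)
  ok_len <- lengths(fields) >= 7L
  lat <- lon <- alt <- rep(NA_real_, length(fields))
  stamp <- rep(NA_real_, length(fields))
  if (any(ok_len)) {
    mat <- do.call(rbind, lapply(fields[ok_len], function(f) f[1:7]))
    lat[ok_len] <- suppressWarnings(as.numeric(mat[, 1]))
    lon[ok_len] <- suppressWarnings(as.numeric(mat[, 2]))
    alt[ok_len] <- suppressWarnings(as.numeric(mat[, 4]))
    stamp[ok_len] <- as.numeric(as.POSIXct(
      paste(trimws(mat[, 6]), trimws(mat[, 7])),
      tz = "UTC", format = "%Y-%m-%d %H:%M:%S"
    ))
  }
  valid <- ok_len & !is.na(lat) & !is.na(lon) & !is.na(stamp) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  n_skip <- length(fields) - sum(valid)
  if (n_skip > 0 && !quiet) {
    message("read_plt: skipped ", n_skip, " malformed line(s) in ", basename(path))
  }
  if (!any(valid)) {
    abort(paste0("no valid track records in ", path), class = "mobiscale_empty_trajectory")
  }

  out <- tibble(
    user_id = user_id,
    file_id = file_id,
    latitude = lat[valid],
    longitude = lon[valid],
    altitude = ifelse(alt[valid] == -777, NA_real_, alt[valid] * 0.3048),
    timestamp = as.POSIXct(stamp[valid], tz = "UTC", origin = "1970-01-01")
  )
  dplyr::arrange(out, .data$timestamp)
}

#' Write track points to a PLT file
#'
#' Inverse of [read_plt()]: writes the six-line Geolife header followed by
#' one record per point. Coordinates are written with six decimal places,
#' altitude converted back to feet (`-777` for missing values).
#'
#' @param trajectory A tibble of track points for a single file (columns
#'   `latitude`, `longitude`, `timestamp`, optionally `altitude`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plt <- function(trajectory, path) {
  stopifnot(all(c("latitude", "longitude", "timestamp") %in% names(trajectory)))
  alt_m <- if ("altitude" %in% names(trajectory)) trajectory$altitude else NA_real_
  alt_ft <- ifelse(is.na(alt_m), -777, alt_m / 0.3048)
  ts <- as.POSIXct(trajectory$timestamp, tz = "UTC")
  frac_days <- as.numeric(ts) / 86400 + 25569 # days since 1899-12-30
  header <- c(
    "Geolife trajectory",
    "WGS 84",
    "Altitude is in Feet",
    "Reserved 3",
    "0,2,255,My Track,0,0,2,8421376",
    "0"
  )
  recs <- sprintf(
    "%.6f,%.6f,0,%.1f,%.10f,%s,%s",
    trajectory$latitude, trajectory$longitude, alt_ft, frac_days,
    format(ts, "%Y-%m-%d", tz = "UTC"), format(ts, "%H:%M:%S", tz = "UTC")
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read every PLT file under a Geolife-style directory tree
#'
#' Walks `<dir>/<user>/Trajectory/*.plt` (falling back to any `*.plt` below
#' `dir` when that layout is absent) and row-binds the parsed points.
#'
#' @param dir Root directory.
#' @inheritParams read_plt
#' @return A tibble of track points from all files (see [read_plt()]).
#' @export
read_plt_dir <- function(dir, quiet = TRUE) {
  if (!dir.exists(dir)) {
    abort(paste0("directory does not exist: ", dir), class = "mobiscale_io_error")
  }
  paths <- list.files(file.path(dir), pattern = "\\.plt$", recursive = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0) {
    abort(paste0("no .plt files under ", dir), class = "mobiscale_io_error")
  }
  purrr::map_dfr(paths, function(p) {
    # <dir>/<user>/Trajectory/<file>.plt -> user folder two levels up
    read_plt(p, quiet = quiet)
  })
}

#' Keep only trajectories recorded for long enough
#'
#' Drops whole files whose recording time, measured as last minus first
#' timestamp, falls below `min_duration`. The default of six hours is the
#' threshold used to discard short GPS logs that cannot yield enough
#' staypoints for stable statistics.
#'
#' @param points A track-point tibble (possibly many files; grouping columns
#'   `user_id` and `file_id` identify a file).
#' @param min_duration Minimum recording time in seconds (default 21600 = 6 h).
#' @return The filtered tibble, file order preserved.
#' @export
filter_trajectories <- function(points, min_duration = 21600) {
  stopifnot(min_duration >= 0)
  points |>
    dplyr::group_by(.data$user_id, .data$file_id) |>
    dplyr::filter(
      as.numeric(max(.data$timestamp)) - as.numeric(min(.data$timestamp)) >=
        min_duration
    ) |>
    dplyr::ungroup()
}

#' Write and read movement-series tables
#'
#' Lossless tab-separated round trip for movement records (one row per
#' displacement). `read_series()` validates that the mandatory columns are
#' present and errors otherwise.
#'
#' @param series A movement-record tibble (see [build_series()]).
#' @param path File path.
#' @return `write_series()` returns `path` invisibly; `read_series()` a tibble.
#' @export
write_series <- function(series, path) {
  readr::write_tsv(series, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("user_id", "file_id", "displacement", "elapsed_time")
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    abort(paste0("series file ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mobiscale_format_error")
  }
  out
}
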