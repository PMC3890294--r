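#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one list. Defaults
#' are the canonical analysis values: 10 m / 120 s staypoint resolution
#' (the spatial resolution of a handheld GPS and the cycle of traffic
#' signals), a 6 h minimum recording time per file, and a
#' more-than-200-staypoint cut for individual-level analysis. A YAML file
#' with any subset of the keys can override the defaults.
#'
#' @param d_max Staypoint spatial resolution (m).
#' @param t_min Staypoint temporal resolution (s).
#' @param min_duration Minimum file recording time (s).
#' @param min_staypoints Individual-level inclusion threshold (strictly
#'   more staypoints than this are required).
#' @param staypoint_rule Confinement rule for [extract_staypoints()].
#' @param bins_per_decade Log-binning resolution.
#' @param n_bootstrap Bootstrap replicates for KS confidence probabilities.
#' @param max_lag Largest lag in correlation-decay profiles.
#' @param seed Seed for the stochastic components (bootstraps).
#' @param file Optional YAML file whose entries override the arguments.
#' @return A named list of class `mobiscale_config`.
#' @export
mobility_config <- function(d_max = 10, t_min = 120, min_duration = 21600,
                            min_staypoints = 200,
                            staypoint_rule = "consecutive",
                            bins_per_decade = 10, n_bootstrap = 1000,
                            max_lag = 20, seed = NULL, file = NULL) {
  cfg <- list(
    d_max = d_max, t_min = t_min, min_duration = min_duration,
    min_staypoints = min_staypoints, staypoint_rule = staypoint_rule,
    bins_per_decade = bins_per_decade, n_bootstrap = n_bootstrap,
    max_lag = max_lag, seed = seed
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      warn(paste("ignoring unknown config keys:",
                 paste(unknown, collapse = ", ")))
    }
    cfg[intersect(names(over), names(cfg))] <-
      over[intersect(names(over), names(cfg))]
  }
  structure(cfg, class = "mobiscale_config")
}

resolve_points <- function(x) {
  if (is.character(x)) read_plt_dir(x) else as_tibble(x)
}

#' Population-level mobility analysis
#'
#' Runs the full population track: file-duration filter, staypoint
#' extraction, series construction, pooled log-binned distributions of
#' displacement, staying time and elapsed time, a two-regime power-law fit
#' of the displacement distribution, the speed-displacement pattern, the
#' aggregated consecutive Kendall's tau (raw and per-user-relative
#' displacements), the lag-decay profiles with their power-law decay fits,
#' and a DFA Hurst exponent of the per-file-concatenated displacement
#' series.
#'
#' @param x A track-point tibble or a directory of PLT files.
#' @param config A [mobility_config()] list.
#' @param quiet Suppress the per-stage funnel messages.
#' @return A list of class `population_report`; see Details for elements.
#' @export
run_population <- function(x, config = mobility_config(), quiet = FALSE) {
  points <- resolve_points(x)
  if (nrow(points) == 0) {
    abort("no track points to analyse", class = "mobiscale_input_error")
  }
  n_files_in <- nrow(dplyr::distinct(points, .data$user_id, .data$file_id))
  points <- filter_trajectories(points, config$min_duration)
  n_files <- nrow(dplyr::distinct(points, .data$user_id, .data$file_id))
  sp <- extract_staypoints(points, config$d_max, config$t_min,
                           rule = config$staypoint_rule)
  series <- build_series(sp)
  if (!quiet) {
    message(sprintf(
      "files: %d in, %d kept (>= %g h); staypoints: %d; movements: %d",
      n_files_in, n_files, config$min_duration / 3600, nrow(sp), nrow(series)
    ))
  }
  if (nrow(series) == 0) {
    abort("no movement records after filtering", class = "mobiscale_input_error")
  }
  series <- add_relative_displacement(series)
  pool <- pool_population(series)
  pos <- pool$displacement[pool$displacement > 0]

  dist_disp <- log_bin(pos, config$bins_per_decade)
  dist_stay <- log_bin(pool$staying_time[pool$staying_time > 0],
                       config$bins_per_decade)
  dist_elapsed <- log_bin(pool$elapsed_time[pool$elapsed_time > 0],
                          config$bins_per_decade)
  two_regime <- tryCatch(fit_two_regime(dist_disp), error = function(e) NULL)

  max_lag <- min(config$max_lag,
                 max(series |>
                       dplyr::count(.data$user_id, .data$file_id) |>
                       dplyr::pull(.data$n)) - 1L)
  profile <- tau_lag_profile(series, max_lag = max_lag)
  profile_rel <- tau_lag_profile(series, max_lag = max_lag,
                                 value = "rel_displacement")

  list(
    counts = list(
      files_in = n_files_in, files_kept = n_files,
      staypoints = nrow(sp), movements = nrow(series),
      total_staying_time_h = sum(sp$staying_time) / 3600,
      total_displacement_km = sum(series$displacement) / 1000
    ),
    series = series,
    dist_displacement = dist_disp,
    dist_staying_time = dist_stay,
    dist_elapsed_time = dist_elapsed,
    two_regime = two_regime,
    speed_pattern = speed_displacement_pattern(series,
                                               config$bins_per_decade),
    tau1 = lagged_tau(series, 1),
    tau1_relative = lagged_tau(series, 1, value = "rel_displacement"),
    lag_profile = profile,
    lag_profile_relative = profile_rel,
    tau_decay = tryCatch(fit_tau_decay(profile), error = function(e) NULL),
    pearson_decay = tryCatch(fit_tau_decay(profile, "pearson_log"),
                             error = function(e) NULL),
    dfa = tryCatch(dfa(series$displacement), error = function(e) NULL),
    staytime_independence = run_staytime_independence(series)
  ) |> structure(class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat("Population mobility report\n")
  cat(sprintf("  %d files, %d staypoints, %d movements\n",
              x$counts$files_kept, x$counts$staypoints, x$counts$movements))
  cat(sprintf("  total staying time %.1f h, total displacement %.2f km\n",
              x$counts$total_staying_time_h, x$counts$total_displacement_km))
  cat(sprintf("  consecutive tau = %.3f (CI %.3f); relative tau = %.3f\n",
              x$tau1$tau, x$tau1$ci_halfwidth, x$tau1_relative$tau))
  if (!is.null(x$dfa)) cat(sprintf("  DFA Hurst H = %.3f\n", x$dfa$hurst))
  invisible(x)
}

#' Independence of staying times and displacements
#'
#' Kendall's tau between each movement's displacement and the staying time
#' at its origin staypoint. Values inside the null CI indicate that how
#' long one stays somewhere carries no information about how far one moves
#' next.
#'
#' @param series A movement-record tibble.
#' @return A `tau_result` row.
#' @export
run_staytime_independence <- function(series) {
  ok <- is.finite(series$preceding_staytime) & is.finite(series$displacement)
  kendall_tau(series$preceding_staytime[ok], series$displacement[ok])
}

summarize_one_user <- function(series, n_staypoints, config) {
  dr <- series$displacement
  pos <- dr[dr > 0]
  t1 <- lagged_tau(series, 1)
  rd <- tryCatch(log_pearson(series)$r_delta, error = function(e) NA_real_)
  h <- tryCatch(dfa(dr)$hurst, error = function(e) NA_real_)
  h_log <- tryCatch(dfa(log(pos))$hurst, error = function(e) NA_real_)
  pl <- tryCatch(
    fit_powerlaw_ks(pos, n_bootstrap = config$n_bootstrap,
                    seed = config$seed, min_tail = min(50, length(pos) %/% 2)),
    error = function(e) NULL
  )
  binned <- tryCatch(log_bin(pos, config$bins_per_decade),
                     error = function(e) NULL)
  r_disp <- tryCatch(loglog_pearson(binned)$R, error = function(e) NA_real_)
  stay <- series$preceding_staytime[series$preceding_staytime > 0]
  r_stay <- tryCatch(
    loglog_pearson(log_bin(stay, config$bins_per_decade))$R,
    error = function(e) NA_real_
  )
  tibble(
    user_id = series$user_id[1],
    n_staypoints = n_staypoints,
    n_displacements = nrow(series),
    mean_displacement = mean(dr),
    max_displacement = max(dr),
    tau1 = t1$tau,
    tau1_ci = t1$ci_halfwidth,
    r_delta = rd,
    hurst = h,
    hurst_log = h_log,
    ks_xmin = if (is.null(pl)) NA_real_ else pl$x_min,
    ks_alpha = if (is.null(pl)) NA_real_ else pl$alpha,
    ks_p = if (is.null(pl)) NA_real_ else pl$p,
    R_displacement = r_disp,
    R_staytime = r_stay
  )
}

#' Per-user mobility summaries
#'
#' Aggregates each user's movement records (pairs formed within files,
#' statistics pooled across the user's files) into one summary row:
#' staypoint and displacement counts, mean and maximum displacement, the
#' consecutive-displacement Kendall's tau, the log-displacement lag-one
#' Pearson coefficient, the DFA Hurst exponent (on the raw displacement
#' series, with a log-displacement variant alongside), the KS power-law fit
#' (estimated lower bound) and the log-log straight-line fit qualities of
#' the displacement and staying-time distributions.
#'
#' @param series A movement-record tibble covering many users.
#' @param staypoint_counts Optional tibble (`user_id`, `n_staypoints`);
#'   when absent, counts are inferred from the identity
#'   `N_staypoints = N_displacements + N_files`.
#' @param config A [mobility_config()]; `min_staypoints` applies strictly
#'   (users need *more* staypoints than the threshold).
#' @return A tibble with one row per retained user.
#' @export
summarize_users <- function(series, staypoint_counts = NULL,
                            config = mobility_config()) {
  if (is.null(staypoint_counts)) {
    staypoint_counts <- series |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(
        n_staypoints = dplyr::n() +
          dplyr::n_distinct(.data$file_id), .groups = "drop"
      )
  }
  keep <- staypoint_counts$user_id[
    staypoint_counts$n_staypoints > config$min_staypoints
  ]
  series |>
    dplyr::filter(.data$user_id %in% keep) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(s) {
      nsp <- staypoint_counts$n_staypoints[
        staypoint_counts$user_id == s$user_id[1]
      ]
      summarize_one_user(s, nsp, config)
    })
}

#' Cross-user correlations between correlation strength and fit quality
#'
#' The six Kendall's taus over users pairing each correlation statistic
#' (`tau1`, `r_delta`, `hurst`) with each fit-quality statistic (`ks_p`,
#' `R_displacement`), with the shared analytic null CI half-width for the
#' retained user count. A positive tau against `ks_p` (and a negative one
#' against `R_displacement`, where better fits are more negative) means
#' users with stronger displacement correlation have displacement
#' distributions closer to a power law.
#'
#' @param summaries A per-user summary tibble from [summarize_users()].
#' @return A tibble with columns `correlation_stat`, `fit_stat`, `tau`,
#'   `n_users`, `ci_halfwidth`; or an empty tibble with a warning when
#'   fewer than three users are available.
#' @export
cross_user_correlations <- function(summaries) {
  if (nrow(summaries) < 3) {
    warn("fewer than 3 users: cross-user correlations not computable")
    return(tibble(correlation_stat = character(), fit_stat = character(),
                  tau = double(), n_users = integer(),
                  ci_halfwidth = double()))
  }
  grid <- tidyr::expand_grid(
    correlation_stat = c("tau1", "r_delta", "hurst"),
    fit_stat = c("ks_p", "R_displacement")
  )
  purrr::pmap_dfr(grid, function(correlation_stat, fit_stat) {
    a <- summaries[[correlation_stat]]
    b <- summaries[[fit_stat]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      return(tibble(correlation_stat = correlation_stat, fit_stat = fit_stat,
                    tau = NA_real_, n_users = sum(ok),
                    ci_halfwidth = NA_real_))
    }
    tr <- kendall_tau(a[ok], b[ok])
    tibble(correlation_stat = correlation_stat, fit_stat = fit_stat,
           tau = tr$tau, n_users = tr$n_pairs,
           ci_halfwidth = tr$ci_halfwidth)
  })
}

#' Individual-level mobility analysis
#'
#' Runs the per-user track: file filter, staypoint extraction, per-user
#' series, the strict more-than-`min_staypoints` user cut, one summary row
#' per retained user and the six cross-user correlations between
#' correlation strength and power-law fit quality.
#'
#' @inheritParams run_population
#' @return A list of class `individual_report` with `summaries`,
#'   `cross_correlations` and `counts`.
#' @export
run_individual <- function(x, config = mobility_config(), quiet = FALSE) {
  points <- resolve_points(x)
  points <- filter_trajectories(points, config$min_duration)
  sp <- extract_staypoints(points, config$d_max, config$t_min,
                           rule = config$staypoint_rule)
  series <- build_series(sp)
  sp_counts <- sp |>
    dplyr::count(.data$user_id, name = "n_staypoints")
  summaries <- summarize_users(series, sp_counts, config)
  if (!quiet) {
    message(sprintf("users: %d with > %d staypoints (of %d)",
                    nrow(summaries), config$min_staypoints,
                    dplyr::n_distinct(sp$user_id)))
  }
  structure(
    list(
      summaries = summaries,
      cross_correlations = cross_user_correlations(summaries),
      counts = list(
        users_total = dplyr::n_distinct(sp$user_id),
        users_kept = nrow(summaries),
        files = nrow(dplyr::distinct(sp, .data$user_id, .data$file_id)),
        staypoints = nrow(sp)
      )
    ),
    class = "individual_report"
  )
}

#' @export
print.individual_report <- function(x, ...) {
  cat(sprintf("Individual mobility report: %d users retained (of %d)\n",
              x$counts$users_kept, x$counts$users_total))
  print(x$summaries)
  invisible(x)
}
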