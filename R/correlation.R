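#' Kendall's tau rank correlation (tau-a)
#'
#' Rank correlation over all element pairs of two equally long series:
#' `tau = 2 / (n (n - 1)) * sum over i < j of sgn(x_i - x_j) sgn(y_i - y_j)`,
#' with `sgn(0) = 0`, so tied pairs contribute zero (the tau-a convention —
#' no tie correction in the denominator). Because tau depends only on
#' orderings it is invariant under strictly monotone transforms of either
#' series, which makes it suitable for displacement data spanning many
#' orders of magnitude.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param level Confidence level for the attached null confidence interval.
#' @return A one-row tibble of class `tau_result`: `tau`, `n_pairs` (the
#'   number of paired observations), `lag` (`NA` here; set by
#'   [lagged_tau()]), `ci_halfwidth` (the normal-approximation null CI
#'   half-width from [tau_ci()]).
#' @export
#' @examples
#' kendall_tau(1:10, (1:10)^3)   # tau = 1: same ordering
#' kendall_tau(1:10, -(1:10))    # tau = -1: reversed
kendall_tau <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "mobiscale_input_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) {
    abort("need at least 2 paired observations", class = "mobiscale_input_error")
  }
  tau <- kendall_pair_sum(x, y) / (n * (n - 1) / 2)
  structure(
    tibble(tau = tau, n_pairs = n, lag = NA_integer_,
           ci_halfwidth = tau_ci(n, level)),
    class = c("tau_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Null confidence-interval half-width for Kendall's tau
#'
#' Under independence, tau is asymptotically normal with variance
#' `2 (2 n + 5) / (9 n (n - 1))`; the half-width is the corresponding
#' two-sided normal quantile. Values of |tau| above this half-width are
#' significant at the given level.
#'
#' @param n_pairs Number of paired observations.
#' @param level Confidence level (default 0.95).
#' @return Half-width of the null interval around zero.
#' @export
#' @examples
#' tau_ci(1000) # ~0.0413
tau_ci <- function(n_pairs, level = 0.95) {
  stopifnot(n_pairs >= 2)
  z <- qnorm(1 - (1 - level) / 2)
  z * sqrt(2 * (2 * n_pairs + 5) / (9 * n_pairs * (n_pairs - 1)))
}

#' Permutation null confidence interval for Kendall's tau
#'
#' Seeded alternative to the analytic formula of [tau_ci()]: `y` is shuffled
#' `n_perm` times and the half-width is the `level` quantile of |tau| under
#' the shuffles.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_perm Number of shuffles (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Half-width of the permutation null interval.
#' @export
tau_ci_permutation <- function(x, y, n_perm = 2000, level = 0.95, seed = NULL) {
  n <- length(x)
  denom <- n * (n - 1) / 2
  with_seed(seed, {
    taus <- vapply(seq_len(n_perm), function(i) {
      kendall_pair_sum(x, sample(y)) / denom
    }, numeric(1))
    unname(stats::quantile(abs(taus), level))
  })
}

# consecutive (lag-Δn) pairs within each file; never spans file boundaries
lag_pairs <- function(series, lag, value = "displacement") {
  series |>
    dplyr::group_by(.data$user_id, .data$file_id) |>
    dplyr::reframe({
      v <- .data[[value]]
      m <- length(v)
      if (m > lag) {
        tibble(x = v[seq_len(m - lag)], y = v[seq(lag + 1, m)])
      } else {
        tibble(x = double(), y = double())
      }
    })
}

#' Lagged Kendall's tau of a displacement series
#'
#' Forms all pairs `(v_n, v_(n + lag))` within each file, pools the pairs
#' across files (pairs never span a file boundary), and applies
#' [kendall_tau()] to the pooled pair set.
#'
#' @param series A movement-record tibble.
#' @param lag Positive integer lag.
#' @param value Column to correlate (default `"displacement"`; use
#'   `"rel_displacement"` after [add_relative_displacement()]).
#' @param level Confidence level for the null CI.
#' @return A `tau_result` row with `lag` filled in.
#' @export
lagged_tau <- function(series, lag = 1, value = "displacement", level = 0.95) {
  stopifnot(lag >= 1)
  pairs <- lag_pairs(series, lag, value)
  if (nrow(pairs) < 2) {
    abort(sprintf("no (or too few) pairs at lag %d", lag),
          class = "mobiscale_input_error")
  }
  out <- kendall_tau(pairs$x, pairs$y, level = level)
  out$lag <- as.integer(lag)
  out
}

#' Lag profile of displacement correlations
#'
#' Computes the lagged Kendall's tau for every lag `1..max_lag`, together
#' with a lag profile of the Pearson autocorrelation of log-displacements
#' (each file's pairs pooled, normalised by the pooled mean and variance of
#' the log series). The slow decay of these profiles with lag is the
#' signature of long-term correlation in the series.
#'
#' @inheritParams lagged_tau
#' @param max_lag Largest lag (lags with no pairs are dropped).
#' @return A tibble of class `lag_decay` with columns `lag`, `tau`,
#'   `n_pairs`, `ci_halfwidth`, `pearson_log`.
#' @export
tau_lag_profile <- function(series, max_lag = 20, value = "displacement",
                            level = 0.95) {
  u_all <- log(series[[value]][series[[value]] > 0])
  mu <- mean(u_all)
  s2 <- mean((u_all - mu)^2)
  rows <- purrr::map(seq_len(max_lag), function(dn) {
    pairs <- lag_pairs(series, dn, value)
    if (nrow(pairs) < 10) return(NULL)
    tr <- kendall_tau(pairs$x, pairs$y, level = level)
    ok <- pairs$x > 0 & pairs$y > 0
    r_log <- if (s2 > 0 && sum(ok) > 2) {
      mean((log(pairs$x[ok]) - mu) * (log(pairs$y[ok]) - mu)) / s2
    } else NA_real_
    tibble(lag = dn, tau = tr$tau, n_pairs = tr$n_pairs,
           ci_halfwidth = tr$ci_halfwidth, pearson_log = r_log)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no usable lags", class = "mobiscale_input_error")
  }
  structure(out, class = c("lag_decay", class(tibble())))
}

#' Power-law fit of a correlation-decay profile
#'
#' OLS fit of log statistic against log lag, restricted to lags with a
#' positive statistic. For the log-Pearson profile the slope also implies a
#' Hurst exponent through the long-memory scaling `r(lag) ~ lag^(2 H - 2)`,
#' reported as `hurst_implied`.
#'
#' @param profile A `lag_decay` tibble from [tau_lag_profile()].
#' @param stat `"tau"` or `"pearson_log"`.
#' @return A list of class `decay_fit`: `decay_exponent` (the log-log
#'   slope, negative for decaying profiles), `n_used`, `stat`,
#'   `hurst_implied` (only for `stat = "pearson_log"`).
#' @export
fit_tau_decay <- function(profile, stat = c("tau", "pearson_log")) {
  stat <- match.arg(stat)
  v <- profile[[stat]]
  keep <- !is.na(v) & v > 0
  if (sum(keep) < 4) {
    abort("need at least 4 positive values to fit the decay",
          class = "mobiscale_fit_error")
  }
  f <- lm(log10(v[keep]) ~ log10(profile$lag[keep]))
  slope <- unname(coef(f)[2])
  structure(
    list(decay_exponent = slope, n_used = sum(keep), stat = stat,
         hurst_implied = if (stat == "pearson_log") 1 + slope / 2 else NA_real_),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit (%s): exponent %.3f over %d lags", x$stat,
              x$decay_exponent, x$n_used))
  if (!is.na(x$hurst_implied)) cat(sprintf(", implied H = %.3f", x$hurst_implied))
  cat("\n")
  invisible(x)
}

#' Lag-one Pearson autocorrelation of log-displacements
#'
#' Correlation between consecutive log-displacements of a series, normalised
#' by the series' own mean and variance of log-displacements. The logarithm
#' tames the heavy tail of raw displacements, which would otherwise let a
#' handful of long trips dominate a product-moment statistic. Pairs are
#' formed within files only.
#'
#' @param series A movement-record tibble (all displacements must be > 0
#'   for the rows used; non-positive displacements are dropped).
#' @param value Column holding displacements.
#' @return An object of class `log_pearson`: `r_delta`, `mean_log`,
#'   `var_log`, `n_pairs`.
#' @export
log_pearson <- function(series, value = "displacement") {
  v <- series[[value]]
  series <- series[!is.na(v) & v > 0, ]
  u <- log(series[[value]])
  if (length(u) < 3) {
    abort("need at least 3 positive displacements",
          class = "mobiscale_input_error")
  }
  mu <- mean(u)
  s2 <- mean((u - mu)^2)
  if (s2 <= .Machine$double.eps * abs(mu)^2 || s2 == 0) {
    abort("zero variance of log-displacements: statistic undefined",
          class = "mobiscale_degenerate_error")
  }
  pairs <- lag_pairs(series, 1, value)
  if (nrow(pairs) < 2) {
    abort("too few consecutive pairs", class = "mobiscale_input_error")
  }
  r <- mean((log(pairs$x) - mu) * (log(pairs$y) - mu)) / s2
  structure(
    list(r_delta = r, mean_log = mu, var_log = s2, n_pairs = nrow(pairs)),
    class = "log_pearson"
  )
}

#' @export
print.log_pearson <- function(x, ...) {
  cat(sprintf("Log-displacement lag-1 Pearson r = %.3f (%d pairs)\n",
              x$r_delta, x$n_pairs))
  invisible(x)
}

#' Consecutive-displacement scatter pattern
#'
#' Two-dimensional log-binned histogram of consecutive displacement pairs
#' `(v_n, v_(n+1))`; positive serial dependence concentrates mass near the
#' diagonal. The `diagonal_mass` summary is the fraction of pairs whose
#' ratio lies within a factor `diag_factor` of one, comparable against a
#' within-file shuffled control to quantify the diagonal excess.
#'
#' @param series A movement-record tibble.
#' @param relative Use per-user relative displacements (adds them if absent).
#' @param bins_per_decade Resolution of the 2-D histogram.
#' @param diag_factor Band half-width (ratio scale) of the diagonal summary.
#' @return A list of class `scatter_pattern`: `pairs`, `grid` (tibble of
#'   `x_center`, `y_center`, `count`), `diagonal_mass`, `n_pairs`.
#' @export
scatter_correlation_pattern <- function(series, relative = FALSE,
                                        bins_per_decade = 10,
                                        diag_factor = 2) {
  value <- "displacement"
  if (relative) {
    if (!"rel_displacement" %in% names(series)) {
      series <- add_relative_displacement(series)
    }
    value <- "rel_displacement"
  }
  pairs <- lag_pairs(series, 1, value)
  pairs <- dplyr::filter(pairs, .data$x > 0, .data$y > 0)
  if (nrow(pairs) == 0) {
    abort("no positive consecutive pairs", class = "mobiscale_input_error")
  }
  edges <- log_bin_edges(c(pairs$x, pairs$y), bins_per_decade)
  ix <- findInterval(pairs$x, edges, rightmost.closed = TRUE)
  iy <- findInterval(pairs$y, edges, rightmost.closed = TRUE)
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  grid <- tibble(ix = ix, iy = iy) |>
    dplyr::count(.data$ix, .data$iy, name = "count") |>
    dplyr::mutate(x_center = centers[.data$ix], y_center = centers[.data$iy]) |>
    dplyr::select("x_center", "y_center", "count")
  structure(
    list(
      pairs = pairs,
      grid = grid,
      diagonal_mass = mean(pairs$y / pairs$x >= 1 / diag_factor &
                             pairs$y / pairs$x <= diag_factor),
      diag_factor = diag_factor,
      n_pairs = nrow(pairs)
    ),
    class = "scatter_pattern"
  )
}
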