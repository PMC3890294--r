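log_bin_edges <- function(x, bins_per_decade) {
  lo <- min(x)
  hi <- max(x)
  if (lo <= 0) {
    abort("log-binning requires strictly positive samples",
          class = "mobiscale_domain_error")
  }
  if (lo == hi) {
    return(c(lo / 10^(0.5 / bins_per_decade), hi * 10^(0.5 / bins_per_decade)))
  }
  n_bins <- max(1L, ceiling((log10(hi) - log10(lo)) * bins_per_decade))
  edges <- 10^seq(log10(lo), by = 1 / bins_per_decade, length.out = n_bins + 1L)
  # guard against 10^log10() rounding excluding the extreme samples
  edges[1] <- min(edges[1], lo)
  edges[length(edges)] <- max(edges[length(edges)], hi * (1 + 1e-12))
  edges
}

#' Log-binned empirical density
#'
#' Bins strictly positive samples into geometrically spaced bins and returns
#' per-bin counts and probability densities (`count / (N * bin width)`), the
#' standard estimator for visualising and fitting heavy-tailed distributions.
#' Densities integrate to one over the binned range.
#'
#' @param samples Strictly positive numeric vector.
#' @param bins_per_decade Number of bins per decade (default 10).
#' @return A tibble of class `binned_dist` with columns `low`, `high`,
#'   `center` (geometric mid-point), `count` and `density`; the sample size
#'   is attached as attribute `n`.
#' @export
#' @examples
#' b <- log_bin(rlnorm(1000))
#' sum(b$density * (b$high - b$low)) # ~1
log_bin <- function(samples, bins_per_decade = 10) {
  samples <- samples[!is.na(samples)]
  if (length(samples) == 0) {
    abort("no samples to bin", class = "mobiscale_domain_error")
  }
  if (any(samples <= 0)) {
    abort("log_bin: all samples must be > 0", class = "mobiscale_domain_error")
  }
  edges <- log_bin_edges(samples, bins_per_decade)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  width <- diff(edges)
  out <- tibble(
    low = edges[-length(edges)],
    high = edges[-1],
    center = sqrt(edges[-length(edges)] * edges[-1]),
    count = counts,
    density = counts / (length(samples) * width)
  )
  structure(out, n = length(samples), class = c("binned_dist", class(out)))
}

#' Two-regime power-law fit of a log-binned density
#'
#' Fits a piecewise power law with a single break: for every interior bin
#' edge that leaves at least `min_side` non-empty bins on each side, an OLS
#' line is fitted to (log center, log density) on each side, and the break
#' minimising the total squared error in log-log space is returned. Captures
#' densities that decay with one exponent at short range and a different one
#' beyond a transition scale.
#'
#' @param dist A `binned_dist` from [log_bin()].
#' @param min_side Minimum non-empty bins per regime (default 3).
#' @return An object of class `two_regime_fit` with fields `break_point`,
#'   `alpha_low`, `alpha_high` (the log-log slopes below/above the break;
#'   negative for decaying laws), `sse`, `sse_single` (single-line fit for
#'   comparison) and the fitted bin table.
#' @export
fit_two_regime <- function(dist, min_side = 3) {
  pts <- dplyr::filter(as_tibble(dist), .data$count > 0)
  if (nrow(pts) < 2 * min_side) {
    abort("too few non-empty bins for a two-regime fit",
          class = "mobiscale_fit_error")
  }
  lx <- log10(pts$center)
  ly <- log10(pts$density)
  sse_of <- function(i) {
    f1 <- lm(ly[1:i] ~ lx[1:i])
    f2 <- lm(ly[(i + 1):length(ly)] ~ lx[(i + 1):length(lx)])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }
  cand <- seq(min_side, nrow(pts) - min_side)
  sses <- vapply(cand, sse_of, numeric(1))
  i_best <- cand[which.min(sses)]
  f_lo <- lm(ly ~ lx, subset = seq_len(i_best))
  f_hi <- lm(ly ~ lx, subset = seq(i_best + 1L, length(lx)))
  f_single <- lm(ly ~ lx)
  structure(
    list(
      break_point = sqrt(pts$center[i_best] * pts$center[i_best + 1L]),
      alpha_low = unname(coef(f_lo)[2]),
      alpha_high = unname(coef(f_hi)[2]),
      sse = min(sses),
      sse_single = sum(f_single$residuals^2),
      bins = pts
    ),
    class = "two_regime_fit"
  )
}

#' @export
print.two_regime_fit <- function(x, ...) {
  cat(sprintf(
    "Two-regime power-law fit: slope %.3f below %.3g, slope %.3f above (SSE %.4g)\n",
    x$alpha_low, x$break_point, x$alpha_high, x$sse
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.two_regime_fit <- function(x, ...) {
  tibble(
    term = c("alpha_low", "alpha_high", "break_point"),
    estimate = c(x$alpha_low, x$alpha_high, x$break_point)
  )
}

#' @exportS3Method generics::glance
glance.two_regime_fit <- function(x, ...) {
  tibble(break_point = x$break_point, alpha_low = x$alpha_low,
         alpha_high = x$alpha_high, sse = x$sse, sse_single = x$sse_single)
}

#' Draw Pareto-distributed samples
#'
#' Continuous power-law (Pareto) deviates with density
#' `p(x) ~ x^(-alpha)` for `x >= x_min`, via inverse-transform sampling.
#'
#' @param n Number of draws.
#' @param alpha Tail exponent of the density (> 1).
#' @param x_min Lower bound (> 0).
#' @return Numeric vector of length `n`.
#' @export
rpareto <- function(n, alpha, x_min = 1) {
  stopifnot(alpha > 1, x_min > 0)
  x_min * runif(n)^(-1 / (alpha - 1))
}

select_xmin_candidates <- function(x_sorted, n_candidates, min_tail) {
  u <- unique(x_sorted)
  # candidates must leave a tail of at least min_tail samples
  n <- length(x_sorted)
  if (n < min_tail) {
    abort(sprintf("need at least %d samples (got %d)", min_tail, n),
          class = "mobiscale_fit_error")
  }
  max_xmin <- x_sorted[n - min_tail + 1L]
  u <- u[u <= max_xmin]
  if (length(u) == 0) {
    abort(sprintf("fewer than %d samples above every candidate lower bound",
                  min_tail),
          class = "mobiscale_fit_error")
  }
  if (length(u) > n_candidates) {
    u <- u[unique(round(seq(1, length(u), length.out = n_candidates)))]
  }
  u
}

fit_pl_once <- function(x_sorted, candidates) {
  scan <- powerlaw_ks_scan(x_sorted, candidates)
  ok <- which(!is.na(scan[, "ks"]))
  if (length(ok) == 0) {
    abort("power-law fit failed: no usable lower bound",
          class = "mobiscale_fit_error")
  }
  k <- ok[which.min(scan[ok, "ks"])]
  list(x_min = candidates[k], alpha = scan[k, "alpha"], ks = scan[k, "ks"],
       n_tail = scan[k, "n_tail"])
}

#' Maximum-likelihood power-law fit with KS lower bound and bootstrap p
#'
#' Fits `p(x) ~ x^-alpha` for `x >= x_min` by continuous maximum likelihood,
#' `alpha = 1 + n / sum(log(x_i / x_min))`. When `x_min = "estimate"` the
#' lower bound is chosen to minimise the Kolmogorov-Smirnov distance between
#' the tail's empirical CDF and the fitted law (the Clauset-Shalizi-Newman
#' procedure). The confidence probability `p` comes from a semiparametric
#' bootstrap: synthetic data sets of the same size are drawn from the fitted
#' law above `x_min` and (with the observed proportion) from the empirical
#' body below it, each refitted by the same procedure, and `p` is the
#' fraction whose KS distance is at least the observed one. Large `p` means
#' the power law is a plausible fit; small `p` rejects it.
#'
#' @param samples Positive numeric vector.
#' @param x_min `"estimate"` or a fixed numeric lower bound.
#' @param n_bootstrap Bootstrap replicates for `p` (default 1000; `0` skips
#'   the bootstrap and returns `p = NA`).
#' @param seed Optional integer seed for the bootstrap.
#' @param n_candidates Maximum number of candidate lower bounds scanned
#'   (log-spaced over the unique sample values; default 100).
#' @param min_tail Minimum number of samples required above the lower bound
#'   (default 50).
#' @return An object of class `powerlaw_fit` with fields `x_min`, `alpha`,
#'   `ks_stat`, `p`, `n_tail`, `n`, `n_bootstrap`, `xmin_fixed`.
#' @export
#' @examples
#' x <- rpareto(2000, alpha = 2.5, x_min = 1)
#' fit_powerlaw_ks(x, n_bootstrap = 0)
fit_powerlaw_ks <- function(samples, x_min = "estimate", n_bootstrap = 1000,
                            seed = NULL, n_candidates = 100, min_tail = 50) {
  samples <- samples[!is.na(samples) & samples > 0]
  n <- length(samples)
  x_sorted <- sort(samples)
  fixed <- is.numeric(x_min)
  candidates <- if (fixed) x_min else {
    select_xmin_candidates(x_sorted, n_candidates, min_tail)
  }
  fit <- fit_pl_once(x_sorted, candidates)
  if (fit$n_tail < min_tail) {
    abort(sprintf("only %d samples above x_min = %g (need >= %d)",
                  fit$n_tail, fit$x_min, min_tail),
          class = "mobiscale_fit_error")
  }

  p <- NA_real_
  if (n_bootstrap > 0) {
    body <- x_sorted[x_sorted < fit$x_min]
    p_tail <- fit$n_tail / n
    ks_boot <- with_seed(seed, vapply(seq_len(n_bootstrap), function(b) {
      take_tail <- runif(n) < p_tail
      y <- numeric(n)
      y[take_tail] <- rpareto(sum(take_tail), fit$alpha, fit$x_min)
      if (any(!take_tail)) {
        y[!take_tail] <- if (length(body) > 0) {
          sample(body, sum(!take_tail), replace = TRUE)
        } else {
          rpareto(sum(!take_tail), fit$alpha, fit$x_min)
        }
      }
      ys <- sort(y)
      cand_b <- if (fixed) x_min else {
        tryCatch(select_xmin_candidates(ys, n_candidates, min_tail),
                 error = function(e) min(ys))
      }
      fit_pl_once(ys, cand_b)$ks
    }, numeric(1)))
    p <- mean(ks_boot >= fit$ks)
  }

  structure(
    list(x_min = unname(fit$x_min), alpha = unname(fit$alpha),
         ks_stat = unname(fit$ks), p = p, n_tail = unname(fit$n_tail),
         n = n, n_bootstrap = n_bootstrap, xmin_fixed = fixed),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: alpha = %.3f, x_min = %.4g (%s), KS = %.4f, p = %s (n_tail = %d)\n",
    x$alpha, x$x_min, if (x$xmin_fixed) "fixed" else "estimated",
    x$ks_stat, ifelse(is.na(x$p), "NA", sprintf("%.3f", x$p)), x$n_tail
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("alpha", "x_min"), estimate = c(x$alpha, x$x_min))
}

#' @exportS3Method generics::glance
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, x_min = x$x_min, ks_stat = x$ks_stat, p = x$p,
         n_tail = x$n_tail, n = x$n)
}

#' Goodness of a straight-line fit in log-log coordinates
#'
#' Fits an OLS line to (log bin center, log density) over the non-empty bins
#' and reports the Pearson correlation coefficient between the two log
#' coordinates. For a decaying power law the coefficient is negative, and
#' `R = -1` corresponds to an exact power law; values near 0 indicate no
#' log-log linearity.
#'
#' @param dist A `binned_dist` from [log_bin()].
#' @param fit_range Optional `c(lo, hi)` restricting the bin centers used.
#' @return An object of class `loglog_fit` with fields `R`, `slope`,
#'   `intercept`, `n_bins`.
#' @export
loglog_pearson <- function(dist, fit_range = NULL) {
  pts <- dplyr::filter(as_tibble(dist), .data$count > 0)
  if (!is.null(fit_range)) {
    pts <- dplyr::filter(pts, .data$center >= fit_range[1],
                         .data$center <= fit_range[2])
  }
  if (nrow(pts) < 3) {
    abort("need at least 3 non-empty bins in range",
          class = "mobiscale_fit_error")
  }
  lx <- log10(pts$center)
  ly <- log10(pts$density)
  f <- lm(ly ~ lx)
  r <- if (stats::sd(ly) == 0) NA_real_ else stats::cor(lx, ly)
  structure(
    list(R = r, slope = unname(coef(f)[2]),
         intercept = unname(coef(f)[1]), n_bins = nrow(pts)),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Log-log linear fit: R = %.4f, slope = %.3f (%d bins)\n",
              x$R, x$slope, x$n_bins))
  invisible(x)
}
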