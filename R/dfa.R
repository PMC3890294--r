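#' Detrended fluctuation analysis
#'
#' Estimates the Hurst exponent of a series: (i) integrate the
#' mean-subtracted series into a profile; (ii) cut the profile into
#' `floor(N / l)` disjoint boxes of size `l` (the trailing remainder is
#' discarded); (iii) remove a least-squares polynomial trend of order
#' `order` inside each box; (iv) average the squared residuals per box;
#' (v) take the root of the across-box mean to get the fluctuation `F(l)`;
#' (vi) the Hurst exponent `H` is the OLS slope of `log F(l)` against
#' `log l`. `H = 0.5` indicates an uncorrelated series, `H > 0.5`
#' long-term persistence.
#'
#' @param x Numeric series.
#' @param box_sizes Integer vector of box sizes; default ~`n_sizes`
#'   log-spaced sizes between `min_box` and `length(x) / 4`.
#' @param order Polynomial detrending order (default 1, linear).
#' @param min_box Smallest default box (default 4; raised to `order + 2`
#'   when necessary so each box fit is overdetermined).
#' @param n_sizes Number of default box sizes (default 20).
#' @return An object of class `dfa_result`: tibble `fluctuation`
#'   (`box_size`, `F`), `hurst`, `order`, `degenerate` (`TRUE` when the
#'   series is constant so all fluctuations vanish and `H` is undefined).
#' @export
#' @examples
#' set.seed(1)
#' dfa(rnorm(2000))$hurst # ~0.5
dfa <- function(x, box_sizes = NULL, order = 1, min_box = 4, n_sizes = 20) {
  x <- as.numeric(x)
  n <- length(x)
  min_box <- max(min_box, order + 2)
  if (is.null(box_sizes)) {
    if (n < 4 * min_box) {
      abort("series too short for DFA", class = "mobiscale_input_error")
    }
    box_sizes <- unique(round(10^seq(log10(min_box), log10(n / 4),
                                     length.out = n_sizes)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < order + 2) || n < 4 * min(box_sizes)) {
    abort("box sizes must be >= order + 2 and the series >= 4x the smallest box",
          class = "mobiscale_input_error")
  }

  profile <- cumsum(x - mean(x))
  f_of_l <- vapply(box_sizes, function(l) {
    n_boxes <- n %/% l
    y <- matrix(profile[seq_len(n_boxes * l)], nrow = l)
    t_design <- stats::poly(seq_len(l), degree = order, raw = TRUE)
    qr_x <- qr(cbind(1, t_design))
    res <- qr.resid(qr_x, y)
    sqrt(mean(res^2))
  }, numeric(1))

  degenerate <- all(f_of_l <= .Machine$double.eps * n)
  hurst <- NA_real_
  if (!degenerate) {
    keep <- f_of_l > 0
    f <- lm(log10(f_of_l[keep]) ~ log10(box_sizes[keep]))
    hurst <- unname(coef(f)[2])
  }
  structure(
    list(
      fluctuation = tibble(box_size = box_sizes, F = f_of_l),
      hurst = hurst,
      order = order,
      n = n,
      degenerate = degenerate
    ),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  if (x$degenerate) {
    cat("DFA: degenerate (constant) series, H undefined\n")
  } else {
    cat(sprintf("DFA (order %d): H = %.3f over %d box sizes (n = %d)\n",
                x$order, x$hurst, nrow(x$fluctuation), x$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dfa_result <- function(x, ...) x$fluctuation

#' @exportS3Method generics::glance
glance.dfa_result <- function(x, ...) {
  tibble(hurst = x$hurst, order = x$order, n = x$n,
         n_boxes = nrow(x$fluctuation), degenerate = x$degenerate)
}
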