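#' Gaussian curve value used in the histogram summaries
#'
#' Evaluates, at a histogram value `x`, either the bell-curve formula
#' \deqn{f(x, \mu, \sigma) = \frac{1}{\sqrt{2 \pi \sigma}}
#'       e^{-(x - \mu)^2 / (2 \sigma^2)},}
#' note the \eqn{\sigma} inside the radical (`fidelity = "printed"`,
#' default), or the standard normal density with \eqn{\sigma\sqrt{2\pi}}
#' normalisation (`fidelity = "standard"`). `curve = "cdf"` returns the
#' Gaussian cumulative distribution instead, since the summaries are also
#' described as cumulative lines.
#'
#' @param x numeric value(s).
#' @param mu,sigma Gaussian location and scale (`sigma > 0`).
#' @param fidelity `"printed"` or `"standard"` normalisation.
#' @param curve `"density"` or `"cdf"`.
#' @return numeric, same length as `x`.
#' @examples
#' gaussian_value(0, 0, 1)              # 1/sqrt(2*pi)
#' gaussian_value(1, 0, 1, curve = "cdf")
#' @export
gaussian_value <- function(x, mu, sigma,
                           fidelity = c("printed", "standard"),
                           curve = c("density", "cdf")) {
  fidelity <- match.arg(fidelity)
  curve <- match.arg(curve)
  if (!is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (curve == "cdf") return(stats::pnorm(x, mu, sigma))
  norm <- if (fidelity == "printed") 1 / sqrt(2 * pi * sigma)
          else 1 / (sigma * sqrt(2 * pi))
  norm * exp(-((x - mu)^2) / (2 * sigma^2))
}

#' Histogram-based Gaussian summary of an image
#'
#' Bins the pixel sample over `[min, max]`, computes the sample mean and
#' the population standard deviation, and evaluates [gaussian_value()] at
#' every bin centre -- the per-image summary line of the comparison plots.
#' A constant image (zero spread) yields a flagged summary with the curve
#' values omitted.
#'
#' @param image numeric matrix.
#' @param n_bins number of histogram bins (>= 2; default 256).
#' @inheritParams gaussian_value
#' @return object of class `image_summary`: list with `mu`, `sigma`,
#'   `n`, `flagged`, `fidelity`, `curve`, and a data frame `bins` with
#'   columns `bin_center`, `count`, `f_value` (`f_value` all `NA` when
#'   flagged).
#' @export
summarize_image <- function(image, n_bins = 256L,
                            fidelity = c("printed", "standard"),
                            curve = c("density", "cdf")) {
  assert_image(image)
  fidelity <- match.arg(fidelity)
  curve <- match.arg(curve)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  v <- as.vector(image)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))   # population convention
  rng <- range(v)
  flagged <- sigma == 0
  if (flagged) {
    breaks <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_bins + 1L)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  fv <- if (flagged) rep(NA_real_, n_bins)
        else gaussian_value(centers, mu, sigma, fidelity, curve)
  structure(list(mu = mu, sigma = sigma, n = length(v), flagged = flagged,
                 fidelity = fidelity, curve = curve,
                 bins = data.frame(bin_center = centers, count = counts,
                                   f_value = fv)),
            class = "image_summary")
}

#' @export
print.image_summary <- function(x, ...) {
  cat(sprintf("image summary: n = %d, mu = %.6g, sigma = %.6g (%s %s)%s\n",
              x$n, x$mu, x$sigma, x$fidelity, x$curve,
              if (x$flagged) " [flagged: zero spread]" else ""))
  invisible(x)
}

#' Write an image summary as a CSV report
#'
#' One row per bin (`bin_center`, `count`, `f_value`) followed by the
#' summary statistics embedded as a commented header line.
#'
#' @param summary an [summarize_image()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "image_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mu=%.17g sigma=%.17g n=%d fidelity=%s curve=%s flagged=%s",
                     summary$mu, summary$sigma, summary$n,
                     summary$fidelity, summary$curve, summary$flagged), con)
  utils::write.csv(summary$bins, con, row.names = FALSE)
  invisible(path)
}
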