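#' Intensity-curvature term before interpolation
#'
#' \eqn{E_0(x,y)} integrates, over the rectangle \eqn{[0,x] \times [0,y]},
#' the product of the pixel intensity \eqn{f(0,0)} and the classic-curvature
#' of the model function evaluated at the origin (the sum of its four second
#' partials, \eqn{4(-2\alpha_3 + 2\alpha_2)}), giving the closed form
#' \deqn{E_0(x,y) = 4 x y \, f(0,0) (-2\alpha_3 + 2\alpha_2).}
#'
#' @inheritParams spline_coefficients
#' @param coeffs list with `alpha2`, `alpha3` (scalars or matrices).
#' @param x,y evaluation point (pixel units); the default unit-pixel corner
#'   `(1, 1)` makes the monomial weights O(1).
#' @return numeric, same shape as the broadcast inputs.
#' @export
icf_e0 <- function(f00, coeffs, x = 1, y = 1) {
  4 * x * y * f00 * (-2 * coeffs$alpha3 + 2 * coeffs$alpha2)
}

#' Polynomial building blocks of the ICF filter equations
#'
#' Evaluates the terms `e1..e12` and `omega` that assemble the
#' post-interpolation intensity-curvature term and the filter input/output
#' functions. `e1`, `e2` weight the intensity-linear part; `e3/e5/e7/e9`
#' are quadratic forms in \eqn{(\alpha_2, \alpha_3)} paired with the
#' monomial blocks `e4/e6/e8/e10`; `e11` carries its own `xy` factor;
#' `e12 = 4(-2\alpha_3 + 2\alpha_2)`; and
#' \eqn{\omega = 4(e_3 e_4 + e_5 e_6 + e_7 e_8 + e_9 e_{10} + e_{11})}.
#'
#' @section Fidelity modes:
#' These expansions are often tabulated with three coefficients that differ
#' from the double integral that defines them: the last term of `e3` quoted
#' as \eqn{\alpha_3^2} where the integral requires \eqn{\alpha_2^2}; `e6`
#' with a minus sign on \eqn{x y^4 / 4} where the integral requires plus;
#' and the \eqn{\alpha_3\alpha_2} coefficient inside `e5` as \eqn{10/3}
#' where the integral requires \eqn{16/3}. `fidelity = "canonical"`
#' (default) follows the integral, validated against adaptive quadrature;
#' `fidelity = "printed"` reproduces the alternative tabulation verbatim
#' for comparison.
#'
#' @inheritParams icf_e0
#' @param fidelity `"canonical"` or `"printed"`, see Details.
#' @return list with elements `e1..e11`, `e12`, `omega` (same shape as the
#'   broadcast inputs) plus the attributes of the call.
#' @export
icf_eterms <- function(coeffs, x = 1, y = 1,
                       fidelity = c("canonical", "printed")) {
  fidelity <- match.arg(fidelity)
  a2 <- coeffs$alpha2; a3 <- coeffs$alpha3
  e1 <- 3 * (x^2 * y / 2 + x * y^2 / 2) - 2 * x * y
  e2 <- -(x^2 * y / 2 + x * y^2 / 2) + 2 * x * y
  e3 <- 1.5 * a3^2 - a3 * a2 +
    (if (fidelity == "printed") a3^2 else a2^2) / 6
  e4 <- x^5 * y / 5 + 0.5 * x^4 * y^2 + (2 / 3) * x^3 * y^3 +
    0.5 * x^2 * y^4 + x * y^5 / 5
  cross5 <- if (fidelity == "printed") 10 / 3 else 16 / 3
  e5 <- -4 * a3^2 + cross5 * a3 * a2 - (4 / 3) * a2^2
  sgn6 <- if (fidelity == "printed") -1 else 1
  e6 <- x^4 * y / 4 + x^3 * y^2 / 2 + x^2 * y^3 / 2 + sgn6 * x * y^4 / 4
  e7 <- 2 * a3^2 - 10 * a3 * a2 + 4 * a2^2
  e8 <- x^3 * y / 3 + x^2 * y^2 / 2 + x * y^3 / 3
  e9 <- 2 * a3^2 + (22 / 3) * a3 * a2 - (16 / 3) * a2^2
  e10 <- x^2 * y / 2 + x * y^2 / 2
  e11 <- (-(4 / 3) * a3^2 - (4 / 3) * a3 * a2 + (8 / 3) * a2^2) * (x * y)
  e12 <- 4 * (-2 * a3 + 2 * a2)
  omega <- 4 * (e3 * e4 + e5 * e6 + e7 * e8 + e9 * e10 + e11)
  list(e1 = e1, e2 = e2, e3 = e3, e4 = e4, e5 = e5, e6 = e6, e7 = e7,
       e8 = e8, e9 = e9, e10 = e10, e11 = e11, e12 = e12, omega = omega)
}

#' Intensity-curvature term after interpolation
#'
#' \eqn{E_{IN}(x,y)} integrates, over \eqn{[0,x] \times [0,y]}, the product
#' of the resampled model \eqn{h_4} and its classic-curvature. The closed
#' form is
#' \deqn{E_{IN} = 4 f(0,0) (\alpha_3 e_1 + \alpha_2 e_2) + \omega.}
#' `mode = "integrated"` instead evaluates the defining double integral by
#' adaptive quadrature ([pracma::integral2()]); it is slower and scalar-only
#' but serves as a ground-truth oracle for the closed form.
#'
#' @inheritParams icf_eterms
#' @param f00 pixel intensity (scalar or matrix; scalar only for
#'   `mode = "integrated"`).
#' @param mode `"closed"` (vectorised closed form) or `"integrated"`.
#' @export
icf_ein <- function(f00, coeffs, x = 1, y = 1,
                    mode = c("closed", "integrated"),
                    fidelity = c("canonical", "printed")) {
  mode <- match.arg(mode)
  fidelity <- match.arg(fidelity)
  if (mode == "closed") {
    tm <- icf_eterms(coeffs, x, y, fidelity)
    return(4 * f00 * (coeffs$alpha3 * tm$e1 + coeffs$alpha2 * tm$e2) + tm$omega)
  }
  stopifnot(length(f00) == 1L, length(coeffs$alpha2) == 1L,
            length(coeffs$alpha3) == 1L, length(x) == 1L, length(y) == 1L)
  if (x == 0 || y == 0) return(0)
  integrand <- function(u, v) {
    4 * h4_eval(coeffs, f00, u, v) * h4_deriv2(coeffs, u, v)
  }
  res <- pracma::integral2(integrand, 0, x, 0, y,
                           reltol = 1e-10, maxlist = 10000)
  if (!is.finite(res$Q))
    stop("quadrature for the integrated intensity-curvature term did not converge",
         call. = FALSE)
  res$Q
}

#' Behaviour decomposition of the ICF
#'
#' Splits the ICF into the three convolution-driven components of its
#' canonical representation
#' \deqn{\Delta E = \frac{f(0,0)\,\zeta}{f(0,0)\,\gamma + \lambda}}
#' with \eqn{\zeta = e_{12}}, \eqn{\gamma = 4(\alpha_3 e_1 + \alpha_2 e_2)}
#' and \eqn{\lambda = \omega}. The numerical prevalence of these components
#' over the pixel intensity determines whether the ICF image looks like the
#' departing image or like a high-pass filtered signal.
#'
#' @inheritParams icf_eterms
#' @return list with `zeta`, `gamma`, `lam` (same shape as the inputs).
#' @export
icf_decomposition <- function(coeffs, x = 1, y = 1,
                              fidelity = c("canonical", "printed")) {
  tm <- icf_eterms(coeffs, x, y, match.arg(fidelity))
  list(zeta = tm$e12,
       gamma = 4 * (coeffs$alpha3 * tm$e1 + coeffs$alpha2 * tm$e2),
       lam = tm$omega)
}

#' Per-pixel ICF maps of an image
#'
#' Computes, for every pixel, the intensity-curvature terms \eqn{E_0} and
#' \eqn{E_{IN}}, their ratio \eqn{\Delta E = E_0 / E_{IN}} (the ICF image),
#' and the transfer function \eqn{TF = \Delta E / f(0,0)}. Pixels whose
#' denominator magnitude falls below `tol` are set to zero and flagged:
#' flat neighbourhoods carry no curvature signal, matching the null
#' response of a high-pass filter to constant input.
#'
#' @param image numeric intensity matrix.
#' @param x,y intra-pixel evaluation point of the ICF polynomials
#'   (default `(1, 1)`, the unit-pixel corner).
#' @param tol degeneracy tolerance for the denominators; default
#'   `1e-12 * diff(range(image))^2` (with a tiny positive floor so constant
#'   images are fully degenerate).
#' @param fidelity passed to [icf_eterms()].
#' @param neighbor_mode passed to [coefficient_maps()].
#' @return object of class `icf_result`: list with matrices `e0`, `ein`,
#'   `delta_e`, `tf`, logical masks `degenerate` (`|EIN| < tol`) and
#'   `tf_degenerate` (`|f00| < tol`, additionally zeroed in `tf`), the
#'   coefficient maps `alpha2`, `alpha3`, and the settings used.
#' @examples
#' img <- synth_image(synth_spec("sphere", size = c(32, 32)))
#' res <- icf_image(img)
#' range(res$delta_e)
#' @export
icf_image <- function(image, x = 1, y = 1, tol = NULL,
                      fidelity = c("canonical", "printed"),
                      neighbor_mode = c("nearest", "bilinear")) {
  assert_image(image)
  fidelity <- match.arg(fidelity)
  neighbor_mode <- match.arg(neighbor_mode)
  if (is.null(tol)) {
    rng <- diff(range(image))
    tol <- max(1e-12 * rng^2, .Machine$double.xmin)
  }
  stopifnot(tol > 0)
  co <- coefficient_maps(image, neighbor_mode)
  e0 <- icf_e0(image, co, x, y)
  ein <- icf_ein(image, co, x, y, mode = "closed", fidelity = fidelity)
  degenerate <- abs(ein) < tol
  delta_e <- array(0, dim(image))
  delta_e[!degenerate] <- e0[!degenerate] / ein[!degenerate]
  tf_degenerate <- abs(image) < tol
  tf <- array(0, dim(image))
  ok <- !degenerate & !tf_degenerate
  tf[ok] <- delta_e[ok] / image[ok]
  structure(list(e0 = e0, ein = ein, delta_e = delta_e, tf = tf,
                 degenerate = degenerate, tf_degenerate = tf_degenerate,
                 alpha2 = co$alpha2, alpha3 = co$alpha3,
                 point = c(x = x, y = y), tol = tol,
                 fidelity = fidelity, neighbor_mode = neighbor_mode),
            class = "icf_result")
}

#' @export
print.icf_result <- function(x, ...) {
  cat(sprintf("ICF result: %d x %d pixels, evaluation point (%g, %g), %s mode\n",
              nrow(x$delta_e), ncol(x$delta_e), x$point[["x"]], x$point[["y"]],
              x$fidelity))
  cat(sprintf("  delta_e range [%.6g, %.6g], %d degenerate pixels (%.1f%%)\n",
              min(x$delta_e), max(x$delta_e), sum(x$degenerate),
              100 * mean(x$degenerate)))
  invisible(x)
}

#' Filter output and input functions of the ICF-based high-pass filter
#'
#' The transfer function \eqn{TF = Y/X = \Delta E / f(0,0)} yields the
#' output sample
#' \deqn{y[n] = \frac{x[n] e_{12}}{4 (x[n] \alpha_3 e_1 + x[n] \alpha_2 e_2) + \omega}}
#' and, solving for the input, the algebraic inverse
#' \deqn{x[n] = \frac{\omega \, y[n]}{e_{12} - 4 y[n] (\alpha_3 e_1 + \alpha_2 e_2)}.}
#' Feeding `xn = f00` to `icf_filter_output()` reproduces \eqn{\Delta E} at
#' evaluation points with \eqn{x y = 1} (the default).
#'
#' @param xn filter input sample (the pixel intensity).
#' @param yn filter output sample.
#' @param coeffs list with `alpha2`, `alpha3`.
#' @param terms e-terms from [icf_eterms()] at the same evaluation point.
#' @param tol magnitude below which the denominator marks the sample
#'   degenerate (returned as `NA`).
#' @return numeric, `NA` where the denominator is degenerate.
#' @export
icf_filter_output <- function(xn, coeffs, terms, tol = .Machine$double.xmin) {
  den <- 4 * (xn * coeffs$alpha3 * terms$e1 + xn * coeffs$alpha2 * terms$e2) +
    terms$omega
  out <- xn * terms$e12 / den
  out[abs(den) < tol] <- NA_real_
  out
}

#' @rdname icf_filter_output
#' @export
icf_filter_input <- function(yn, coeffs, terms, tol = .Machine$double.xmin) {
  den <- terms$e12 -
    4 * yn * (coeffs$alpha3 * terms$e1 + coeffs$alpha2 * terms$e2)
  out <- terms$omega * yn / den
  out[abs(den) < tol] <- NA_real_
  out
}

#' Image-like versus gradient-like classification of the ICF
#'
#' Labels each pixel by the numerical prevalence of the convolution
#' components \eqn{\zeta, \gamma, \lambda} over the pixel intensity
#' \eqn{f(0,0)}, following the characterization table of prevalence
#' patterns. A
#' component is "largely smaller" (\eqn{\ll}) than the intensity when
#' \eqn{|f(0,0)| \ge factor \cdot |component|}, and "largely bigger"
#' (\eqn{\gg}) when \eqn{|component| \ge factor \cdot |f(0,0)|}. The eight
#' definite prevalence patterns map to:
#' \itemize{
#' \item image-like: all three \eqn{\ll}; or \eqn{\zeta \gg, \gamma \gg,
#'   \lambda \ll} (the intensity cancels and the ICF reduces to
#'   \eqn{\zeta/\gamma});
#' \item gradient-like: the remaining six patterns in which the prevalence
#'   is mixed or fully reversed.
#' }
#' Every other combination (some component neither largely smaller nor
#' largely bigger) is `indeterminate`.
#'
#' @param f00 pixel intensity (scalar or matrix).
#' @param zeta,gamma,lam decomposition components, e.g. from
#'   [icf_decomposition()].
#' @param factor prevalence factor defining "largely" (> 1; default 10).
#' @return character vector/matrix with values `"image-like"`,
#'   `"gradient-like"`, `"indeterminate"`.
#' @export
classify_icf_behavior <- function(f00, zeta, gamma, lam, factor = 10) {
  stopifnot(factor > 1)
  sm <- function(v) abs(f00) >= factor * abs(v)   # v << f00
  bg <- function(v) abs(v) >= factor * abs(f00)   # v >> f00
  sz <- sm(zeta); sg <- sm(gamma); sl <- sm(lam)
  bz <- bg(zeta); bge <- bg(gamma); bl <- bg(lam)
  image_like <- (sz & sg & sl) | (bz & bge & sl)
  gradient_like <- (bz & sg & sl) | (sz & bge & sl) | (sz & sg & bl) |
    (sz & bge & bl) | (bz & sg & bl) | (bz & bge & bl)
  out <- array("indeterminate", dim = dim(as.array(f00 + zeta + gamma + lam)))
  out[gradient_like] <- "gradient-like"
  out[image_like] <- "image-like"
  if (is.matrix(f00)) dim(out) <- dim(f00) else out <- as.vector(out)
  out
}

#' @rdname classify_icf_behavior
#' @param image intensity matrix; the decomposition is computed per pixel.
#' @param x,y,fidelity,neighbor_mode forwarded to the engine.
#' @return `classify_icf_map()` returns a character matrix of labels.
#' @export
classify_icf_map <- function(image, x = 1, y = 1, factor = 10,
                             fidelity = c("canonical", "printed"),
                             neighbor_mode = c("nearest", "bilinear")) {
  assert_image(image)
  co <- coefficient_maps(image, match.arg(neighbor_mode))
  dec <- icf_decomposition(co, x, y, match.arg(fidelity))
  classify_icf_behavior(image, dec$zeta, dec$gamma, dec$lam, factor)
}
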