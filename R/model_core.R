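#' Bivariate cubic B-spline model function and its derivatives
#'
#' The model fitted at each pixel is
#' \deqn{h_4(x, y) = f(0,0) + \alpha_3 [\tfrac12 s^3 - s^2 + \tfrac23]
#'       + \alpha_2 [-\tfrac16 s^3 + s^2 - 2 s + \tfrac43], \quad s = x + y,}
#' where \eqn{f(0,0)} is the pixel intensity and the coefficients are the
#' diagonal finite differences
#' \eqn{\alpha_2 = f(0,0) - f(1/2, 1/2)},
#' \eqn{\alpha_3 = f(0,0) - f(-1/2, -1/2)}.
#' The intra-pixel coordinates \eqn{(x, y)} are measured from the pixel
#' centre in pixel units; the model depends on them only through the sum
#' \eqn{s = x + y}.
#'
#' @param f00 pixel intensity at the origin of the pixel coordinate system.
#' @param f_plus intensity sampled at the (+1/2, +1/2) diagonal neighbour.
#' @param f_minus intensity sampled at the (-1/2, -1/2) diagonal neighbour.
#' @return `spline_coefficients()` returns a list with elements `alpha2` and
#'   `alpha3` (same shape as the inputs).
#' @examples
#' co <- spline_coefficients(5, 3, 5)     # alpha2 = 2, alpha3 = 0
#' h4_eval(co, f00 = 5, x = 0, y = 0)
#' @export
spline_coefficients <- function(f00, f_plus, f_minus) {
  if (!all(is.finite(f00), is.finite(f_plus), is.finite(f_minus)))
    stop("neighborhood intensities must all be finite", call. = FALSE)
  list(alpha2 = f00 - f_plus, alpha3 = f00 - f_minus)
}

#' @rdname spline_coefficients
#' @param coeffs list with numeric `alpha2`, `alpha3` as returned by
#'   [spline_coefficients()]; vectors/matrices are accepted and recycled
#'   against `x + y`.
#' @param x,y intra-pixel evaluation coordinates (pixel units).
#' @export
h4_eval <- function(coeffs, f00, x, y) {
  s <- x + y
  f00 +
    coeffs$alpha3 * (0.5 * s^3 - s^2 + 2 / 3) +
    coeffs$alpha2 * (-s^3 / 6 + s^2 - 2 * s + 4 / 3)
}

#' @rdname spline_coefficients
#' @details `h4_deriv1()` is the common value of the two first partial
#'   derivatives (they coincide because the model is a function of
#'   \eqn{x + y}); `h4_deriv2()` is the common value of all four second
#'   partials, which at the origin reduces to
#'   \eqn{-2\alpha_3 + 2\alpha_2}.
#' @export
h4_deriv1 <- function(coeffs, x, y) {
  s <- x + y
  coeffs$alpha3 * (1.5 * s^2 - 2 * s) +
    coeffs$alpha2 * (-0.5 * s^2 + 2 * s - 2)
}

#' @rdname spline_coefficients
#' @export
h4_deriv2 <- function(coeffs, x, y) {
  s <- x + y
  coeffs$alpha3 * (3 * s - 2) + coeffs$alpha2 * (-s + 2)
}

# Diagonal-neighbour sampling for a whole image with mirror padding.
# mode "nearest": f_plus = image[r+1, c+1], f_minus = image[r-1, c-1].
# mode "bilinear": interpolate at the true (+-1/2, +-1/2) offsets, i.e. the
# mean of the 2x2 block between the pixel and its diagonal neighbour.
#' Diagonal finite-difference coefficient maps for an image
#'
#' Computes the per-pixel model coefficients \eqn{\alpha_2, \alpha_3} for a
#' whole image, using one pixel of mirror (reflect) padding so border
#' coefficients stay finite and vanish on flat borders.
#'
#' @param image numeric matrix of intensities.
#' @param neighbor_mode `"nearest"` samples the nearest diagonal pixels;
#'   `"bilinear"` interpolates the half-pixel offsets (mean of the
#'   2x2 block straddling the offset).
#' @return list with matrices `alpha2`, `alpha3` the size of `image`.
#' @export
coefficient_maps <- function(image, neighbor_mode = c("nearest", "bilinear")) {
  assert_image(image)
  neighbor_mode <- match.arg(neighbor_mode)
  nr <- nrow(image); nc <- ncol(image)
  p <- mirror_pad(image, 1L)
  if (neighbor_mode == "nearest") {
    f_plus  <- p[3:(nr + 2), 3:(nc + 2), drop = FALSE]
    f_minus <- p[1:nr, 1:nc, drop = FALSE]
  } else {
    ctr <- p[2:(nr + 1), 2:(nc + 1), drop = FALSE]
    f_plus <- (ctr +
                 p[2:(nr + 1), 3:(nc + 2), drop = FALSE] +
                 p[3:(nr + 2), 2:(nc + 1), drop = FALSE] +
                 p[3:(nr + 2), 3:(nc + 2), drop = FALSE]) / 4
    f_minus <- (ctr +
                  p[2:(nr + 1), 1:nc, drop = FALSE] +
                  p[1:nr, 2:(nc + 1), drop = FALSE] +
                  p[1:nr, 1:nc, drop = FALSE]) / 4
  }
  spline_coefficients(image, f_plus, f_minus)
}
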