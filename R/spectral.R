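#' k-space magnitude of an image
#'
#' Unnormalised forward 2D discrete Fourier transform with the DC bin
#' shifted to the grid centre, plus the magnitude and a `log(1+magnitude)`
#' display companion. For a real image the magnitude is symmetric under
#' point reflection about the DC bin (Hermitian symmetry).
#'
#' @param image numeric matrix.
#' @return object of class `kspace_grid`: list with `spectrum` (complex,
#'   DC-centred), `magnitude`, `log_magnitude`.
#' @examples
#' ks <- kspace_magnitude(matrix(1, 8, 8))
#' ks$magnitude[5, 5]   # DC bin: 1 * 8^2
#' @export
kspace_magnitude <- function(image) {
  assert_image(image)
  sp <- fftshift2(stats::fft(image))
  structure(list(spectrum = sp,
                 magnitude = Mod(sp),
                 log_magnitude = log1p(Mod(sp))),
            class = "kspace_grid")
}

#' @export
print.kspace_grid <- function(x, ...) {
  cat(sprintf("k-space grid %d x %d, peak magnitude %.6g\n",
              nrow(x$magnitude), ncol(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Inverse-Fourier reconstruction through a filter image
#'
#' Treats the input image (typically an ICF or high-pass filtered map) as
#' real-valued k-space data with DC at the centre, un-shifts it, applies
#' the inverse transform (normalised by 1/N), and returns the modulus
#' image -- the "reconstruction through" the filter. A complex matrix is
#' accepted too, so a round trip through [kspace_magnitude()]'s `spectrum`
#' recovers the original image.
#'
#' @param filter_image real (or complex) matrix interpreted as centred
#'   k-space data.
#' @param mode `"modulus"` (default) or `"real_part"` of the inverse
#'   transform.
#' @return real matrix, same shape.
#' @export
kspace_reconstruct <- function(filter_image, mode = c("modulus", "real_part")) {
  mode <- match.arg(mode)
  if (!is.matrix(filter_image) || length(filter_image) == 0L)
    stop("`filter_image` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(Re(filter_image))) || !all(is.finite(Im(filter_image))))
    stop("`filter_image` contains non-finite values", call. = FALSE)
  rec <- stats::fft(ifftshift2(filter_image), inverse = TRUE) / length(filter_image)
  if (mode == "modulus") Mod(rec) else Re(rec)
}

#' Element-wise difference map between two images
#'
#' @param a,b same-shape numeric matrices.
#' @return `a - b`.
#' @export
difference_map <- function(a, b) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("`a` and `b` must have the same shape", call. = FALSE)
  a - b
}

#' Fraction of spectral energy in the central low-frequency band
#'
#' Operational high-pass measure: the share of total spectral energy
#' (squared magnitude) inside the central band of bins around DC, spanning
#' 1/`band` of the bins per axis (default 1/8).
#'
#' @param image numeric matrix.
#' @param band band denominator; the band spans `ceiling(n/band)` bins per
#'   axis, centred on the DC bin.
#' @return scalar in `[0, 1]` (`NaN` for an all-zero image).
#' @export
lowfreq_energy_fraction <- function(image, band = 8L) {
  ks <- kspace_magnitude(image)
  p <- ks$magnitude^2
  nr <- nrow(p); nc <- ncol(p)
  cr <- floor(nr / 2) + 1L; cc <- floor(nc / 2) + 1L
  hr <- max(1L, ceiling(nr / band)) ; hc <- max(1L, ceiling(nc / band))
  rows <- max(1L, cr - hr %/% 2L):min(nr, cr + (hr - 1L) %/% 2L)
  cols <- max(1L, cc - hc %/% 2L):min(nc, cc + (hc - 1L) %/% 2L)
  sum(p[rows, cols]) / sum(p)
}
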