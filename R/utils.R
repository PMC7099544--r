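# internal helpers shared across modules

#' @keywords internal
assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (length(image) == 0L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(image)
}

# Mirror (reflect) padding by `k` pixels on every side. The edge row/column is
# not repeated: pad row 0 mirrors row 2 (OpenCV BORDER_REFLECT_101). Constant
# borders therefore yield zero finite differences.
#' @keywords internal
mirror_pad <- function(image, k = 1L) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- reflect_index(nr, k)
  ci <- reflect_index(nc, k)
  image[ri, ci, drop = FALSE]
}

#' @keywords internal
reflect_index <- function(n, k) {
  if (n == 1L) return(rep(1L, n + 2L * k))
  base <- seq.int(-k, n - 1L + k)
  period <- 2L * (n - 1L)
  m <- base %% period
  m <- ifelse(m >= n, period - m, m)
  m + 1L
}

# fftshift / ifftshift for matrices: move the DC bin (1,1) to the grid centre
# (floor(n/2)+1) and back; exact inverses for odd sizes too.
#' @keywords internal
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[shift_index(nr, inverse = FALSE), shift_index(nc, inverse = FALSE), drop = FALSE]
}

#' @keywords internal
ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[shift_index(nr, inverse = TRUE), shift_index(nc, inverse = TRUE), drop = FALSE]
}

#' @keywords internal
shift_index <- function(n, inverse) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c((h + 1L):n, 1L:h)
}

# Affine min-max rescale to [0, 1]; constant inputs map to 0.
#' @keywords internal
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}
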