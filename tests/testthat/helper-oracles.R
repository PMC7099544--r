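# Independent scalar oracles used to cross-check the vectorised engine.

# Reflect an out-of-range index back into 1..n (edge not repeated), matching
# one-pixel mirror padding.
reflect1 <- function(i, n) {
  if (i < 1L) 2L - i else if (i > n) 2L * n - i else i
}

# Brute-force per-pixel ICF: explicit neighbour indexing and adaptive 2D
# quadrature of the defining integrand (no shared code with the closed-form
# engine path).
icf_oracle <- function(img, x = 1, y = 1, tol = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(tol)) tol <- max(1e-12 * diff(range(img))^2, .Machine$double.xmin)
  de <- matrix(0, nr, nc)
  deg <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      f0 <- img[r, c]
      a2 <- f0 - img[reflect1(r + 1L, nr), reflect1(c + 1L, nc)]
      a3 <- f0 - img[reflect1(r - 1L, nr), reflect1(c - 1L, nc)]
      e0 <- 4 * x * y * f0 * (-2 * a3 + 2 * a2)
      h4 <- function(u, v) {
        s <- u + v
        f0 + a3 * (0.5 * s^3 - s^2 + 2 / 3) +
          a2 * (-s^3 / 6 + s^2 - 2 * s + 4 / 3)
      }
      curv <- function(u, v) {
        s <- u + v
        a3 * (3 * s - 2) + a2 * (-s + 2)
      }
      ein <- if (a2 == 0 && a3 == 0) 0 else
        pracma::integral2(function(u, v) 4 * h4(u, v) * curv(u, v),
                          0, x, 0, y, reltol = 1e-10)$Q
      if (abs(ein) < tol) deg[r, c] <- TRUE else de[r, c] <- e0 / ein
    }
  }
  list(delta_e = de, degenerate = deg)
}

# Central finite difference of a scalar function of one displacement.
central_diff <- function(f, h = 1e-5) (f(h) - f(-h)) / (2 * h)

# Randomised spline coefficient draw.
random_coeffs <- function() {
  list(alpha2 = stats::runif(1, -10, 10), alpha3 = stats::runif(1, -10, 10))
}
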