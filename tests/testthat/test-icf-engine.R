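test_that("pre-interpolation curvature term follows its closed form", {
  expect_equal(icf_e0(1, list(alpha2 = 1, alpha3 = 0), 1, 1), 8)
  expect_equal(icf_e0(17, list(alpha2 = 3, alpha3 = 3), 0.7, 0.2), 0)
  expect_equal(icf_e0(2, list(alpha2 = 0, alpha3 = 1), 0.5, 0.5), -4)
})

test_that("e-terms evaluate their polynomials and quadratic forms", {
  co <- list(alpha2 = 1, alpha3 = 0)
  tm <- icf_eterms(co, 1, 1)
  expect_equal(tm$e1, 1)
  expect_equal(tm$e2, 1)
  expect_equal(tm$e12, 8)
  tm0 <- icf_eterms(list(alpha2 = 0, alpha3 = 0), 0.3, 1.7)
  expect_equal(tm0$omega, 0)   # all omega summands quadratic in the alphas
  expect_equal(tm0$e12, 0)
  # e12 is linear in the coefficient difference
  set.seed(21)
  for (i in 1:10) {
    co <- random_coeffs()
    expect_equal(icf_eterms(co)$e12, 4 * (-2 * co$alpha3 + 2 * co$alpha2))
  }
})

test_that("printed fidelity reproduces the published slips, canonical the integral", {
  co <- list(alpha2 = 2, alpha3 = -1)
  can <- icf_eterms(co, 1, 1, "canonical")
  pri <- icf_eterms(co, 1, 1, "printed")
  expect_equal(pri$e3 - can$e3, (co$alpha3^2 - co$alpha2^2) / 6)
  expect_equal(pri$e5 - can$e5, (10 / 3 - 16 / 3) * co$alpha3 * co$alpha2)
  expect_equal(pri$e6 - can$e6, -2 * 1 / 4)   # sign flip of x*y^4/4 at (1,1)
  # canonical closed form matches adaptive quadrature of the definition
  set.seed(22)
  for (i in 1:10) {
    co <- random_coeffs()
    f0 <- stats::runif(1, 0, 50)
    closed <- icf_ein(f0, co, 1, 1, "closed", "canonical")
    quad <- icf_ein(f0, co, 1, 1, "integrated")
    expect_equal(closed, quad, tolerance = 1e-6)
  }
  # and at non-unit evaluation points
  q <- icf_ein(3, co, 0.6, 1.3, "integrated")
  expect_equal(icf_ein(3, co, 0.6, 1.3, "closed"), q, tolerance = 1e-6)
})

test_that("post-interpolation term vanishes for a flat neighbourhood", {
  expect_equal(icf_ein(42, list(alpha2 = 0, alpha3 = 0), 1, 1), 0)
  expect_equal(icf_ein(42, list(alpha2 = 0, alpha3 = 0), 1, 1,
                       "integrated"), 0)
})

test_that("ICF image handles constant, impulse and ramp inputs", {
  cst <- matrix(7, 8, 8)
  rc <- icf_image(cst)
  expect_true(all(rc$degenerate))
  expect_true(all(rc$delta_e == 0))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 10
  ri <- icf_image(imp)
  touched <- abs(ri$delta_e) > 0
  # only pixels whose diagonal reach touches the impulse can respond
  expect_true(all(which(touched, arr.ind = TRUE)[, 1] %in% 4:6))
  expect_true(all(which(touched, arr.ind = TRUE)[, 2] %in% 4:6))
  expect_true(ri$degenerate[1, 1])

  ramp <- outer(0:7, 0:7, `+`) * 1.0
  rr <- icf_image(ramp)
  oracle <- icf_oracle(ramp)
  nd <- !rr$degenerate
  expect_equal(rr$degenerate, oracle$degenerate)
  expect_equal(rr$delta_e[nd], oracle$delta_e[nd], tolerance = 1e-8)
})

test_that("maps keep the image shape and contain no non-finite values", {
  img <- synth_image(synth_spec("vessel_phantom", size = c(24, 40)))
  res <- icf_image(img)
  for (f in list(res$e0, res$ein, res$delta_e, res$tf)) {
    expect_identical(dim(f), dim(img))
    expect_true(all(is.finite(f)))
  }
  expect_identical(res$degenerate, abs(res$ein) < res$tol)
  nd <- !res$degenerate
  expect_equal(res$delta_e[nd], res$e0[nd] / res$ein[nd])
  ok <- nd & !res$tf_degenerate
  expect_equal(res$tf[ok], res$delta_e[ok] / img[ok])
})

test_that("ICF is invariant under global intensity scaling", {
  img <- synth_image(synth_spec("torus", size = c(32, 32)))
  r1 <- icf_image(img)
  r2 <- icf_image(img * 7.3)
  expect_identical(r1$degenerate, r2$degenerate)
  nd <- !r1$degenerate
  expect_equal(r2$delta_e[nd], r1$delta_e[nd], tolerance = 1e-9)
})

test_that("filter output reproduces the ICF and inverts exactly", {
  img <- synth_image(synth_spec("sphere", size = c(24, 24)))
  res <- icf_image(img)
  co <- coefficient_maps(img)
  tm <- icf_eterms(co)
  y <- icf_filter_output(img, co, tm)
  nd <- !res$degenerate & !is.na(y)
  expect_equal(y[nd], res$delta_e[nd], tolerance = 1e-12)
  xr <- icf_filter_input(y, co, tm)
  ok <- nd & !is.na(xr)
  expect_gt(sum(ok), 0)
  expect_equal(xr[ok], img[ok], tolerance = 1e-9)
  # degenerate signal flags
  z <- list(alpha2 = 0, alpha3 = 0)
  tz <- icf_eterms(z)
  expect_true(is.na(icf_filter_output(5, z, tz)))
  # zero output maps to zero input when e12 is nonzero
  co1 <- list(alpha2 = 1, alpha3 = 0)
  expect_equal(icf_filter_input(0, co1, icf_eterms(co1)), 0)
})

test_that("decomposition reconstructs the ICF ratio at unit evaluation point", {
  img <- synth_image(synth_spec("ellipse", size = c(32, 32)))
  res <- icf_image(img)
  co <- coefficient_maps(img)
  dec <- icf_decomposition(co)
  nd <- !res$degenerate
  lhs <- img[nd] * dec$zeta[nd] / (img[nd] * dec$gamma[nd] + dec$lam[nd])
  expect_equal(lhs, res$delta_e[nd], tolerance = 1e-9)
  expect_equal(dec$zeta, icf_eterms(co)$e12)
})

test_that("behaviour classifier follows the characterization table", {
  f <- 10
  # definite columns: (zeta, gamma, lam) prevalence -> label
  cases <- list(
    list(z = 1,    g = 1,    l = 1,    lab = "image-like"),     # all <<
    list(z = 1e4,  g = 1,    l = 1,    lab = "gradient-like"),  # zeta >>
    list(z = 1,    g = 1e4,  l = 1,    lab = "gradient-like"),  # gamma >>
    list(z = 1,    g = 1,    l = 1e4,  lab = "gradient-like"),  # lam >>
    list(z = 1e4,  g = 1e4,  l = 1,    lab = "image-like"),     # zeta,gamma >>
    list(z = 1,    g = 1e4,  l = 1e4,  lab = "gradient-like"),
    list(z = 1e4,  g = 1,    l = 1e4,  lab = "gradient-like"),
    list(z = 1e4,  g = 1e4,  l = 1e4,  lab = "gradient-like"))  # all >>
  f00 <- 1000  # components at 1 are << f00; at 1e4 are >> f00, factor 10
  for (cs in cases)
    expect_identical(
      classify_icf_behavior(f00, cs$z, cs$g, cs$l, factor = f), cs$lab)
  # mixed magnitudes with no definite prevalence
  expect_identical(classify_icf_behavior(1, 2, 2, 2, factor = f),
                   "indeterminate")
  # signs do not matter, only magnitudes
  expect_identical(classify_icf_behavior(-1000, -1, 1, -1, factor = f),
                   "image-like")
  # matrix input keeps shape
  lab <- classify_icf_behavior(matrix(1000, 2, 2), matrix(1, 2, 2),
                               matrix(1, 2, 2), matrix(1, 2, 2))
  expect_identical(dim(lab), c(2L, 2L))
  expect_true(all(lab == "image-like"))
})
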