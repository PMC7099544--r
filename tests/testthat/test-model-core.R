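test_that("spline coefficients are the diagonal finite differences", {
  expect_equal(spline_coefficients(5, 3, 5), list(alpha2 = 2, alpha3 = 0))
  expect_equal(spline_coefficients(7, 7, 7), list(alpha2 = 0, alpha3 = 0))
  expect_equal(spline_coefficients(0, 7, -7), list(alpha2 = -7, alpha3 = 7))
  expect_error(spline_coefficients(NA_real_, 1, 2), "finite")
  expect_error(spline_coefficients(1, Inf, 2), "finite")
})

test_that("model function evaluates its bracket constants at the origin", {
  expect_equal(h4_eval(list(alpha2 = 0, alpha3 = 0), 1, 0.3, -0.7), 1)
  expect_equal(h4_eval(list(alpha2 = 0, alpha3 = 1), 0, 0, 0), 2 / 3)
  expect_equal(h4_eval(list(alpha2 = 1, alpha3 = 0), 0, 0, 0), 4 / 3)
})

test_that("first derivative constant term and zero cases", {
  expect_equal(h4_deriv1(list(alpha2 = 1, alpha3 = 0), 0, 0), -2)
  expect_equal(h4_deriv1(list(alpha2 = 0, alpha3 = 0), 0.4, 1.1), 0)
})

test_that("second derivative direct substitutions", {
  expect_equal(h4_deriv2(list(alpha2 = 2, alpha3 = 1), 0, 0), 2)
  expect_equal(h4_deriv2(list(alpha2 = 0, alpha3 = 0), 0.2, 0.9), 0)
  expect_equal(h4_deriv2(list(alpha2 = 1, alpha3 = 1), 1, 1), 4)
})

test_that("analytic derivatives match central finite differences of the model", {
  set.seed(11)
  for (i in 1:50) {
    co <- random_coeffs()
    f0 <- stats::runif(1, -5, 50)
    x0 <- stats::runif(1, -1, 1); y0 <- stats::runif(1, -1, 1)
    d1 <- h4_deriv1(co, x0, y0)
    fd_x <- central_diff(function(h) h4_eval(co, f0, x0 + h, y0))
    fd_y <- central_diff(function(h) h4_eval(co, f0, x0, y0 + h))
    expect_equal(fd_x, d1, tolerance = 1e-6)
    expect_equal(fd_y, d1, tolerance = 1e-6)
    d2 <- h4_deriv2(co, x0, y0)
    fd_xx <- central_diff(function(h) h4_deriv1(co, x0 + h, y0))
    fd_xy <- central_diff(function(h) h4_deriv1(co, x0, y0 + h))
    expect_equal(fd_xx, d2, tolerance = 1e-6)
    expect_equal(fd_xy, d2, tolerance = 1e-6)
  }
})

test_that("model depends on (x, y) only through their sum, and is linear", {
  set.seed(12)
  for (i in 1:25) {
    co <- random_coeffs()
    f0 <- stats::runif(1, 0, 10)
    s <- stats::runif(1, -2, 2)
    t <- stats::runif(1, -1, 1)
    expect_equal(h4_eval(co, f0, s - t, t), h4_eval(co, f0, s, 0))
    a <- stats::runif(1, -3, 3)
    scaled <- list(alpha2 = a * co$alpha2, alpha3 = a * co$alpha3)
    expect_equal(h4_eval(scaled, a * f0, s, t), a * h4_eval(co, f0, s, t))
  }
})

test_that("coefficient maps index diagonal neighbours with mirror padding", {
  img <- matrix(as.numeric(1:12), 3, 4)
  co <- coefficient_maps(img)
  # interior pixel (2,2): f00 = 5, f_plus = img[3,3] = 9, f_minus = img[1,1] = 1
  expect_equal(co$alpha2[2, 2], 5 - 9)
  expect_equal(co$alpha3[2, 2], 5 - 1)
  # corner (1,1): mirror reflects to img[2,2] on both sides
  expect_equal(co$alpha2[1, 1], img[1, 1] - img[2, 2])
  expect_equal(co$alpha3[1, 1], img[1, 1] - img[2, 2])
  # constant image: all coefficients vanish, both modes
  cst <- matrix(3, 5, 5)
  for (m in c("nearest", "bilinear")) {
    cm <- coefficient_maps(cst, m)
    expect_true(all(cm$alpha2 == 0) && all(cm$alpha3 == 0))
  }
  # bilinear mode averages the 2x2 block at the half-pixel offset
  cb <- coefficient_maps(img, "bilinear")
  expect_equal(cb$alpha2[2, 2], 5 - mean(img[2:3, 2:3]))
  expect_equal(cb$alpha3[2, 2], 5 - mean(img[1:2, 1:2]))
})
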