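test_that("traditional HPF obeys the convolution contracts", {
  expect_equal(sum(hpf_kernel()), 0)
  cst <- matrix(5, 10, 10)
  expect_true(all(traditional_hpf(cst) == 0))
  # unit impulse reproduces the flipped kernel around the centre
  k <- matrix(c(0, 1, 0, 2, -4, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- traditional_hpf(imp, k)
  expect_equal(out[4:6, 4:6], k[3:1, 3:1])
  expect_true(all(out[-(4:6), ] == 0))
  # symmetric zero-sum kernel annihilates an affine ramp in the interior
  ramp <- outer(1:12, 1:12, `+`) * 1.0
  rr <- traditional_hpf(ramp)
  expect_equal(rr[2:11, 2:11], matrix(0, 10, 10))
  # invalid kernels
  expect_error(traditional_hpf(cst, matrix(1, 2, 2)), "odd")
  expect_error(traditional_hpf(cst, matrix(1, 3, 3)), "sum to zero")
})

test_that("transfer-function map zeroes degenerate input pixels", {
  img <- matrix(c(0, 2, 4, 8), 2, 2)
  out <- matrix(1, 2, 2)
  tf <- transfer_function_map(out, img)
  expect_true(tf$degenerate[1, 1])
  expect_equal(tf$tf[1, 1], 0)
  expect_equal(tf$tf[2, 2], 1 / 8)
})

test_that("PSO is deterministic with monotone global-best cost", {
  img <- synth_image(synth_spec("sphere", size = c(12, 12)))
  tgt <- traditional_hpf(img)
  cfg <- pso_config(n_particles = 10L, n_iterations = 40L, seed = 9L)
  a <- pso_hpf(img, tgt, cfg)
  b <- pso_hpf(img, tgt, cfg)
  expect_identical(a$output, b$output)
  expect_identical(a$state$cost_history, b$state$cost_history)
  expect_true(all(diff(a$state$cost_history) <= 0))
  # per-pixel global best costs never increase either (spot check via rerun
  # with longer budget: prefix history must match)
  long <- pso_hpf(img, tgt, pso_config(n_particles = 10L, n_iterations = 80L,
                                       seed = 9L))
  expect_identical(long$state$cost_history[1:41], a$state$cost_history)
})

test_that("initial particle positions sum exactly to the pixel intensity", {
  img <- synth_image(synth_spec("torus", size = c(10, 14)))
  r <- pso_hpf(img, traditional_hpf(img),
               pso_config(n_particles = 7L, n_iterations = 2L, seed = 3L))
  expect_identical(rowSums(r$state$initial_positions), as.vector(img))
})

test_that("frozen swarm dynamics keep velocity and cost constant", {
  cfg <- pso_config(n_particles = 1L, n_iterations = 6L, inertia = 1,
                    cognitive_weight = 0, social_weight = 0, seed = 5L)
  r <- pso_hpf(matrix(5, 1, 1), matrix(0, 1, 1), cfg)
  expect_equal(length(unique(r$state$cost_history)), 1L)
  expect_equal(r$output[1, 1], r$state$global_best$velocities[1])
})

test_that("PSO rejects malformed inputs and stops early when asked", {
  img <- matrix(1, 4, 4)
  expect_error(pso_hpf(img, matrix(NaN, 4, 4)), "finite")
  expect_error(pso_hpf(img, matrix(0, 2, 2)), "same shape")
  r <- pso_hpf(img, traditional_hpf(img),
               pso_config(n_particles = 5L, n_iterations = 500L,
                          seed = 1L, tolerance = 1e-6))
  expect_lt(r$state$iterations_run, 500L)
})

test_that("PSO output approaches a zero target", {
  img <- synth_image(synth_spec("sphere", size = c(8, 8)))
  r <- pso_hpf(img, matrix(0, 8, 8),
               pso_config(n_particles = 20L, n_iterations = 100L, seed = 2L))
  h <- r$state$cost_history
  expect_lt(h[length(h)], h[1])
  expect_lt(mean(abs(r$output)), mean(abs(img)))
})
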