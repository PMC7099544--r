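#' Traditional convolutional high-pass filter
#'
#' 2D convolution with a zero-sum kernel and mirror padding. The default
#' kernel is the common 3x3 sharpening Laplacian (centre 8, neighbours -1),
#' whose zero sum guarantees a null response to constant input and whose
#' symmetry annihilates affine ramps on interior pixels.
#'
#' @param image numeric intensity matrix.
#' @param kernel odd-sided numeric matrix summing to zero (within 1e-12).
#' @return filtered matrix, same shape as `image`.
#' @examples
#' img <- synth_image(synth_spec("sphere", size = c(32, 32)))
#' hp <- traditional_hpf(img)
#' @export
traditional_hpf <- function(image, kernel = hpf_kernel()) {
  assert_image(image)
  if (!is.matrix(kernel) || nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0)
    stop("kernel must be a matrix with odd side lengths", call. = FALSE)
  if (abs(sum(kernel)) > 1e-12)
    stop("high-pass kernel must sum to zero", call. = FALSE)
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  p <- mirror_pad(image, max(kr, kc))
  off <- max(kr, kc)
  out <- matrix(0, nr, nc)
  # kernel applied as in image processing: the impulse response is the
  # kernel rotated by 180 degrees
  kf <- kernel
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kf[i, j]
      if (w == 0) next
      r0 <- off - kr + i - 1L
      c0 <- off - kc + j - 1L
      out <- out + w * p[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
    }
  }
  out
}

#' @rdname traditional_hpf
#' @export
hpf_kernel <- function() {
  matrix(c(-1, -1, -1,
           -1,  8, -1,
           -1, -1, -1), nrow = 3, byrow = TRUE)
}

#' Transfer-function image of a filtered image
#'
#' Element-wise ratio of filter output to input with the same degenerate
#' handling as the ICF engine: pixels with input magnitude below `tol` are
#' zeroed and flagged.
#'
#' @param filtered,image same-shape matrices (output and input).
#' @param tol degeneracy tolerance; default as in [icf_image()].
#' @return list with matrix `tf` and logical matrix `degenerate`.
#' @export
transfer_function_map <- function(filtered, image, tol = NULL) {
  assert_image(image); assert_image(filtered, "filtered")
  if (!all(dim(filtered) == dim(image)))
    stop("`filtered` and `image` must have the same shape", call. = FALSE)
  if (is.null(tol))
    tol <- max(1e-12 * diff(range(image))^2, .Machine$double.xmin)
  degenerate <- abs(image) < tol
  tf <- array(0, dim(image))
  tf[!degenerate] <- filtered[!degenerate] / image[!degenerate]
  list(tf = tf, degenerate = degenerate)
}

#' PSO configuration
#'
#' @param n_particles particles per pixel (>= 1).
#' @param n_iterations iteration budget (>= 1).
#' @param inertia,cognitive_weight,social_weight non-negative velocity
#'   update weights (defaults 0.72, 1.49, 1.49 -- the widely used
#'   constriction-equivalent setting).
#' @param seed integer fixing all randomness.
#' @param tolerance early-stop threshold: stop when the mean global-best
#'   cost improves by less than this over 10 iterations (0 disables).
#' @return list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 30L, n_iterations = 200L,
                       inertia = 0.72, cognitive_weight = 1.49,
                       social_weight = 1.49, seed = 1L, tolerance = 0) {
  stopifnot(n_particles >= 1, n_iterations >= 1,
            inertia >= 0, cognitive_weight >= 0, social_weight >= 0,
            tolerance >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 inertia = inertia, cognitive_weight = cognitive_weight,
                 social_weight = social_weight, seed = as.integer(seed),
                 tolerance = tolerance),
            class = "pso_config")
}

#' Particle-swarm-optimization high-pass filter
#'
#' Runs an independent scalar particle swarm at every pixel. The particle
#' velocity is the high-pass signal candidate: the cost of a particle is
#' the squared difference between its velocity and the target high-pass
#' response at that pixel (by default the traditional HPF response).
#' Initial positions are uniform random numbers rescaled so their sum
#' equals the pixel intensity; initial velocities are uniform over
#' plus/minus the image intensity range. Updates follow the standard
#' additive rule
#' \deqn{v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x), \qquad
#'       x \leftarrow x + v,}
#' with fresh uniform multipliers \eqn{r_1, r_2} each iteration. The
#' filtered output pixel is the velocity recorded at the global-best cost.
#'
#' All randomness comes from one generator stream seeded by `cfg$seed`
#' with particle order fixed, so identical inputs give bit-identical
#' outputs and cost histories.
#'
#' @param image intensity matrix.
#' @param target same-shape matrix of target high-pass responses; default
#'   `traditional_hpf(image)`.
#' @param cfg a [pso_config()].
#' @return list with `output` (matrix of global-best velocities), and
#'   `state`: positions, velocities, personal/global bests, per-pixel
#'   global-best costs, and `cost_history` (mean global-best cost per
#'   iteration, iteration 0 first).
#' @export
pso_hpf <- function(image, target = traditional_hpf(image), cfg = pso_config()) {
  assert_image(image)
  if (!all(is.finite(target))) stop("`target` must be finite", call. = FALSE)
  if (!all(dim(target) == dim(image)))
    stop("`image` and `target` must have the same shape", call. = FALSE)
  if (!inherits(cfg, "pso_config")) stop("`cfg` must be a pso_config()", call. = FALSE)
  np <- length(image)
  P <- cfg$n_particles
  tgt <- as.vector(target)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  # positions: uniform draws rescaled so each pixel's particles sum to the
  # pixel intensity (zero-intensity pixels start the whole swarm at zero)
  u <- matrix(stats::runif(np * P), np, P)
  rs <- rowSums(u)
  intens <- as.vector(image)
  pos <- u * (intens / rs)
  # make the sum constraint hold to the last bit: snap all but the last
  # particle to a power-of-two grid (so their floating-point sum is exact)
  # and give the last particle the exact remainder
  if (P > 1L) {
    q <- ifelse(intens == 0, 1, 2^(floor(log2(abs(intens))) - 45L))
    pos[, -P] <- round(pos[, -P, drop = FALSE] / q) * q
    pos[, P] <- intens - rowSums(pos[, -P, drop = FALSE])
  } else {
    pos[, 1L] <- intens
  }
  vspan <- diff(range(image))
  if (vspan <= 0) vspan <- 1
  vel <- matrix(stats::runif(np * P, -vspan, vspan), np, P)

  init_pos <- pos
  cost <- (vel - tgt)^2
  pbest_pos <- pos
  pbest_cost <- cost
  gidx <- max.col(-cost, ties.method = "first")
  sel <- cbind(seq_len(np), gidx)
  gbest_pos <- pos[sel]
  gbest_vel <- vel[sel]
  gbest_cost <- cost[sel]
  history <- numeric(cfg$n_iterations + 1L)
  history[1L] <- mean(gbest_cost)

  n_done <- 0L
  for (t in seq_len(cfg$n_iterations)) {
    r1 <- matrix(stats::runif(np * P), np, P)
    r2 <- matrix(stats::runif(np * P), np, P)
    vel <- cfg$inertia * vel +
      cfg$cognitive_weight * r1 * (pbest_pos - pos) +
      cfg$social_weight * r2 * (gbest_pos - pos)
    pos <- pos + vel
    cost <- (vel - tgt)^2
    imp <- cost < pbest_cost
    pbest_cost[imp] <- cost[imp]
    pbest_pos[imp] <- pos[imp]
    gidx <- max.col(-cost, ties.method = "first")
    sel <- cbind(seq_len(np), gidx)
    newc <- cost[sel]
    better <- newc < gbest_cost
    gbest_cost[better] <- newc[better]
    gbest_pos[better] <- pos[sel][better]
    gbest_vel[better] <- vel[sel][better]
    history[t + 1L] <- mean(gbest_cost)
    n_done <- t
    if (cfg$tolerance > 0 && t > 10L &&
        history[t + 1L - 10L] - history[t + 1L] < cfg$tolerance) break
  }
  history <- history[seq_len(n_done + 1L)]
  out <- matrix(gbest_vel, nrow(image), ncol(image))
  list(output = out,
       state = list(initial_positions = init_pos,
                    positions = pos, velocities = vel,
                    personal_best = list(positions = pbest_pos,
                                         costs = pbest_cost),
                    global_best = list(positions = gbest_pos,
                                       velocities = gbest_vel,
                                       costs = matrix(gbest_cost,
                                                      nrow(image), ncol(image))),
                    cost_history = history,
                    iterations_run = n_done,
                    config = cfg))
}
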