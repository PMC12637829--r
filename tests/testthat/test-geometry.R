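test_that("axis estimation recovers the stacking direction", {
  sp <- ideal_fibril_spec(strrep("A", 16), path = "U_bend",
                          rise = 4.8, twist = 0, n_layers = 5)
  m <- make_ideal_fibril(sp)$model
  ax <- estimate_axis(m)
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-9)

  # equivariance under a known rotation
  R <- rotation_xyz(0.4, -0.9, 1.3)
  ax2 <- estimate_axis(rotate_model(m, R, shift = c(5, -2, 9)))
  expect_lt(max(abs(ax2$direction - as.numeric(R %*% c(0, 0, 1)))), 1e-6)

  expect_error(estimate_axis(ca_layer()), ">= 2 layers")
})

test_that("axis estimation tolerates centroid jitter", {
  sp <- ideal_fibril_spec(strrep("A", 16), path = "U_bend",
                          rise = 4.8, twist = 0, n_layers = 3)
  base <- make_ideal_fibril(sp)$model
  angs <- vapply(1:100, function(s) {
    set.seed(s)
    m <- base
    # sigma = 0.1 A jitter applied per chain shifts each layer centroid
    for (ch in unique(m$atoms$chain)) {
      i <- m$atoms$chain == ch
      m$atoms[i, c("x", "y", "z")] <-
        sweep(as.matrix(m$atoms[i, c("x", "y", "z")]), 2,
              rnorm(3, 0, 0.1), "+")
    }
    acos(min(1, abs(sum(estimate_axis(m)$direction * c(0, 0, 1))))) *
      180 / pi
  }, numeric(1))
  # simulation-derived bounds for a 3-layer, 4.8 A rise stack: the
  # typical error is about 1 degree, the upper tail stays small
  expect_lt(mean(angs), 1.2)
  expect_lt(unname(quantile(angs, 0.9)), 2)
  expect_lt(max(angs), 4)
})

test_that("best-fit plane minimizes orthogonal distances", {
  # coplanar points
  pts <- cbind(runif(20), runif(20), 0.7)
  expect_lt(best_fit_plane(pts)$rmsd, 1e-9)

  # 8 points on a circle with z alternating +-1: for radius 3 the
  # orthogonal-least-squares plane is z = 0 and the rmsd is exactly 1
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(3 * cos(th), 3 * sin(th), rep(c(1, -1), 4))
  fit <- best_fit_plane(pts)
  expect_lt(abs(abs(fit$plane$normal[3]) - 1), 1e-9)
  expect_equal(fit$rmsd, 1, tolerance = 1e-9)
  # for a unit circle the in-plane spread (RMS 1/sqrt(2) per axis) is
  # smaller than the out-of-plane spread, so the optimal plane is
  # vertical with rmsd 1/sqrt(2) -- strictly better than z = 0
  small <- best_fit_plane(cbind(cos(th), sin(th), rep(c(1, -1), 4)))
  expect_equal(small$rmsd, 1 / sqrt(2), tolerance = 1e-9)
  expect_lt(abs(small$plane$normal[3]), 1e-9)

  # random clouds vs the brute-force normal-grid oracle
  set.seed(11)
  for (i in 1:10) {
    pts <- matrix(rnorm(30), 10, 3) %*% diag(c(3, 2, 0.5))
    expect_equal(best_fit_plane(pts)$rmsd, brute_force_plane_rmsd(pts),
                 tolerance = 1e-6)
  }

  expect_error(best_fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("warping RMSD statistics behave on constructed layers", {
  # perfectly planar layer: both statistics vanish
  sp <- ideal_fibril_spec(strrep("A", 24), path = "U_bend",
                          rise = 4.8, twist = 0, n_layers = 5)
  m <- make_ideal_fibril(sp)$model
  w <- warping_rmsd(m)
  expect_lt(w$rmsd_normal_plane, 1e-9)
  expect_lt(w$rmsd_best_fit, 1e-9)

  # sinusoidal heights z_i = a sin(2 pi i / n): RMS about the normal
  # plane is a / sqrt(2)
  n <- 64; a <- 2
  spw <- ideal_fibril_spec(strrep("A", n), path = "U_bend",
                           rise = 4.8, twist = 0, n_layers = 5,
                           warp = list(amplitude = a, period = n))
  mw <- make_ideal_fibril(spw)$model
  ww <- warping_rmsd(mw, axis = fibril_axis(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(ww$rmsd_normal_plane, a / sqrt(2), tolerance = 0.01)
  expect_lte(ww$rmsd_best_fit, ww$rmsd_normal_plane + 1e-9)

  # rigid-motion invariance of both statistics
  R <- rotation_xyz(-0.3, 0.8, 0.5)
  wr <- warping_rmsd(rotate_model(mw, R, c(-4, 7, 11)))
  expect_equal(wr$rmsd_normal_plane, ww$rmsd_normal_plane,
               tolerance = 1e-6)
  expect_equal(wr$rmsd_best_fit, ww$rmsd_best_fit, tolerance = 1e-6)
})

test_that("helical stack and rise/twist measurement are mutually inverse", {
  # deposited-symmetry parameter pairs used as constructions
  params <- list(c(4.83, -1.82), c(4.81, -1.31), c(4.76, -3.96),
                 c(4.79, 3.95), c(4.83, -1.77), c(4.86, 1.50))
  layer <- make_ideal_fibril(
    ideal_fibril_spec(strrep("A", 20), path = "U_bend",
                      n_layers = 1))$model
  for (p in params) {
    stack <- build_helical_stack(layer, p[1], p[2], 6)
    h <- measure_rise_twist(stack)
    expect_equal(h$rise, p[1], tolerance = 1e-6)
    expect_equal(h$twist, p[2], tolerance = 1e-6)
  }
})

test_that("pure-translation stacks have zero twist", {
  layer <- make_ideal_fibril(
    ideal_fibril_spec(strrep("A", 12), path = "linear", n_layers = 1))$model
  stack <- build_helical_stack(layer, 4.8, 0, 4)
  h <- measure_rise_twist(stack)
  expect_lt(abs(h$twist), 1e-9)
  expect_equal(h$rise, 4.8, tolerance = 1e-9)
  # layer k is a pure translation of layer 0
  a <- stack$atoms
  l0 <- as.matrix(a[a$chain == "A", c("x", "y", "z")])
  l3 <- as.matrix(a[a$chain == "D", c("x", "y", "z")])
  expect_lt(max(abs(sweep(l3, 2, c(0, 0, 3 * 4.8)) - l0)), 1e-9)
})

test_that("cumulative stack rotation matches composed rotations", {
  layer <- make_ideal_fibril(
    ideal_fibril_spec(strrep("A", 10), path = "U_bend", n_layers = 1))$model
  stack <- build_helical_stack(layer, 4.83, -1.82, 100)
  a <- stack$atoms
  ax <- fibril_axis(colMeans(as.matrix(
    layer$atoms[, c("x", "y", "z")])), c(0, 0, 1))
  # oracle: compose the per-layer rotation 99 times about the axis
  th <- -1.82 * pi / 180
  Rk <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R99 <- diag(3)
  for (i in 1:99) R99 <- R99 %*% Rk
  l0 <- sweep(as.matrix(a[a$chain == stack$layers[1], c("x", "y", "z")]),
              2, ax$anchor)
  l99 <- sweep(as.matrix(a[a$chain == stack$layers[100], c("x", "y", "z")]),
               2, ax$anchor + c(0, 0, 99 * 4.83))
  expect_lt(max(abs(l0 %*% t(R99) - l99)), 1e-9)
  # 99 * -1.82 = -180.18 degrees modulo 360
  ang <- atan2(R99[2, 1], R99[1, 1]) * 180 / pi
  d <- (ang - (-180.18)) %% 360
  expect_lt(min(d, 360 - d), 1e-9)
})

test_that("rise/twist recovery is robust to coordinate noise", {
  errs <- vapply(1:50, function(s) {
    sp <- ideal_fibril_spec(strrep("A", 24), path = "U_bend",
                            rise = 4.79, twist = 3.95, n_layers = 5,
                            noise_sigma = 0.05, seed = s)
    m <- make_ideal_fibril(sp)$model
    abs(measure_rise_twist(m)$twist - 3.95)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("crossover length follows the half-turn formula", {
  expect_equal(crossover_length(helical_params(4.83, -1.82)), 477.7,
               tolerance = 0.1 / 477.7)
  expect_equal(crossover_length(helical_params(4.76, -3.96)), 216.4,
               tolerance = 0.1 / 216.4)
  # doubling the twist halves the crossover
  expect_equal(crossover_length(helical_params(4.83, -3.64)),
               crossover_length(helical_params(4.83, -1.82)) / 2)
  expect_error(crossover_length(helical_params(4.8, 0)), "undefined")
})

test_that("handedness is anchored to the right-hand-rule convention", {
  expect_equal(handedness(3.95), "right")
  expect_equal(handedness(-1.82), "left")
  expect_equal(handedness(0), "undefined")
  expect_equal(helical_params(4.79, 3.95)$handedness, "right")
})

test_that("segment superposition matches the quaternion oracle", {
  sp <- ideal_fibril_spec(strrep("A", 20), path = "U_bend", n_layers = 1)
  m <- make_ideal_fibril(sp)$model
  span <- residue_span(3, 12)

  # self-superposition
  self <- segment_rmsd(m, span, "A", m, span, "A")
  expect_lt(self$rmsd, 1e-9)
  expect_lt(max(abs(self$rotation - diag(3))), 1e-9)

  # rotated/translated copy: zero rmsd, rotation recovered
  R <- rotation_xyz(1.1, 0.2, -0.7)
  m2 <- rotate_model(m, R, c(3, -8, 2))
  sup <- segment_rmsd(m, span, "A", m2, span, "A")
  expect_lt(sup$rmsd, 1e-9)
  expect_lt(max(abs(sup$rotation - R)), 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  # noisy pairs against Horn's quaternion method
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(30), 10, 3) * 3
    Y <- X %*% t(rotation_xyz(runif(1), runif(1), runif(1))) +
      matrix(rnorm(30, 0, 0.5), 10, 3)
    ma <- fibril_model(make_atoms("A", rep(1:10, each = 1), "CA", X))
    mb <- fibril_model(make_atoms("A", rep(1:10, each = 1), "CA", Y))
    got <- segment_rmsd(ma, residue_span(1, 10), "A",
                        mb, residue_span(1, 10), "A")
    expect_equal(got$rmsd, quaternion_rmsd(X, Y), tolerance = 1e-6)
  }

  expect_error(segment_rmsd(m, residue_span(1, 5), "A",
                            m, residue_span(1, 9), "A"),
               "equal numbers")
})
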