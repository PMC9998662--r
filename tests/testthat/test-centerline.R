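test_that("tangent angle matches symmetry and the brute-force moment oracle", {
  # horizontal ridge: intensity varies only with y -> theta = 0
  fr_h <- ridge_frame(41, 41, c(20, 20), 0)
  expect_equal(local_tangent_angle(fr_h, c(20, 20))$theta, 0)
  # vertical ridge -> -pi/2 (pi/2 is mapped into [-pi/2, pi/2))
  fr_v <- ridge_frame(41, 41, c(20, 20), pi / 2)
  expect_equal(local_tangent_angle(fr_v, c(20, 20))$theta, -pi / 2)
  # oblique ridges: compare with independent brute-force moment sums
  for (ang in c(pi / 6, -pi / 3, 1.2)) {
    fr <- ridge_frame(41, 41, c(20, 20), ang)
    got <- local_tangent_angle(fr, c(20, 20))$theta
    oracle <- brute_force_orientation(fr, c(20, 20), 15)
    expect_equal(got, oracle, tolerance = 1e-12)
    want <- ((ang + pi / 2) %% pi) - pi / 2
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("tangent angle flags degenerate patches and is scale invariant", {
  flat <- matrix(1, 41, 41)
  expect_true(local_tangent_angle(flat, c(20, 20))$degenerate)
  dark <- matrix(0, 41, 41)
  expect_true(local_tangent_angle(dark, c(20, 20))$degenerate)
  fr <- ridge_frame(41, 41, c(20, 20), pi / 6)
  expect_equal(local_tangent_angle(fr * 773.2, c(20, 20))$theta,
               local_tangent_angle(fr, c(20, 20))$theta)
})

test_that("branch continuation minimizes angle jumps against enumeration", {
  # oracle: enumerate all shifts by multiples of pi and pick the minimizer
  oracle <- function(theta, anchor) {
    out <- numeric(length(theta)); prev <- anchor
    for (i in seq_along(theta)) {
      cand <- theta[i] + pi * (-12:12)
      out[i] <- cand[which.min(abs(cand - prev))]
      prev <- out[i]
    }
    out
  }
  expect_equal(continue_branch(c(0.1, -1.5), anchor = 0.1),
               oracle(c(0.1, -1.5), 0.1))
  expect_equal(continue_branch(c(0.1, -1.5), anchor = 0.1)[2], -1.5 + pi)
  expect_equal(continue_branch(c(pi / 2 - 0.01, -pi / 2 + 0.01))[2],
               pi / 2 + 0.01)
  const <- rep(0.3, 5)
  expect_equal(continue_branch(const), const)
  set.seed(42)
  for (i in 1:20) {
    th <- runif(30, -pi / 2, pi / 2)
    a <- runif(1, -pi, pi)
    got <- continue_branch(th, a)
    expect_equal(got, oracle(th, a))
    expect_true(all(abs(diff(got)) <= pi / 2 + 1e-12))
  }
  expect_error(continue_branch(numeric(0)), "empty")
})

test_that("a straight ridge yields the exact chord", {
  sc <- scene_params(n_frames = 1, noise_sd = 0, shaft_intensity = 0,
                     width_px = 96, height_px = 48,
                     filopodia = list(filo_params(
                       base_xy = c(20, 24),
                       length_model = length_constant(3))))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cv <- solve_centerline(fr, c(tr$base_x, tr$base_y),
                         c(tr$tip_x, tr$tip_y), 0.064)
  expect_true(attr(cv, "converged"))
  chord_um <- sqrt((tr$tip_x - tr$base_x)^2 +
                     (tr$tip_y - tr$base_y)^2) * 0.064
  expect_equal(curve_length(cv), chord_um, tolerance = 1e-9)
  expect_equal(max(abs(cv$y_um - 24 * 0.064)), 0, tolerance = 1e-9)
})

test_that("quarter-arc ridge length and shape match the analytic oracle", {
  R_px <- 20
  L_um <- (pi / 2) * R_px * 0.064
  sc <- scene_params(n_frames = 1, noise_sd = 0, width_px = 96,
                     height_px = 96,
                     filopodia = list(filo_params(
                       base_xy = c(12, 70), orientation = 0,
                       length_model = length_constant(L_um),
                       curvature_per_um = -1 / (R_px * 0.064))))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cv <- solve_centerline(fr, c(tr$base_x, tr$base_y),
                         c(tr$tip_x, tr$tip_y), 0.064)
  expect_lt(abs(curve_length(cv) / L_um - 1), 0.02)
  truth <- arc_centerline(c(12, 70), 0, -1 / R_px, (pi / 2) * R_px, 2000)
  dev_px <- vapply(seq_len(nrow(cv)), function(i)
    min(sqrt((truth$x - cv$x_um[i] / 0.064)^2 +
               (truth$y - cv$y_um[i] / 0.064)^2)), numeric(1))
  expect_lt(max(dev_px), 1)
  # endpoints pinned to the tracked anchors
  expect_equal(cv$x_um[1] / 0.064, tr$base_x, tolerance = 1e-9)
  expect_equal(cv$x_um[nrow(cv)] / 0.064, tr$tip_x, tolerance = 1e-9)
  # unit-speed parameterization: node spacing uniform in arc length
  seg <- sqrt(diff(cv$x_um)^2 + diff(cv$y_um)^2)
  expect_lt(max(abs(seg / mean(seg) - 1)), 1e-3)
  # length can never undercut the straight chord
  chord <- sqrt((tr$tip_x - tr$base_x)^2 + (tr$tip_y - tr$base_y)^2) * 0.064
  expect_gte(curve_length(cv), chord)
})

test_that("centerline recovery is 90-degree rotation equivariant", {
  R_px <- 20
  L_um <- (pi / 2) * R_px * 0.064
  sc <- scene_params(n_frames = 1, noise_sd = 0, width_px = 96,
                     height_px = 96, shaft_intensity = 0,
                     filopodia = list(filo_params(
                       base_xy = c(20, 70), orientation = 0,
                       length_model = length_constant(L_um),
                       curvature_per_um = -1 / (R_px * 0.064))))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cv <- solve_centerline(fr, c(tr$base_x, tr$base_y),
                         c(tr$tip_x, tr$tip_y), 0.064)
  # rotate frame by 90 degrees clockwise in pixel space:
  # (x, y) -> (H - 1 - y, x) maps onto the transposed-flipped matrix
  H <- nrow(fr)
  fr_rot <- t(fr)[, H:1, drop = FALSE]
  rot <- function(p) c(H - 1 - p[2], p[1])
  cv_r <- solve_centerline(fr_rot, rot(c(tr$base_x, tr$base_y)),
                           rot(c(tr$tip_x, tr$tip_y)), 0.064)
  expect_lt(abs(curve_length(cv_r) / curve_length(cv) - 1), 0.01)
})

test_that("centerline is invariant to uniform intensity rescaling", {
  sc <- scene_params(n_frames = 1, noise_sd = 0, width_px = 96,
                     height_px = 96,
                     filopodia = list(filo_params(
                       base_xy = c(12, 70), orientation = -0.4,
                       length_model = length_constant(2.5),
                       curvature_per_um = 3)))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cv1 <- solve_centerline(fr, c(tr$base_x, tr$base_y),
                          c(tr$tip_x, tr$tip_y), 0.064)
  cv2 <- solve_centerline(fr * 41.7, c(tr$base_x, tr$base_y),
                          c(tr$tip_x, tr$tip_y), 0.064)
  expect_equal(cv1$x_um, cv2$x_um)
  expect_equal(cv1$y_um, cv2$y_um)
})

test_that("relaxation displacement is non-increasing after the first step", {
  sc <- scene_params(n_frames = 1, noise_sd = 0, width_px = 96,
                     height_px = 96,
                     filopodia = list(filo_params(
                       base_xy = c(12, 70), orientation = -0.3,
                       length_model = length_constant(3),
                       curvature_per_um = 2.5)))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cv <- solve_centerline(fr, c(tr$base_x, tr$base_y),
                         c(tr$tip_x, tr$tip_y), 0.064)
  trace <- attr(cv, "max_disp_px_trace")
  if (length(trace) > 2)
    expect_true(all(diff(trace[-1]) <= 1e-6))
})

test_that("non-convergence raises a condition carrying the last iterate", {
  sc <- scene_params(n_frames = 1, noise_sd = 0, width_px = 96,
                     height_px = 96,
                     filopodia = list(filo_params(
                       base_xy = c(12, 70), orientation = 0,
                       length_model = length_constant(2),
                       curvature_per_um = -5)))
  ds <- simulate_scene(sc, seed = 1)
  fr <- movie_frame(ds$geometry, 1)$frame
  tr <- ds$tracks
  cond <- tryCatch(
    solve_centerline(fr, c(tr$base_x, tr$base_y), c(tr$tip_x, tr$tip_y),
                     0.064, max_iter = 1L),
    filotrace_no_convergence = function(c) c)
  expect_s3_class(cond, "filotrace_no_convergence")
  expect_s3_class(cond$curve, "filo_centerline")
  expect_false(attr(cond$curve, "converged"))
})

test_that("degenerate inputs are rejected", {
  fr <- ridge_frame(41, 41, c(20, 20), 0)
  expect_error(solve_centerline(fr, c(10, 20), c(10.5, 20), 0.064),
               "degenerate")
  fr_bad <- fr; fr_bad[5, 5] <- NaN
  expect_error(solve_centerline(fr_bad, c(5, 20), c(35, 20), 0.064),
               "finite")
})

test_that("curve length sums node distances and needs two nodes", {
  two <- tibble::tibble(x_um = c(0, 3), y_um = c(0, 0))
  expect_equal(curve_length(two), 3)
  th <- seq(0, pi / 2, length.out = 2001)
  quarter <- tibble::tibble(x_um = cos(th), y_um = sin(th))
  expect_equal(curve_length(quarter), pi / 2, tolerance = 1e-3)
  expect_error(curve_length(two[1, ]), "2 nodes")
})

test_that("trace_centerlines stacks per-frame curves with lengths", {
  sc <- scene_params(n_frames = 3, noise_sd = 0.05, width_px = 96,
                     height_px = 48,
                     filopodia = list(filo_params(
                       base_xy = c(12, 24),
                       length_model = length_sinusoid(2.5, 0.3, 60))))
  ds <- simulate_scene(sc, seed = 2)
  curves <- trace_centerlines(ds$geometry, ds$tracks, pipeline_config())
  expect_setequal(unique(curves$frame), 1:3)
  lens <- centerline_lengths(curves)
  expect_equal(nrow(lens), 3)
  expect_equal(lens$length_um, ds$truth$length_um, tolerance = 0.05)
})
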