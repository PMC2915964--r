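test_that("pose_matrix composes translation, scale and rotation in order", {
  expect_equal(pose_matrix(pose(0, 0, 1, 0)), diag(3))
  # pure translation of a centered point
  Tm <- pose_matrix(pose(2, 3, 1, 0))
  expect_equal(drop(Tm %*% c(1, 1, 1)), c(3, 4, 1))
  # M(0,0) H(2) R(pi/2) maps centered (1, 0) to (0, 2)
  Tm <- pose_matrix(pose(0, 0, 2, pi / 2))
  expect_equal(drop(Tm %*% c(1, 0, 1)), c(0, 2, 1))
  # similarity structure
  p <- pose(1.5, -2, 1.7, 0.4)
  Tm <- pose_matrix(p)
  expect_equal(Tm[3, ], c(0, 0, 1))
  expect_equal(det(Tm[1:2, 1:2]), p$h^2)
  expect_error(pose(h = 0), "positive")
  expect_error(pose(h = -1), "positive")
})

test_that("theta is stored wrapped into (-pi, pi]", {
  expect_equal(pose(theta = 3 * pi)$theta, pi)
  expect_equal(pose(theta = -pi / 2)$theta, -pi / 2)
  expect_lt(abs(pose(theta = 2 * pi)$theta), 1e-12)
})

test_that("apply_pose pulls correctly: identity, lossless shift, rotation inverse", {
  leaf <- test_leaf(24)
  expect_equal(apply_pose(leaf, pose()), leaf$pixels)
  # integer translation with nearest neighbour preserves foreground count
  sh <- apply_pose(leaf, pose(a = 2, b = -1), interp = "nearest")
  expect_equal(sum(sh), sum(leaf$pixels))
  expect_equal(sh[5:20, 6:21], leaf$pixels[6:21, 4:19])
  # rotating by pi twice returns the original up to interpolation error
  r1 <- apply_pose(leaf, pose(theta = pi))
  r2 <- apply_pose(r1, pose(theta = pi))
  expect_lte(max(abs(r2 - leaf$pixels)), 0.5)
})

test_that("joint_energy matches the explicit double-loop oracle", {
  expect_equal(joint_energy(list(diag(4))), 0)
  im <- matrix(0, 4, 4); im[2:3, 2:3] <- 1
  expect_equal(joint_energy(list(im, im, im)), 0)
  im2 <- im; im2[2, 2] <- 0; im2[1, 4] <- 1
  expect_equal(joint_energy(list(im, im2)), brute_energy(list(im, im2)))
  set.seed(3)
  imgs <- lapply(1:4, function(i) random_shape(5))
  expect_equal(joint_energy(imgs), brute_energy(imgs))
  expect_error(joint_energy(list(im, matrix(0, 5, 5))), "dimensions")
})

test_that("analytic energy gradient matches central finite differences", {
  leaf <- test_leaf(28)
  ss <- shape_set(list(leaf, leaf, leaf))
  set.seed(11)
  poses <- lapply(1:3, function(i)
    pose(runif(1, -2, 2), runif(1, -2, 2), exp(runif(1, -0.1, 0.1)),
         runif(1, -0.3, 0.3)))
  g <- energy_gradient(ss, poses, sigma = 1)
  S <- lapply(ss$images, function(im) shapeqtl:::smooth_image(im$pixels, 1))
  Efun <- function(pv) {
    pl <- lapply(1:3, function(i) pose(pv[i], pv[3 + i], pv[6 + i], pv[9 + i]))
    joint_energy(lapply(1:3, function(i) apply_pose(S[[i]], pl[[i]])))
  }
  p0 <- c(vapply(poses, `[[`, numeric(1), "a"),
          vapply(poses, `[[`, numeric(1), "b"),
          vapply(poses, `[[`, numeric(1), "h"),
          vapply(poses, `[[`, numeric(1), "theta"))
  fd <- vapply(seq_along(p0), function(k) {
    e <- 1e-5
    up <- p0; up[k] <- up[k] + e
    dn <- p0; dn[k] <- dn[k] - e
    (Efun(up) - Efun(dn)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g - matrix(fd, 3, 4))) / max(abs(fd)), 1e-3)
})

test_that("gradient is zero at a minimum and for a single shape", {
  leaf <- test_leaf(20)
  ss <- shape_set(list(leaf, leaf))
  g <- energy_gradient(ss, list(pose(), pose()))
  expect_equal(max(abs(g)), 0)
  ss1 <- shape_set(list(leaf))
  expect_equal(energy_gradient(ss1, list(pose())), matrix(0, 1, 4),
               ignore_attr = TRUE)
})

test_that("joint energy is invariant under a shared rigid pose", {
  leaf <- test_leaf(32)
  other <- generate_leaf(leaf_params(n_lobes = 4, lobe_depth = 0.2,
                                     base_radius = 0.22), 32)
  base <- lapply(list(leaf, other), function(im)
    shapeqtl:::smooth_image(im$pixels, 1))
  e0 <- joint_energy(base)
  common <- pose(a = 1.3, b = -0.8, h = 1, theta = 0.15)
  moved <- lapply(base, function(im) apply_pose(im, common))
  expect_lt(abs(joint_energy(moved) - e0), 1e-2)
})

test_that("alignment is a fixed point for identical aligned shapes", {
  leaf <- test_leaf(24)
  al <- align_shapes(shape_set(list(leaf, leaf, leaf)))
  expect_true(al$converged)
  expect_equal(al$energy_trace[length(al$energy_trace)], 0)
  for (p in al$poses) {
    expect_equal(c(p$a, p$b, p$theta), c(0, 0, 0))
    expect_equal(p$h, 1)
  }
})

test_that("descent strictly decreases the energy of disjoint translates", {
  small <- matrix(0, 24, 24)
  small[4:9, 4:9] <- 1
  far <- matrix(0, 24, 24)
  far[16:21, 16:21] <- 1
  raw_E <- joint_energy(list(small, far))
  al <- suppressWarnings(align_shapes(shape_set(list(
    shape_image(small), shape_image(far)))))
  tr <- al$energy_trace
  expect_lt(tr[length(tr)], raw_E)
  expect_true(all(diff(tr) <= 0))
})

test_that("known pose perturbations are recovered relative to the gauge", {
  leaf <- test_leaf(48)
  pert <- perturb_poses(shape_set(rep(list(leaf), 5)), max_shift = 2,
                        max_log_scale = log(1.06), max_angle = 10 * pi / 180,
                        seed = 8)
  al <- suppressWarnings(align_shapes(pert$shapes))
  expect_true(all(diff(al$energy_trace) <= 0))
  Tq1 <- pose_matrix(pert$poses[[1]])
  for (i in seq_along(al$poses)) {
    expected <- shapeqtl:::pose_from_matrix(Tq1 %*% solve(pose_matrix(pert$poses[[i]])))
    got <- al$poses[[i]]
    expect_lt(abs(got$a - expected$a), 0.5)
    expect_lt(abs(got$b - expected$b), 0.5)
    expect_lt(abs(got$h / expected$h - 1), 0.02)
    expect_lt(abs(got$theta - expected$theta), 2 * pi / 180)
  }
})
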