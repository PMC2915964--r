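test_that("generate_leaf rasterises the stated polar boundary", {
  # a plain disk: area close to pi r^2
  disk <- generate_leaf(leaf_params(n_lobes = 1, lobe_depth = 0, base_radius = 0.3,
                                    elongation = 1, serration = 0), 64)
  r <- 0.3 * 64
  expect_lt(abs(sum(disk$pixels) - pi * r^2) / (pi * r^2), 0.05)
  # five-lobed leaf keeps its area under a 72 degree rotation
  lobed <- generate_leaf(leaf_params(n_lobes = 5, lobe_depth = 0.4,
                                     base_radius = 0.26), 64)
  rot <- apply_pose(lobed, pose(theta = 2 * pi / 5), interp = "nearest")
  expect_lt(abs(sum(rot) - sum(lobed$pixels)) / sum(lobed$pixels), 0.03)
  expect_s3_class(lobed, "shape_image")
  # oversized boundary is rejected
  expect_error(generate_leaf(leaf_params(base_radius = 0.45, lobe_depth = 0.3), 32),
               "grid")
})

test_that("simulated populations have the documented dimensions", {
  pop <- simulate_population("big", n = 30, L = 16, sigma2 = 1, seed = 2)
  expect_equal(dim(pop$genotypes$values), c(30, 11))
  expect_equal(dim(pop$phenotypes$values), c(30, 256))
  expect_equal(pop$map$positions_cM, seq(0, 100, by = 10))
  expect_equal(pop$qtl_position_cM, 25)
  expect_equal(length(pop$shapes$images), 30)
})

test_that("xi agrees with the QTL genotype and drives the mixture truthfully", {
  pop <- simulate_population("big", n = 80, L = 16, sigma2 = 0, seed = 31)
  # noiseless: each phenotype row equals exactly one of the true means
  mu1 <- vectorize_lexicographic(pop$mu1_img)
  mu2 <- vectorize_lexicographic(pop$mu2_img)
  for (i in seq_len(80)) {
    target <- if (pop$xi[i] == 1) mu1 else mu2
    expect_identical(unname(pop$phenotypes$values[i, ]), unname(target))
  }
  expect_true(all(pop$xi %in% c(0, 1)))
  # group means recover truth to machine precision
  expect_equal(colMeans(pop$phenotypes$values[pop$xi == 1, ]), mu1)
})

test_that("phenotype noise has the CLT-consistent per-pixel behaviour", {
  pop <- simulate_population("big", n = 500, L = 16, sigma2 = 1, seed = 77)
  mu1 <- vectorize_lexicographic(pop$mu1_img)
  sel <- pop$xi == 1
  n1 <- sum(sel)
  dev <- abs(colMeans(pop$phenotypes$values[sel, ]) - mu1)
  expect_gte(mean(dev <= 4 / sqrt(n1)), 0.99)
})

test_that("simulation is a pure function of its seed", {
  a <- simulate_population("small-wild", n = 15, L = 16, sigma2 = 1, seed = 5)
  b <- simulate_population("small-wild", n = 15, L = 16, sigma2 = 1, seed = 5)
  expect_identical(a$phenotypes$values, b$phenotypes$values)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$shapes$images[[7]]$pixels, b$shapes$images[[7]]$pixels)
  c <- simulate_population("small-wild", n = 15, L = 16, sigma2 = 1, seed = 6)
  expect_false(identical(a$phenotypes$values, c$phenotypes$values))
})

test_that("a noiseless population is fitted exactly by the EM", {
  pop <- simulate_population("big", n = 40, L = 16, sigma2 = 0, seed = 12)
  w <- qtl_weights(pop$genotypes, position_cM = 25)
  fit <- run_em(pop$phenotypes, w)
  mu1 <- vectorize_lexicographic(pop$mu1_img)
  mu2 <- vectorize_lexicographic(pop$mu2_img)
  expect_lt(max(abs(fit$model$mu1 - mu1)), 1e-6)
  expect_lt(max(abs(fit$model$mu2 - mu2)), 1e-6)
})

test_that("perturb_poses is bounded, deterministic, and returns truth", {
  leaf <- test_leaf(32)
  ss <- shape_set(rep(list(leaf), 4))
  none <- perturb_poses(ss, 0, 0, 0, seed = 3)
  for (i in 1:4) {
    expect_equal(none$shapes$images[[i]]$pixels, leaf$pixels)
    expect_equal(none$poses[[i]]$h, 1)
  }
  p1 <- perturb_poses(ss, 2, 0.05, 0.2, seed = 3)
  p2 <- perturb_poses(ss, 2, 0.05, 0.2, seed = 3)
  expect_identical(p1$shapes$images[[2]]$pixels, p2$shapes$images[[2]]$pixels)
  for (p in p1$poses) {
    expect_lte(abs(p$a), 2); expect_lte(abs(p$b), 2)
    expect_lte(abs(log(p$h)), 0.05); expect_lte(abs(p$theta), 0.2)
  }
})

test_that("fixture directories carry the full input contract", {
  dir <- withr::local_tempdir()
  pop <- simulate_fixture("big", n = 6, L = 16, seed = 4, outdir = dir)
  expect_length(list.files(file.path(dir, "shapes"), pattern = "\\.png$"), 6)
  expect_true(file.exists(file.path(dir, "map.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$qtl_position_cM, 25)
  expect_equal(truth$scheme, "big")
  # shapes re-read bit-exactly
  im <- load_shape(file.path(dir, "shapes", "progeny_1.png"))
  expect_equal(im$pixels, pop$shapes$images[[1]]$pixels)
})
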