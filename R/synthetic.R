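#' Parameters of a synthetic leaf silhouette
#'
#' A leaf is rasterised from the polar boundary
#' `rho(phi) = base_radius * L * (1 - lobe_depth * cos(n_lobes * phi)) *
#' (1 + serration * cos(12 phi))`, with the y axis stretched by
#' `elongation`. The presets mimic the gross morphology of lobed wild
#' cucurbit leaves versus smoother, more elongated cultivated ones.
#'
#' @param n_lobes number of lobes (>= 1).
#' @param lobe_depth lobe modulation depth in \[0, 1).
#' @param base_radius mean radius as a fraction of L, in (0, 0.5).
#' @param elongation y/x aspect ratio (> 0).
#' @param serration amplitude of the high-frequency boundary term (>= 0).
#' @return a list of class `leaf_params`.
#' @export
leaf_params <- function(n_lobes = 5, lobe_depth = 0.3, base_radius = 0.28,
                        elongation = 1, serration = 0) {
  stopifnot(n_lobes >= 1, lobe_depth >= 0, lobe_depth < 1,
            base_radius > 0, base_radius < 0.5, elongation > 0, serration >= 0)
  structure(list(n_lobes = as.integer(n_lobes), lobe_depth = lobe_depth,
                 base_radius = base_radius, elongation = elongation,
                 serration = serration),
            class = "leaf_params")
}

#' Rasterise a leaf silhouette
#'
#' Deterministic: a pixel is foreground when its (elongation-corrected)
#' polar radius about the image center is at most `rho(phi)`.
#'
#' @param params a [leaf_params()].
#' @param L grid side in pixels.
#' @return a [shape_image].
#' @export
generate_leaf <- function(params, L) {
  stopifnot(inherits(params, "leaf_params"), L >= 8)
  rho_max <- params$base_radius * L * (1 + params$lobe_depth) * (1 + params$serration)
  if (rho_max * max(1, params$elongation) > L / 2 - 1)
    stop("leaf boundary exits the grid; reduce base_radius/elongation", call. = FALSE)
  ctr <- (L + 1) / 2
  xs <- matrix(rep(seq_len(L), each = L), L, L)
  ys <- matrix(rep(seq_len(L), times = L), L, L)
  dx <- xs - ctr
  dy <- (ys - ctr) / params$elongation
  phi <- atan2(dy, dx)
  rho <- params$base_radius * L *
    (1 - params$lobe_depth * cos(params$n_lobes * phi)) *
    (1 + params$serration * cos(12 * phi))
  if (any(rho <= 0)) stop("leaf boundary radius must stay positive", call. = FALSE)
  shape_image((sqrt(dx^2 + dy^2) <= rho) * 1)
}

#' Named genotype-shape presets for the simulation schemes
#'
#' `"big"` pairs a deeply lobed, round wild-type leaf (genotype QQ) with a
#' nearly unlobed, elongated cultivated leaf (Qq) — a QTL with a large
#' shape effect. `"small-wild"` and `"small-cultivar"` pair two wild-type
#' (respectively cultivated) leaves that differ only slightly in lobe
#' depth (respectively elongation) — small-effect QTLs. `"null"` uses the
#' same leaf for both genotypes, i.e. no QTL.
#'
#' @param scheme one of `"big"`, `"small-wild"`, `"small-cultivar"`,
#'   `"null"`.
#' @return list with elements `QQ` and `Qq`, each a [leaf_params()].
#' @export
scheme_presets <- function(scheme = c("big", "small-wild", "small-cultivar", "null")) {
  scheme <- match.arg(scheme)
  wild <- leaf_params(n_lobes = 5, lobe_depth = 0.45, base_radius = 0.28,
                      elongation = 1, serration = 0.05)
  cult <- leaf_params(n_lobes = 5, lobe_depth = 0.08, base_radius = 0.26,
                      elongation = 1.3, serration = 0.02)
  switch(scheme,
    "big" = list(QQ = wild, Qq = cult),
    "small-wild" = list(
      QQ = wild,
      Qq = leaf_params(n_lobes = 5, lobe_depth = 0.35, base_radius = 0.28,
                       elongation = 1, serration = 0.05)),
    "small-cultivar" = list(
      QQ = cult,
      Qq = leaf_params(n_lobes = 5, lobe_depth = 0.08, base_radius = 0.26,
                       elongation = 1.15, serration = 0.02)),
    "null" = list(QQ = wild, Qq = wild))
}

#' Default simulation linkage map
#'
#' One linkage group with 11 equally spaced markers at 0, 10, ..., 100 cM.
#'
#' @return a [linkage_map()].
#' @export
default_map <- function() {
  linkage_map(paste0("M", 1:11), seq(0, 100, by = 10))
}

#' Simulate a backcross shape-mapping population
#'
#' Builds the two genotype leaf shapes for the chosen scheme, converts
#' each to its true mean signed-distance field `mu_j`, simulates backcross
#' genotypes along the map together with the QTL genotype at
#' `qtl_position_cM`, and draws phenotypes
#' `Y_i = xi_i mu_1 + (1 - xi_i) mu_2 + e_i` with `e_i` iid normal per
#' pixel (covariance `sigma2 * I`), where `xi_i = 1` when progeny i
#' carries QQ. Noisy shapes are the zero-level thresholdings of the
#' phenotype fields.
#'
#' @param scheme preset name, see [scheme_presets()].
#' @param n progeny count (default 200).
#' @param L grid side (default 75).
#' @param map linkage map (default [default_map()]).
#' @param qtl_position_cM true QTL position (default 25 cM, the middle of
#'   the third marker interval of the default map).
#' @param sigma2 residual variance per pixel (default 1, identity
#'   covariance).
#' @param seed integer seed; the population is a pure function of
#'   (arguments, seed).
#' @return an object of class `simulated_population` with fields `shapes`
#'   (a [shape_set]), `phenotypes` (a `phenotype_matrix` holding the noisy
#'   SDF fields), `genotypes`, `map`, `qtl_position_cM`, `xi`, `mu1_img`,
#'   `mu2_img` (true mean SDF grids), `shape_QQ`, `shape_Qq` (true binary
#'   genotype shapes), `sigma2_true`, `scheme`, `seed`.
#' @export
simulate_population <- function(scheme = "big", n = 200, L = 75,
                                map = default_map(), qtl_position_cM = 25,
                                sigma2 = 1, seed = 1) {
  stopifnot(n >= 2)
  preset <- scheme_presets(scheme)
  shape_QQ <- generate_leaf(preset$QQ, L)
  shape_Qq <- generate_leaf(preset$Qq, L)
  mu1_img <- signed_distance(shape_QQ)$values
  mu2_img <- signed_distance(shape_Qq)$values
  mu1 <- vectorize_lexicographic(mu1_img)
  mu2 <- vectorize_lexicographic(mu2_img)

  # simulate markers and the QTL jointly as one Markov chain, then drop
  # the QTL column: xi is exact by construction
  aug_pos <- sort(unique(c(map$positions_cM, qtl_position_cM)))
  qtl_idx <- which(aug_pos == qtl_position_cM)
  aug_map <- linkage_map(paste0("L", seq_along(aug_pos)), aug_pos)
  aug_geno <- simulate_genotypes(aug_map, n, seed = seed)
  qtl_geno <- aug_geno$values[, qtl_idx]
  keep <- match(map$positions_cM, aug_pos)
  genotypes <- structure(list(values = aug_geno$values[, keep, drop = FALSE],
                              ids = aug_geno$ids, map = map),
                         class = "backcross_genotypes")
  xi <- as.numeric(qtl_geno == 1L)

  m <- L * L
  Y <- withr::with_seed(seed + 1L, {
    E <- matrix(rnorm(n * m, sd = sqrt(sigma2)), n, m)
    outer(xi, mu1) + outer(1 - xi, mu2) + E
  })
  phen <- structure(list(values = Y, ids = genotypes$ids, L = L, n = n, m = m),
                    class = "phenotype_matrix")
  images <- lapply(seq_len(n), function(i) {
    fg <- (unvectorize(Y[i, ], L) <= 0) * 1
    shape_image(fg, id = genotypes$ids[i])
  })
  structure(list(shapes = shape_set(images, ids = genotypes$ids),
                 phenotypes = phen, genotypes = genotypes, map = map,
                 qtl_position_cM = qtl_position_cM, xi = xi,
                 mu1_img = mu1_img, mu2_img = mu2_img,
                 shape_QQ = shape_QQ, shape_Qq = shape_Qq,
                 sigma2_true = sigma2, scheme = scheme, seed = seed),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf("simulated_population: scheme '%s', n = %d, L = %d, QTL at %.1f cM (seed %d)\n",
              x$scheme, x$phenotypes$n, x$phenotypes$L, x$qtl_position_cM, x$seed))
  invisible(x)
}

#' Apply random pose perturbations to a shape set
#'
#' Draws an independent uniform pose within the given bounds for each
#' shape, applies it (bilinear, re-binarised at 0.5), and returns both the
#' perturbed shapes and the true poses — ground truth for alignment
#' recovery experiments.
#'
#' @param shapes a [shape_set()].
#' @param max_shift translation bound in pixels (for both a and b).
#' @param max_log_scale bound on |log h|.
#' @param max_angle rotation bound in radians.
#' @param seed integer seed.
#' @return list with `shapes` (perturbed [shape_set]) and `poses` (list of
#'   true [pose()] objects).
#' @export
perturb_poses <- function(shapes, max_shift = 0, max_log_scale = 0,
                          max_angle = 0, seed = 1) {
  stopifnot(inherits(shapes, "shape_set"),
            max_shift >= 0, max_log_scale >= 0, max_angle >= 0)
  n <- shapes$n
  poses <- withr::with_seed(seed, lapply(seq_len(n), function(i)
    pose(a = runif(1, -max_shift, max_shift),
         b = runif(1, -max_shift, max_shift),
         h = exp(runif(1, -max_log_scale, max_log_scale)),
         theta = runif(1, -max_angle, max_angle))))
  imgs <- lapply(seq_len(n), function(i) {
    out <- (apply_pose(shapes$images[[i]], poses[[i]]) > 0.5) * 1
    nf <- sum(out)
    if (nf == 0 || nf == length(out))
      stop("pose perturbation pushed shape ", shapes$ids[i],
           " outside the grid", call. = FALSE)
    shape_image(out, id = shapes$ids[i])
  })
  list(shapes = shape_set(imgs, ids = shapes$ids), poses = poses)
}

#' Write a simulated population as a fixture directory
#'
#' Emits the pipeline's input contract: one PNG per progeny under
#' `shapes/`, `map.csv`, `genotypes.csv`, and `truth.json` recording the
#' scheme, seed, sigma2 and true QTL position.
#'
#' @param pop a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(pop, dir) {
  dir.create(file.path(dir, "shapes"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(pop$shapes$n))
    write_shape_png(pop$shapes$images[[i]],
                    file.path(dir, "shapes", paste0(pop$shapes$ids[i], ".png")))
  write_linkage_map(pop$map, file.path(dir, "map.csv"))
  write_genotypes(pop$genotypes, file.path(dir, "genotypes.csv"))
  jsonlite::write_json(list(scheme = pop$scheme, seed = pop$seed,
                            sigma2 = pop$sigma2_true,
                            qtl_position_cM = pop$qtl_position_cM,
                            n = pop$shapes$n, L = pop$shapes$L),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
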