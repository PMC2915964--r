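#' Run configuration for the end-to-end mapping pipeline
#'
#' All knobs of the align -> embed -> scan -> test workflow in one
#' serialisable list, so a run is reproducible from (inputs, config,
#' seed). `as_run_config()` merges a YAML file or list of overrides onto
#' the defaults.
#'
#' @param shapes_dir directory of shape images (PNG/PGM/text).
#' @param map_csv,genotypes_csv linkage map and genotype CSV paths.
#' @param out_dir output directory.
#' @param align whether to run joint pose alignment (disable for data
#'   simulated without pose variation).
#' @param alignment an [align_config()].
#' @param binarize_threshold threshold for aligned images before the SDF.
#' @param load_threshold grayscale threshold when reading shape files.
#' @param grid_by scan-grid spacing in cM.
#' @param em_tol,em_max_iter EM settings.
#' @param n_perm,alpha permutation-test settings.
#' @param seed integer seed for the permutation stream.
#' @return a list of class `run_config`.
#' @export
run_config <- function(shapes_dir = NULL, map_csv = NULL, genotypes_csv = NULL,
                       out_dir = "shapeqtl_out", align = TRUE,
                       alignment = align_config(), binarize_threshold = 0.5,
                       load_threshold = 0.5, grid_by = 1,
                       em_tol = 1e-6, em_max_iter = 200,
                       n_perm = 1000, alpha = 0.05, seed = 1) {
  structure(list(shapes_dir = shapes_dir, map_csv = map_csv,
                 genotypes_csv = genotypes_csv, out_dir = out_dir,
                 align = align, alignment = alignment,
                 binarize_threshold = binarize_threshold,
                 load_threshold = load_threshold, grid_by = grid_by,
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param x a `run_config`, a YAML file path, or a named list of overrides.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  ov <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  stopifnot(is.list(ov))
  cfg <- run_config()
  ac <- ov$alignment
  ov$alignment <- NULL
  for (k in names(ov)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k, call. = FALSE)
    cfg[[k]] <- ov[[k]]
  }
  if (!is.null(ac)) for (k in names(ac)) cfg$alignment[[k]] <- ac[[k]]
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[shapeqtl] %s | %s", stage,
                  paste(sprintf("%s=%s", names(c(...)), c(...)), collapse = " ")))
}

#' Run the full shape-QTL mapping pipeline
#'
#' Stages: read shapes, (optionally) align them jointly, embed as signed
#' distance phenotypes, scan the genome for the QTL, calibrate the peak by
#' permutation, and write every artifact to `out_dir`: the alignment
#' report, the phenotype matrix (computed once and reused across
#' permutations), the LR profile CSV and JSON summary, the reconstructed
#' genotype-mean shapes, and the per-progeny log-densities under each
#' fitted component at the peak.
#'
#' @param config a [run_config()], YAML path, or named override list.
#' @param shapes optional in-memory [shape_set] (skips `shapes_dir`).
#' @param genotypes optional in-memory `backcross_genotypes`.
#' @return a list of class `pipeline_result`: `scan` (a `scan_result` with
#'   threshold attached), `significant`, `phenotypes`, `aligned`,
#'   `mean_shape_QQ`, `mean_shape_Qq`, `out_dir`.
#' @export
run_shape_mapping <- function(config = run_config(), shapes = NULL,
                              genotypes = NULL) {
  cfg <- as_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(shapes)) {
    files <- sort(list.files(cfg$shapes_dir, full.names = TRUE,
                             pattern = "\\.(png|pgm|txt)$"))
    if (!length(files)) stop("no shape files found in ", cfg$shapes_dir, call. = FALSE)
    imgs <- lapply(files, function(f)
      load_shape(f, threshold = cfg$load_threshold,
                 id = tools::file_path_sans_ext(basename(f))))
    shapes <- shape_set(imgs)
  }
  stage_log("load", n = shapes$n, L = shapes$L)

  if (is.null(genotypes)) {
    map <- read_linkage_map(cfg$map_csv)
    genotypes <- read_genotypes(cfg$genotypes_csv, map)
  }
  map <- genotypes$map

  # pair progeny by id: file listings are lexicographic, genotype rows are not
  ord <- match(genotypes$ids, shapes$ids)
  if (anyNA(ord))
    stop("genotype ids missing among shape ids: ",
         paste(genotypes$ids[is.na(ord)][1:3], collapse = ", "), call. = FALSE)
  shapes <- shape_set(shapes$images[ord], ids = shapes$ids[ord])

  if (cfg$align) {
    aligned <- align_shapes(shapes, cfg$alignment)
    stage_log("align", iterations = aligned$n_iter,
              final_E = signif(aligned$energy_trace[length(aligned$energy_trace)], 4))
    write_alignment_report(aligned, file.path(cfg$out_dir, "alignment.csv"))
  } else {
    aligned <- shapes
    stage_log("align", skipped = TRUE)
  }

  phen <- build_phenotypes(aligned, binarize_threshold = cfg$binarize_threshold)
  write_phenotypes(phen, file.path(cfg$out_dir, "phenotypes.csv"))
  stage_log("embed", n = phen$n, m = phen$m)

  grid <- scan_grid(map, by = cfg$grid_by)
  scan <- qtl_scan(phen, genotypes, map, grid,
                   tol = cfg$em_tol, max_iter = cfg$em_max_iter)
  stage_log("scan", positions = length(grid),
            peak_lr = signif(scan$peak_lr, 5), peak_cM = scan$peak_position_cM)

  thr <- permutation_threshold(phen, genotypes, map, grid,
                               n_perm = cfg$n_perm, alpha = cfg$alpha,
                               seed = cfg$seed,
                               tol = cfg$em_tol, max_iter = cfg$em_max_iter)
  scan <- set_threshold(scan, thr, cfg$alpha, cfg$n_perm, cfg$seed)
  significant <- scan$peak_lr > scan$threshold
  stage_log("threshold", alpha = cfg$alpha, n_perm = cfg$n_perm,
            threshold = signif(scan$threshold, 5), significant = significant)

  write_scan(scan, file.path(cfg$out_dir, "scan.csv"),
             file.path(cfg$out_dir, "summary.json"))

  # reconstructed genotype-mean shapes and per-progeny density summaries
  mod <- scan$peak_model
  mQQ <- reconstruct_shape(mod$mu1, phen$L)
  mQq <- reconstruct_shape(mod$mu2, phen$L)
  if (inherits(mQQ, "shape_image"))
    write_shape_text(mQQ, file.path(cfg$out_dir, "mean_shape_QQ.txt"))
  if (inherits(mQq, "shape_image"))
    write_shape_text(mQq, file.path(cfg$out_dir, "mean_shape_Qq.txt"))
  dens <- data.frame(
    id = phen$ids,
    logdens_QQ = apply(phen$values, 1, log_density, mu = mod$mu1,
                       sigma2 = mod$sigma2),
    logdens_Qq = apply(phen$values, 1, log_density, mu = mod$mu2,
                       sigma2 = mod$sigma2))
  if (!is.null(scan$peak_posteriors)) {
    dens$posterior_QQ <- scan$peak_posteriors[, 1]
    dens$posterior_Qq <- scan$peak_posteriors[, 2]
  }
  write.csv(dens, file.path(cfg$out_dir, "densities.csv"), row.names = FALSE)

  structure(list(scan = scan, significant = significant, phenotypes = phen,
                 aligned = aligned, mean_shape_QQ = mQQ, mean_shape_Qq = mQq,
                 out_dir = cfg$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$scan)
  cat("artifacts in:", x$out_dir, "\n")
  invisible(x)
}

#' Simulate a population and write it as a fixture directory
#'
#' Convenience wrapper pairing [simulate_population()] with
#' [write_fixture_dir()]; the emitted directory is exactly the input
#' contract of [run_shape_mapping()].
#'
#' @inheritParams simulate_population
#' @param outdir target directory.
#' @return the `simulated_population`, invisibly.
#' @export
simulate_fixture <- function(scheme = "big", n = 200, L = 75, seed = 1,
                             sigma2 = 1, outdir) {
  pop <- simulate_population(scheme = scheme, n = n, L = L,
                             sigma2 = sigma2, seed = seed)
  write_fixture_dir(pop, outdir)
  stage_log("simulate", scheme = scheme, n = n, L = L, seed = seed, outdir = outdir)
  invisible(pop)
}
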