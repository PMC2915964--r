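#' Positions at which to test for a QTL
#'
#' Default scan grid: every `by` cM across the map span, plus every marker
#' position.
#'
#' @param map a [linkage_map()].
#' @param by grid spacing in cM (default 1).
#' @return sorted numeric vector of test positions.
#' @export
scan_grid <- function(map, by = 1) {
  span <- range(map$positions_cM)
  sort(unique(c(seq(span[1], span[2], by = by), map$positions_cM)))
}

# LR fit at one test position. omega is the n x 2 prior-weight matrix.
# To guarantee LR >= 0 the EM is run both from the genotype-informed hard
# start and from the null solution, and the better fit is kept. Positions
# where a component has (numerically) no prior mass are a single effective
# component, so LR = 0 there.
fit_position <- function(Y, om, null_fit, tol = 1e-6, max_iter = 200) {
  if (min(colSums(om)) < 1e-8) {
    model <- new_mixture_model(null_fit$mu0, null_fit$mu0, null_fit$sigma2_0,
                               loglik = null_fit$loglik0)
    return(list(model = model, state = NULL, lr = 0))
  }
  best <- run_em(Y, om, tol = tol, max_iter = max_iter)
  if (best$model$loglik < null_fit$loglik0) {
    # informative start found a worse optimum than the null: reseed from the
    # null solution so the nested-model LR cannot go negative
    null_init <- new_mixture_model(null_fit$mu0, null_fit$mu0, null_fit$sigma2_0)
    fit2 <- run_em(Y, om, init = null_init, tol = tol, max_iter = max_iter)
    if (fit2$model$loglik > best$model$loglik) best <- fit2
  }
  best$lr <- max(2 * (best$model$loglik - null_fit$loglik0), 0)
  best
}

#' Genome scan for a shape QTL
#'
#' At each test position the flanking-marker mixture weights are computed,
#' the two-component mixture is fitted by EM, and the likelihood-ratio
#' statistic `LR = 2 (loglik_mixture - loglik_null)` is recorded; the
#' single-component null is fitted once. The profile is nonnegative by
#' construction (the EM is additionally seeded from the null solution and
#' the better fit kept).
#'
#' @param Y a `phenotype_matrix` or n x m matrix.
#' @param genotypes a `backcross_genotypes`.
#' @param map a [linkage_map()]; defaults to the one in `genotypes`.
#' @param grid test positions; defaults to [scan_grid()] at 1 cM.
#' @param tol,max_iter EM settings passed to [run_em()].
#' @param keep_models keep the fitted model at the peak position (default
#'   TRUE).
#' @return an object of class `scan_result`: `positions_cM`, `lr`,
#'   `peak_position_cM`, `peak_lr`, `peak_model`, `peak_posteriors`,
#'   `null_fit`, plus `threshold`/`alpha`/`n_permutations`/`seed` slots
#'   filled by [permutation_threshold()].
#' @export
qtl_scan <- function(Y, genotypes, map = NULL, grid = NULL,
                     tol = 1e-6, max_iter = 200, keep_models = TRUE) {
  Y <- as_Y(Y)
  if (is.null(map)) map <- genotypes$map
  if (is.null(grid)) grid <- scan_grid(map)
  if (nrow(genotypes$values) != nrow(Y))
    stop("genotypes and phenotypes disagree on the number of progeny", call. = FALSE)
  null_fit <- fit_null(Y)
  omegas <- lapply(grid, function(pos) qtl_weights(genotypes, map, pos)$omega)
  lr <- numeric(length(grid))
  best <- NULL
  for (k in seq_along(grid)) {
    fit <- tryCatch(
      fit_position(Y, omegas[[k]], null_fit, tol = tol, max_iter = max_iter),
      error = function(e)
        stop(sprintf("EM failed at %.2f cM: %s", grid[k], conditionMessage(e)),
             call. = FALSE))
    lr[k] <- fit$lr
    if (is.null(best) || fit$lr > best$lr) best <- c(fit, list(k = k))
  }
  peak <- which.max(lr)
  structure(list(positions_cM = grid, lr = lr,
                 peak_position_cM = grid[peak], peak_lr = lr[peak],
                 peak_model = if (keep_models) best$model else NULL,
                 peak_posteriors = if (keep_models && !is.null(best$state))
                   best$state$posteriors else NULL,
                 null_fit = null_fit,
                 threshold = NULL, alpha = NULL, n_permutations = NULL,
                 seed = NULL),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d positions; peak LR = %.2f at %.1f cM\n",
              length(x$positions_cM), x$peak_lr, x$peak_position_cM))
  if (!is.null(x$threshold))
    cat(sprintf("  permutation threshold (alpha = %g, %d permutations): %.2f -> %s\n",
                x$alpha, x$n_permutations, x$threshold,
                if (x$peak_lr > x$threshold) "significant QTL" else "no significant QTL"))
  invisible(x)
}

#' @export
plot.scan_result <- function(x, ...) {
  graphics::plot(x$positions_cM, x$lr, type = "l", xlab = "map position (cM)",
                 ylab = "LR statistic", ...)
  if (!is.null(x$threshold))
    graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Permutation threshold for the genome-scan peak
#'
#' Breaks the phenotype-genotype link by shuffling whole phenotype rows
#' against the (fixed) genotype matrix, reruns the full scan per
#' permutation, and returns the empirical `1 - alpha` quantile (type 7) of
#' the max-LR distribution. Shuffling rows preserves the within-shape
#' correlation structure of each phenotype vector.
#'
#' @inheritParams qtl_scan
#' @param n_perm number of permutations (>= 20).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed for the permutation stream.
#' @param grid test positions (defaults to [scan_grid()]).
#' @return scalar threshold, with the max-LR draws in attribute
#'   `"max_lr"`.
#' @export
permutation_threshold <- function(Y, genotypes, map = NULL, grid = NULL,
                                  n_perm = 1000, alpha = 0.05, seed = 1,
                                  tol = 1e-6, max_iter = 200) {
  Y <- as_Y(Y)
  stopifnot(n_perm >= 20, alpha > 0, alpha < 1)
  if (n_perm * alpha < 1)
    warning("n_perm * alpha < 1: threshold resolution is insufficient")
  if (is.null(map)) map <- genotypes$map
  if (is.null(grid)) grid <- scan_grid(map)
  n <- nrow(Y)
  omegas <- lapply(grid, function(pos) qtl_weights(genotypes, map, pos)$omega)
  perms <- withr::with_seed(seed,
    lapply(seq_len(n_perm), function(b) sample.int(n)))
  max_lr <- vapply(perms, function(pm) {
    Yp <- Y[pm, , drop = FALSE]
    null_fit <- fit_null(Yp)  # identical to the unpermuted null, kept explicit
    max(vapply(omegas, function(om)
      fit_position(Yp, om, null_fit, tol = tol, max_iter = max_iter)$lr,
      numeric(1)))
  }, numeric(1))
  thr <- unname(quantile(max_lr, probs = 1 - alpha, type = 7))
  attr(thr, "max_lr") <- max_lr
  thr
}

#' Attach a permutation threshold to a scan result
#'
#' @param scan a `scan_result`.
#' @param threshold value from [permutation_threshold()].
#' @param alpha,n_perm,seed provenance of the threshold.
#' @return the updated `scan_result`.
#' @export
set_threshold <- function(scan, threshold, alpha, n_perm, seed) {
  scan$threshold <- as.numeric(threshold)
  scan$alpha <- alpha
  scan$n_permutations <- n_perm
  scan$seed <- seed
  scan
}

#' Write a scan profile and summary
#'
#' @param scan a `scan_result`.
#' @param csv_path profile CSV (`position_cM, lr`).
#' @param json_path optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_scan <- function(scan, csv_path, json_path = NULL) {
  write.csv(data.frame(position_cM = scan$positions_cM,
                       lr = signif(scan$lr, 12)),
            csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- list(peak_position_cM = scan$peak_position_cM, peak_lr = scan$peak_lr,
              threshold = scan$threshold, alpha = scan$alpha,
              n_perm = scan$n_permutations, seed = scan$seed)
    jsonlite::write_json(s[!vapply(s, is.null, logical(1))], json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
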