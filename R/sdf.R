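#' Signed distance function of a binary shape
#'
#' Embeds the shape contour as the zero level set of a signed distance
#' field: each background pixel carries the exact Euclidean distance
#' (pixel center to pixel center) to the nearest foreground pixel, and
#' each foreground pixel carries minus the distance to the nearest
#' background pixel. The minimum magnitude is therefore 1 and the zero
#' level set lies between pixels; thresholding the field at 0 recovers
#' the input exactly.
#'
#' @param image a [shape_image] or a 0/1 matrix with both classes present.
#' @return an object of class `signed_distance_map` with fields `L` and
#'   `values` (negative inside, positive outside).
#' @export
signed_distance <- function(image) {
  px <- if (inherits(image, "shape_image")) image$pixels else image
  stopifnot(is.matrix(px), nrow(px) == ncol(px))
  nf <- sum(px == 1)
  if (nf == 0 || nf == length(px))
    stop("degenerate shape: need both foreground and background pixels", call. = FALSE)
  inside <- as.matrix(EBImage::distmap(px, metric = "euclidean"))
  outside <- as.matrix(EBImage::distmap(1 - px, metric = "euclidean"))
  structure(list(L = nrow(px), values = outside - inside),
            class = "signed_distance_map")
}

#' @export
print.signed_distance_map <- function(x, ...) {
  cat(sprintf("signed_distance_map: %d x %d, range [%.3f, %.3f]\n",
              x$L, x$L, min(x$values), max(x$values)))
  invisible(x)
}

#' Build the phenotype matrix from aligned shapes
#'
#' Each aligned (real-valued) image is binarised at `binarize_threshold`,
#' embedded as a signed distance field, and stacked lexicographically
#' (column-major) into one row of the n x m phenotype matrix, m = L^2.
#'
#' @param aligned an `aligned_shape_set` from [align_shapes()], a
#'   [shape_set] (already aligned / simulated without pose variation), or a
#'   plain list of L x L matrices.
#' @param binarize_threshold threshold in (0, 1) applied to interpolated
#'   images before the distance transform.
#' @param ids progeny identifiers (taken from the input when available).
#' @return an object of class `phenotype_matrix` with fields `values`
#'   (n x m), `ids`, `L`, `n`, `m`.
#' @export
build_phenotypes <- function(aligned, binarize_threshold = 0.5, ids = NULL) {
  stopifnot(binarize_threshold > 0, binarize_threshold < 1)
  if (inherits(aligned, "shape_set")) {
    imgs <- lapply(aligned$images, function(im) im$pixels)
    if (is.null(ids)) ids <- aligned$ids
  } else if (inherits(aligned, "aligned_shape_set")) {
    imgs <- aligned$images
    if (is.null(ids)) ids <- aligned$ids
  } else {
    imgs <- aligned
  }
  n <- length(imgs)
  L <- nrow(imgs[[1]])
  if (is.null(ids)) ids <- paste0("progeny_", seq_len(n))
  Y <- matrix(NA_real_, n, L * L)
  for (i in seq_len(n)) {
    bin <- (imgs[[i]] > binarize_threshold) * 1
    nf <- sum(bin)
    if (nf == 0 || nf == length(bin))
      stop(sprintf("progeny '%s': binarised image is degenerate (all %s)",
                   ids[i], if (nf == 0) "background" else "foreground"),
           call. = FALSE)
    Y[i, ] <- vectorize_lexicographic(signed_distance(bin)$values)
  }
  structure(list(values = Y, ids = as.character(ids), L = L, n = n, m = L * L),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix: n = %d progeny, m = %d variables (L = %d)\n",
              x$n, x$m, x$L))
  invisible(x)
}

#' Reconstruct a binary shape from a mean SDF vector
#'
#' Un-stacks a length-m vector into its L x L grid and thresholds at the
#' zero level set (values <= 0 become foreground). Used to render the
#' estimated genotype mean shapes.
#'
#' @param mean_vector length-`L^2` numeric vector (e.g. a fitted `mu`).
#' @param L grid side.
#' @return a [shape_image]; warns if the field has no sign change (empty or
#'   full reconstruction) and then returns the degenerate 0/1 matrix
#'   unclassed.
#' @export
reconstruct_shape <- function(mean_vector, L) {
  grid <- unvectorize(mean_vector, L)
  fg <- (grid <= 0) * 1
  nf <- sum(fg)
  if (nf == 0 || nf == length(fg)) {
    warning("degenerate reconstruction: mean field has no zero crossing (",
            if (nf == 0) "empty" else "full", " shape)")
    return(fg)
  }
  shape_image(fg)
}

#' Dice similarity coefficient between two binary shapes
#'
#' `2 |A intersect B| / (|A| + |B|)` over foreground pixels; 1 for
#' identical shapes, 0 for disjoint ones.
#'
#' @param a,b [shape_image] objects or 0/1 matrices of equal size.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "shape_image")) a$pixels else a
  pb <- if (inherits(b, "shape_image")) b$pixels else b
  stopifnot(all(dim(pa) == dim(pb)))
  denom <- sum(pa == 1) + sum(pb == 1)
  if (denom == 0) return(NaN)
  2 * sum(pa == 1 & pb == 1) / denom
}

#' Read and write phenotype matrices as CSV
#'
#' The CSV has an `id` column followed by one column per variable index
#' (`v1 ... vm`); values round-trip to 12 significant digits.
#'
#' @param phen a `phenotype_matrix`.
#' @param path CSV path.
#' @return `write_phenotypes`: `path` invisibly; `read_phenotypes`: a
#'   `phenotype_matrix`.
#' @export
write_phenotypes <- function(phen, path) {
  stopifnot(inherits(phen, "phenotype_matrix"))
  df <- data.frame(id = phen$ids,
                   signif(phen$values, 12),
                   check.names = FALSE)
  names(df) <- c("id", paste0("v", seq_len(phen$m)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df$id)
  Y <- as.matrix(df[, -1, drop = FALSE])
  dimnames(Y) <- NULL
  m <- ncol(Y)
  L <- as.integer(round(sqrt(m)))
  if (L * L != m)
    stop("phenotype CSV has ", m, " variables, not a perfect square", call. = FALSE)
  structure(list(values = Y, ids = ids, L = L, n = nrow(Y), m = m),
            class = "phenotype_matrix")
}
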