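#' Linkage map of ordered markers
#'
#' @param marker_names character vector of M marker names.
#' @param positions_cM nondecreasing numeric vector of map positions in
#'   centiMorgans; duplicated positions are collapsed (first name kept).
#' @return an object of class `linkage_map` with fields `marker_names`,
#'   `positions_cM`, `M`.
#' @export
linkage_map <- function(marker_names, positions_cM) {
  stopifnot(length(marker_names) == length(positions_cM))
  if (is.unsorted(positions_cM))
    stop("marker positions must be nondecreasing", call. = FALSE)
  keep <- !duplicated(positions_cM)
  marker_names <- as.character(marker_names[keep])
  positions_cM <- as.numeric(positions_cM[keep])
  if (length(positions_cM) < 2)
    stop("a linkage map needs at least two distinct marker positions", call. = FALSE)
  structure(list(marker_names = marker_names, positions_cM = positions_cM,
                 M = length(positions_cM)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage_map: %d markers spanning %.1f cM\n",
              x$M, diff(range(x$positions_cM))))
  invisible(x)
}

#' Haldane map function
#'
#' Converts map distance (cM) to a recombination fraction assuming no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM nonnegative map distance(s) in centiMorgans.
#' @return recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be nonnegative", call. = FALSE)
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate backcross marker genotypes along a linkage map
#'
#' Each progeny's genotype vector is a Markov chain over the ordered
#' markers: the first marker is QQ (1) or Qq (2) with probability 1/2
#' each, and the state switches across each interval with probability
#' equal to its Haldane recombination fraction (no interference).
#'
#' @param map a [linkage_map()].
#' @param n number of progeny.
#' @param seed integer RNG seed (required for reproducibility).
#' @return an object of class `backcross_genotypes`: list with `values`
#'   (n x M matrix of 1/2), `ids`, `map`.
#' @export
simulate_genotypes <- function(map, n, seed) {
  stopifnot(inherits(map, "linkage_map"), n >= 1)
  rfs <- haldane_r(diff(map$positions_cM))
  G <- withr::with_seed(seed, {
    G <- matrix(0L, n, map$M)
    G[, 1] <- sample(c(1L, 2L), n, replace = TRUE)
    for (k in seq_along(rfs)) {
      swap <- runif(n) < rfs[k]
      G[, k + 1] <- ifelse(swap, 3L - G[, k], G[, k])
    }
    G
  })
  structure(list(values = G, ids = paste0("progeny_", seq_len(n)), map = map),
            class = "backcross_genotypes")
}

#' @export
print.backcross_genotypes <- function(x, ...) {
  cat(sprintf("backcross_genotypes: %d progeny x %d markers (1 = QQ, 2 = Qq)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Conditional QTL-genotype probabilities given flanking markers
#'
#' For a putative QTL between two flanking markers with recombination
#' fractions r1 (to the left marker) and r2 (to the right marker), with
#' inter-marker fraction `r = r1 + r2 - 2 r1 r2` under no interference,
#' the probability that a backcross individual carries QTL genotype QQ is
#' the standard flanking-marker table:
#' \tabular{ll}{
#'   flanking (1,1) \tab (1-r1)(1-r2) / (1-r) \cr
#'   flanking (1,2) \tab (1-r1) r2 / r \cr
#'   flanking (2,1) \tab r1 (1-r2) / r \cr
#'   flanking (2,2) \tab r1 r2 / (1-r)
#' }
#' with `omega_2 = 1 - omega_1`. At a marker position the weights collapse
#' to the indicator of that marker's genotype.
#'
#' @param genotypes a [simulate_genotypes()] result or an n x M matrix of
#'   1/2 codes.
#' @param map a [linkage_map()] (taken from `genotypes` when omitted).
#' @param position_cM test position, inside the map span.
#' @return an object of class `mixture_weights`: list with `omega` (n x 2,
#'   rows summing to one), `position_cM`.
#' @export
qtl_weights <- function(genotypes, map = NULL, position_cM) {
  if (inherits(genotypes, "backcross_genotypes")) {
    if (is.null(map)) map <- genotypes$map
    G <- genotypes$values
  } else G <- genotypes
  stopifnot(inherits(map, "linkage_map"))
  if (anyNA(G)) stop("missing marker genotypes are not supported", call. = FALSE)
  pos <- map$positions_cM
  if (position_cM < pos[1] || position_cM > pos[map$M])
    stop(sprintf("test position %.2f cM lies outside the map span [%.2f, %.2f]",
                 position_cM, pos[1], pos[map$M]), call. = FALSE)
  n <- nrow(G)
  hit <- which(abs(pos - position_cM) < 1e-9)
  if (length(hit)) {
    w1 <- as.numeric(G[, hit[1]] == 1L)
  } else {
    left <- max(which(pos < position_cM))
    right <- left + 1L
    r1 <- haldane_r(position_cM - pos[left])
    r2 <- haldane_r(pos[right] - position_cM)
    r <- r1 + r2 - 2 * r1 * r2
    w_table <- c(`11` = (1 - r1) * (1 - r2) / (1 - r),
                 `12` = (1 - r1) * r2 / r,
                 `21` = r1 * (1 - r2) / r,
                 `22` = r1 * r2 / (1 - r))
    cls <- paste0(G[, left], G[, right])
    w1 <- unname(w_table[cls])
  }
  structure(list(omega = cbind(w1, 1 - w1, deparse.level = 0),
                 position_cM = position_cM),
            class = "mixture_weights")
}

#' Read and write linkage maps and genotype matrices as CSV
#'
#' Map CSV columns: `marker, chrom, pos_cM` (a single linkage group is
#' assumed). Genotype CSV: `id` column then one 1/2-coded column per
#' marker.
#'
#' @param map a [linkage_map()]; `genotypes` a `backcross_genotypes`.
#' @param path CSV path.
#' @param genotypes genotype object for `write_genotypes`.
#' @return writers return `path` invisibly; readers return the object.
#' @export
write_linkage_map <- function(map, path) {
  write.csv(data.frame(marker = map$marker_names, chrom = 1L,
                       pos_cM = map$positions_cM),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  df <- read.csv(path)
  linkage_map(df$marker, df$pos_cM)
}

#' @rdname write_linkage_map
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = genotypes$ids, genotypes$values)
  names(df) <- c("id", genotypes$map$marker_names)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linkage_map
#' @param map_for_read linkage map to attach when reading genotypes.
#' @export
read_genotypes <- function(path, map_for_read) {
  df <- read.csv(path)
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- NULL
  storage.mode(G) <- "integer"
  if (!all(G %in% c(1L, 2L)))
    stop("genotype entries must be coded 1 (QQ) or 2 (Qq)", call. = FALSE)
  structure(list(values = G, ids = as.character(df$id), map = map_for_read),
            class = "backcross_genotypes")
}
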