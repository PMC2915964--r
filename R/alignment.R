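#' Pose parameters of a similarity transform
#'
#' A pose `p = [a, b, h, theta]` holds the x/y translation (pixels), the
#' isotropic scale (h > 0) and the in-plane rotation (radians, stored in
#' (-pi, pi]). Poses act about the image center ((L+1)/2, (L+1)/2), not the
#' coordinate origin, so scaling and rotation keep shapes inside the grid.
#'
#' @param a,b translations along x (columns) and y (rows), in pixels.
#' @param h isotropic scale, must be positive.
#' @param theta rotation in radians.
#' @return an object of class `pose_parameters`.
#' @export
pose <- function(a = 0, b = 0, h = 1, theta = 0) {
  if (!is.finite(h) || h <= 0)
    stop("invalid pose: scale h must be positive", call. = FALSE)
  theta <- atan2(sin(theta), cos(theta))  # wrap into (-pi, pi]
  if (theta == -pi) theta <- pi
  structure(list(a = a, b = b, h = h, theta = theta), class = "pose_parameters")
}

#' @export
print.pose_parameters <- function(x, ...) {
  cat(sprintf("pose: a=%.4f b=%.4f h=%.4f theta=%.4f rad (%.2f deg)\n",
              x$a, x$b, x$h, x$theta, x$theta * 180 / pi))
  invisible(x)
}

#' Homogeneous transform matrix of a pose
#'
#' Returns the 3 x 3 matrix `T[p] = M(a, b) %*% H(h) %*% R(theta)` — a
#' translation, a scaling and an in-plane rotation composed in that order —
#' acting on homogeneous coordinates measured from the image center. A
#' centered point v maps to `(a, b) + h * R(theta) %*% v`.
#'
#' @param p a [pose()] object.
#' @return 3 x 3 numeric matrix; the upper-left 2 x 2 block has determinant
#'   `h^2` and the bottom row is (0, 0, 1).
#' @export
pose_matrix <- function(p) {
  stopifnot(inherits(p, "pose_parameters"))
  M <- diag(3); M[1, 3] <- p$a; M[2, 3] <- p$b
  H <- diag(c(p$h, p$h, 1))
  R <- diag(3)
  R[1, 1] <- cos(p$theta); R[1, 2] <- -sin(p$theta)
  R[2, 1] <- sin(p$theta); R[2, 2] <- cos(p$theta)
  M %*% H %*% R
}

# Recover (a, b, h, theta) from a similarity matrix in centered coordinates.
pose_from_matrix <- function(Tm) {
  h <- sqrt(abs(det(Tm[1:2, 1:2])))
  theta <- atan2(Tm[2, 1], Tm[1, 1])
  pose(a = Tm[1, 3], b = Tm[2, 3], h = h, theta = theta)
}

# Bilinear sampling of `img` (L x L, x = column, y = row) at coordinate
# fields ux, uy, with zero value outside the domain. Returns the sampled
# field and, if deriv, the exact partial derivatives of the interpolant.
sample_bilinear <- function(img, ux, uy, deriv = FALSE) {
  L <- nrow(img)
  P <- matrix(0, L + 2L, L + 2L)
  P[2:(L + 1L), 2:(L + 1L)] <- img
  inside <- ux > 0 & ux < L + 1 & uy > 0 & uy < L + 1
  x <- pmin(pmax(ux, 0), L + 1)
  y <- pmin(pmax(uy, 0), L + 1)
  x0 <- pmin(floor(x), L)  # keep x0 + 1 a valid padded column
  y0 <- pmin(floor(y), L)
  fx <- x - x0
  fy <- y - y0
  np <- L + 2L
  # padded linear indices; padded row = y + 1, padded col = x + 1
  i00 <- (y0 + 1L) + (x0)     * np  # P[y0+1, x0+1]
  i01 <- (y0 + 2L) + (x0)     * np  # y0+2 (y + 1)
  i10 <- (y0 + 1L) + (x0 + 1L) * np # x0+2 (x + 1)
  i11 <- (y0 + 2L) + (x0 + 1L) * np
  v00 <- P[i00]; v01 <- P[i01]; v10 <- P[i10]; v11 <- P[i11]
  val <- (1 - fx) * ((1 - fy) * v00 + fy * v01) + fx * ((1 - fy) * v10 + fy * v11)
  val[!inside] <- 0
  if (!deriv) return(list(value = val))
  dx <- (1 - fy) * (v10 - v00) + fy * (v11 - v01)
  dy <- (1 - fx) * (v01 - v00) + fx * (v11 - v10)
  dx[!inside] <- 0
  dy[!inside] <- 0
  list(value = val, dx = dx, dy = dy)
}

# Inverse-transform coordinate fields for pull-sampling under pose
# (a, b, h, theta): u = c + R(-theta) (x - c - t) / h.
pose_pull_coords <- function(L, a, b, h, theta) {
  ctr <- (L + 1) / 2
  xs <- matrix(rep(seq_len(L), each = L), L, L)   # x = column index
  ys <- matrix(rep(seq_len(L), times = L), L, L)  # y = row index
  dx <- xs - ctr - a
  dy <- ys - ctr - b
  ct <- cos(theta); st <- sin(theta)
  wx <- (ct * dx + st * dy) / h
  wy <- (-st * dx + ct * dy) / h
  list(ux = ctr + wx, uy = ctr + wy, wx = wx, wy = wy)
}

#' Apply a pose to an image
#'
#' Pull-samples the input at the inverse-transformed coordinates:
#' `out(x, y) = in(T[p]^-1 (x, y))`, with coordinates outside the domain
#' evaluating to background (0). Bilinear interpolation is the default;
#' nearest-neighbour is lossless for integer translations and is used to
#' snap aligned images back to binary for display.
#'
#' @param image a [shape_image] or a plain numeric L x L matrix.
#' @param p a [pose()].
#' @param interp `"bilinear"` or `"nearest"`.
#' @return numeric L x L matrix with values in the range of the input.
#' @export
apply_pose <- function(image, p, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  img <- if (inherits(image, "shape_image")) image$pixels else image
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  L <- nrow(img)
  co <- pose_pull_coords(L, p$a, p$b, p$h, p$theta)
  if (interp == "bilinear")
    return(sample_bilinear(img, co$ux, co$uy)$value)
  xi <- round(co$ux); yi <- round(co$uy)
  ok <- xi >= 1 & xi <= L & yi >= 1 & yi <= L
  out <- matrix(0, L, L)
  out[ok] <- img[cbind(yi[ok], xi[ok])]
  out
}

# Gaussian pre-smoothing so spatial gradients of binary images exist.
smooth_image <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, brush, boundary = 0))
}

#' Joint alignment energy of a set of images
#'
#' The pairwise image-difference energy over the image domain Omega:
#' normalised form `E = sum_{i<j} sum((Ii - Ij)^2) / sum((Ii + Ij)^2)`
#' (default), or the raw form `sum_{i<j} sum((Ii - Ij)^2)`. The
#' denominator removes the degenerate minimum in which every shape is
#' shrunk to nothing.
#'
#' @param images list of equal-sized numeric matrices (transformed images).
#' @param normalized use the normalised form (default TRUE).
#' @return nonnegative scalar; 0 for identical images or a single image.
#' @export
joint_energy <- function(images, normalized = TRUE) {
  n <- length(images)
  if (n <= 1) return(0)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all images must have the same dimensions", call. = FALSE)
  E <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum((images[[i]] - images[[j]])^2)
    if (normalized) {
      den <- sum((images[[i]] + images[[j]])^2)
      if (den > 0) E <- E + num / den
    } else E <- E + num
  }
  E
}

# Energy and analytic gradient for smoothed source images `S` (list) at
# pose parameterisation q (n x 4 matrix: a, b, s = log h, theta).
# Returns list(E, grad n x 4). The gradient flows through the exact
# derivative of the bilinear interpolant and the Jacobian of the inverse
# coordinates in each pose component.
energy_and_gradient <- function(S, q, normalized = TRUE, want_grad = TRUE) {
  n <- length(S)
  L <- nrow(S[[1]])
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    h <- exp(q[i, 3]); theta <- q[i, 4]
    co <- pose_pull_coords(L, q[i, 1], q[i, 2], h, theta)
    sm <- sample_bilinear(S[[i]], co$ux, co$uy, deriv = want_grad)
    tr[[i]] <- c(sm, co, list(h = h, theta = theta))
  }
  E <- 0
  A <- if (want_grad) lapply(seq_len(n), function(i) matrix(0, L, L)) else NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    di <- tr[[i]]$value - tr[[j]]$value
    num <- sum(di^2)
    if (normalized) {
      su <- tr[[i]]$value + tr[[j]]$value
      den <- sum(su^2)
      if (den <= 0) next
      E <- E + num / den
      if (want_grad) {
        co_ij <- 2 * di / den - (2 * num / den^2) * su
        A[[i]] <- A[[i]] + co_ij
        A[[j]] <- A[[j]] - 2 * di / den - (2 * num / den^2) * su
      }
    } else {
      E <- E + num
      if (want_grad) {
        A[[i]] <- A[[i]] + 2 * di
        A[[j]] <- A[[j]] - 2 * di
      }
    }
  }
  if (!want_grad) return(list(E = E, grad = NULL))
  grad <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    t_i <- tr[[i]]
    ct <- cos(t_i$theta); st <- sin(t_i$theta); h <- t_i$h
    gx <- t_i$dx; gy <- t_i$dy; Ai <- A[[i]]
    # du/da = (-ct, st)/h ; du/db = (-st, -ct)/h ; du/ds = -(w) ; du/dtheta = (wy, -wx)
    grad[i, 1] <- sum(Ai * (gx * (-ct / h) + gy * (st / h)))
    grad[i, 2] <- sum(Ai * (gx * (-st / h) + gy * (-ct / h)))
    grad[i, 3] <- sum(Ai * (-gx * t_i$wx - gy * t_i$wy))
    grad[i, 4] <- sum(Ai * (gx * t_i$wy - gy * t_i$wx))
  }
  list(E = E, grad = grad)
}

#' Analytic gradient of the joint alignment energy
#'
#' Partial derivatives of [joint_energy()] with respect to each pose
#' component (a, b, h, theta) of each shape, evaluated on Gaussian-smoothed
#' copies of the input shapes (binary images have no spatial derivatives).
#'
#' @param shapes a [shape_set()].
#' @param poses list of n [pose()] objects.
#' @param normalized energy variant, as in [joint_energy()].
#' @param sigma Gaussian pre-smoothing bandwidth in pixels.
#' @return n x 4 matrix with columns (a, b, h, theta).
#' @export
energy_gradient <- function(shapes, poses, normalized = TRUE, sigma = 1) {
  stopifnot(inherits(shapes, "shape_set"), length(poses) == shapes$n)
  S <- lapply(shapes$images, function(im) smooth_image(im$pixels, sigma))
  q <- t(vapply(poses, function(p) c(p$a, p$b, log(p$h), p$theta), numeric(4)))
  g <- energy_and_gradient(S, q, normalized = normalized)$grad
  # chain rule from s = log h back to h
  hs <- vapply(poses, function(p) p$h, numeric(1))
  g[, 3] <- g[, 3] / hs
  colnames(g) <- c("a", "b", "h", "theta")
  g
}

#' Alignment configuration
#'
#' @param normalized use the normalised pairwise energy (default TRUE).
#' @param tol relative energy-change stopping tolerance.
#' @param max_iter maximum descent iterations.
#' @param step0 initial line-search step (scaled so the largest pose
#'   component moves `step0` units on the first trial).
#' @param sigma Gaussian pre-smoothing bandwidth (pixels).
#' @param reference_index index of the gauge shape whose pose is frozen at
#'   identity.
#' @return a list of class `align_config`.
#' @export
align_config <- function(normalized = TRUE, tol = 1e-6, max_iter = 500,
                         step0 = 0.1, sigma = 1, reference_index = 1) {
  structure(list(normalized = normalized, tol = tol, max_iter = max_iter,
                 step0 = step0, sigma = sigma, reference_index = reference_index),
            class = "align_config")
}

#' Jointly align a set of binary shapes
#'
#' Estimates a pose (translation, scale, rotation) per shape by steepest
#' gradient descent with backtracking line search on the joint pairwise
#' energy. Scale is optimised as log h so positivity is automatic; the
#' reference shape's pose is frozen at identity to pin the common frame.
#' Poses are warm-started from foreground centroids (translation) and
#' square-rooted foreground areas (scale), with zero initial rotation.
#'
#' @param shapes a [shape_set()] with n >= 2 images.
#' @param config an [align_config()].
#' @return an object of class `aligned_shape_set` with fields `images`
#'   (bilinear-transformed real-valued images), `poses`, `energy_trace`
#'   (non-increasing), `converged`, `n_iter`, `ids`, `L`.
#' @export
align_shapes <- function(shapes, config = align_config()) {
  stopifnot(inherits(shapes, "shape_set"))
  n <- shapes$n
  if (n < 2) stop("alignment needs at least two shapes", call. = FALSE)
  L <- shapes$L
  ref <- config$reference_index
  S <- lapply(shapes$images, function(im) smooth_image(im$pixels, config$sigma))

  # moment-based warm start relative to the reference shape
  ctr <- (L + 1) / 2
  stats_of <- function(px) {
    fg <- which(px == 1, arr.ind = TRUE)
    c(cx = mean(fg[, 2]), cy = mean(fg[, 1]), area = nrow(fg))
  }
  st <- t(vapply(shapes$images, function(im) stats_of(im$pixels), numeric(3)))
  q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    if (i == ref) next
    q[i, 1] <- st[ref, "cx"] - st[i, "cx"]
    q[i, 2] <- st[ref, "cy"] - st[i, "cy"]
    q[i, 3] <- 0.5 * log(st[ref, "area"] / st[i, "area"])
  }

  eg <- energy_and_gradient(S, q, normalized = config$normalized)
  trace <- eg$E
  alpha <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    g <- eg$grad
    g[ref, ] <- 0
    gmax <- max(abs(g))
    if (gmax < 1e-12 || eg$E < 1e-14) { converged <- TRUE; break }
    if (is.na(alpha)) alpha <- config$step0 / gmax
    accepted <- FALSE
    first_try <- TRUE
    for (k in 1:40) {
      q_new <- q - alpha * g
      e_new <- energy_and_gradient(S, q_new, normalized = config$normalized,
                                   want_grad = FALSE)$E
      if (e_new < eg$E) { accepted <- TRUE; break }
      alpha <- alpha * 0.5
      first_try <- FALSE
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    rel <- (eg$E - e_new) / max(eg$E, .Machine$double.eps)
    q <- q_new
    eg <- energy_and_gradient(S, q, normalized = config$normalized)
    trace <- c(trace, eg$E)
    if (first_try) alpha <- alpha * 2
    if (rel < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("alignment did not converge within max_iter = ", config$max_iter)

  poses <- lapply(seq_len(n), function(i)
    pose(a = q[i, 1], b = q[i, 2], h = exp(q[i, 3]), theta = q[i, 4]))
  aligned <- lapply(seq_len(n), function(i)
    apply_pose(shapes$images[[i]], poses[[i]], interp = "bilinear"))
  structure(list(images = aligned, poses = poses, energy_trace = trace,
                 converged = converged, n_iter = iter, ids = shapes$ids, L = L),
            class = "aligned_shape_set")
}

#' @export
print.aligned_shape_set <- function(x, ...) {
  cat(sprintf("aligned_shape_set: %d shapes, %d x %d; E %.4g -> %.4g in %d iterations%s\n",
              length(x$images), x$L, x$L, x$energy_trace[1],
              x$energy_trace[length(x$energy_trace)], x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Write a per-shape alignment report
#'
#' @param aligned an `aligned_shape_set` from [align_shapes()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(aligned, path) {
  df <- data.frame(
    id = aligned$ids,
    a = vapply(aligned$poses, function(p) p$a, numeric(1)),
    b = vapply(aligned$poses, function(p) p$b, numeric(1)),
    h = vapply(aligned$poses, function(p) p$h, numeric(1)),
    theta = vapply(aligned$poses, function(p) p$theta, numeric(1)),
    final_energy = aligned$energy_trace[length(aligned$energy_trace)]
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
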