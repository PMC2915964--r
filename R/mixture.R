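#' Gaussian log-density of a phenotype vector
#'
#' Under the working covariance `Sigma = sigma2 * I` the m variables are
#' independent, so the multivariate-normal log-density is the sum of m
#' univariate terms: `-(m/2) log(2 pi sigma2) - ||y - mu||^2 / (2 sigma2)`.
#'
#' @param y,mu numeric vectors of equal length.
#' @param sigma2 positive residual variance, common to both genotypes.
#' @return scalar log-density.
#' @export
log_density <- function(y, mu, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  stopifnot(length(y) == length(mu))
  m <- length(y)
  -(m / 2) * log(2 * pi * sigma2) - sum((y - mu)^2) / (2 * sigma2)
}

# Fast n x 2 matrix of per-progeny component log-densities.
# Uses ||Y_i - mu||^2 = rowSums(Y^2) - 2 Y mu + ||mu||^2 so each component
# costs one matrix-vector product.
component_logliks <- function(Y, rY, mu1, mu2, sigma2) {
  m <- ncol(Y)
  cst <- -(m / 2) * log(2 * pi * sigma2)
  q1 <- rY - 2 * drop(Y %*% mu1) + sum(mu1^2)
  q2 <- rY - 2 * drop(Y %*% mu2) + sum(mu2^2)
  cbind(cst - q1 / (2 * sigma2), cst - q2 / (2 * sigma2))
}

new_mixture_model <- function(mu1, mu2, sigma2, loglik = NA_real_) {
  structure(list(mu1 = mu1, mu2 = mu2, sigma2 = sigma2, loglik = loglik),
            class = "qtl_mixture_model")
}

#' @export
print.qtl_mixture_model <- function(x, ...) {
  cat(sprintf("qtl_mixture_model: m = %d, sigma2 = %.4g, loglik = %.4f\n",
              length(x$mu1), x$sigma2, x$loglik))
  invisible(x)
}

check_weights <- function(w, n) {
  om <- if (inherits(w, "mixture_weights")) w$omega else w
  stopifnot(is.matrix(om), ncol(om) == 2)
  if (nrow(om) != n)
    stop("mixture weights and phenotypes disagree on n", call. = FALSE)
  if (any(om < 0) || any(abs(rowSums(om) - 1) > 1e-8))
    stop("each omega row must be nonnegative and sum to one", call. = FALSE)
  om
}

as_Y <- function(Y) if (inherits(Y, "phenotype_matrix")) Y$values else Y

#' Mixture log-likelihood of the phenotype matrix
#'
#' `sum_i log(omega_1|i f1(Y_i) + omega_2|i f2(Y_i))`, evaluated in log
#' space with log-sum-exp: with m in the thousands the raw densities
#' underflow double precision catastrophically.
#'
#' @param Y a `phenotype_matrix` or plain n x m matrix.
#' @param w a [qtl_weights()] result or n x 2 matrix of prior weights.
#' @param model a `qtl_mixture_model` (fields `mu1`, `mu2`, `sigma2`).
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(Y, w, model) {
  Y <- as_Y(Y)
  om <- check_weights(w, nrow(Y))
  ll <- component_logliks(Y, rowSums(Y^2), model$mu1, model$mu2, model$sigma2)
  sum(logsumexp_rows(log(om) + ll))
}

# rowwise log(exp(a1) + exp(a2)) for an n x 2 matrix; -Inf rows allowed.
logsumexp_rows <- function(A) {
  mx <- pmax(A[, 1], A[, 2])
  out <- mx + log(exp(A[, 1] - mx) + exp(A[, 2] - mx))
  out[mx == -Inf] <- -Inf
  out
}

#' E step: posterior QTL-genotype probabilities
#'
#' Bayes rule per progeny,
#' `Pi_j|i = omega_j|i f_j(Y_i) / sum_j' omega_j'|i f_j'(Y_i)`,
#' computed via log-space normalisation.
#'
#' @inheritParams mixture_loglik
#' @return n x 2 matrix of posteriors; rows sum to one.
#' @export
e_step <- function(Y, w, model) {
  Y <- as_Y(Y)
  om <- check_weights(w, nrow(Y))
  ll <- component_logliks(Y, rowSums(Y^2), model$mu1, model$mu2, model$sigma2)
  A <- log(om) + ll
  norm <- logsumexp_rows(A)
  if (any(!is.finite(norm)))
    stop("zero posterior mass for progeny ",
         paste(which(!is.finite(norm)), collapse = ", "), call. = FALSE)
  exp(A - norm)
}

#' M step: update genotype means and the common variance
#'
#' Posterior-weighted means per genotype and the pooled residual variance
#' across genotypes and variables:
#' `mu_jk = sum_i Pi_j|i y_ik / sum_i Pi_j|i`,
#' `sigma2 = (1/(n m)) sum_ijk Pi_j|i (y_ik - mu_jk)^2`.
#'
#' @param Y a `phenotype_matrix` or n x m matrix.
#' @param posteriors n x 2 matrix of posterior probabilities.
#' @return an updated `qtl_mixture_model` (loglik left `NA`).
#' @export
m_step <- function(Y, posteriors) {
  Y <- as_Y(Y)
  n <- nrow(Y); m <- ncol(Y)
  w1 <- posteriors[, 1]; w2 <- posteriors[, 2]
  s1 <- sum(w1); s2 <- sum(w2)
  if (s1 < 1e-8 || s2 < 1e-8)
    stop("empty mixture component (posterior mass ",
         format(min(s1, s2)), ")", call. = FALSE)
  mu1 <- drop(crossprod(Y, w1)) / s1
  mu2 <- drop(crossprod(Y, w2)) / s2
  rY <- rowSums(Y^2)
  q1 <- sum(w1 * rY) - 2 * sum(w1 * drop(Y %*% mu1)) + s1 * sum(mu1^2)
  q2 <- sum(w2 * rY) - 2 * sum(w2 * drop(Y %*% mu2)) + s2 * sum(mu2^2)
  sigma2 <- max((q1 + q2) / (n * m), 1e-12)
  new_mixture_model(mu1, mu2, sigma2)
}

#' Single-component (no-QTL) maximum likelihood fit
#'
#' Closed form: `mu0` is the column-mean vector, `sigma2_0` the total mean
#' squared deviation, and the log-likelihood follows from the independent
#' Gaussian model. A variance floor of 1e-12 guards degenerate data.
#'
#' @param Y a `phenotype_matrix` or n x m matrix.
#' @return list with `mu0`, `sigma2_0`, `loglik0`.
#' @export
fit_null <- function(Y) {
  Y <- as_Y(Y)
  n <- nrow(Y); m <- ncol(Y)
  stopifnot(n >= 2)
  mu0 <- colMeans(Y)
  ss <- sum(rowSums(Y^2)) - n * sum(mu0^2)
  sigma2_0 <- max(ss / (n * m), 1e-12)
  loglik0 <- -(n * m / 2) * (log(2 * pi * sigma2_0) + ss / (n * m) / sigma2_0)
  list(mu0 = mu0, sigma2_0 = sigma2_0, loglik0 = loglik0)
}

# Deterministic initialisation: hard-assign each progeny to the component
# with the larger prior weight (ties to component 1).
init_from_weights <- function(Y, om) {
  hard <- cbind(as.numeric(om[, 1] >= om[, 2]), as.numeric(om[, 1] < om[, 2]))
  m_step(Y, hard)
}

#' Fit the two-component mixture by EM
#'
#' Alternates [e_step()] and [m_step()] from a deterministic start until
#' the log-likelihood changes by less than `tol` or `max_iter` is reached.
#' EM ascent guarantees a non-decreasing log-likelihood trace. If a
#' component empties mid-run the fit is restarted once from a perturbed
#' initialisation before failing.
#'
#' @param Y a `phenotype_matrix` or n x m matrix.
#' @param w prior mixture weights ([qtl_weights()] result or n x 2 matrix).
#' @param init optional `qtl_mixture_model` start; default hard-assigns by
#'   the larger prior weight.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `model` (a `qtl_mixture_model` with final `loglik`)
#'   and `state` (fields `posteriors`, `loglik_trace`, `converged`,
#'   `n_iter`).
#' @export
run_em <- function(Y, w, init = NULL, tol = 1e-6, max_iter = 200) {
  Y <- as_Y(Y)
  om <- check_weights(w, nrow(Y))
  attempt <- function(model) {
    trace <- numeric(0)
    post <- NULL
    converged <- FALSE
    iter <- 0L
    rY <- rowSums(Y^2)
    repeat {
      iter <- iter + 1L
      ll <- component_logliks(Y, rY, model$mu1, model$mu2, model$sigma2)
      A <- log(om) + ll
      norm <- logsumexp_rows(A)
      post <- exp(A - norm)
      loglik <- sum(norm)
      trace <- c(trace, loglik)
      if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      model <- m_step(Y, post)
    }
    model$loglik <- trace[length(trace)]
    list(model = model,
         state = list(posteriors = post, loglik_trace = trace,
                      converged = converged, n_iter = iter))
  }
  start <- if (is.null(init)) init_from_weights(Y, om) else init
  res <- tryCatch(attempt(start), error = function(e) e)
  if (inherits(res, "error")) {
    null0 <- fit_null(Y)
    sd0 <- sqrt(null0$sigma2_0)
    perturbed <- new_mixture_model(start$mu1 + 0.1 * sd0,
                                   start$mu2 - 0.1 * sd0,
                                   start$sigma2)
    res <- attempt(perturbed)  # second failure propagates
  }
  res
}
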