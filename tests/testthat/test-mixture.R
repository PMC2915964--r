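test_that("log_density matches closed forms and a product-of-normals oracle", {
  expect_equal(log_density(0, 0, 1), -0.5 * log(2 * pi))
  expect_equal(log_density(0, 0, 1), -0.918939, tolerance = 1e-6)
  for (m in c(3, 7)) {
    mu <- rep(0.3, m)
    expect_equal(log_density(mu, mu, 1), -(m / 2) * log(2 * pi))
  }
  set.seed(21)
  y <- rnorm(4); mu <- rnorm(4); s2 <- 0.6
  expect_equal(log_density(y, mu, s2),
               log(prod(dnorm(y, mu, sqrt(s2)))))
  expect_error(log_density(1, 1, 0), "positive")
})

test_that("mixture log-likelihood matches a 50-digit reference on a toy set", {
  Y <- rbind(c(0.3, -1.2), c(2.1, 0.4))
  model <- list(mu1 = c(0, -1), mu2 = c(2, 0.5), sigma2 = 0.7)
  om <- rbind(c(0.8, 0.2), c(0.35, 0.65))
  # reference value computed with 50-digit arithmetic, frozen
  expect_equal(mixture_loglik(Y, om, model), -3.7133097292633755788,
               tolerance = 1e-13)
  post <- e_step(Y, om, model)
  expect_equal(post[1, 1], 0.99560117217942109068, tolerance = 1e-12)
  expect_equal(post[2, 1], 0.0057387790334573034837, tolerance = 1e-12)
})

test_that("degenerate mixtures reduce to single components", {
  set.seed(2)
  Y <- matrix(rnorm(12), 4, 3)
  mu <- rnorm(3)
  model <- list(mu1 = mu, mu2 = mu, sigma2 = 1.3)
  om <- cbind(runif(4, 0.1, 0.9)); om <- cbind(om, 1 - om)
  # identical components: likelihood ignores omega, posteriors equal omega
  expect_equal(mixture_loglik(Y, om, model),
               sum(apply(Y, 1, log_density, mu = mu, sigma2 = 1.3)))
  expect_equal(e_step(Y, om, model), om, ignore_attr = TRUE)
  # prior certainty survives the E step
  om10 <- cbind(rep(1, 4), rep(0, 4))
  model2 <- list(mu1 = mu, mu2 = mu + 1, sigma2 = 1.3)
  expect_equal(mixture_loglik(Y, om10, model2),
               sum(apply(Y, 1, log_density, mu = mu, sigma2 = 1.3)))
  expect_equal(e_step(Y, om10, model2), om10, ignore_attr = TRUE)
})

test_that("e_step equals the direct Bayes oracle on small instances", {
  # hand value: m=1, y=0, mu=(0,2), s2=1, omega=(1/2,1/2)
  post <- e_step(matrix(0, 1, 1), matrix(0.5, 1, 2),
                 list(mu1 = 0, mu2 = 2, sigma2 = 1))
  expect_equal(post[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(post[1, 1], 0.880797, tolerance = 1e-6)
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(2:4, 1); m <- sample(1:3, 1)
    Y <- matrix(rnorm(n * m, sd = 2), n, m)
    om1 <- runif(n, 0.05, 0.95)
    om <- cbind(om1, 1 - om1)
    model <- list(mu1 = rnorm(m), mu2 = rnorm(m), sigma2 = runif(1, 0.3, 2))
    expect_equal(e_step(Y, om, model),
                 brute_posterior(Y, om, model$mu1, model$mu2, model$sigma2),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("m_step reproduces hand-computed weighted means and pooled variance", {
  Y <- matrix(c(1, 2, 4), 3, 1)
  post <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.1, 0.9))
  mod <- m_step(Y, post)
  expect_equal(mod$mu1, 2.2 / 1.4)
  expect_equal(mod$mu1, 1.571429, tolerance = 1e-6)
  expect_equal(mod$mu2, 4.8 / 1.6)
  s2 <- (0.8 * (1 - 2.2 / 1.4)^2 + 0.5 * (2 - 2.2 / 1.4)^2 + 0.1 * (4 - 2.2 / 1.4)^2 +
         0.2 * (1 - 3)^2 + 0.5 * (2 - 3)^2 + 0.9 * (4 - 3)^2) / 3
  expect_equal(mod$sigma2, s2)
  # hard posteriors give per-group means
  post_hard <- rbind(c(1, 0), c(1, 0), c(0, 1))
  mh <- m_step(Y, post_hard)
  expect_equal(mh$mu1, 1.5)
  expect_equal(mh$mu2, 4)
  # uniform posteriors collapse to the grand mean
  mu <- m_step(Y, matrix(0.5, 3, 2))
  expect_equal(mu$mu1, mu$mu2)
  expect_equal(mu$mu1, mean(Y))
  expect_error(m_step(Y, rbind(c(1, 0), c(1, 0), c(1, 0))), "empty")
})

test_that("fit_null gives the closed-form single-component MLE", {
  Y <- matrix(c(0, 2), 2, 1)
  nf <- fit_null(Y)
  expect_equal(nf$mu0, 1)
  expect_equal(nf$sigma2_0, 1)
  expect_equal(nf$loglik0, sum(dnorm(c(0, 2), 1, 1, log = TRUE)))
  # identical rows hit the variance floor without error
  nf2 <- fit_null(matrix(1, 3, 2))
  expect_equal(nf2$sigma2_0, 1e-12)
})

test_that("EM ascends, converges, and recovers simulated parameters", {
  pop <- simulate_population("big", n = 120, L = 20, sigma2 = 1, seed = 14)
  w <- qtl_weights(pop$genotypes, position_cM = 25)
  fit <- run_em(pop$phenotypes, w)
  tr <- fit$state$loglik_trace
  expect_true(all(diff(tr) >= -1e-8))
  expect_true(fit$state$converged)
  expect_true(all(abs(rowSums(fit$state$posteriors) - 1) < 1e-10))
  # mean recovery within noise tolerance
  mu1_true <- vectorize_lexicographic(pop$mu1_img)
  mu2_true <- vectorize_lexicographic(pop$mu2_img)
  n1 <- sum(pop$xi)
  expect_lt(sqrt(mean((fit$model$mu1 - mu1_true)^2)), 3 / sqrt(n1))
  expect_lt(sqrt(mean((fit$model$mu2 - mu2_true)^2)), 3 / sqrt(120 - n1))
  expect_lt(abs(fit$model$sigma2 - 1), 0.1)
  # posterior classification accuracy
  acc <- mean((fit$state$posteriors[, 1] > 0.5) == (pop$xi == 1))
  expect_gt(acc, 0.95)
  # nesting: null never beats the mixture
  expect_gte(fit$model$loglik, fit_null(pop$phenotypes)$loglik0 - 1e-6)
})

test_that("uninformative weights with a symmetric start reduce to the null fit", {
  set.seed(6)
  Y <- matrix(rnorm(40), 8, 5)
  nf <- fit_null(Y)
  om <- matrix(0.5, 8, 2)
  init <- list(mu1 = nf$mu0, mu2 = nf$mu0, sigma2 = nf$sigma2_0)
  fit <- run_em(Y, om, init = init)
  expect_equal(fit$model$mu1, nf$mu0)
  expect_equal(fit$model$mu2, nf$mu0)
  expect_equal(fit$model$sigma2, nf$sigma2_0)
  expect_equal(fit$model$loglik, nf$loglik0)
  expect_lte(fit$state$n_iter, 2)  # symmetric stationary point
})
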