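test_that("indicator means combine offset, loading and unique error on the log scale", {
  O <- matrix(c(10, 5, 2, 8), 2, 2)
  expect_equal(exp(indicator_log_means(c(0, 0), c(1, 1), O)), O)
  lm1 <- indicator_log_means(c(1, 0), c(0.45, 0.7), O)
  expect_equal(exp(lm1[1, 1]), 10 * exp(0.45))
  # offset linearity
  lm2 <- indicator_log_means(c(1, 0), c(0.45, 0.7), 2 * O)
  expect_equal(exp(lm2), 2 * exp(lm1))
  expect_error(indicator_log_means(c(0, 0), c(1, 1), O * 0), "positive")
})

test_that("prevalence means respect mode-specific intercept structure", {
  E <- matrix(c(3, 3), 2, 1)
  H <- c(1L, 1L)
  # null effects reproduce the expectations
  expect_equal(exp(prevalence_log_means(c(0, 0), 1, matrix(0, 1, 1), E, H,
                                        "constrained")), E)
  # two areas in one higher area, f = (0, log 2): delta ratio 1:2
  d <- exp(prevalence_log_means(c(0, log(2)), 1, matrix(0, 1, 1), E, H,
                                "constrained"))
  expect_equal(d[2] / d[1], 2)
  # unconstrained common intercept multiplies every mean by exp(c)
  d0 <- exp(prevalence_log_means(c(0.1, -0.3), 1, 0, E, H, "unconstrained"))
  d1 <- exp(prevalence_log_means(c(0.1, -0.3), 1, 0.7, E, H, "unconstrained"))
  expect_equal(d1, exp(0.7) * d0)
  expect_error(
    prevalence_log_means(c(0, 0), 1, matrix(0, 2, 1), E, H, "unconstrained"),
    "length-Q")
})

test_that("aggregation sums small-area means within higher areas and conserves totals", {
  expect_equal(aggregate_means(matrix(1:3, 3, 1), c(1L, 2L, 3L)),
               matrix(1:3, 3, 1))
  expect_equal(aggregate_means(matrix(c(1, 2, 3), 3, 1), c(1L, 1L, 2L)),
               matrix(c(3, 3), 2, 1))
  set.seed(5)
  delta <- matrix(rexp(20), 10, 2)
  H <- sample(1:3, 10, replace = TRUE)
  agg <- aggregate_means(delta, H, 3)
  expect_equal(colSums(agg), colSums(delta))
})

test_that("log-posterior equals an independent term-by-term evaluation", {
  d <- scale_expected(tiny_data(P = 2, Q = 1, L = 1))
  dims <- d$dims
  set.seed(10)
  state <- list(
    f = rnorm(4, 0, 0.3), u = matrix(rnorm(8, 0, 0.2), 4, 2),
    lambda_y = c(0.5, 1.2), lambda_z = 1, beta = 0.3,
    gamma = matrix(c(-0.1, 0.2), 2, 1),
    kappa = 0.6, sigma2_f = 0.8, sigma2_u = 0.1)
  lp <- log_posterior(state, d, "constrained")
  expect_true(is.finite(lp))

  # independent recomputation, term by term, straight from the model
  y <- as.matrix(d$areas[c("y_1", "y_2")])
  O <- as.matrix(d$areas[c("O_1", "O_2")])
  E <- as.matrix(d$areas["E_1"])
  Z <- as.matrix(d$higher["Z_1"])
  X <- as.matrix(d$areas["x_1"])
  H <- c(1L, 1L, 2L, 2L)
  mu <- O * exp(outer(state$f, state$lambda_y) + state$u)
  delta <- E * exp(state$gamma[H, 1] + state$f)
  Delta <- rbind(sum(delta[1:2]), sum(delta[3:4]))
  g <- as_prev_graph(d)
  oracle <- sum(dpois(y, mu, log = TRUE)) +
    sum(dpois(Z, Delta, log = TRUE)) +
    dleroux(state$f, drop(X %*% state$beta), state$kappa, state$sigma2_f, g) +
    sum(dnorm(state$u, 0, sqrt(state$sigma2_u), log = TRUE)) +
    dgamma(1 / state$sigma2_f, 1, 1, log = TRUE) +
    dgamma(1 / state$sigma2_u, 1, 1, log = TRUE) +
    sum(dgamma(state$lambda_y, 1, 1, log = TRUE)) +
    dnorm(state$beta, 0, 10, log = TRUE) +
    sum(dnorm(state$gamma, 0, 10, log = TRUE))
  expect_equal(lp, oracle, tolerance = 1e-10)
})

test_that("perturbing one intercept changes the log-posterior by the predictable delta", {
  d <- scale_expected(tiny_data(P = 1, Q = 1, L = 1))
  set.seed(11)
  state <- list(f = rnorm(4, 0, 0.2), u = matrix(0, 4, 1),
                lambda_y = 0.8, lambda_z = 1, beta = -0.2,
                gamma = matrix(0, 2, 1), kappa = 0.4,
                sigma2_f = 1, sigma2_u = 0.5)
  lp0 <- log_posterior(state, d, "constrained")
  state2 <- state
  state2$gamma[1, 1] <- 1
  lp1 <- log_posterior(state2, d, "constrained")

  E <- d$areas$E_1
  delta0 <- E * exp(state$f)
  D0 <- sum(delta0[1:2]); D1 <- exp(1) * D0
  Z1 <- d$higher$Z_1[1]
  expected_delta <- (Z1 * log(D1) - D1) - (Z1 * log(D0) - D0) +
    dnorm(1, 0, 10, log = TRUE) - dnorm(0, 0, 10, log = TRUE)
  expect_equal(lp1 - lp0, expected_delta, tolerance = 1e-10)
})

test_that("log-posterior is invariant to a consistent relabelling of areas", {
  d <- scale_expected(tiny_data(P = 2, Q = 1, L = 1))
  set.seed(12)
  state <- list(f = rnorm(4, 0, 0.3), u = matrix(rnorm(8, 0, 0.2), 4, 2),
                lambda_y = c(0.5, 1.2), lambda_z = 1, beta = 0.3,
                gamma = matrix(c(-0.1, 0.2), 2, 1),
                kappa = 0.6, sigma2_f = 0.8, sigma2_u = 0.1)
  perm <- c(4, 2, 1, 3)
  dp <- d
  dp$areas <- d$areas[perm, ]
  dp <- prev_data(dp$areas, dp$higher, dp$edges)
  statep <- state
  statep$f <- state$f[perm]
  statep$u <- state$u[perm, , drop = FALSE]
  expect_equal(log_posterior(statep, scale_expected(dp), "constrained"),
               log_posterior(state, d, "constrained"), tolerance = 1e-10)
})

test_that("Poisson totals split multinomially given their sum (two-area enumeration)", {
  # conditional on Delta = delta1 + delta2, the joint Poisson law of
  # (z1, z2) given z1 + z2 = n is Binomial(n, delta1 / Delta)
  delta <- exp(prevalence_log_means(c(0.3, -0.2), 1, matrix(0.1, 1, 1),
                                    matrix(c(4, 6), 2, 1), c(1L, 1L),
                                    "constrained"))
  n <- 7
  joint <- function(k) dpois(k, delta[1]) * dpois(n - k, delta[2])
  cond <- vapply(0:n, joint, numeric(1))
  cond <- cond / sum(cond)
  expect_equal(cond, dbinom(0:n, n, delta[1] / sum(delta)), tolerance = 1e-12)
})
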