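test_that("regression mean is an intercept-free linear combination", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(regression_mean(X, c(0, 0, 0)), rep(0, 4))
  expect_equal(regression_mean(matrix(1, 3, 1), -0.199), rep(-0.199, 3))
  set.seed(7)
  beta <- rnorm(3)
  brute <- vapply(1:4, function(j) sum(beta * X[j, ]), numeric(1))
  expect_equal(regression_mean(X, beta), brute)
  expect_error(regression_mean(X, c(1, 2)), "length")
})

test_that("conditional moments follow the mixing formula in the limits and by hand", {
  g3 <- path_graph(3)
  # exchangeable limit
  cm <- leroux_conditional(f = c(0.3, 0, -0.1), eta = c(1, 2, 3),
                           kappa = 0, sigma2_f = 2.5, graph = g3)
  expect_equal(cm$mean, c(1, 2, 3))
  expect_equal(cm$var, rep(2.5, 3))
  # middle node of a path: neighbours' residuals 0.3 and -0.1
  cm <- leroux_conditional(f = c(0.3, 0, -0.1), eta = 0, kappa = 0.5,
                           sigma2_f = 1, graph = g3, j = 2)
  expect_equal(cm$mean, 0.5 * 0.2 / 1.5)
  expect_equal(cm$var, 1 / 1.5)
  # intrinsic limit: neighbour average, variance sigma2/m
  cm <- leroux_conditional(f = c(0.4, 0, -0.2), eta = c(1, 0.5, 2), kappa = 1,
                           sigma2_f = 3, graph = g3, j = 2)
  expect_equal(cm$mean, 0.5 + ((0.4 - 1) + (-0.2 - 2)) / 2)
  expect_equal(cm$var, 3 / 2)
})

test_that("stated conditionals agree with the joint precision on random small graphs", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    g <- random_graph(n)
    kappa <- runif(1, 0, 0.99)
    sigma2 <- runif(1, 0.2, 3)
    eta <- rnorm(n)
    f <- rnorm(n)
    Qp <- leroux_precision(g, kappa, sigma2)
    cm <- leroux_conditional(f, eta, kappa, sigma2, g)
    for (j in seq_len(n)) {
      ref <- conditional_from_precision(j, f, eta, Qp)
      expect_equal(cm$mean[j], ref$mean, tolerance = 1e-10)
      expect_equal(cm$var[j], ref$var, tolerance = 1e-10)
    }
  }
})

test_that("joint log-density matches closed forms, Brook's identity and permutation symmetry", {
  # single isolated node: normal with variance sigma2/(1-kappa)
  g1 <- path_graph(1)
  expect_equal(dleroux(0.7, eta = 0.2, kappa = 0.3, sigma2_f = 2, g1),
               dnorm(0.7, 0.2, sqrt(2 / 0.7), log = TRUE), tolerance = 1e-12)
  # kappa = 0: iid normals
  g <- random_graph(5)
  f <- rnorm(5); eta <- rnorm(5)
  expect_equal(dleroux(f, eta, 0, 1.3, g),
               sum(dnorm(f, eta, sqrt(1.3), log = TRUE)), tolerance = 1e-10)
  # finite differences of the joint reproduce the conditional (Brook's lemma),
  # on a 4-cycle
  g4 <- as_prev_graph(tibble::tibble(from = c("v1", "v2", "v3", "v4"),
                                     to = c("v2", "v3", "v4", "v1")),
                      paste0("v", 1:4))
  set.seed(3)
  f <- rnorm(4); eta <- rnorm(4); kappa <- 0.8; s2 <- 0.7
  for (j in 1:4) {
    cm <- leroux_conditional(f, eta, kappa, s2, g4, j = j)
    f2 <- f; f2[j] <- f[j] + 0.37
    diff_joint <- dleroux(f2, eta, kappa, s2, g4) - dleroux(f, eta, kappa, s2, g4)
    diff_cond <- dnorm(f2[j], cm$mean, sqrt(cm$var), log = TRUE) -
      dnorm(f[j], cm$mean, sqrt(cm$var), log = TRUE)
    expect_equal(diff_joint, diff_cond, tolerance = 1e-10)
  }
  # permutation equivariance
  perm <- c(3, 1, 4, 2, 5)
  gp <- as_prev_graph(tibble::tibble(
    from = paste0("v", perm[match(g$edges[, 1], 1:5)]),
    to = paste0("v", perm[match(g$edges[, 2], 1:5)])), paste0("v", 1:5))
  f5 <- rnorm(5); eta5 <- rnorm(5)
  fp <- f5; fp[perm] <- f5; ep <- eta5; ep[perm] <- eta5
  expect_equal(dleroux(f5, eta5, 0.6, 1.1, g),
               dleroux(fp, ep, 0.6, 1.1, gp), tolerance = 1e-10)
})

test_that("near-intrinsic log-density differences approach the pairwise-difference form", {
  g <- path_graph(4)
  f1 <- c(0.2, -0.1, 0.3, -0.4)
  f2 <- f1 + c(0.15, -0.05, -0.2, 0.1)  # equal sums
  expect_equal(sum(f1), sum(f2))
  icar_diff <- dleroux(f2, 0, 1, 2, g, improper = TRUE) -
    dleroux(f1, 0, 1, 2, g, improper = TRUE)
  near <- dleroux(f2, 0, 1 - 1e-7, 2, g) - dleroux(f1, 0, 1 - 1e-7, 2, g)
  expect_equal(near, icar_diff, tolerance = 1e-5)
  expect_error(dleroux(f1, 0, 1, 2, g), "improper")
  expect_error(rleroux(1, 0, 1, 2, g), "improper")
})

test_that("field sampler is seed-reproducible and matches its target moments", {
  g <- make_grid_geography(3, 3, 1)
  gg <- as_prev_graph(g$edges, g$areas$area_id)
  set.seed(99)
  a <- rleroux(1, 0, 0.5, 1, gg)
  set.seed(99)
  b <- rleroux(1, 0, 0.5, 1, gg)
  expect_identical(a, b)

  # kappa = 0: empirical variance matches sigma2_f
  set.seed(1)
  d0 <- rleroux(4000, 0, 0, 0.8, gg)
  expect_equal(mean(apply(d0, 2, var)), 0.8, tolerance = 0.05)

  # empirical covariance matches the precision inverse on the 3x3 grid
  set.seed(2)
  dr <- rleroux(10000, 1.5, 0.7, 0.9, gg)
  Sigma <- solve(as.matrix(leroux_precision(gg, 0.7, 0.9)))
  expect_equal(colMeans(dr), rep(1.5, 9), tolerance = 0.05)
  expect_lt(max(abs(cov(dr) - Sigma)), 0.03)
})
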