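test_that("constructor validates membership, counts and adjacency with named rows", {
  d <- tiny_data()
  expect_s3_class(d, "prev_data")
  expect_identical(d$dims, list(N_L = 4L, N_H = 2L, P = 2L, Q = 1L, L = 1L))

  bad <- tiny_data()
  bad$areas$higher_id[2] <- "C"
  expect_error(prev_data(bad$areas, bad$higher, bad$edges), "unknown higher area 'C'")

  bad <- tiny_data()
  bad$areas$y_1[3] <- 2.5
  expect_error(prev_data(bad$areas, bad$higher, bad$edges), "non-integer")

  bad <- tiny_data()
  bad$areas$O_2[1] <- 0
  expect_error(prev_data(bad$areas, bad$higher, bad$edges), "strictly positive")

  bad <- tiny_data()
  expect_error(
    prev_data(bad$areas, bad$higher,
              tibble::tibble(from = "w1", to = "w9")),
    "unknown area id 'w9'")
  expect_error(
    prev_data(bad$areas, bad$higher,
              tibble::tibble(from = "w1", to = "w1")),
    "self-loop")
})

test_that("duplicate and reversed edges collapse; isolated and disconnected graphs work", {
  d <- tiny_data()
  dup <- dplyr::bind_rows(d$edges, tibble::tibble(from = "w2", to = "w1"))
  expect_warning(d2 <- prev_data(d$areas, d$higher, dup[c(1, 4, 2, 3, 1), ]),
                 regexp = NA)
  expect_equal(nrow(d2$edges), 3)

  # one isolated area: degree zero, disconnected warning
  expect_warning(
    d3 <- prev_data(d$areas, d$higher,
                    tibble::tibble(from = c("w1", "w2"), to = c("w2", "w3"))),
    "disconnected")
  g <- as_prev_graph(d3)
  expect_equal(g$m, c(1L, 2L, 1L, 0L))

  # single area, empty edge list
  a1 <- d$areas[1, ]
  h1 <- d$higher[1, ]
  d4 <- suppressMessages(prev_data(a1, h1, tibble::tibble()))
  expect_equal(as_prev_graph(d4)$m, 0L)
})

test_that("covariates are standardised by the loader when needed", {
  d <- tiny_data()
  d$areas$x_1 <- c(10, 20, 30, 40)
  expect_message(d2 <- prev_data(d$areas, d$higher, d$edges), "standardising")
  expect_equal(mean(d2$areas$x_1), 0, tolerance = 1e-12)
  expect_equal(sd(d2$areas$x_1), 1, tolerance = 1e-12)
  expect_error(prev_data(d$areas, d$higher, d$edges, standardize_x = FALSE),
               "not standardised")
})

test_that("write-then-read round-trips a synthetic dataset", {
  sim <- simulate_prev_data(n_row = 4, n_col = 4, n_higher = 4, seed = 11)
  dir <- withr::local_tempdir()
  write_prev_data(sim$data, dir)
  back <- read_prev_data(file.path(dir, "areas.csv"),
                         file.path(dir, "adjacency.csv"),
                         file.path(dir, "higher.csv"))
  expect_identical(back$dims, sim$data$dims)
  expect_identical(back$areas$area_id, sim$data$areas$area_id)
  expect_identical(back$edges, sim$data$edges)
  num <- vapply(sim$data$areas, is.numeric, logical(1))
  expect_equal(as.data.frame(back$areas[num]),
               as.data.frame(sim$data$areas[num]), tolerance = 1e-12)
  expect_equal(back$higher, sim$data$higher)

  # and a second round trip reproduces the same dataset
  dir2 <- withr::local_tempdir()
  write_prev_data(back, dir2)
  back2 <- read_prev_data(file.path(dir2, "areas.csv"),
                          file.path(dir2, "adjacency.csv"),
                          file.path(dir2, "higher.csv"))
  expect_equal(as.data.frame(back2$areas), as.data.frame(back$areas),
               tolerance = 1e-12)
  expect_identical(back2$edges, back$edges)
})

test_that("expected counts follow the population-times-rate schedule", {
  pop <- tibble::tibble(area_id = "a", sex = "m", ageband = "40-44",
                        population = 100)
  rates <- tibble::tibble(outcome = "chd", sex = "m", ageband = "40-44",
                          rate = 0.05)
  expect_equal(compute_expected_counts(pop, rates)$expected, 5)

  pop2 <- tibble::tibble(area_id = "a", sex = c("m", "f"), ageband = "all",
                         population = c(100, 200))
  rates2 <- tibble::tibble(outcome = "chd", sex = c("m", "f"), ageband = "all",
                           rate = c(0.1, 0.05))
  expect_equal(compute_expected_counts(pop2, rates2)$expected, 20)

  # zero schedule gives zero expectations (rejected downstream by the validator)
  rates0 <- dplyr::mutate(rates2, rate = 0)
  expect_equal(compute_expected_counts(pop2, rates0)$expected, 0)

  # linearity in populations
  set.seed(1)
  pop3 <- tibble::tibble(area_id = rep(c("a", "b"), each = 4),
                         sex = rep(c("m", "f"), 4),
                         ageband = rep(c("y", "o"), each = 2, times = 2),
                         population = runif(8, 50, 500))
  rates3 <- tidyr::expand_grid(
    outcome = c("chd", "smi"), sex = c("m", "f"), ageband = c("y", "o"))
  rates3$rate <- runif(nrow(rates3), 0, 0.2)
  e1 <- compute_expected_counts(pop3, rates3)
  e2 <- compute_expected_counts(dplyr::mutate(pop3, population = 2 * population),
                                rates3)
  expect_equal(e2$expected, 2 * e1$expected)

  expect_error(
    compute_expected_counts(dplyr::mutate(pop2, ageband = "odd"), rates2),
    "no matching rate")
})

test_that("internal-standard scaling balances totals, keeps proportions, is idempotent", {
  d <- tiny_data(P = 1, Q = 1)
  d$areas$y_1 <- c(3L, 1L, 0L, 0L)
  d$areas$O_1 <- c(1, 1, 1, 1)
  s <- scale_expected(d)
  expect_equal(s$areas$O_1, rep(1, 4))  # totals already 4 = 4
  d$areas$y_1 <- c(3L, 1L, 2L, 2L)
  s <- scale_expected(d)
  expect_equal(sum(s$areas$O_1), sum(d$areas$y_1))
  expect_equal(s$areas$O_1 / s$areas$O_1[1], d$areas$O_1 / d$areas$O_1[1])
  expect_equal(scale_expected(s)$areas$O_1, s$areas$O_1)
  # prevalence side: region-wide standard prevalence ratio becomes 1
  expect_equal(sum(s$areas$E_1), sum(s$higher$Z_1))
})
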