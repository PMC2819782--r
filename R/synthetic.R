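#' Rectangular lattice geography with nested higher areas
#'
#' Builds a rook-adjacency grid of `n_row * n_col` small areas, partitioned
#' into `n_higher` contiguous higher areas. When `n_higher` factorises as
#' `a * b` with `a | n_row` and `b | n_col` the higher areas are rectangular
#' blocks; otherwise quasi-equal contiguous strips (row-major runs) are used
#' and a notice is emitted.
#'
#' @param n_row,n_col Grid dimensions (>= 1).
#' @param n_higher Number of higher areas (<= number of cells).
#' @return List with tibbles `areas` (`area_id`, `higher_id`, `row`, `col`)
#'   and `edges` (`from`, `to`).
#' @examples
#' g <- make_grid_geography(2, 2, 1)
#' nrow(g$edges)  # 4 rook edges on a 2x2 grid
#' @export
make_grid_geography <- function(n_row, n_col, n_higher) {
  stopifnot(n_row >= 1, n_col >= 1, n_higher >= 1,
            n_higher <= n_row * n_col)
  n <- n_row * n_col
  idx <- function(r, c) (r - 1L) * n_col + c
  ids <- sprintf("a%0*d", nchar(n), seq_len(n))

  # block partition when a compatible factorisation exists
  divs <- seq_len(n_higher)[n_higher %% seq_len(n_higher) == 0]
  ok <- divs[n_row %% divs == 0 & n_col %% (n_higher %/% divs) == 0]
  rc <- expand.grid(r = seq_len(n_row), c = seq_len(n_col))
  rc <- rc[order(rc$r, rc$c), ]
  if (length(ok) > 0) {
    a <- ok[which.min(abs(ok - sqrt(n_higher * n_row / n_col)))]
    b <- n_higher %/% a
    hr <- n_row %/% a; hc <- n_col %/% b
    block <- ((rc$r - 1L) %/% hr) * b + (rc$c - 1L) %/% hc + 1L
  } else {
    inform("n_higher does not tile the grid into blocks; using contiguous row-major strips")
    cell <- idx(rc$r, rc$c)
    block <- pmin(((cell - 1L) * n_higher) %/% n + 1L, n_higher)
  }
  hid <- sprintf("h%0*d", nchar(n_higher), block)

  from <- integer(); to <- integer()
  for (r in seq_len(n_row)) for (cc in seq_len(n_col)) {
    if (cc < n_col) { from <- c(from, idx(r, cc)); to <- c(to, idx(r, cc + 1L)) }
    if (r < n_row) { from <- c(from, idx(r, cc)); to <- c(to, idx(r + 1L, cc)) }
  }
  list(
    areas = tibble(area_id = ids, higher_id = hid[order(idx(rc$r, rc$c))],
                   row = rep(seq_len(n_row), each = n_col),
                   col = rep(seq_len(n_col), times = n_row)),
    edges = tibble(from = ids[from], to = ids[to])
  )
}

#' Simulate a two-scale prevalence dataset from the model
#'
#' Generates data with the model's exact statistical structure on a lattice
#' geography: standardised covariates, a Leroux latent factor with
#' regression mean, Poisson indicator counts with unique errors, latent
#' small-area prevalence counts, and their higher-area totals. Defaults
#' mirror the magnitudes estimated in the London CHD application
#' (high spatial correlation, loadings around 0.4-0.8, income-type effects
#' around +/-0.2) on a 20x20 grid of 400 small areas in 16 higher areas.
#'
#' @param n_row,n_col,n_higher Geography, as in [make_grid_geography()].
#' @param P,Q,L Numbers of indicators, prevalence outcomes and covariates.
#' @param kappa,sigma2_f True spatial correlation and conditional variance
#'   of the latent factor.
#' @param sigma2_u True unique-error variance of the indicator equations.
#' @param beta True cause coefficients (length L).
#' @param lambda_y True indicator loadings (length P, positive).
#' @param lambda_z True prevalence loadings (length Q); the first must be 1.
#' @param gamma True higher-area intercepts: `N_H x Q` matrix, or `NULL` to
#'   draw them as `N(0, gamma_sd^2)`.
#' @param gamma_sd Spread of the drawn higher-area intercepts.
#' @param offset_median,offset_sdlog Log-normal size distribution of the
#'   expected counts `O` and expected prevalences `E` (median count per
#'   area-indicator, log-scale sd).
#' @param seed Optional seed for reproducibility.
#' @return Object of class `prev_sim`: list with the [prev_data] in `data`
#'   and a `truth` list holding every generated quantity (`f`, `u`, `eta`,
#'   `gamma`, latent small-area counts `z`, and a `params` tibble aligned
#'   with [tidy()] terms).
#' @export
simulate_prev_data <- function(n_row = 20, n_col = 20, n_higher = 16,
                               P = 4, Q = 1, L = 3,
                               kappa = 0.9, sigma2_f = 1, sigma2_u = 0.05,
                               beta = NULL, lambda_y = NULL,
                               lambda_z = rep(1, Q),
                               gamma = NULL, gamma_sd = 0.2,
                               offset_median = 20, offset_sdlog = 0.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- rep_len(c(-0.2, 0.18, 0.05), L)
  if (is.null(lambda_y)) lambda_y <- rep_len(c(0.45, 0.41, 0.72, 0.77), P)
  stopifnot(length(beta) == L, length(lambda_y) == P,
            length(lambda_z) == Q, abs(lambda_z[1] - 1) < 1e-12,
            all(lambda_y > 0), sigma2_f > 0, sigma2_u >= 0,
            kappa >= 0, kappa < 1)

  geo <- make_grid_geography(n_row, n_col, n_higher)
  N <- nrow(geo$areas)
  g <- as_prev_graph(geo$edges, ids = geo$areas$area_id)
  H <- match(geo$areas$higher_id, unique(geo$areas$higher_id))
  hid <- unique(geo$areas$higher_id)
  NH <- length(hid)

  X <- if (L > 0) scale(matrix(rnorm(N * L), N, L)) else matrix(0, N, 0)
  eta <- regression_mean(X, beta)
  f <- rleroux(1, eta, kappa, sigma2_f, g)
  u <- matrix(rnorm(N * P, 0, sqrt(sigma2_u)), N, P)
  O <- matrix(rlnorm(N * P, log(offset_median), offset_sdlog), N, P)
  E <- matrix(rlnorm(N * Q, log(offset_median), offset_sdlog), N, Q)
  if (is.null(gamma)) gamma <- matrix(rnorm(NH * Q, 0, gamma_sd), NH, Q)
  gamma <- as.matrix(gamma)
  stopifnot(nrow(gamma) == NH, ncol(gamma) == Q)

  mu <- exp(indicator_log_means(f, lambda_y, O, u))
  y <- matrix(rpois(N * P, mu), N, P)
  delta <- exp(prevalence_log_means(f, lambda_z, gamma, E, H, "constrained"))
  z <- matrix(rpois(N * Q, delta), N, Q)
  Z <- aggregate_means(z, H, NH)

  areas <- geo$areas[c("area_id", "higher_id")]
  for (p in seq_len(P)) areas[[paste0("y_", p)]] <- y[, p]
  for (p in seq_len(P)) areas[[paste0("O_", p)]] <- O[, p]
  for (q in seq_len(Q)) areas[[paste0("E_", q)]] <- E[, q]
  for (l in seq_len(L)) areas[[paste0("x_", l)]] <- X[, l]
  higher <- tibble(higher_id = hid)
  for (q in seq_len(Q)) higher[[paste0("Z_", q)]] <- as.integer(Z[, q])

  params <- tibble(
    term = c(paste0("beta[", seq_len(L), "]"), "kappa",
             "sigma2_f", "sigma2_u",
             paste0("lambda_y[", seq_len(P), "]"),
             paste0("lambda_z[", seq_len(Q), "]")),
    value = c(beta, kappa, sigma2_f, sigma2_u, lambda_y, lambda_z))

  structure(
    list(data = prev_data(areas, higher, geo$edges),
         geography = geo,
         truth = list(f = f, u = u, eta = eta, gamma = gamma, z = z,
                      params = params)),
    class = "prev_sim")
}

#' @export
print.prev_sim <- function(x, ...) {
  cat("<prev_sim> synthetic two-scale dataset\n")
  print(x$data)
  invisible(x)
}

#' True parameter values of a simulated dataset
#'
#' @param sim A `prev_sim` object from [simulate_prev_data()].
#' @return Tibble `term`, `value` matching the terms reported by
#'   [tidy()] on a fit of the same data.
#' @export
truth_parameters <- function(sim) {
  stopifnot(inherits(sim, "prev_sim"))
  sim$truth$params
}
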