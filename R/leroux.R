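#' Regression mean of the latent morbidity factor
#'
#' The multiple-cause part of the model: the latent factor is centred at
#' `eta_j = sum_l beta_l * x_jl`, a regression through the origin (no
#' intercept; the level of the factor is identified by the absence of
#' intercepts in the measurement equations).
#'
#' @param x Covariate matrix (N x L) or a [prev_data] object.
#' @param beta Coefficient vector of length L.
#' @return Numeric vector `eta` of length N.
#' @export
regression_mean <- function(x, beta) {
  if (inherits(x, "prev_data")) x <- covariates(x)
  x <- as.matrix(x)
  if (ncol(x) != length(beta))
    abort(sprintf("beta has length %d but x has %d column(s)",
                  length(beta), ncol(x)))
  if (ncol(x) == 0) return(rep(0, nrow(x)))
  drop(x %*% beta)
}

covariates <- function(x) block_matrix(x$areas, "x", x$dims$L)

#' Leroux precision matrix
#'
#' Precision of the latent spatial factor:
#' `(1/sigma2_f) * (kappa * (D - W) + (1 - kappa) * I)`, where `W` is the
#' 0/1 adjacency matrix and `D = diag(m_j)` holds neighbour counts. For
#' `kappa < 1` this is positive definite (also on disconnected graphs);
#' `kappa = 1` gives the singular intrinsic CAR precision.
#'
#' @param graph A `prev_graph` (or [prev_data]) describing adjacency.
#' @param kappa Spatial correlation parameter in `[0, 1]`.
#' @param sigma2_f Conditional variance parameter (> 0).
#' @return A sparse symmetric [Matrix::Matrix] of size N x N.
#' @export
leroux_precision <- function(graph, kappa, sigma2_f = 1) {
  g <- as_prev_graph(graph)
  stopifnot(kappa >= 0, kappa <= 1, sigma2_f > 0)
  n <- g$n
  Q <- Matrix::Diagonal(n, kappa * g$m + (1 - kappa))
  if (nrow(g$edges) > 0) {
    W <- Matrix::sparseMatrix(i = c(g$edges[, 1], g$edges[, 2]),
                              j = c(g$edges[, 2], g$edges[, 1]),
                              x = 1, dims = c(n, n))
    Q <- Q - kappa * W
  }
  Q / sigma2_f
}

#' Full conditional moments of the Leroux factor
#'
#' The defining single-site conditionals of the prior, extended with the
#' regression mean: with residuals `r_h = f_h - eta_h`,
#' `E(f_j | f_-j) = eta_j + kappa * sum(r over neighbours) / (1 - kappa + kappa * m_j)`
#' and `Var(f_j | f_-j) = sigma2_f / (1 - kappa + kappa * m_j)`.
#'
#' @param f Current latent values (length N).
#' @param eta Regression means (length N, recycled scalar allowed).
#' @param kappa,sigma2_f Leroux parameters.
#' @param graph Adjacency (`prev_graph` or [prev_data]).
#' @param j Optional area index (or vector of indices); default all areas.
#' @return Tibble with columns `area`, `mean`, `var`.
#' @export
leroux_conditional <- function(f, eta, kappa, sigma2_f, graph, j = NULL) {
  g <- as_prev_graph(graph)
  eta <- rep_len(eta, g$n)
  if (is.null(j)) j <- seq_len(g$n)
  r <- f - eta
  denom <- 1 - kappa + kappa * g$m[j]
  rsum <- vapply(g$nbr[j], function(h) sum(r[h]), numeric(1))
  tibble(area = j,
         mean = eta[j] + kappa * rsum / denom,
         var = sigma2_f / denom)
}

#' Log-density of the Leroux latent field
#'
#' Proper multivariate normal log-density of `f` with mean `eta` and
#' precision `leroux_precision(graph, kappa, sigma2_f)`, including the
#' normalising constant. For `kappa = 1` the joint is improper; with
#' `improper = TRUE` the unnormalised intrinsic pairwise-difference form
#' `-(1/(2*sigma2_f)) * sum over edges (f_j - f_h)^2` is returned instead.
#'
#' @inheritParams leroux_conditional
#' @param improper Allow the `kappa = 1` intrinsic limit (unnormalised).
#' @param log Return the log density (default) or the density.
#' @return Scalar log-density.
#' @export
dleroux <- function(f, eta, kappa, sigma2_f, graph, improper = FALSE,
                    log = TRUE) {
  g <- as_prev_graph(graph)
  eta <- rep_len(eta, g$n)
  r <- f - eta
  if (kappa >= 1) {
    if (!improper)
      abort("kappa = 1 gives an improper joint; set improper = TRUE for the intrinsic pairwise-difference form")
    e <- g$edges
    ld <- -sum((r[e[, 1]] - r[e[, 2]])^2) / (2 * sigma2_f)
    return(if (log) ld else exp(ld))
  }
  Q <- leroux_precision(g, kappa, sigma2_f)
  ld <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
  out <- 0.5 * ld - 0.5 * g$n * log(2 * pi) -
    0.5 * sum(r * as.numeric(Q %*% r))
  if (log) out else exp(out)
}

#' Draw from the Leroux latent field
#'
#' Exact joint draw via Cholesky factorisation of the precision matrix,
#' `f = eta + U^{-1} z` with `U` the upper Cholesky factor and `z` standard
#' normal. Reproducible under [set.seed()].
#'
#' @inheritParams dleroux
#' @param n_draws Number of independent fields to draw.
#' @return A vector (one draw) or `n_draws` x N matrix.
#' @export
rleroux <- function(n_draws = 1, eta, kappa, sigma2_f, graph) {
  g <- as_prev_graph(graph)
  if (kappa >= 1) abort("kappa = 1 gives an improper joint; cannot sample")
  eta <- rep_len(eta, g$n)
  Q <- as.matrix(leroux_precision(g, kappa, sigma2_f))
  U <- chol(Q)
  z <- matrix(rnorm(n_draws * g$n), g$n, n_draws)
  out <- t(eta + backsolve(U, z))
  if (n_draws == 1) drop(out) else out
}
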