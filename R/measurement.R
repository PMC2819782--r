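#' Poisson log-means for the small-area indicators
#'
#' Measurement equations for the observed indicators:
#' `log mu_jp = log O_jp + lambda_p * f_j + u_jp`. No intercepts appear,
#' which fixes the location of the latent factor.
#'
#' @param f Latent factor values (length N_L).
#' @param lambda_y Positive loadings, length P.
#' @param O Expected-count matrix N_L x P (strictly positive).
#' @param u Optional unique-error matrix N_L x P (default 0), absorbing
#'   residual overdispersion.
#' @return Matrix of `log(mu)`, N_L x P.
#' @export
indicator_log_means <- function(f, lambda_y, O, u = NULL) {
  O <- as.matrix(O)
  if (any(O <= 0)) abort("all expected counts O must be positive")
  if (ncol(O) != length(lambda_y))
    abort("lambda_y length must equal ncol(O)")
  if (is.null(u)) u <- matrix(0, nrow(O), ncol(O))
  log(O) + outer(f, lambda_y) + u
}

#' Poisson log-means for small-area prevalence
#'
#' The disaggregation model for the unobserved small-area prevalence counts.
#' Constrained mode uses one intercept per higher area and outcome
#' (`log delta_jq = log E_jq + gamma[q, H_j] + lambda_z_q * f_j`), which by
#' the Poisson-multinomial equivalence pins the higher-area totals to the
#' observed `Z_iq`. Unconstrained mode replaces `gamma[q, H_j]` by a single
#' `gamma_q`, preserving only the region-wide total.
#'
#' @param f Latent factor values (length N_L).
#' @param lambda_z Prevalence loadings, length Q; the first is fixed at 1
#'   for identification of the factor scale.
#' @param gamma Constrained mode: matrix N_H x Q; unconstrained: vector of
#'   length Q.
#' @param E Expected-prevalence matrix N_L x Q (strictly positive).
#' @param membership Integer vector: higher-area index (1..N_H) of each
#'   small area.
#' @param mode `"constrained"` or `"unconstrained"`.
#' @return Matrix of `log(delta)`, N_L x Q.
#' @export
prevalence_log_means <- function(f, lambda_z, gamma, E, membership,
                                 mode = c("constrained", "unconstrained")) {
  mode <- match.arg(mode)
  E <- as.matrix(E)
  if (any(E <= 0)) abort("all expected prevalence counts E must be positive")
  Q <- ncol(E)
  if (length(lambda_z) != Q) abort("lambda_z length must equal ncol(E)")
  if (mode == "constrained") {
    gamma <- as.matrix(gamma)
    if (ncol(gamma) != Q)
      abort("constrained mode needs an N_H x Q gamma matrix")
    gterm <- gamma[membership, , drop = FALSE]
  } else {
    if (is.matrix(gamma) && nrow(gamma) > 1)
      abort("unconstrained mode needs a length-Q gamma vector")
    gterm <- matrix(rep(as.numeric(gamma), each = nrow(E)), nrow(E), Q)
  }
  log(E) + gterm + outer(f, lambda_z)
}

#' Aggregate small-area means to higher areas
#'
#' `Delta_iq = sum over areas j with H_j = i of delta_jq` -- the Poisson
#' means of the observed higher-area totals.
#'
#' @param delta Small-area mean matrix N_L x Q.
#' @param membership Higher-area index (1..N_H) per small area.
#' @param n_higher Number of higher areas (defaults to `max(membership)`).
#' @return Matrix N_H x Q.
#' @export
aggregate_means <- function(delta, membership, n_higher = max(membership)) {
  delta <- as.matrix(delta)
  out <- matrix(0, n_higher, ncol(delta))
  for (q in seq_len(ncol(delta)))
    out[, q] <- as.numeric(rowsum(delta[, q], membership,
                                  reorder = TRUE)[as.character(seq_len(n_higher)), 1])
  out
}

#' Joint log-posterior of the shared-factor prevalence model
#'
#' Evaluates, up to the parameterisation conventions documented below, the
#' sum of: the Poisson log-likelihood of the indicator counts `y` given
#' `mu`; the Poisson log-likelihood of the higher-area totals `Z` given
#' `Delta`; the Leroux log-density of `f` around `eta = X beta`; normal
#' `N(0, sigma2_u)` terms for the unique errors `u`; Gamma(1,1) log-priors
#' on the precisions `1/sigma2_f` and `1/sigma2_u` and on every free
#' loading; `N(0, 100)` log-priors on `beta` and `gamma`; and a `U(0, 1)`
#' prior on `kappa` (log-prior 0 inside the unit interval). Variance priors
#' are evaluated on the precision scale.
#'
#' @param state Named list with elements `f`, `u`, `lambda_y`, `lambda_z`,
#'   `beta`, `gamma`, `kappa`, `sigma2_f`, `sigma2_u`.
#' @param data A [prev_data] object (already scaled; see [scale_expected()]).
#' @param mode `"constrained"` or `"unconstrained"`.
#' @return Scalar log-posterior (can be `-Inf` for invalid states).
#' @export
log_posterior <- function(state, data,
                          mode = c("constrained", "unconstrained")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "prev_data"))
  d <- data$dims
  s <- state
  if (abs(s$lambda_z[1] - 1) > 1e-12)
    abort("identification requires lambda_z[1] = 1")
  if (any(s$lambda_y <= 0) || any(s$lambda_z <= 0) ||
      s$sigma2_f <= 0 || s$sigma2_u <= 0 ||
      s$kappa <= 0 || s$kappa >= 1) return(-Inf)

  y <- block_matrix(data$areas, "y", d$P)
  O <- block_matrix(data$areas, "O", d$P)
  E <- block_matrix(data$areas, "E", d$Q)
  Z <- block_matrix(data$higher, "Z", d$Q)
  H <- membership_index(data)
  g <- as_prev_graph(data)

  lmu <- indicator_log_means(s$f, s$lambda_y, O, s$u)
  ldelta <- prevalence_log_means(s$f, s$lambda_z, s$gamma, E, H, mode)
  Delta <- aggregate_means(exp(ldelta), H, d$N_H)
  eta <- regression_mean(covariates(data), s$beta)

  lp <- sum(dpois(y, exp(lmu), log = TRUE)) +
    sum(dpois(Z, Delta, log = TRUE)) +
    dleroux(s$f, eta, s$kappa, s$sigma2_f, g) +
    sum(dnorm(s$u, 0, sqrt(s$sigma2_u), log = TRUE)) +
    dgamma(1 / s$sigma2_f, 1, 1, log = TRUE) +
    dgamma(1 / s$sigma2_u, 1, 1, log = TRUE) +
    sum(dgamma(s$lambda_y, 1, 1, log = TRUE)) +
    sum(dnorm(s$beta, 0, 10, log = TRUE)) +
    sum(dnorm(as.numeric(s$gamma), 0, 10, log = TRUE))
  if (d$Q > 1)
    lp <- lp + sum(dgamma(s$lambda_z[-1], 1, 1, log = TRUE))
  lp
}
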