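#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance over retained
#' draws and `pD = Dbar - D(theta_bar)` the effective number of parameters.
#' The plug-in deviance is evaluated at the posterior mean of the log-scale
#' linear predictor (the Poisson mean is the exponential of that mean), the
#' standard plug-in parameterisation for log-linear models. Scope `"y"`
#' restricts attention to the small-area indicator likelihood -- the
#' goodness-of-fit focus for comparing constrained and unconstrained
#' disaggregation, which fit the higher-area totals by construction to
#' different degrees; `"full"` adds the higher-area total likelihood.
#'
#' @param fit A `prev_fit` object.
#' @param scope `"y"` (indicator likelihood only) or `"full"`.
#' @return Tibble with columns `scope`, `dbar`, `p_d`, `dic`.
#' @export
dic <- function(fit, scope = c("y", "full")) {
  scope <- match.arg(scope)
  stopifnot(inherits(fit, "prev_fit"))
  if (fit$n_retained < 1) abort("no retained draws")
  d <- fit$dims
  y <- block_matrix(fit$data$areas, "y", d$P)
  O <- block_matrix(fit$data$areas, "O", d$P)
  Z <- block_matrix(fit$data$higher, "Z", d$Q)

  dev_y <- unlist(lapply(fit$chains, function(ch) ch$dev_y))
  dev_z <- unlist(lapply(fit$chains, function(ch) ch$dev_z))

  mlp <- Reduce(`+`, lapply(fit$chains, function(ch) ch$mean_linpred_y)) /
    length(fit$chains)
  plug_y <- -2 * sum(dpois(y, O * exp(mlp), log = TRUE))

  if (scope == "y") {
    dbar <- mean(dev_y)
    plug <- plug_y
  } else {
    mld <- Reduce(`+`, lapply(fit$chains, function(ch) ch$mean_logdelta)) /
      length(fit$chains)
    Delta_plug <- aggregate_means(exp(mld), fit$membership, d$N_H)
    plug <- plug_y - 2 * sum(dpois(Z, Delta_plug, log = TRUE))
    dbar <- mean(dev_y + dev_z)
  }
  tibble(scope = scope, dbar = dbar, p_d = dbar - plug, dic = 2 * dbar - plug)
}

#' Mixed predictive p-values for the indicator counts
#'
#' Posterior predictive checking in which the random effects are re-drawn
#' from their priors before replicating data: at each retained draw, a
#' replicate latent field is sampled from the Leroux joint given the
#' sampled `kappa`, `sigma2_f` and `beta`, replicate unique errors from
#' `N(0, sigma2_u)`, and replicate counts from the Poisson measurement
#' equations. The p-value uses the half-mass convention
#' `p = Pr(y_rep > y) + 0.5 * Pr(y_rep = y)`, so extreme values in either
#' tail mark poorly fitted counts.
#'
#' @param fit A `prev_fit` object.
#' @param draws Number of retained draws to use (spread evenly over the
#'   chains; default 500). Fewer than 100 triggers a warning.
#' @param seed Seed for the replication randomness.
#' @return Tibble `area_id`, `indicator`, `observed`, `p_mix`.
#' @export
mixed_predictive <- function(fit, draws = 500, seed = 1L) {
  stopifnot(inherits(fit, "prev_fit"))
  d <- fit$dims
  if (draws > fit$n_retained * length(fit$chains))
    draws <- fit$n_retained * length(fit$chains)
  if (draws < 100)
    warn(sprintf("only %d draws used for mixed predictive p-values; estimates will be noisy", draws))
  y <- block_matrix(fit$data$areas, "y", d$P)
  O <- block_matrix(fit$data$areas, "O", d$P)
  X <- covariates(fit$data)
  g <- fit$graph
  per_chain <- ceiling(draws / length(fit$chains))
  idx <- unique(round(seq(1, fit$n_retained, length.out = per_chain)))

  set.seed(seed)
  gt <- matrix(0, d$N_L, d$P)  # count y_rep > y
  eq <- matrix(0, d$N_L, d$P)  # count y_rep == y
  n_used <- 0
  for (ch in fit$chains) {
    for (t in idx) {
      eta <- if (d$L > 0) drop(X %*% ch$beta[t, seq_len(d$L)]) else
        rep(0, d$N_L)
      kap <- min(ch$kappa[t], 1 - 1e-9)
      f_rep <- rleroux(1, eta, kap, ch$sigma2_f[t], g)
      u_rep <- matrix(rnorm(d$N_L * d$P, 0, sqrt(ch$sigma2_u[t])),
                      d$N_L, d$P)
      mu_rep <- exp(indicator_log_means(f_rep, ch$lambda_y[t, ], O, u_rep))
      y_rep <- matrix(rpois(d$N_L * d$P, mu_rep), d$N_L, d$P)
      gt <- gt + (y_rep > y)
      eq <- eq + (y_rep == y)
      n_used <- n_used + 1
    }
  }
  p <- (gt + 0.5 * eq) / n_used
  tibble(area_id = rep(fit$data$areas$area_id, d$P),
         indicator = rep(seq_len(d$P), each = d$N_L),
         observed = as.vector(y), p_mix = as.vector(p))
}

#' Proportion of extreme predictive p-values
#'
#' Share of p-values below `lower` or above `upper`; under a well-fitting
#' model about `lower + (1 - upper)` (0.10 with the defaults) is expected.
#'
#' @param p Numeric vector of p-values, or the tibble returned by
#'   [mixed_predictive()] (its `p_mix` column is used).
#' @param lower,upper Tail cut-offs (defaults 0.05 and 0.95).
#' @return Scalar proportion in `[0, 1]`.
#' @export
tail_proportion <- function(p, lower = 0.05, upper = 0.95) {
  if (is.data.frame(p)) p <- p$p_mix
  mean(p < lower | p > upper)
}
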