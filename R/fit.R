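#' Fit the shared-factor prevalence model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler for the full model: Poisson
#' measurement equations for the small-area indicators, a Leroux latent
#' morbidity factor with multiple-cause regression mean, and a Poisson
#' model for the higher-area prevalence totals, either constrained to
#' reproduce them per higher area (one intercept per higher area and
#' outcome, the Poisson-multinomial device) or unconstrained (one global
#' intercept per outcome).
#'
#' Expected counts are internally rescaled with [scale_expected()] before
#' fitting, so region-wide observed and expected totals agree. The first
#' prevalence loading is fixed at 1, identifying the scale of the factor;
#' the absence of intercepts in the indicator equations identifies its
#' level.
#'
#' Chain 1 starts from a deterministic state (`f = u = 0`, loadings 1,
#' `beta = 0`, `kappa = 0.5`, unit variances, intercepts chosen so the
#' fitted totals match the observed totals at `f = 0`); later chains jitter
#' every block for overdispersed starts. Random-walk step sizes adapt
#' toward 44% acceptance during burn-in only.
#'
#' @param data A [prev_data] object.
#' @param mode `"constrained"` (default) or `"unconstrained"`.
#' @param chains Number of chains (>= 2 to compute R-hat).
#' @param iter Iterations per chain (default 10000).
#' @param burnin Burn-in iterations discarded per chain (default `iter/2`,
#'   i.e. inference from the second half of each chain).
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed; per-chain seeds are derived from it.
#' @param likelihood Set `FALSE` for a prior-only run (the data enter no
#'   update; useful for validating the sampler against the priors).
#' @return An object of class `prev_fit` with per-chain draws of every
#'   parameter block, stored small-area prevalence means `delta`, deviance
#'   traces, acceptance rates and plug-in accumulators. Use [tidy()],
#'   [glance()], [dic()], [relative_risks()], [srr()],
#'   [mixed_predictive()], [gelman_rubin()] on it.
#' @examples
#' \donttest{
#' sim <- simulate_prev_data(n_row = 6, n_col = 6, n_higher = 4, seed = 1)
#' fit <- fit_prevalence(sim$data, chains = 2, iter = 400, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_prevalence <- function(data, mode = c("constrained", "unconstrained"),
                           chains = 2, iter = 10000,
                           burnin = floor(iter / 2), thin = 1, seed = 1L,
                           likelihood = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "prev_data"), chains >= 1,
            burnin < iter, thin >= 1)
  data <- scale_expected(data)
  d <- data$dims
  constrained <- mode == "constrained"

  y <- block_matrix(data$areas, "y", d$P)
  O <- block_matrix(data$areas, "O", d$P)
  E <- block_matrix(data$areas, "E", d$Q)
  Z <- block_matrix(data$higher, "Z", d$Q)
  X <- covariates(data)
  H <- membership_index(data)
  g <- as_prev_graph(data)

  # eigenvalues of D - W, once: they carry the Leroux log-determinant
  DW <- diag(g$m, g$n)
  if (nrow(g$edges) > 0) {
    DW[g$edges] <- DW[g$edges] - 1
    DW[g$edges[, 2:1, drop = FALSE]] <- DW[g$edges[, 2:1, drop = FALSE]] - 1
  }
  eig <- if (g$n > 1) eigen(DW, symmetric = TRUE, only.values = TRUE)$values
         else as.numeric(DW)

  nbr0 <- lapply(g$nbr, function(v) as.integer(v - 1L))
  members0 <- lapply(seq_len(d$N_H), function(i) as.integer(which(H == i) - 1L))

  gamma_init <- function() {
    if (constrained) {
      Esum <- aggregate_means(E, H, d$N_H)
      log(pmax(Z, 0.5) / Esum)
    } else {
      matrix(log(pmax(colSums(Z), 0.5) / colSums(E)), 1, d$Q)
    }
  }

  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, chains)

  run_one <- function(c) {
    set.seed(chain_seeds[c])
    init <- list(
      f = rep(0, d$N_L), u = matrix(0, d$N_L, d$P),
      lambda_y = rep(1, d$P), lambda_z = rep(1, d$Q),
      beta = rep(0, max(d$L, 1)), gamma = gamma_init(),
      kappa = 0.5, sigma2_f = 1, sigma2_u = 1)
    if (c > 1) {  # overdispersed start
      init$f <- rnorm(d$N_L, 0, 0.3)
      init$u <- matrix(rnorm(d$N_L * d$P, 0, 0.2), d$N_L, d$P)
      init$lambda_y <- exp(rnorm(d$P, 0, 0.3))
      if (d$Q > 1) init$lambda_z[-1] <- exp(rnorm(d$Q - 1, 0, 0.3))
      init$beta <- rnorm(max(d$L, 1), 0, 0.3)
      init$gamma <- init$gamma + rnorm(length(init$gamma), 0, 0.2)
      init$kappa <- plogis(rnorm(1, 0, 1))
      init$sigma2_f <- exp(rnorm(1, 0, 0.5))
      init$sigma2_u <- exp(rnorm(1, 0, 0.5))
    }
    .run_chain_cpp(y, O, E, Z, X, as.integer(H - 1L), nbr0, members0,
                   eig, constrained, as.integer(iter), as.integer(burnin),
                   as.integer(thin), init, likelihood)
  }
  runs <- lapply(seq_len(chains), run_one)

  structure(
    list(chains = runs, data = data, graph = g, mode = mode,
         dims = d, membership = H, eig = eig,
         config = list(chains = chains, iter = iter, burnin = burnin,
                       thin = thin, seed = seed,
                       chain_seeds = chain_seeds,
                       likelihood = likelihood),
         n_retained = runs[[1]]$n_retained),
    class = "prev_fit")
}

#' @export
print.prev_fit <- function(x, ...) {
  cat(sprintf(
    "<prev_fit> %s-mode fit: %d chain(s) x %d retained draws (%d iterations, %d burn-in)\n",
    x$mode, x$config$chains, x$n_retained, x$config$iter, x$config$burnin))
  acc <- sapply(x$chains, function(ch) ch$accept)
  cat("mean acceptance (f, u, kappa):",
      paste(sprintf("%.2f", rowMeans(acc)), collapse = ", "), "\n")
  invisible(x)
}

# ---- draw access -----------------------------------------------------------

# named list of per-chain matrices (draws x k) for every scalar parameter
scalar_draws <- function(fit) {
  d <- fit$dims
  lab <- list(
    beta = if (d$L > 0) paste0("beta[", seq_len(d$L), "]") else character(),
    kappa = "kappa", sigma2_f = "sigma2_f", sigma2_u = "sigma2_u",
    lambda_y = paste0("lambda_y[", seq_len(d$P), "]"),
    lambda_z = paste0("lambda_z[", seq_len(d$Q), "]"),
    gamma = if (fit$mode == "constrained")
      as.vector(outer(fit$data$higher$higher_id, seq_len(d$Q),
                      function(i, q) paste0("gamma[", i, ",", q, "]")))
    else paste0("gamma[", seq_len(d$Q), "]"))
  out <- lapply(fit$chains, function(ch) {
    m <- cbind(
      if (d$L > 0) ch$beta[, seq_len(d$L), drop = FALSE] else NULL,
      ch$kappa, ch$sigma2_f, ch$sigma2_u, ch$lambda_y, ch$lambda_z, ch$gamma)
    colnames(m) <- unlist(lab, use.names = FALSE)
    m
  })
  out
}

#' Posterior draws in long format
#'
#' @param fit A `prev_fit` object.
#' @param parameters Optional character vector restricting to these
#'   parameter names (e.g. `"kappa"`, `"beta[1]"`).
#' @return Tibble with columns `chain`, `iteration`, `term`, `value`.
#' @export
tidy_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "prev_fit"))
  ds <- scalar_draws(fit)
  purrr::imap_dfr(ds, function(m, c) {
    if (!is.null(parameters)) m <- m[, intersect(colnames(m), parameters),
                                     drop = FALSE]
    tibble(chain = as.integer(c), iteration = rep(seq_len(nrow(m)), ncol(m)),
           term = rep(colnames(m), each = nrow(m)),
           value = as.vector(m))
  })
}

# ---- convergence -----------------------------------------------------------

#' Gelman-Rubin potential scale reduction factors
#'
#' Classic two-or-more-chain PSRF: with `n` retained draws per chain,
#' within-chain variance `W`, between-chain variance `B`,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains have mixed; parameters exceeding `threshold` are flagged.
#'
#' @param fit A `prev_fit` with at least 2 chains, or a list of
#'   equal-length numeric matrices / vectors (one per chain).
#' @param parameters Optional restriction, as in [tidy_draws()].
#' @param threshold Flagging threshold (default 1.1).
#' @return Tibble `term`, `rhat`, `flagged`.
#' @export
gelman_rubin <- function(fit, parameters = NULL, threshold = 1.1) {
  if (inherits(fit, "prev_fit")) {
    if (fit$config$chains < 2)
      abort("Gelman-Rubin diagnostics need at least 2 chains")
    ds <- scalar_draws(fit)
  } else {
    ds <- lapply(fit, function(m) {
      m <- as.matrix(m)
      if (is.null(colnames(m))) colnames(m) <- paste0("par", seq_len(ncol(m)))
      m
    })
    if (length(ds) < 2) abort("need at least 2 chains")
  }
  if (!is.null(parameters))
    ds <- lapply(ds, function(m) m[, intersect(colnames(m), parameters),
                                   drop = FALSE])
  n <- nrow(ds[[1]])
  if (n < 10) abort("need at least 10 retained draws per chain")
  terms <- colnames(ds[[1]])
  rhat <- vapply(terms, function(tm) {
    x <- sapply(ds, function(m) m[, tm])
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (W == 0) return(if (B == 0) 1 else Inf)
    # floored at 1: identical chains indicate convergence, not super-efficiency
    sqrt(max(((n - 1) / n * W + B / n) / W, 1))
  }, numeric(1))
  tibble(term = terms, rhat = unname(rhat), flagged = rhat > threshold)
}

# batch-means Monte Carlo standard error, pooled over chains
batch_mcse <- function(chains_x) {
  per <- vapply(chains_x, function(x) {
    n <- length(x)
    nb <- max(2L, floor(sqrt(n)))
    bs <- floor(n / nb)
    bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                 numeric(1))
    var(bm) * bs / n  # variance of the chain mean
  }, numeric(1))
  sqrt(mean(per) / length(chains_x))
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy posterior summaries of a fitted model
#'
#' One row per scalar model parameter with posterior mean, sd, batch-means
#' Monte Carlo standard error, central 95% interval and (for multi-chain
#' fits) the Gelman-Rubin factor.
#'
#' @param x A `prev_fit` object.
#' @param parameters Optional restriction, as in [tidy_draws()].
#' @param conf.level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `mcse`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.prev_fit <- function(x, parameters = NULL, conf.level = 0.95, ...) {
  ds <- scalar_draws(x)
  if (!is.null(parameters))
    ds <- lapply(ds, function(m) m[, intersect(colnames(m), parameters),
                                   drop = FALSE])
  terms <- colnames(ds[[1]])
  a <- (1 - conf.level) / 2
  rh <- if (x$config$chains >= 2 && nrow(ds[[1]]) >= 10)
    gelman_rubin(x, parameters = parameters) else NULL
  out <- purrr::map_dfr(terms, function(tm) {
    v <- unlist(lapply(ds, function(m) m[, tm]), use.names = FALSE)
    tibble(term = tm, estimate = mean(v), std.error = sd(v),
           mcse = batch_mcse(lapply(ds, function(m) m[, tm])),
           conf.low = unname(quantile(v, a)),
           conf.high = unname(quantile(v, 1 - a)))
  })
  if (!is.null(rh)) out <- left_join(out, rh[c("term", "rhat")], by = "term")
  else out$rhat <- NA_real_
  out
}

#' One-row model summary
#'
#' @param x A `prev_fit` object.
#' @param ... Unused.
#' @return Tibble with retained-draw counts, the indicator-scope and
#'   full-likelihood DIC decompositions, the largest R-hat over scalar
#'   parameters, and the mean latent-factor acceptance rate.
#' @export
glance.prev_fit <- function(x, ...) {
  dy <- dic(x, scope = "y")
  df <- dic(x, scope = "full")
  rh <- if (x$config$chains >= 2) max(gelman_rubin(x)$rhat) else NA_real_
  tibble(n_chains = x$config$chains, n_retained = x$n_retained,
         dbar_y = dy$dbar, p_d_y = dy$p_d, dic_y = dy$dic,
         dic_full = df$dic, rhat_max = rh,
         accept_f = mean(sapply(x$chains, function(ch) ch$accept["f"])))
}
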