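# Posterior summaries of small-area prevalence: relative risks xi = delta/E,
# standardised relative risks, hotspot labels, and the check that fitted
# higher-area totals reproduce the observed ones.

# per-outcome list of xi draw matrices (draws x N_L), chains stacked
xi_draws <- function(fit) {
  d <- fit$dims
  E <- block_matrix(fit$data$areas, "E", d$Q)
  lapply(seq_len(d$Q), function(q) {
    cols <- (q - 1) * d$N_L + seq_len(d$N_L)
    do.call(rbind, lapply(fit$chains, function(ch)
      sweep(ch$delta[, cols, drop = FALSE], 2, E[, q], "/")))
  })
}

#' Small-area relative prevalence risks
#'
#' The relative risk of area `j` is `xi_j = delta_j / E_j`, the model's
#' small-area prevalence relative to its age-sex expectation; summaries are
#' taken over the retained draws of `delta` (mean of per-draw ratios).
#'
#' @param fit A `prev_fit` object.
#' @param probs Quantiles to report (default 2.5% and 97.5%).
#' @return Tibble `area_id`, `higher_id`, `outcome`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
relative_risks <- function(fit, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "prev_fit"))
  d <- fit$dims
  xs <- xi_draws(fit)
  purrr::map_dfr(seq_len(d$Q), function(q) {
    x <- xs[[q]]
    tibble(area_id = fit$data$areas$area_id,
           higher_id = fit$data$areas$higher_id,
           outcome = q,
           estimate = colMeans(x),
           std.error = apply(x, 2, sd),
           conf.low = apply(x, 2, quantile, probs[1]),
           conf.high = apply(x, 2, quantile, probs[2]))
  })
}

#' Standardised relative risks
#'
#' At every retained draw the relative risks are centred and scaled across
#' areas: `SRR_j = (xi_j - mean(xi)) / sd(xi)` with the sample (n-1)
#' standard deviation, so at each draw the SRRs have mean 0 and sd 1 across
#' areas. Posterior means of the SRRs locate areas relative to the regional
#' prevalence surface in units of its cross-area spread; exceedance
#' probabilities for the +/-1 thresholds are reported alongside.
#'
#' @param fit A `prev_fit` object.
#' @return Tibble `area_id`, `higher_id`, `outcome`, `srr` (posterior
#'   mean), `pr_above_1`, `pr_below_minus_1`.
#' @export
srr <- function(fit) {
  stopifnot(inherits(fit, "prev_fit"))
  d <- fit$dims
  if (d$N_L < 2) abort("SRRs need at least two areas")
  xs <- xi_draws(fit)
  purrr::map_dfr(seq_len(d$Q), function(q) {
    x <- xs[[q]]
    mu <- rowMeans(x)
    s <- sqrt(pmax(rowSums((x - mu)^2), 0) / (ncol(x) - 1))
    bad <- s == 0
    if (any(bad)) {
      warn(sprintf("%d draw(s) with zero cross-area variance skipped", sum(bad)))
      x <- x[!bad, , drop = FALSE]; mu <- mu[!bad]; s <- s[!bad]
    }
    z <- (x - mu) / s
    tibble(area_id = fit$data$areas$area_id,
           higher_id = fit$data$areas$higher_id,
           outcome = q,
           srr = colMeans(z),
           pr_above_1 = colMeans(z > 1),
           pr_below_minus_1 = colMeans(z < -1))
  })
}

#' Three-way hotspot classification
#'
#' Labels each area by its posterior mean SRR: `"high"` above the upper
#' threshold, `"low"` below the lower one, `"middle"` otherwise. The
#' conventional choices are one or two cross-area standard deviations.
#'
#' @param srr_tbl Output of [srr()], or any data frame with an `srr` column.
#' @param thresholds Length-2 numeric `(lower, upper)`, default `c(-1, 1)`.
#' @return The input with a `label` factor column added.
#' @export
classify_srr <- function(srr_tbl, thresholds = c(-1, 1)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  srr_tbl %>%
    mutate(label = factor(
      dplyr::case_when(.data$srr > thresholds[2] ~ "high",
                       .data$srr < thresholds[1] ~ "low",
                       TRUE ~ "middle"),
      levels = c("low", "middle", "high")))
}

#' Per-area prevalence summary table
#'
#' Joins relative risks, SRRs and hotspot labels into the per-area output
#' table.
#'
#' @param fit A `prev_fit` object.
#' @param thresholds Passed to [classify_srr()].
#' @return Tibble of class `prev_area_summary`.
#' @export
area_summary <- function(fit, thresholds = c(-1, 1)) {
  rr <- relative_risks(fit)
  ss <- classify_srr(srr(fit), thresholds)
  out <- left_join(rr, ss, by = c("area_id", "higher_id", "outcome"))
  class(out) <- c("prev_area_summary", class(out))
  out
}

#' @rdname area_summary
#' @param x An area summary table.
#' @param file Output CSV path.
#' @export
write_area_summary <- function(x, file) {
  readr::write_csv(as.data.frame(x), file)
  invisible(file)
}

#' Check fitted higher-area totals against the observed ones
#'
#' For each higher area and outcome, compares the posterior mean of
#' `Delta_iq` (the fitted total of small-area prevalence means) with the
#' observed total `Z_iq`. In constrained mode every per-area discrepancy
#' should be small (the Poisson-multinomial device pins the totals); in
#' unconstrained mode only the region-wide total is preserved, so per-area
#' discrepancies are informative about disagreement between the latent
#' morbidity surface and the recorded totals.
#'
#' @param fit A `prev_fit` object.
#' @return Tibble `higher_id`, `outcome`, `Z`, `Delta_hat`,
#'   `rel_discrepancy` (`|Delta_hat - Z| / Z`), with the per-outcome global
#'   relative discrepancy in attribute `"global"`.
#' @export
aggregation_check <- function(fit) {
  stopifnot(inherits(fit, "prev_fit"))
  d <- fit$dims
  Z <- block_matrix(fit$data$higher, "Z", d$Q)
  delta_mean <- Reduce(`+`, lapply(fit$chains, function(ch)
    colMeans(ch$delta))) / length(fit$chains)
  delta_mean <- matrix(delta_mean, d$N_L, d$Q)
  Delta_hat <- aggregate_means(delta_mean, fit$membership, d$N_H)
  out <- purrr::map_dfr(seq_len(d$Q), function(q) {
    dh <- Delta_hat[, q]; zz <- Z[, q]
    tibble(higher_id = fit$data$higher$higher_id, outcome = q,
           Z = zz, Delta_hat = dh, rel_discrepancy = abs(dh - zz) / zz)
  })
  attr(out, "global") <- tibble(
    outcome = seq_len(d$Q),
    Z_total = colSums(Z),
    Delta_total = colSums(Delta_hat),
    rel_discrepancy = abs(colSums(Delta_hat) - colSums(Z)) / colSums(Z))
  out
}
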