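#' London PCT CHD prevalence fixture
#'
#' The packaged 31-row table of officially recorded CHD treated-prevalence
#' totals for London Primary Care Trusts, expected totals under an external
#' age-sex standard, and average household income. Reproduced verbatim from
#' its source including two transcription quirks (a duplicated
#' Islington/Hillingdon row and two relative risks off by one unit in the
#' third decimal); see the package's `extdata/README.md`.
#'
#' @return Tibble with columns `pct`, `observed`, `expected`,
#'   `rr_published`, `rr_rank_published`, `income`, `income_rank_published`.
#' @export
london_heart <- function() {
  readr::read_csv(system.file("extdata", "london_pct_chd.csv",
                              package = "prevfactor", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' PCT prevalence risk versus income report
#'
#' Computes per-PCT prevalence relative risks `RR = observed / expected`
#' (reported rounded to 3 decimals), ranks both the risks and incomes
#' ascending (1 = lowest, average ranks for ties), and reports the rank
#' correlation between prevalence risk and income (Pearson correlation of
#' the two average-tie rank vectors, i.e. Spearman). A negative value
#' reflects higher recorded prevalence in lower-income PCTs.
#'
#' @param data A data frame with columns `pct`, `observed`, `expected`,
#'   `income`; defaults to the packaged [london_heart()] table.
#' @return Tibble `pct`, `observed`, `expected`, `rr`, `rr_rank`, `income`,
#'   `income_rank`, with the rank correlation in attribute
#'   `"rank_correlation"` (also printed by [print.pct_risk_table()]).
#' @examples
#' rep <- pct_risk_table()
#' rep[rep$pct == "Newham", ]  # RR 12495/9433 = 1.325
#' attr(rep, "rank_correlation")
#' @export
pct_risk_table <- function(data = london_heart()) {
  stopifnot(all(c("pct", "observed", "expected", "income") %in% names(data)))
  rr_exact <- data$observed / data$expected
  out <- tibble(pct = data$pct,
                observed = data$observed,
                expected = data$expected,
                rr = round(rr_exact, 3),
                rr_rank = rank(rr_exact),
                income = data$income,
                income_rank = rank(data$income))
  attr(out, "rank_correlation") <- cor(out$rr_rank, out$income_rank)
  class(out) <- c("pct_risk_table", class(out))
  out
}

#' @export
print.pct_risk_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("rank correlation (prevalence risk vs income): %.2f\n",
              attr(x, "rank_correlation")))
  invisible(x)
}
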