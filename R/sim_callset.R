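#' Simulate a methylation call set directly from a cell profile
#'
#' Bypasses read simulation: per CpG site, coverage is drawn as
#' Poisson(`mean_cov`) (or fixed when `fixed_cov = TRUE`) and the
#' methylated count as Binomial(coverage, p) from the cell's per-site
#' probability, optionally corrupted by bisulfite conversion failure
#' (an unmethylated observation is read as methylated with probability
#' `conversion_failure`). Used for cohort- and DMR-scale experiments
#' where the read-level machinery is exercised elsewhere.
#'
#' @param profile `cell_profile` from [simulate_cell_methylome()].
#' @param mean_cov mean per-site coverage.
#' @param seed integer seed.
#' @param fixed_cov if TRUE every covered site gets exactly `mean_cov`
#'   observations.
#' @param conversion_failure probability an unmethylated observation is
#'   misread as methylated.
#' @return `methylation_calls` (sites with zero coverage are absent).
#' @export
simulate_callset <- function(profile, mean_cov = 10, seed = 1L,
                             fixed_cov = FALSE, conversion_failure = 0) {
  sites <- profile$prob
  local_seed(seed, {
    n <- if (fixed_cov) rep(as.integer(mean_cov), nrow(sites))
    else stats::rpois(nrow(sites), mean_cov)
    meth <- stats::rbinom(nrow(sites), n, sites$p)
    if (conversion_failure > 0) {
      unm <- n - meth
      meth <- meth + stats::rbinom(nrow(sites), unm, conversion_failure)
    }
    keep <- n > 0
    methylation_calls(
      data.table::data.table(chrom = sites$chrom[keep],
                             pos = sites$pos[keep],
                             meth = meth[keep],
                             unmeth = (n - meth)[keep]),
      cell_id = profile$cell_id)
  })
}
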