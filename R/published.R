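# Published model-fit summaries for the two sperm-heteromorphism study
# systems, used for desk-scale consistency checks of the AIC parameter-count
# convention and the chi-square reference distribution.

#' Published evolutionary-rate model fits (reference values)
#'
#' Summary statistics of the ten published observed-vs-common rate-model
#' comparisons for the Drosophila obscura-group and Lepidoptera
#' sperm-heteromorphism datasets: sample size, number of traits,
#' log-likelihoods of both models, the LRT statistic with its degrees of
#' freedom, the p-value as printed (two decimals, or `<0.001`), and both
#' AIC values as printed. These are reported values, not computed by this
#' package; they parameterise consistency checks — e.g. that
#' `AIC = -2 logL + 2k` with `k_obs = 2p`, `k_common = p + 1` reproduces
#' every printed AIC, and that the chi-square upper tail at (LRT, df)
#' reproduces every printed p-value.
#'
#' @return A data.frame with one row per published comparison.
#' @export
published_fits <- function() {
  data.frame(
    analysis = c("drosophila_4trait", "lepidoptera_3trait",
                 "fertile_head_vs_flagellum", "nonfertile_head_vs_flagellum",
                 "head_fertile_vs_nonfertile", "flagellum_fertile_vs_nonfertile",
                 "fertile_head_vs_receptacle", "fertile_flagellum_vs_receptacle",
                 "nonfertile_head_vs_receptacle", "nonfertile_flagellum_vs_receptacle"),
    n = c(15L, 12L, 12L, 12L, 12L, 12L, 11L, 11L, 11L, 11L),
    p = c(4L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    logL_obs = c(46.71, 21.35, 4.86, 20.00, 9.89, 6.76, 3.75, 2.13, 9.55, 1.37),
    logL_common = c(25.54, 17.10, 1.94, 16.56, -1.36, 4.96, 2.59, 1.94, 1.62, -0.55),
    LRT = c(42.32, 8.50, 5.84, 6.88, 22.50, 3.59, 2.32, 0.38, 15.86, 3.85),
    df = c(3L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    p_printed = c("<0.001", "0.01", "0.02", "<0.01", "<0.001", "0.06",
                  "0.13", "0.53", "<0.001", "0.0499"),
    AIC_obs = c(-77.41, -30.69, -1.72, -31.99, -11.78, -5.51, 0.51, 3.74,
                -11.10, 5.26),
    AIC_common = c(-41.09, -26.19, 2.11, -27.11, 8.72, -3.92, 0.83, 2.11,
                   2.76, 7.10),
    stringsAsFactors = FALSE
  )
}

#' Published observed rate-matrix diagonals (reference values)
#'
#' Per-trait Brownian rates of the two published multi-trait analyses
#' (log10-units squared per unit branch length), as printed. Used to
#' parameterise the synthetic-data presets and to check rate-ratio
#' arithmetic (e.g. fertile/non-fertile total length 0.99/0.29 = 3.4).
#'
#' @return Named list with `drosophila` and `lepidoptera` rate vectors.
#' @export
published_rates <- function() {
  list(
    drosophila = c(fertile_total = 0.99, nonfertile_total = 0.29,
                   wing = 0.03, seminal_receptacle = 1.09),
    lepidoptera = c(fertile_total = 0.053, nonfertile_total = 0.014,
                    forewing = 0.032)
  )
}
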