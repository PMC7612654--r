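#' Endpoint of the MUSE lupus trial example
#'
#' Four-outcome systemic lupus erythematosus endpoint used throughout the
#' worked examples: SLEDAI (continuous), PGA (continuous), BILAG (ordinal,
#' five levels) and a corticosteroid-taper indicator (binary). Effects are
#' the published trial estimates: mean differences 0.88 (SLEDAI) and 0.38
#' (PGA); latent effects 0.24 (BILAG, response rates 0.97 vs 0.95) and 0.40
#' (Taper, 0.54 vs 0.38), entered as the printed two-decimal estimates.
#' Latent correlations are the trial estimates
#' \eqn{\rho_{12}=0.448, \rho_{13}=0.521, \rho_{14}=0.003, \rho_{23}=0.448,
#' \rho_{24}=-0.031, \rho_{34}=0.066}.
#'
#' @param sigma1_sq Assumed SLEDAI variance (default 18; the design studies
#'   18, 19, 20).
#' @param sigma2_sq Assumed PGA variance (default 0.35; the design studies
#'   0.35 to 0.65).
#' @return A [mixed_endpoint()] with K = 4, `k_m` = 2.
#' @examples
#' muse_endpoint()
#' @export
muse_endpoint <- function(sigma1_sq = 18, sigma2_sq = 0.35) {
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.448
  corr[1, 3] <- corr[3, 1] <- 0.521
  corr[1, 4] <- corr[4, 1] <- 0.003
  corr[2, 3] <- corr[3, 2] <- 0.448
  corr[2, 4] <- corr[4, 2] <- -0.031
  corr[3, 4] <- corr[4, 3] <- 0.066
  mixed_endpoint(
    dplyr::bind_rows(
      outcome_continuous("SLEDAI", effect = 0.88, sd = sqrt(sigma1_sq)),
      outcome_continuous("PGA", effect = 0.38, sd = sqrt(sigma2_sq)),
      outcome_ordinal("BILAG", n_levels = 5, prob_T = 0.97, prob_C = 0.95,
                      effect = 0.24),
      outcome_binary("Taper", prob_T = 0.54, prob_C = 0.38, effect = 0.40)
    ),
    corr = corr
  )
}

#' Four-outcome equicorrelated design grid endpoint
#'
#' Builds the K = 4 endpoint (two continuous with unit variance, one
#' five-level ordinal, one binary) with all effects given on the
#' standardized/latent scale and a common correlation `rho`, as used in the
#' sample-size grid studies.
#'
#' @param delta Length-4 vector of standardized effects (continuous,
#'   continuous, ordinal, binary).
#' @param rho Common correlation between every pair of outcomes.
#' @return A [mixed_endpoint()].
#' @examples
#' grid_endpoint(delta = rep(0.12, 4), rho = 0)
#' @export
grid_endpoint <- function(delta = rep(0.12, 4), rho = 0) {
  stopifnot(length(delta) == 4)
  mixed_endpoint(
    dplyr::bind_rows(
      outcome_continuous("y1", effect = delta[1], sd = 1),
      outcome_continuous("y2", effect = delta[2], sd = 1),
      outcome_ordinal("y3", n_levels = 5, effect = delta[3]),
      outcome_binary("y4", effect = delta[4])
    ),
    rho = rho
  )
}
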