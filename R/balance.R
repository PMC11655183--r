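#' Annual carbon balance with quadrature uncertainty
#'
#' `C = NEE-C + CH4-C`, both terms in g C m-2 yr-1; standard deviations add
#' in quadrature.
#'
#' @param nee_c annual NEE, g CO2-C m-2 yr-1.
#' @param nee_sd its standard deviation.
#' @param ch4_c annual CH4-C balance, g CH4-C m-2 yr-1.
#' @param ch4_sd its standard deviation.
#' @return list with `value` and `sd`, g C m-2 yr-1.
#' @examples
#' c_balance(-262.4, 7.8, 36.1, 3.4)   # -226.3 +- 8.5
#' @export
c_balance <- function(nee_c, nee_sd = 0, ch4_c = 0, ch4_sd = 0) {
  list(value = nee_c + ch4_c, sd = sqrt(nee_sd^2 + ch4_sd^2))
}

#' Annual greenhouse-gas balance in CO2 equivalents
#'
#' CO2-C and CH4-C are converted to gas masses with the molar mass ratios
#' 44/12 and 16/12, CH4 is weighted by its global warming potential, and the
#' sum is expressed in t CO2-eq ha-1 yr-1 (factor 0.01 from g m-2).
#' Standard deviations propagate in quadrature.
#'
#' @inheritParams c_balance
#' @param gwp global warming potential of CH4 (default 27, 100-year
#'   horizon).
#' @param co2_per_c,ch4_per_c mass ratios; integer molar masses by default
#'   (44/12, 16/12), which reproduce conventionally rounded published
#'   balances; exact atomic masses selectable.
#' @return list with `value` and `sd`, t CO2-eq ha-1 yr-1.
#' @examples
#' ghg_balance(-262.4, 7.8, 36.1, 3.4, gwp = 27)   # 3.38 +- 1.26
#' @export
ghg_balance <- function(nee_c, nee_sd = 0, ch4_c = 0, ch4_sd = 0, gwp = 27,
                        co2_per_c = 44 / 12, ch4_per_c = 16 / 12) {
  if (gwp <= 0) stop("gwp must be > 0")
  value <- (nee_c * co2_per_c + ch4_c * ch4_per_c * gwp) * 0.01
  sd <- 0.01 * sqrt((nee_sd * co2_per_c)^2 + (ch4_sd * ch4_per_c * gwp)^2)
  list(value = value, sd = sd)
}

#' Share of CH4 in the total CO2-equivalent balance
#'
#' `100 * |CH4 CO2-eq| / (|CH4 CO2-eq| + |CO2 CO2-eq|)`, in percent.
#'
#' @inheritParams ghg_balance
#' @return percent.
#' @examples
#' ch4_equiv_share(-262.4, 36.1, gwp = 27)   # ~57
#' @export
ch4_equiv_share <- function(nee_c, ch4_c, gwp = 27,
                            co2_per_c = 44 / 12, ch4_per_c = 16 / 12) {
  co2_eq <- abs(nee_c * co2_per_c)
  ch4_eq <- abs(ch4_c * ch4_per_c * gwp)
  if (co2_eq + ch4_eq == 0) stop("both components are zero")
  100 * ch4_eq / (ch4_eq + co2_eq)
}

#' Annual site balances and cross-site ratio report
#'
#' Assembles per-site C and greenhouse-gas balances from annual CO2 flux
#' sums and CH4 scalar inputs, and reports cross-site ratios with the first
#' site as the reference: respiration of the second site relative to the
#' first, GPP of the first relative to the second, and the NEE difference.
#'
#' @param sites `data.frame` with one row per site and columns `site_id`,
#'   `gpp`, `reco`, `nee` (g CO2-C m-2 yr-1), `nee_sd`, `ch4` (g CH4-C m-2
#'   yr-1), `ch4_sd`.
#' @param gwp global warming potential of CH4.
#' @return list with `balances` (per-site `data.frame`: the inputs plus
#'   `c_balance`, `c_sd`, `ghg`, `ghg_sd`, `ch4_share` percent) and, when
#'   exactly two sites are present, `ratios` (`reco_ratio_pct`,
#'   `gpp_ratio_pct`, `nee_difference`, rounded percentages).
#' @export
site_summary <- function(sites, gwp = 27) {
  need <- c("site_id", "gpp", "reco", "nee", "nee_sd", "ch4", "ch4_sd")
  stopifnot(all(need %in% names(sites)))
  bal <- sites
  cb <- Map(c_balance, sites$nee, sites$nee_sd, sites$ch4, sites$ch4_sd)
  gb <- Map(ghg_balance, sites$nee, sites$nee_sd, sites$ch4, sites$ch4_sd,
            MoreArgs = list(gwp = gwp))
  bal$c_balance <- vapply(cb, `[[`, numeric(1), "value")
  bal$c_sd <- vapply(cb, `[[`, numeric(1), "sd")
  bal$ghg <- vapply(gb, `[[`, numeric(1), "value")
  bal$ghg_sd <- vapply(gb, `[[`, numeric(1), "sd")
  bal$ch4_share <- mapply(ch4_equiv_share, sites$nee, sites$ch4,
                          MoreArgs = list(gwp = gwp))
  out <- list(balances = bal)
  if (nrow(sites) == 2) {
    if (sites$reco[1] == 0 || sites$gpp[2] == 0) stop("division by zero")
    out$ratios <- list(
      reco_ratio_pct = round(100 * sites$reco[2] / sites$reco[1]),
      gpp_ratio_pct = round(100 * sites$gpp[1] / sites$gpp[2]),
      nee_difference = sites$nee[1] - sites$nee[2])
  }
  out
}
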