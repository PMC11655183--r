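#' Describe one bog surface source (microform or branch canopy)
#'
#' A microform specification carries the areal share and the "true" model
#' parameters used by the synthetic-data generator: a Lloyd-Taylor basal
#' respiration and temperature sensitivity, a rectangular-hyperbola light
#' response, an annual CH4-C balance (taken as a scalar input, e.g. from a
#' companion CH4 study) and the microform's water-level offset from the site
#' mean.
#'
#' @param name label, e.g. `"hummock"`, `"hollow"`, `"nT_hummock"`,
#'   `"T_hollow"` or `"branch"`.
#' @param areal_share fraction of ground area in `[0, 1]`. The branch source
#'   is weighted by leaf area index instead and must use `areal_share = 0`.
#' @param r_ref basal respiration at the 10 degC reference temperature,
#'   g CO2-C m-2 h-1 (per m2 of leaf for the branch source). Must be > 0.
#' @param e0 Lloyd-Taylor activation-energy-like parameter, K. Must be >= 0.
#' @param alpha initial slope of the light response,
#'   g CO2-C per umol photons. Must be >= 0.
#' @param gp_max light-saturated gross photosynthesis, g CO2-C m-2 h-1
#'   (per m2 leaf for the branch). Must be >= 0.
#' @param ch4_annual annual CH4-C balance, g CH4-C m-2 yr-1.
#' @param ch4_sd standard deviation of `ch4_annual`.
#' @param wl_offset water level offset from the site mean, m (positive =
#'   wetter than site mean).
#' @return an object of class `microform_spec` (a named list).
#' @seealso [site_scenario()]
#' @export
microform_spec <- function(name, areal_share, r_ref, e0, alpha, gp_max,
                           ch4_annual = 0, ch4_sd = 0, wl_offset = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(areal_share) || areal_share < 0 || areal_share > 1)
    stop("areal_share must be in [0, 1]")
  if (!is.numeric(r_ref) || r_ref <= 0) stop("r_ref must be > 0")
  if (e0 < 0) stop("e0 must be >= 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (gp_max < 0) stop("gp_max must be >= 0")
  if (identical(name, "branch") && areal_share != 0)
    stop("branch source carries LAI weight, not an areal share")
  structure(
    list(name = name, areal_share = areal_share,
         r_ref = r_ref, e0 = e0, alpha = alpha, gp_max = gp_max,
         ch4_annual = ch4_annual, ch4_sd = ch4_sd, wl_offset = wl_offset),
    class = "microform_spec")
}

#' Assemble a site scenario for the synthetic-data generator
#'
#' A scenario is the stated world a synthetic run emulates: the set of surface
#' sources with their areal shares, an optional biweekly tree-LAI series (the
#' branch weight), the start of the hydrological year and the site mean water
#' level and air temperature.
#'
#' @param site_id site label, e.g. `"open"` or `"tree"`.
#' @param microforms list of [microform_spec()] objects. Ground-microform
#'   areal shares must sum to 1 within 1e-9.
#' @param tree_lai `NULL` (open site) or a `data.frame` with columns `date`
#'   (`Date`, strictly increasing) and `lai` (m2 leaf m-2 ground, >= 0).
#' @param hydro_year_start `Date`; first day of the hydrological year.
#' @param mean_t_air annual mean air temperature, degC.
#' @param mean_wl site mean water level, m relative to surface (negative
#'   below).
#' @param seed integer seed for this scenario's stochastic components.
#' @return an object of class `site_scenario`.
#' @examples
#' sc <- open_site_scenario()
#' names(sc$microforms)
#' @export
site_scenario <- function(site_id, microforms, tree_lai = NULL,
                          hydro_year_start = as.Date("2020-11-01"),
                          mean_t_air = 9.9, mean_wl = -0.14, seed = 1L) {
  stopifnot(is.list(microforms), length(microforms) >= 1L)
  ok <- vapply(microforms, inherits, logical(1), "microform_spec")
  if (!all(ok)) stop("all microforms must be microform_spec objects")
  names(microforms) <- vapply(microforms, `[[`, character(1), "name")
  ground <- microforms[names(microforms) != "branch"]
  shares <- vapply(ground, `[[`, numeric(1), "areal_share")
  if (abs(sum(shares) - 1) > 1e-9)
    stop("ground-microform areal shares must sum to 1 (got ",
         format(sum(shares), digits = 12), ")")
  if (!is.null(tree_lai)) {
    stopifnot(is.data.frame(tree_lai), all(c("date", "lai") %in% names(tree_lai)))
    if (any(tree_lai$lai < 0)) stop("LAI must be >= 0")
    if (is.unsorted(tree_lai$date, strictly = TRUE))
      stop("LAI dates must be strictly increasing")
  }
  if ("branch" %in% names(microforms) && is.null(tree_lai))
    stop("a branch source requires a tree_lai series")
  structure(
    list(site_id = site_id, microforms = microforms, tree_lai = tree_lai,
         hydro_year_start = as.Date(hydro_year_start),
         mean_t_air = mean_t_air, mean_wl = mean_wl,
         seed = as.integer(seed)),
    class = "site_scenario")
}

#' @export
print.site_scenario <- function(x, ...) {
  cat("<site_scenario>", x$site_id, "\n")
  cat("  hydrological year from", format(x$hydro_year_start), "\n")
  for (mf in x$microforms)
    cat(sprintf("  %-11s share %.3f  R_ref %.3f  E0 %4.0f  alpha %.4f  GP_max %.2f\n",
                mf$name, mf$areal_share, mf$r_ref, mf$e0, mf$alpha, mf$gp_max))
  if (!is.null(x$tree_lai))
    cat("  tree LAI:", nrow(x$tree_lai), "observations, peak",
        format(max(x$tree_lai$lai), digits = 3), "\n")
  invisible(x)
}

#' Default open-site scenario
#'
#' Two microforms — hollow (56.5% of ground area) and hummock (43.5%) — with
#' no tree canopy, a permanently high water level and respiration/light
#' response parameters that echo the annual flux magnitudes of a successfully
#' rewetted bog: hummocks respire and assimilate more per unit area than
#' hollows.
#'
#' @param seed integer seed.
#' @return a [site_scenario()].
#' @export
open_site_scenario <- function(seed = 1L) {
  site_scenario(
    site_id = "open",
    microforms = list(
      microform_spec("hollow", 0.565, r_ref = 0.055, e0 = 150,
                     alpha = 0.0009, gp_max = 0.30,
                     ch4_annual = 49.8, ch4_sd = 5.5, wl_offset = 0.11),
      microform_spec("hummock", 0.435, r_ref = 0.125, e0 = 180,
                     alpha = 0.0012, gp_max = 0.45,
                     ch4_annual = 18.3, ch4_sd = 3.0, wl_offset = 0.01)),
    mean_t_air = 9.9, mean_wl = -0.14, seed = seed)
}

#' Default tree-site scenario
#'
#' Four ground microforms (hummocks/hollows near to and distant from trees,
#' hummocks covering 61.9% of the ground) plus a birch branch source weighted
#' by a biweekly LAI series peaking near 1 in mid-July. Ground respiration is
#' higher and ground photosynthesis lower than at the open site; the branch
#' source dominates uptake per unit leaf area during the vegetation period.
#'
#' @param seed integer seed.
#' @return a [site_scenario()].
#' @export
tree_site_scenario <- function(seed = 2L) {
  lai_dates <- seq(as.Date("2021-05-01"), as.Date("2021-10-29"), by = 14)
  lai <- c(0.05, 0.20, 0.45, 0.70, 0.90, 1.00, 0.97, 0.90,
           0.75, 0.55, 0.35, 0.15, 0.03)
  site_scenario(
    site_id = "tree",
    microforms = list(
      microform_spec("nT_hollow", 0.200, r_ref = 0.090, e0 = 160,
                     alpha = 0.0007, gp_max = 0.18,
                     ch4_annual = 15.5, ch4_sd = 3.0, wl_offset = 0.09),
      microform_spec("T_hollow", 0.181, r_ref = 0.100, e0 = 160,
                     alpha = 0.0006, gp_max = 0.16,
                     ch4_annual = 15.5, ch4_sd = 3.0, wl_offset = 0.11),
      microform_spec("nT_hummock", 0.310, r_ref = 0.130, e0 = 190,
                     alpha = 0.0008, gp_max = 0.20,
                     ch4_annual = 2.0, ch4_sd = 1.0, wl_offset = -0.02),
      microform_spec("T_hummock", 0.309, r_ref = 0.150, e0 = 190,
                     alpha = 0.0008, gp_max = 0.19,
                     ch4_annual = 2.0, ch4_sd = 1.0, wl_offset = -0.06),
      microform_spec("branch", 0, r_ref = 0.050, e0 = 120,
                     alpha = 0.0015, gp_max = 0.45)),
    tree_lai = data.frame(date = lai_dates, lai = lai),
    mean_t_air = 9.9, mean_wl = -0.21, seed = seed)
}

#' Interpolate the tree LAI on arbitrary dates
#'
#' Linear interpolation between the biweekly observations, zero outside the
#' observed span (leaf-off season).
#'
#' @param scenario a [site_scenario()].
#' @param dates `Date` vector.
#' @return numeric LAI values (0 for a scenario without trees).
#' @export
lai_at <- function(scenario, dates) {
  if (is.null(scenario$tree_lai)) return(rep(0, length(dates)))
  s <- scenario$tree_lai
  out <- stats::approx(as.numeric(s$date), s$lai, xout = as.numeric(as.Date(dates)),
                       rule = 1)$y
  out[is.na(out)] <- 0
  out
}

# Areal shares of the ground microforms, named.
ground_shares <- function(scenario) {
  g <- scenario$microforms[names(scenario$microforms) != "branch"]
  vapply(g, `[[`, numeric(1), "areal_share")
}
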