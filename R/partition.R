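#' Aggregate gap-filled EC records to daily fluxes
#'
#' Sums the complete (gap-filled) half-hourly GPP, Reco and NEE series to
#' daily totals. Every day must have its full 48 records.
#'
#' @param ec EC records from [generate_ec()] (gap-filled columns are used).
#' @return `data.frame` with `date`, `gpp`, `reco`, `nee` in
#'   g CO2-C m-2 d-1; `nee = gpp + reco` asserted.
#' @export
ec_daily <- function(ec) {
  day <- as.Date(ec$timestamp, tz = "UTC")
  cnt <- table(day)
  if (any(cnt != 48))
    stop("incomplete day(s): ", paste(names(cnt)[cnt != 48], collapse = ", "))
  gpp <- tapply(ec$gpp, day, sum)
  reco <- tapply(ec$reco, day, sum)
  nee <- tapply(ec$nee, day, sum)
  stopifnot(max(abs(nee - (gpp + reco))) < 1e-9)
  data.frame(date = as.Date(names(gpp)), gpp = as.numeric(gpp),
             reco = as.numeric(reco), nee = as.numeric(nee))
}

#' Partition one day of EC fluxes across surface sources
#'
#' Chamber-model daily flux densities are turned into relative weights —
#' areal share times flux density for ground microforms, LAI times flux
#' density for the branch source — separately for GPP and Reco. The relative
#' weights distribute the day's EC GPP and Reco across sources; partitioned
#' NEE is the per-source sum of the two. Conservation (sum of source fluxes
#' equals the EC flux) holds by construction. If all weights of a flux kind
#' vanish while the EC flux does not, the areal shares are used as weights
#' and the day is flagged.
#'
#' @param daily one day of [daily_reconstruct()] output (all sources).
#' @param scenario a [site_scenario()].
#' @param lai LAI on that day (scalar; 0 without trees).
#' @param ec_gpp,ec_reco the day's EC GPP (<= 0) and Reco (>= 0),
#'   g CO2-C m-2 d-1.
#' @return `data.frame`, one row per source: `date`, `microform`, `rel_gpp`,
#'   `rel_reco`, `gpp`, `reco`, `nee` (g CO2-C m-2 ground d-1), `fallback`.
#' @export
partition_day <- function(daily, scenario, lai, ec_gpp, ec_reco) {
  mf_names <- names(scenario$microforms)
  stopifnot(all(daily$microform %in% mf_names))
  daily <- daily[match(mf_names, daily$microform), , drop = FALSE]
  if (anyNA(daily$microform)) stop("missing source(s) for this day")
  w_area <- vapply(scenario$microforms, function(m)
    if (identical(m$name, "branch")) lai else m$areal_share, numeric(1))
  if (any(w_area * daily$reco < 0)) stop("negative Reco weight")
  w_gpp <- w_area * abs(daily$gpp)
  w_reco <- w_area * daily$reco
  fallback <- FALSE
  if (sum(w_gpp) == 0 && ec_gpp != 0) { w_gpp <- w_area; fallback <- TRUE }
  if (sum(w_reco) == 0 && ec_reco != 0) { w_reco <- w_area; fallback <- TRUE }
  rel_gpp <- if (sum(w_gpp) > 0) w_gpp / sum(w_gpp) else w_gpp
  rel_reco <- if (sum(w_reco) > 0) w_reco / sum(w_reco) else w_reco
  gpp_i <- rel_gpp * ec_gpp
  reco_i <- rel_reco * ec_reco
  data.frame(date = daily$date[1], microform = mf_names,
             rel_gpp = unname(rel_gpp), rel_reco = unname(rel_reco),
             gpp = unname(gpp_i), reco = unname(reco_i),
             nee = unname(gpp_i + reco_i), fallback = fallback,
             row.names = NULL)
}

#' Partition every day of a span
#'
#' Applies [partition_day()] to each date present in both the reconstructed
#' chamber-model series and the daily EC table.
#'
#' @param daily_sources output of [daily_reconstruct()].
#' @param scenario a [site_scenario()].
#' @param ec_days output of [ec_daily()].
#' @return long `data.frame` of partitioned days (see [partition_day()])
#'   plus the day's EC totals `ec_gpp`, `ec_reco`, `ec_nee`.
#' @export
partition_days <- function(daily_sources, scenario, ec_days) {
  dates <- intersect(as.character(unique(daily_sources$date)),
                     as.character(ec_days$date))
  lai <- lai_at(scenario, as.Date(dates))
  out <- vector("list", length(dates))
  for (k in seq_along(dates)) {
    d <- as.Date(dates[k])
    ds <- daily_sources[daily_sources$date == d, , drop = FALSE]
    e <- ec_days[ec_days$date == d, ]
    p <- partition_day(ds, scenario, lai[k], e$gpp, e$reco)
    p$ec_gpp <- e$gpp; p$ec_reco <- e$reco; p$ec_nee <- e$nee
    out[[k]] <- p
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage contributions from annual values
#'
#' Shares are computed on absolute values so that GPP contributions are
#' positive percentages.
#'
#' @param x numeric vector of annual per-source values.
#' @return percentages summing to 100 (0s if all-zero input).
#' @export
contribution_shares <- function(x) {
  s <- sum(abs(x))
  if (s == 0) return(rep(0, length(x)))
  100 * abs(x) / s
}

#' Annual source contributions over a hydrological year
#'
#' Sums partitioned daily fluxes per source over a complete hydrological
#' year and derives percentage shares of the site totals.
#'
#' @param partitioned output of [partition_days()].
#' @param hydro_year_start first day of the hydrological year; the year is
#'   `hydro_year_start` to `hydro_year_start + 364`.
#' @return `data.frame`, one row per source: annual `reco`, `gpp`, `nee`
#'   (g CO2-C m-2 yr-1) and `share_reco`, `share_gpp` (percent).
#' @export
annual_sums <- function(partitioned,
                        hydro_year_start = min(partitioned$date)) {
  span <- seq(as.Date(hydro_year_start), as.Date(hydro_year_start) + 364, 1)
  have <- unique(partitioned$date)
  missing <- span[!span %in% have]
  if (length(missing))
    stop("missing day(s) in hydrological year: ",
         paste(utils::head(format(missing), 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" ... (%d total)", length(missing)))
  p <- partitioned[partitioned$date %in% span, , drop = FALSE]
  mfs <- unique(p$microform)
  agg <- function(col) vapply(mfs, function(m)
    sum(p[[col]][p$microform == m]), numeric(1))
  reco <- agg("reco"); gpp <- agg("gpp"); nee <- agg("nee")
  data.frame(microform = mfs, reco = unname(reco), gpp = unname(gpp),
             nee = unname(nee),
             share_reco = unname(contribution_shares(reco)),
             share_gpp = unname(contribution_shares(gpp)),
             row.names = NULL)
}
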