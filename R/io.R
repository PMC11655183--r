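# Tabular I/O: plain CSV with ISO-8601 timestamps and a commented header
# documenting units and the atmospheric sign convention.

.SIGN_NOTE <- "atmospheric sign convention: negative = ecosystem uptake, positive = emission"

#' Write a bogflux table as CSV
#'
#' POSIXct columns are written as ISO-8601 UTC strings, `Date` columns as
#' `YYYY-MM-DD`. A comment header (lines starting with `#`) documents the
#' content; [read_bogflux_csv()] skips it.
#'
#' @param df `data.frame`.
#' @param path output path.
#' @param what one-line description for the header.
#' @return `path`, invisibly.
#' @export
write_bogflux_csv <- function(df, path, what = "") {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    else if (inherits(df[[nm]], "Date"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(what)) writeLines(paste("#", what), con)
  writeLines(paste("#", .SIGN_NOTE), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a bogflux CSV
#'
#' Inverse of [write_bogflux_csv()]: skips comment lines and restores
#' `timestamp`-like columns to POSIXct (UTC) and `date`-like columns to
#' `Date`.
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_bogflux_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (grepl("(^|_)(timestamp|time)$", nm) && is.character(df[[nm]]))
      df[[nm]] <- as.POSIXct(df[[nm]], format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
    else if (grepl("(^|_)date$", nm) && is.character(df[[nm]]))
      df[[nm]] <- as.Date(df[[nm]])
  }
  df
}

#' Serialise a site scenario to JSON
#'
#' @param scenario a [site_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  x <- list(
    site_id = scenario$site_id,
    hydro_year_start = format(scenario$hydro_year_start),
    mean_t_air = scenario$mean_t_air, mean_wl = scenario$mean_wl,
    seed = scenario$seed,
    microforms = lapply(unname(scenario$microforms), function(m)
      m[c("name", "areal_share", "r_ref", "e0", "alpha", "gp_max",
          "ch4_annual", "ch4_sd", "wl_offset")]),
    tree_lai = if (is.null(scenario$tree_lai)) NULL else
      list(date = format(scenario$tree_lai$date),
           lai = scenario$tree_lai$lai))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a site scenario from JSON
#'
#' @param path path written by [write_scenario_json()].
#' @return a [site_scenario()].
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mfs <- lapply(x$microforms, function(m)
    microform_spec(m$name, m$areal_share, m$r_ref, m$e0, m$alpha, m$gp_max,
                   m$ch4_annual, m$ch4_sd, m$wl_offset))
  lai <- if (is.null(x$tree_lai)) NULL else
    data.frame(date = as.Date(unlist(x$tree_lai$date)),
               lai = unlist(x$tree_lai$lai))
  site_scenario(x$site_id, mfs, tree_lai = lai,
                hydro_year_start = as.Date(x$hydro_year_start),
                mean_t_air = x$mean_t_air, mean_wl = x$mean_wl,
                seed = x$seed)
}
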