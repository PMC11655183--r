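#' Thresholds for pairing chamber and eddy-covariance fluxes
#'
#' The pairing rule set: a PAR floor of 150 W m-2 for light-dependent fluxes,
#' a 20% relative PAR difference, 2 degC air/soil temperature differences, a
#' 90-min tolerance for chamber-chamber pairing, and a 4-day / 2-h
#' (time-of-day) tolerance for pairing with EC half-hours.
#'
#' @param par_threshold minimum PAR for NEE/GPP pairing, W m-2.
#' @param d_par maximum relative PAR difference (fraction).
#' @param d_t_air maximum air temperature difference, degC (NEE/GPP).
#' @param d_t_soil maximum soil temperature difference, degC (Reco).
#' @param chamber_tolerance chamber-chamber time tolerance, s.
#' @param ec_tolerance EC pairing tolerance, s.
#' @param ec_daytime_tolerance EC time-of-day tolerance, s.
#' @param par_to_w conversion factor PAR umol m-2 s-1 per W m-2.
#' @return a named list of class `pairing_thresholds`.
#' @export
pairing_thresholds <- function(par_threshold = 150, d_par = 0.20,
                               d_t_air = 2, d_t_soil = 2,
                               chamber_tolerance = 90 * 60,
                               ec_tolerance = 4 * 86400,
                               ec_daytime_tolerance = 2 * 3600,
                               par_to_w = .PAR_TO_W) {
  th <- list(par_threshold = par_threshold, d_par = d_par,
             d_t_air = d_t_air, d_t_soil = d_t_soil,
             chamber_tolerance = chamber_tolerance,
             ec_tolerance = ec_tolerance,
             ec_daytime_tolerance = ec_daytime_tolerance,
             par_to_w = par_to_w)
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  structure(th, class = "pairing_thresholds")
}

# Relative PAR difference between two observations (fraction of their mean).
.rel_dpar <- function(p1, p2) {
  m <- (p1 + p2) / 2
  ifelse(m > 0, abs(p1 - p2) / m, 0)
}

# Greedy one-to-one pairing of two observation pools of the same flux type.
# Returns a data.frame of index pairs (i into a, j into b) ordered by match
# quality (smallest relative PAR difference for light fluxes, smallest time
# difference for Reco).
.pair_pools <- function(a, b, flux_type, th) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  light <- flux_type %in% c("NEE", "GPP")
  cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  dt <- abs(as.numeric(a$timestamp[cand$i]) - as.numeric(b$timestamp[cand$j]))
  ok <- dt <= th$chamber_tolerance
  if (light) {
    pw_a <- a$par[cand$i] / th$par_to_w
    pw_b <- b$par[cand$j] / th$par_to_w
    dpar <- .rel_dpar(a$par[cand$i], b$par[cand$j])
    ok <- ok & pw_a >= th$par_threshold & pw_b >= th$par_threshold &
      dpar <= th$d_par &
      abs(a$t_air[cand$i] - b$t_air[cand$j]) <= th$d_t_air
    metric <- dpar
  } else {
    ok <- ok & abs(a$t_soil[cand$i] - b$t_soil[cand$j]) <= th$d_t_soil
    metric <- dt
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand$metric <- metric[ok]
  cand <- cand[order(cand$metric), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_a[cand$i[r]] && !used_b[cand$j[r]]) {
      keep[r] <- TRUE
      used_a[cand$i[r]] <- TRUE
      used_b[cand$j[r]] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

# Representative summary of a member set: area-weighted value plus mean
# time / PAR / temperature context.
.composite_row <- function(members, site_id, flux_type) {
  data.frame(
    site_id = site_id, flux_type = flux_type,
    timestamp = as.POSIXct(mean(as.numeric(members$timestamp)), tz = "UTC",
                           origin = "1970-01-01"),
    par = if (all(is.na(members$par))) NA_real_ else
      mean(members$par, na.rm = TRUE),
    t_air = mean(members$t_air), t_soil = mean(members$t_soil),
    value = sum(members$weight * members$flux),
    n_members = nrow(members),
    has_branch = any(members$microform == "branch"))
}

#' Assemble chamber observations into ecosystem-scale composite fluxes
#'
#' Hummock-hollow observation pairs are formed within the chamber time
#' tolerance and the relevant difference thresholds (PAR floor, relative
#' PAR and air temperature for NEE/GPP; soil temperature for Reco), choosing
#' per pair the candidate with the smallest relative PAR difference (light
#' fluxes) or smallest time difference (Reco). At a site with near-tree (T)
#' and distant (nT) variants, the T-pair and nT-pair are combined by the same
#' criteria. Each flux is weighted by its microform's areal share; in the
#' vegetation period (May-October) the branch flux, weighted by the current
#' LAI, is added. Every observation is used in at most one group per flux
#' type (greedy one-to-one matching ordered by match quality).
#'
#' @param obs flux observations (NEE, Reco and derived GPP in one table,
#'   QC-passed rows are used).
#' @param scenario a [site_scenario()] supplying areal shares and the LAI
#'   series.
#' @param thresholds a [pairing_thresholds()].
#' @param veg_period integer months in which branch fluxes are included.
#' @param strict if `TRUE` (default), a vegetation-period group without an
#'   eligible branch observation is dropped; if `FALSE` it is kept without
#'   the branch member.
#' @return `data.frame` of composites (`group_id`, `site_id`, `flux_type`,
#'   `timestamp`, `par`, `t_air`, `t_soil`, `value`, `n_members`,
#'   `has_branch`) with a `members` attribute (`group_id`, `microform`,
#'   `obs_id`, `weight`, `flux`).
#' @export
build_groups <- function(obs, scenario, thresholds = pairing_thresholds(),
                         veg_period = 5:10, strict = TRUE) {
  th <- thresholds
  obs <- obs[obs$qc_pass, , drop = FALSE]
  shares <- ground_shares(scenario)
  tree_site <- any(grepl("^n?T_", names(shares)))
  groups <- list(); members <- list(); gid <- 0L
  for (ft in intersect(c("NEE", "Reco", "GPP"), unique(obs$flux_type))) {
    o <- obs[obs$flux_type == ft, , drop = FALSE]
    light <- ft %in% c("NEE", "GPP")
    pair_sets <- if (tree_site)
      list(c("T_hummock", "T_hollow"), c("nT_hummock", "nT_hollow"))
    else list(c("hummock", "hollow"))
    pair_members <- list()
    for (ps in pair_sets) {
      a <- o[o$microform == ps[1], , drop = FALSE]
      b <- o[o$microform == ps[2], , drop = FALSE]
      pr <- .pair_pools(a, b, ft, th)
      if (is.null(pr)) next
      for (r in seq_len(nrow(pr))) {
        m <- rbind(a[pr$i[r], ], b[pr$j[r], ])
        m$weight <- shares[m$microform]
        pair_members[[length(pair_members) + 1L]] <-
          list(set = paste(ps, collapse = "+"), members = m)
      }
    }
    if (tree_site) {
      # combine one T-pair with one nT-pair by the same criteria
      t_pairs <- Filter(function(p) grepl("^T_", p$set), pair_members)
      nt_pairs <- Filter(function(p) grepl("^nT_", p$set), pair_members)
      rep_df <- function(lst) do.call(rbind, lapply(lst, function(p)
        .composite_row(p$members, scenario$site_id, ft)))
      if (length(t_pairs) == 0 || length(nt_pairs) == 0) next
      ra <- rep_df(t_pairs); rb <- rep_df(nt_pairs)
      pr <- .pair_pools(ra, rb, ft, th)
      if (is.null(pr)) next
      combos <- lapply(seq_len(nrow(pr)), function(r)
        rbind(t_pairs[[pr$i[r]]]$members, nt_pairs[[pr$j[r]]]$members))
    } else {
      combos <- lapply(pair_members, `[[`, "members")
    }
    # branch augmentation in the vegetation period
    br <- o[o$microform == "branch", , drop = FALSE]
    used_br <- logical(nrow(br))
    for (m in combos) {
      rep_row <- .composite_row(m, scenario$site_id, ft)
      mon <- as.POSIXlt(rep_row$timestamp, tz = "UTC")$mon + 1
      if (!is.null(scenario$tree_lai) && mon %in% veg_period) {
        cand <- which(!used_br)
        if (length(cand)) {
          dt <- abs(as.numeric(br$timestamp[cand]) -
                      as.numeric(rep_row$timestamp))
          ok <- dt <= th$chamber_tolerance
          if (light) {
            dpar <- .rel_dpar(br$par[cand], rep_row$par)
            ok <- ok & dpar <= th$d_par &
              br$par[cand] / th$par_to_w >= th$par_threshold
            metric <- dpar
          } else metric <- dt
          cand <- cand[ok]; metric <- metric[ok]
        }
        if (length(cand)) {
          j <- cand[which.min(metric)]
          used_br[j] <- TRUE
          bm <- br[j, ]
          bm$weight <- lai_at(scenario,
                              as.Date(rep_row$timestamp, tz = "UTC"))
          m <- rbind(m, bm)
        } else if (strict) next
      }
      gid <- gid + 1L
      g <- .composite_row(m, scenario$site_id, ft)
      g$group_id <- sprintf("%s_%s_%03d", scenario$site_id, ft, gid)
      groups[[length(groups) + 1L]] <- g
      members[[length(members) + 1L]] <- data.frame(
        group_id = g$group_id, microform = m$microform, obs_id = m$obs_id,
        weight = m$weight, flux = m$flux, timestamp = m$timestamp,
        par = m$par, t_air = m$t_air, t_soil = m$t_soil)
    }
  }
  if (length(groups) == 0) {
    res <- data.frame()
    attr(res, "members") <- data.frame()
    return(res)
  }
  res <- do.call(rbind, groups)
  res <- res[c("group_id", setdiff(names(res), "group_id"))]
  rownames(res) <- NULL
  attr(res, "members") <- do.call(rbind, members)
  res
}

#' Match chamber composites with eddy-covariance half-hours
#'
#' Each composite is matched to the EC record (quality flag 0, measured, not
#' gap-filled) minimising the relative PAR difference (NEE/GPP) or the time
#' difference (Reco) among records within +-4 days, the same time of day
#' +-2 h, relative PAR difference <= 20% and EC PAR above the 150 W m-2 floor
#' for light fluxes. Unmatched composites are dropped with a reported count.
#'
#' @param groups composites from [build_groups()].
#' @param ec EC records from [generate_ec()] with an additional `par` column
#'   (umol m-2 s-1, e.g. joined from the driver series).
#' @param thresholds a [pairing_thresholds()].
#' @return `data.frame`, one row per matched pair: the composite columns plus
#'   `ec_timestamp`, `ec_value` (same flux kind, g CO2-C m-2 30 min-1) and
#'   `ec_par`.
#' @export
match_ec <- function(groups, ec, thresholds = pairing_thresholds()) {
  th <- thresholds
  if (!"par" %in% names(ec)) stop("EC records must carry PAR context")
  ec <- ec[!is.na(ec$qc_flag) & ec$qc_flag == 0 & !ec$gapfilled, , drop = FALSE]
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    light <- g$flux_type %in% c("NEE", "GPP")
    dt <- as.numeric(ec$timestamp) - as.numeric(g$timestamp)
    tod <- (dt %% 86400); tod <- pmin(tod, 86400 - tod)
    ok <- abs(dt) <= th$ec_tolerance & tod <= th$ec_daytime_tolerance
    if (light) {
      dpar <- .rel_dpar(ec$par, g$par)
      ok <- ok & dpar <= th$d_par & ec$par / th$par_to_w >= th$par_threshold
      metric <- dpar
    } else metric <- abs(dt)
    if (!any(ok)) next
    j <- which(ok)[which.min(metric[ok])]
    g$ec_timestamp <- ec$timestamp[j]
    g$ec_value <- switch(g$flux_type, NEE = ec$nee[j], GPP = ec$gpp[j],
                         Reco = ec$reco[j])
    g$ec_par <- ec$par[j]
    out[[i]] <- g
  }
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    message("match_ec: ", dropped, " composite(s) unmatched and dropped")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rainbow test for linearity of a simple regression
#'
#' Compares the residual sum of squares of the full fit with the fit on the
#' central subsample (fraction `fraction`, centred on the median of
#' `order_by`). Under linearity the statistic is F-distributed with
#' `(n - m, m - k)` degrees of freedom.
#'
#' @param x regressor values.
#' @param y response values.
#' @param fraction subsample fraction (default 0.5).
#' @param order_by ordering variable (default `abs(x)`, the flux magnitude).
#' @return list with `statistic`, `p_value`, `df1`, `df2`.
#' @export
rainbow_test <- function(x, y, fraction = 0.5, order_by = abs(x)) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 6)
  m <- ceiling(fraction * n)
  ord <- order(order_by)
  from <- floor((n - m) / 2) + 1L
  mid <- ord[from:(from + m - 1L)]
  rss_full <- sum(stats::resid(stats::lm(y ~ x))^2)
  rss_sub <- sum(stats::resid(stats::lm(y[mid] ~ x[mid]))^2)
  k <- 2L
  stat <- ((rss_full - rss_sub) / (n - m)) / (rss_sub / (m - k))
  list(statistic = stat,
       p_value = stats::pf(stat, n - m, m - k, lower.tail = FALSE),
       df1 = n - m, df2 = m - k)
}

#' Regress chamber composites against matched EC fluxes
#'
#' Ordinary least squares of the composite chamber flux on the EC flux per
#' flux kind, with flux-range and offset summaries and a rainbow linearity
#' check (central 50% subsample ordered by EC flux magnitude).
#'
#' @param pairs matched pairs from [match_ec()].
#' @return `data.frame`, one row per site and flux kind: `slope`,
#'   `intercept`, `r_squared`, `n`, flux ranges of both methods, the mean
#'   offset (chamber - EC) and the rainbow `p_value`.
#' @export
compare_methods <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs to compare")
  out <- list()
  for (site in unique(pairs$site_id)) {
    for (ft in unique(pairs$flux_type[pairs$site_id == site])) {
      p <- pairs[pairs$site_id == site & pairs$flux_type == ft, ]
      if (nrow(p) < 3) stop("need at least 3 pairs for ", site, "/", ft)
      fit <- stats::lm(value ~ ec_value, data = p)
      rt <- if (nrow(p) >= 6)
        rainbow_test(p$ec_value, p$value)$p_value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        site_id = site, flux_type = ft,
        slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
        r_squared = summary(fit)$r.squared, n = nrow(p),
        chamber_min = min(p$value), chamber_max = max(p$value),
        ec_min = min(p$ec_value), ec_max = max(p$ec_value),
        offset = mean(p$value - p$ec_value),
        rainbow_p = rt)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
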