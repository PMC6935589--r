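# Assisted gene flow planning: donor-recipient matching by predicted
# environmental optimum within the regression confidence band, geographic
# tie-breaking by great-circle distance.

#' Great-circle distance in kilometres
#'
#' Haversine formula on a spherical Earth of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return Distance in km (vectorized).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stopf("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Populations eligible as donors for a target environment
#'
#' A population is eligible iff its genotype-predicted environment lies
#' within `z` residual standard deviations of the target value — the
#' confidence band of the BLUP regression.
#'
#' @param fit a `blup_fit`.
#' @param target_env target environmental value (standardized units).
#' @param z band half-width in residual SDs (1.96 = 95% band).
#' @return Character vector of eligible population ids.
#' @export
eligible_donors <- function(fit, target_env, z = 1.96) {
  stopifnot(inherits(fit, "blup_fit"))
  if (z < 0) stopf("z must be >= 0")
  fit$pops[abs(fit$fitted - target_env) <= z * fit$residual_sd]
}

#' Plan assisted gene flow for every population and variable
#'
#' For each recipient population and fitted variable, the target is the
#' recipient's (current or scenario) environmental value. If the recipient's
#' own predicted optimum lies within the band, no transfer is needed.
#' Otherwise the geographically closest eligible donor is selected (ties
#' broken by lexicographic population id); if none is eligible the status is
#' `no_donor_available`.
#'
#' @param fits named list of `blup_fit` objects.
#' @param env a `std_env`.
#' @param pop_table data.frame with pop_id, latitude, longitude.
#' @param scenario `"current"` or a scenario name from `env`.
#' @param z band half-width in residual SDs.
#' @return data.frame of class `agf_plan`: recipient, variable, scenario,
#'   status, donor, distance_km, target_env, donor_pred_env,
#'   predicted_residual.
#' @export
plan_agf <- function(fits, env, pop_table, scenario = "current", z = 1.96) {
  if (!length(fits)) stopf("no fitted variables supplied")
  validate_pop_table(pop_table)
  M <- env_matrix(env, scenario)
  rows <- list()
  for (fit in fits) {
    v <- fit$variable
    if (!v %in% colnames(M)) stopf("scenario lacks variable '%s'", v)
    pops <- fit$pops
    if (!all(pops %in% pop_table$pop_id))
      stopf("pop_table lacks coordinates for: %s",
            paste(setdiff(pops, pop_table$pop_id), collapse = ", "))
    coo <- pop_table[match(pops, pop_table$pop_id), ]
    for (p in pops) {
      target <- M[p, v]
      elig <- eligible_donors(fit, target, z)
      if (p %in% elig) {
        rows[[length(rows) + 1]] <- data.frame(
          recipient = p, variable = v, scenario = scenario,
          status = "none_needed", donor = NA_character_,
          distance_km = NA_real_, target_env = target,
          donor_pred_env = fit$fitted[p],
          predicted_residual = abs(fit$fitted[p] - target),
          stringsAsFactors = FALSE)
        next
      }
      donors <- setdiff(elig, p)
      if (!length(donors)) {
        rows[[length(rows) + 1]] <- data.frame(
          recipient = p, variable = v, scenario = scenario,
          status = "no_donor_available", donor = NA_character_,
          distance_km = NA_real_, target_env = target,
          donor_pred_env = NA_real_, predicted_residual = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      ip <- match(p, pops)
      dist <- haversine_km(coo$latitude[ip], coo$longitude[ip],
                           coo$latitude[match(donors, pops)],
                           coo$longitude[match(donors, pops)])
      ord <- order(dist, donors)   # distance, then lexicographic id
      best <- donors[ord[1]]
      rows[[length(rows) + 1]] <- data.frame(
        recipient = p, variable = v, scenario = scenario,
        status = "donor", donor = best, distance_km = dist[ord[1]],
        target_env = target, donor_pred_env = fit$fitted[best],
        predicted_residual = abs(fit$fitted[best] - target),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agf_plan", "data.frame")
  out
}

#' Write an AGF plan as GeoJSON arrows
#'
#' Each planned transfer becomes a LineString feature from donor to
#' recipient, for mapping.
#'
#' @param plan an `agf_plan`.
#' @param pop_table data.frame with pop_id, latitude, longitude.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agf_geojson <- function(plan, pop_table, path) {
  tr <- plan[plan$status == "donor", , drop = FALSE]
  feats <- lapply(seq_len(nrow(tr)), function(i) {
    d <- pop_table[match(tr$donor[i], pop_table$pop_id), ]
    r <- pop_table[match(tr$recipient[i], pop_table$pop_id), ]
    list(type = "Feature",
         properties = list(donor = tr$donor[i], recipient = tr$recipient[i],
                           variable = tr$variable[i],
                           scenario = tr$scenario[i],
                           distance_km = tr$distance_km[i]),
         geometry = list(type = "LineString",
                         coordinates = list(c(d$longitude, d$latitude),
                                            c(r$longitude, r$latitude))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
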