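#' @title Zonal and protected-area reporting
#' @description Summaries of the classified connectivity network against
#'   reporting zones, a protected-area mask and a landcover raster:
#'   proportional zone ranking, inside/outside-protection split, and a
#'   landcover-by-protection cross-tabulation, all in hectares from cell
#'   counts.
#' @name zonal
NULL

cell_area_ha <- function(raster) raster$cell_size^2 / 1e4

#' Rank zones by proportional network coverage
#'
#' Per zone: total area, network area (permanent + stepping cells), the
#' proportion covered, and a competition rank (rank 1 = highest proportion;
#' tied proportions share the smallest applicable rank and the next rank is
#' skipped, so tied blocks leave gaps).
#'
#' @param network classified `cs_raster` from [classify_network()].
#' @param zones aligned `cs_raster` of integer zone codes covering the
#'   extent.
#' @return data.frame `zone_id, zone_area_ha, network_area_ha, proportion,
#'   rank`, ordered by rank then zone id.
#' @export
rank_zones <- function(network, zones) {
  stop_if_geometry_differs(network, zones, "network and zone rasters")
  ha <- cell_area_ha(zones)
  z <- as.vector(zones$values)
  net <- as.vector(network_mask(network))
  ok <- !is.na(z)
  zone_ids <- sort(unique(z[ok]))
  zone_area <- as.numeric(table(factor(z[ok], levels = zone_ids))) * ha
  net_area <- as.numeric(tapply(net[ok], factor(z[ok], levels = zone_ids),
                                sum)) * ha
  net_area[is.na(net_area)] <- 0
  prop <- ifelse(zone_area > 0, net_area / zone_area, 0)
  out <- data.frame(zone_id = zone_ids, zone_area_ha = zone_area,
                    network_area_ha = net_area, proportion = prop,
                    rank = rank(-prop, ties.method = "min"))
  out[order(out$rank, out$zone_id), ]
}

#' Network overlap with a protected-area mask
#'
#' @param network classified `cs_raster`.
#' @param protected aligned binary `cs_raster` (1 = protected).
#' @return list `inside_ha`, `outside_ha`, `inside_fraction`. An empty
#'   network reports fraction 0 with a warning.
#' @export
protected_overlap <- function(network, protected) {
  stop_if_geometry_differs(network, protected, "network and protected rasters")
  ha <- cell_area_ha(network)
  net <- network_mask(network)
  prot <- !is.na(protected$values) & protected$values == 1
  inside <- sum(net & prot) * ha
  outside <- sum(net & !prot) * ha
  if (inside + outside == 0) {
    warning("empty network: inside fraction undefined, reported as 0")
    frac <- 0
  } else frac <- inside / (inside + outside)
  list(inside_ha = inside, outside_ha = outside, inside_fraction = frac)
}

#' Landcover tally of the network, split by protection
#'
#' Cross-tabulates network cells by landcover class and protected flag,
#' reporting hectares outside and inside the protected mask per class.
#'
#' @param network classified `cs_raster`.
#' @param landcover aligned `cs_raster` of integer class codes.
#' @param protected aligned binary `cs_raster`.
#' @return data.frame `landcover_class, area_outside_ha, area_inside_ha`.
#' @export
landcover_tally <- function(network, landcover, protected) {
  stop_if_geometry_differs(network, landcover, "network and landcover rasters")
  stop_if_geometry_differs(network, protected, "network and protected rasters")
  ha <- cell_area_ha(network)
  net <- network_mask(network)
  lc <- as.vector(landcover$values)
  prot <- !is.na(protected$values) & protected$values == 1
  classes <- sort(unique(lc[!is.na(lc)]))
  inside <- outside <- numeric(length(classes))
  for (k in seq_along(classes)) {
    in_class <- net & !is.na(lc) & lc == classes[k]
    inside[k] <- sum(in_class & prot) * ha
    outside[k] <- sum(in_class & !prot) * ha
  }
  data.frame(landcover_class = classes,
             area_outside_ha = outside, area_inside_ha = inside)
}
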