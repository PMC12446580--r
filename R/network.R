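#' @title Scenario comparison and network classification
#' @description Stack species current maps, express every scenario in
#'   z-units of the current-climate reference, summarise the distributions,
#'   and classify the top-decile permanent / stepping-stone connectivity
#'   network.
#' @name network
NULL

#' Sum species current maps cell-wise
#'
#' @param maps list of aligned `cs_raster` current maps (at least one).
#'   Nodata at a cell in any input propagates to the output.
#' @return `cs_raster` of the stacked (summed) connectivity.
#' @export
stack_species <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  out <- maps[[1]]$values
  for (m in maps[-1]) {
    stop_if_geometry_differs(maps[[1]], m, "species maps")
    out <- out + m$values   # NA propagates
  }
  raster_like(maps[[1]], out)
}

# Population mean and sd (denominator N) over non-nodata cells.
population_moments <- function(v) {
  x <- v[!is.na(v)]
  n <- length(x)
  if (n < 1) stop("surface has no non-nodata cells")
  mu <- mean(x)
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / n), n = n)
}

#' Relative z-score standardisation against the reference scenario
#'
#' `z_i = (value_i - ref_mean) / ref_sd`, where the mean and standard
#' deviation (population denominator N) come from the *reference*
#' (current-climate) surface. Standardising the reference by itself yields
#' mean 0 and sd 1 exactly; future scenarios standardised with the same
#' constants read directly as "so many reference standard deviations above
#' or below the contemporary average".
#'
#' @param surface `cs_raster` to standardise.
#' @param reference either a `cs_raster` (its own mean/sd are used) or a
#'   numeric `c(mean, sd)`.
#' @param scenario label stored with the result.
#' @return object of class `cs_standardised`: fields `z` (`cs_raster`),
#'   `reference_mean`, `reference_sd`, `scenario`.
#' @export
relative_standardise <- function(surface, reference = surface,
                                 scenario = "current") {
  if (inherits(reference, "cs_raster")) {
    mo <- population_moments(reference$values)
    ref_mean <- mo$mean; ref_sd <- mo$sd
  } else {
    ref_mean <- reference[1]; ref_sd <- reference[2]
  }
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop("reference standard deviation must be positive (constant reference?)")
  structure(list(
    z = raster_like(surface, (surface$values - ref_mean) / ref_sd),
    reference_mean = ref_mean, reference_sd = ref_sd, scenario = scenario),
    class = "cs_standardised")
}

#' @export
print.cs_standardised <- function(x, ...) {
  cat(sprintf("<cs_standardised> scenario %s (ref mean %.4g, ref sd %.4g)\n",
              x$scenario, x$reference_mean, x$reference_sd))
  print(x$z)
  invisible(x)
}

as_z_raster <- function(z) {
  if (inherits(z, "cs_standardised")) z$z
  else if (inherits(z, "cs_raster")) z
  else stop("expected a cs_standardised or cs_raster")
}

#' Moment summary of a connectivity surface
#'
#' Min, max, range, mean, standard deviation, variance, skewness and excess
#' kurtosis over non-nodata cells, all with population (N) denominators:
#' skewness `m3 / m2^1.5`, kurtosis `m4 / m2^2 - 3`.
#'
#' @param z `cs_standardised` or `cs_raster` (>= 2 non-nodata cells).
#' @return one-row data.frame of the eight statistics.
#' @export
summary_stats <- function(z) {
  v <- as_z_raster(z)$values
  x <- v[!is.na(v)]
  if (length(x) < 2) stop("need at least two non-nodata cells")
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  data.frame(min = min(x), max = max(x), range = max(x) - min(x),
             mean = mu, sd = sqrt(m2), variance = m2,
             skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Scenario summary table
#'
#' Statistics as rows, scenarios as columns (the layout of the published
#' per-scenario histogram summaries).
#'
#' @param surfaces named list of `cs_standardised`/`cs_raster` objects.
#' @return data.frame with a `statistic` column plus one column per scenario.
#' @export
scenario_stats_table <- function(surfaces) {
  stats_list <- lapply(surfaces, summary_stats)
  out <- data.frame(statistic = c("min", "max", "range", "mean", "sd",
                                  "variance", "skewness", "kurtosis"))
  for (nm in names(surfaces)) out[[nm]] <- as.numeric(stats_list[[nm]][1, ])
  out
}

#' Pearson correlation between two surfaces
#'
#' Computed over cells that are non-nodata in both rasters.
#'
#' @param a,b aligned `cs_raster` (or `cs_standardised`) objects.
#' @return Pearson r.
#' @export
surface_correlation <- function(a, b) {
  a <- as_z_raster(a); b <- as_z_raster(b)
  stop_if_geometry_differs(a, b)
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 2) stop("need at least two jointly non-nodata cells")
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("surface_correlation: constant input")
  stats::cor(x, y)
}

#' Top-decile connectivity mask
#'
#' Marks the `ceil(decile_fraction * N)` highest-valued non-nodata cells of
#' the surface, ties broken by row-major cell order. Selecting a fixed
#' fraction of each scenario's own surface guarantees every scenario
#' contributes the same amount of space to the network comparison.
#'
#' @param z `cs_standardised` or `cs_raster` with at least 10 non-nodata
#'   cells.
#' @param decile_fraction selected fraction (default 0.1 = top decile).
#' @return binary `cs_raster` (1 = selected).
#' @export
top_decile_mask <- function(z, decile_fraction = 0.1) {
  r <- as_z_raster(z)
  v <- as.vector(t(r$values))          # row-major
  ok <- which(!is.na(v))
  if (length(ok) < 10) stop("need at least 10 non-nodata cells")
  k <- ceiling(decile_fraction * length(ok))
  sel <- ok[order(-v[ok], ok)][seq_len(k)]
  out <- rep(NA_real_, length(v))
  out[ok] <- 0
  out[sel] <- 1
  raster_like(r, matrix(out, nrow(r$values), ncol(r$values), byrow = TRUE))
}

#' Network class codes
#'
#' Integer codes of the per-cell network classification and their labels.
#' @export
network_classes <- c(none = 0, permanent = 1, stepping_c50 = 2,
                     stepping_5090 = 3, impermanent = 4)

#' Classify the permanent / stepping-stone connectivity network
#'
#' Per-cell truth table over the three scenario top-decile masks
#' (current, 2050, 2090):
#' present in all three = `permanent`; current + 2050 only = `stepping_c50`;
#' 2050 + 2090 only = `stepping_5090`; any single scenario, or
#' current + 2090 without 2050, = `impermanent` (a cell cannot bridge a
#' period it is absent from); absent everywhere = `none`. The landscape
#' connectivity network is the union of the permanent and stepping classes.
#'
#' @param mask_current,mask_2050,mask_2090 aligned binary `cs_raster` masks.
#' @return `cs_raster` of integer codes ([network_classes]), with the legend
#'   attached as attribute `legend`.
#' @export
classify_network <- function(mask_current, mask_2050, mask_2090) {
  stop_if_geometry_differs(mask_current, mask_2050, "decile masks")
  stop_if_geometry_differs(mask_current, mask_2090, "decile masks")
  a <- mask_current$values == 1
  b <- mask_2050$values == 1
  d <- mask_2090$values == 1
  out <- matrix(network_classes[["none"]], nrow(a), ncol(a))
  out[a & b & d] <- network_classes[["permanent"]]
  out[a & b & !d] <- network_classes[["stepping_c50"]]
  out[!a & b & d] <- network_classes[["stepping_5090"]]
  out[(a & !b & !d) | (!a & b & !d) | (!a & !b & d) |
        (a & !b & d)] <- network_classes[["impermanent"]]
  out[is.na(a) | is.na(b) | is.na(d)] <- NA
  res <- raster_like(mask_current, out)
  attr(res, "legend") <- network_classes
  res
}

#' Cells belonging to the connectivity network
#'
#' @param network classified `cs_raster` from [classify_network()].
#' @return logical matrix: permanent or stepping-stone cells.
#' @export
network_mask <- function(network) {
  v <- network$values
  !is.na(v) & v %in% network_classes[c("permanent", "stepping_c50",
                                       "stepping_5090")]
}

#' Write the network legend as a JSON sidecar
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_legend <- function(path) {
  jsonlite::write_json(as.list(network_classes), path, auto_unbox = TRUE)
  invisible(path)
}
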