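#' @title Predictor derivation
#' @description Turn raw landscape layers into model-ready predictors:
#'   eight-direction distance to feature, topographic position index,
#'   resolution aggregation, and a greedy collinearity screen.
#' @name predictors
NULL

#' Eight-direction grid distance to the nearest feature
#'
#' Shortest-path distance on the 8-neighbour lattice, with orthogonal steps
#' costing one cell size and diagonal steps `sqrt(2)` cell sizes. This is the
#' chamfer metric (not straight-line Euclidean distance), matching
#' eight-direction grid-distance tools. Computed by repeated forward/backward
#' chamfer sweeps until convergence, which equals the Dijkstra shortest-path
#' distance on the lattice. `NA` cells are carried through as `NA`.
#'
#' @param feature_raster binary `cs_raster`; cells with value 1 are features.
#' @return `cs_raster` of distances in metres (0 on feature cells).
#' @export
grid_distance <- function(feature_raster) {
  v <- feature_raster$values
  cs <- feature_raster$cell_size
  feat <- !is.na(v) & v == 1
  if (!any(feat)) stop("grid_distance: no feature cells, distance undefined")
  nr <- nrow(v); nc <- ncol(v)
  d <- matrix(Inf, nr, nc)
  d[feat] <- 0
  orth <- cs; diag <- sqrt(2) * cs
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {       # forward sweep
      best <- d[r, cc]
      if (r > 1)            best <- min(best, d[r - 1, cc] + orth)
      if (cc > 1)           best <- min(best, d[r, cc - 1] + orth)
      if (r > 1 && cc > 1)  best <- min(best, d[r - 1, cc - 1] + diag)
      if (r > 1 && cc < nc) best <- min(best, d[r - 1, cc + 1] + diag)
      if (best < d[r, cc]) { d[r, cc] <- best; changed <- TRUE }
    }
    for (r in rev(seq_len(nr))) for (cc in rev(seq_len(nc))) {  # backward
      best <- d[r, cc]
      if (r < nr)            best <- min(best, d[r + 1, cc] + orth)
      if (cc < nc)           best <- min(best, d[r, cc + 1] + orth)
      if (r < nr && cc < nc) best <- min(best, d[r + 1, cc + 1] + diag)
      if (r < nr && cc > 1)  best <- min(best, d[r + 1, cc - 1] + diag)
      if (best < d[r, cc]) { d[r, cc] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  d[is.na(v)] <- NA
  raster_like(feature_raster, d)
}

# Focal sum over a (2*radius+1)^2 square window truncated at edges, via a
# padded summed-area table; `na_as_zero` values contribute 0, counts likewise.
focal_sum <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1, nc + 1)
  p[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - radius, 1); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1); c2 <- pmin(seq_len(nc) + radius, nc)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    out[i, ] <- p[r2[i] + 1, c2 + 1] - p[r2[i] + 1, c1] -
      p[r1[i], c2 + 1] + p[r1[i], c1]
  }
  out
}

#' Topographic position index
#'
#' Per-cell elevation minus the mean elevation of a square focal window of
#' side `2 * window_radius_cells + 1` centred on the cell, truncated (not
#' wrapped) at grid edges. Positive values are local ridges/peaks, negative
#' values valleys. A 250 m window at 50 m resolution corresponds to
#' `window_radius_cells = 2`.
#'
#' @param dem `cs_raster` of elevations.
#' @param window_radius_cells window radius in cells (>= 1).
#' @return `cs_raster` of TPI values.
#' @export
tpi <- function(dem, window_radius_cells) {
  if (window_radius_cells < 1) stop("window_radius_cells must be >= 1")
  v <- dem$values
  if (2 * window_radius_cells + 1 > max(dim(v)))
    stop("focal window larger than the grid")
  ok <- !is.na(v)
  vz <- v; vz[!ok] <- 0
  s <- focal_sum(vz, window_radius_cells)
  n <- focal_sum(ok + 0, window_radius_cells)
  out <- v - s / n
  out[!ok] <- NA
  raster_like(dem, out)
}

#' Aggregate a raster to a coarser resolution
#'
#' Each output cell summarises a `factor x factor` block of input cells by
#' the block mean (continuous layers) or mode (categorical layers; ties go to
#' the smallest code). Grids not divisible by `factor` are padded with nodata
#' on the south/east edges; nodata is ignored within blocks.
#'
#' @param raster `cs_raster`.
#' @param factor positive integer aggregation factor.
#' @param method `"mean"` or `"mode"`.
#' @return `cs_raster` with `cell_size * factor`.
#' @export
aggregate_raster <- function(raster, factor, method = c("mean", "mode")) {
  method <- match.arg(method)
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1) return(raster)
  v <- raster$values
  nr <- ceiling(nrow(v) / factor) * factor
  nc <- ceiling(ncol(v) / factor) * factor
  pad <- matrix(NA_real_, nr, nc)
  pad[seq_len(nrow(v)), seq_len(ncol(v))] <- v
  onr <- nr %/% factor; onc <- nc %/% factor
  out <- matrix(NA_real_, onr, onc)
  for (i in seq_len(onr)) for (j in seq_len(onc)) {
    block <- pad[((i - 1) * factor + 1):(i * factor),
                 ((j - 1) * factor + 1):(j * factor)]
    block <- block[!is.na(block)]
    if (length(block) == 0) next
    out[i, j] <- if (method == "mean") mean(block) else {
      tab <- table(block)
      as.numeric(names(tab)[which.max(tab)])  # ties: smallest code (table order)
    }
  }
  cs_raster(out, cell_size = raster$cell_size * factor,
            origin = c(raster$origin[1],
                       raster$origin[2] + nrow(v) * raster$cell_size -
                         onr * factor * raster$cell_size),
            nodata = raster$nodata)
}

#' Greedy collinearity filter
#'
#' Layers are scanned in the caller-supplied ecological priority order; a
#' layer is retained iff its absolute Pearson correlation with every
#' already-retained layer is at most `threshold`. Correlations use the
#' listwise-complete cell set (cells where any layer is nodata are dropped).
#' Ties between correlated layers are therefore resolved by the priority
#' list, mirroring expert choice of the more ecologically plausible layer.
#'
#' @param stack `cs_stack`.
#' @param threshold absolute correlation threshold in (0, 1).
#' @param priority character vector covering all layer names, most-preferred
#'   first. Defaults to stack order.
#' @return `cs_stack` of retained layers (priority order), with a
#'   `report` attribute: data.frame `layer, retained, max_abs_r_with_retained`.
#' @export
collinearity_filter <- function(stack, threshold = 0.70, priority = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(priority)) priority <- stack$names
  if (!setequal(priority, stack$names))
    stop("priority must cover exactly the stack's layer names")
  if (length(stack) < 2) return(stack)
  m <- stack_matrix(stack)
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  retained <- character(0)
  maxr <- stats::setNames(rep(NA_real_, length(priority)), priority)
  for (nm in priority) {
    if (length(retained) == 0) {
      retained <- nm; maxr[nm] <- 0
      next
    }
    r <- abs(stats::cor(m[, nm], m[, retained, drop = FALSE]))
    maxr[nm] <- max(r)
    if (all(r <= threshold)) retained <- c(retained, nm)
  }
  report <- data.frame(layer = priority,
                       retained = priority %in% retained,
                       max_abs_r_with_retained = unname(maxr[priority]))
  out <- stack_subset(stack, retained)
  attr(out, "report") <- report
  out
}

#' Write a collinearity report CSV
#' @param filtered output of [collinearity_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collinearity_report <- function(filtered, path) {
  report <- attr(filtered, "report")
  if (is.null(report)) stop("no collinearity report attached")
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
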