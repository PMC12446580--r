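#' @title Synthetic landscape generators
#' @description Generators for climate fields, landcover, linear features,
#'   occurrences, zones and protected masks with the statistical structure the
#'   connectivity analysis assumes (spatial autocorrelation, clumped classes,
#'   suitability-driven sampling), so every downstream stage can be exercised
#'   without external geodata.
#' @name synthetic_data
NULL

# Separable Gaussian smoothing of a matrix, edges renormalised (truncated,
# not wrapped). Implemented as banded row/column smoother matrices so the
# result is exact for the truncated kernel.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- stats::dnorm(-half:half, sd = sigma)
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      s[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    s
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Smoothed seeded white noise plus a linear north-south gradient, scaled to
# unit variance before the gradient is added. Assumes an active RNG stream.
random_field <- function(n_rows, n_cols, sigma = 3, gradient = 1) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smooth_matrix(w, sigma)
  f <- (f - mean(f)) / stats::sd(as.vector(f))
  if (gradient != 0) {
    lat <- (n_rows - seq_len(n_rows)) / max(1, n_rows - 1)  # 0 south, 1 north
    f <- f + gradient * matrix(lat, n_rows, n_cols)
  }
  f
}

#' Generate a stack of smooth climate-like layers
#'
#' Each layer is low-frequency seeded noise plus a latitudinal gradient,
#' mimicking bioclimatic surfaces. `scenario_shift` is an additive per-layer
#' offset emulating warming between climate scenarios: the 2050/2090
#' projections of a scenario family are the current-climate fields plus a
#' deterministic shift, so current and future stacks stay cell-wise paired.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_layers number of layers (at least 2).
#' @param scenario_shift single number or length-`n_layers` vector of additive
#'   offsets (same units as the layer).
#' @param seed integer RNG seed.
#' @param cell_size cell edge length in metres.
#' @param smoothing Gaussian smoothing radius (cells) controlling spatial
#'   autocorrelation.
#' @return `cs_stack` with layers named `clim1..climK`.
#' @export
gen_climate_stack <- function(n_rows, n_cols, n_layers, scenario_shift = 0,
                              seed = 1, cell_size = 1000, smoothing = 3) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  if (n_layers < 2) stop("n_layers must be at least 2")
  shift <- rep_len(scenario_shift, n_layers)
  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(k) {
      f <- random_field(n_rows, n_cols, sigma = smoothing, gradient = 1) + shift[k]
      cs_raster(f, cell_size = cell_size)
    })
  })
  raster_stack(layers, names = paste0("clim", seq_len(n_layers)))
}

#' Generate a clumped categorical landcover raster
#'
#' A smooth random field is cut at its quantiles into `n_classes` integer
#' codes `1..n_classes`, giving spatially clumped classes that are all
#' present and of roughly equal area.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_classes number of classes, between 2 and 15.
#' @param seed integer RNG seed.
#' @param cell_size cell edge length in metres.
#' @return `cs_raster` of integer codes.
#' @export
gen_landcover <- function(n_rows, n_cols, n_classes, seed = 1, cell_size = 1000) {
  if (n_classes < 2 || n_classes > 15)
    stop("n_classes must be between 2 and 15")
  with_seed(seed, {
    f <- random_field(n_rows, n_cols, sigma = 4, gradient = 0.5)
    q <- stats::quantile(f, probs = seq(0, 1, length.out = n_classes + 1))
    codes <- matrix(as.numeric(cut(f, breaks = q, include.lowest = TRUE,
                                   labels = FALSE)),
                    n_rows, n_cols)
    cs_raster(codes, cell_size = cell_size)
  })
}

#' Generate rasterised linear features (rivers/roads)
#'
#' Each feature is a rasterised random-walk polyline spanning the grid from
#' one boundary edge to the opposite one, so its cells form a single
#' 8-connected component.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_lines number of polylines (0 allowed).
#' @param seed integer RNG seed.
#' @param cell_size cell edge length in metres.
#' @return binary `cs_raster` (1 = feature).
#' @export
gen_linear_features <- function(n_rows, n_cols, n_lines, seed = 1,
                                cell_size = 1000) {
  if (n_lines < 0) stop("n_lines must be non-negative")
  m <- matrix(0, n_rows, n_cols)
  if (n_lines > 0) {
    m <- with_seed(seed, {
      for (i in seq_len(n_lines)) {
        horizontal <- stats::runif(1) < 0.5
        if (horizontal) {
          r <- sample.int(n_rows, 1)
          for (cc in seq_len(n_cols)) {
            m[r, cc] <- 1
            r <- min(n_rows, max(1, r + sample(c(-1L, 0L, 1L), 1)))
          }
        } else {
          cc <- sample.int(n_cols, 1)
          for (r in seq_len(n_rows)) {
            m[r, cc] <- 1
            cc <- min(n_cols, max(1, cc + sample(c(-1L, 0L, 1L), 1)))
          }
        }
      }
      m
    })
  }
  cs_raster(m, cell_size = cell_size)
}

#' Ground-truth occurrence model
#'
#' Logistic-link linear model over predictor layers, used to generate
#' occurrences with a known suitability function so fitted models can be
#' checked for parameter recovery.
#'
#' @param coefficients named numeric vector: `(Intercept)` then one
#'   coefficient per predictor layer name.
#' @return object of class `cs_true_model`.
#' @export
true_model <- function(coefficients) {
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  if (is.null(names(coefficients)) || names(coefficients)[1] != "(Intercept)")
    stop("coefficients must be named, starting with (Intercept)")
  structure(list(coefficients = coefficients, link = "logistic"),
            class = "cs_true_model")
}

# Per-cell suitability implied by a true model over a stack (row-major order).
true_suitability <- function(model, stack) {
  beta <- model$coefficients
  lay <- setdiff(names(beta), "(Intercept)")
  x <- stack_matrix(stack_subset(stack, lay))
  stats::plogis(beta["(Intercept)"] + drop(x %*% beta[lay]))
}

#' Sample presence records from a known suitability function
#'
#' Presence cells are drawn without replacement with probability proportional
#' to `plogis(model . predictors)`; one record per cell, placed at the cell
#' centre.
#'
#' @param model a [true_model()].
#' @param predictor_stack `cs_stack` containing every layer the model names.
#' @param n_presence number of presence records.
#' @param seed integer RNG seed.
#' @return occurrence data.frame with columns `x`, `y`, `presence` (all 1)
#'   and `fold` (`NA`).
#' @export
gen_occurrences <- function(model, predictor_stack, n_presence, seed = 1) {
  stopifnot(inherits(model, "cs_true_model"))
  template <- predictor_stack$layers[[1]]
  ncell <- length(template$values)
  if (n_presence < 1) stop("n_presence must be at least 1")
  if (n_presence > ncell) stop("n_presence exceeds the number of grid cells")
  p <- true_suitability(model, predictor_stack)
  idx <- with_seed(seed, sample.int(ncell, n_presence, prob = p))
  cc <- cell_centres(template)[sort(idx), ]
  data.frame(x = cc$x, y = cc$y, presence = 1, fold = NA_integer_)
}

#' Generate a Voronoi zone partition
#'
#' Every cell is assigned to the nearest of `n_zones` random seed cells
#' (Euclidean distance between cell centres, ties to the lowest zone id),
#' emulating a contiguous reporting-region framework.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_zones number of zones (at most the cell count).
#' @param seed integer RNG seed.
#' @param cell_size cell edge length in metres.
#' @return `cs_raster` of zone codes `1..n_zones`.
#' @export
gen_zones <- function(n_rows, n_cols, n_zones, seed = 1, cell_size = 1000) {
  ncell <- n_rows * n_cols
  if (n_zones < 1) stop("n_zones must be at least 1")
  if (n_zones > ncell) stop("n_zones exceeds the number of grid cells")
  with_seed(seed, {
    sites <- sample.int(ncell, n_zones)
    sr <- (sites - 1) %/% n_cols + 1   # row-major index -> row/col
    sc <- (sites - 1) %% n_cols + 1
    rows <- rep(seq_len(n_rows), each = n_cols)
    cols <- rep(seq_len(n_cols), times = n_rows)
    d2 <- outer(rows, sr, function(a, b) (a - b)^2) +
      outer(cols, sc, function(a, b) (a - b)^2)
    zone <- max.col(-d2, ties.method = "first")
    cs_raster(matrix(zone, n_rows, n_cols, byrow = TRUE),
              cell_size = cell_size)
  })
}

#' Generate a blob-shaped protected-area mask
#'
#' A smooth random field thresholded at its own quantile, producing compact
#' patches covering the requested fraction of the grid (exact to the nearest
#' cell, well within the advertised two percentage points).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param coverage_fraction target covered fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param cell_size cell edge length in metres.
#' @return binary `cs_raster` (1 = protected).
#' @export
gen_protected_mask <- function(n_rows, n_cols, coverage_fraction, seed = 1,
                               cell_size = 1000) {
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in [0, 1]")
  m <- with_seed(seed, {
    f <- random_field(n_rows, n_cols, sigma = 4, gradient = 0)
    k <- round(coverage_fraction * length(f))
    out <- matrix(0, n_rows, n_cols)
    if (k > 0) out[order(f, decreasing = TRUE)[seq_len(k)]] <- 1
    out
  })
  cs_raster(m, cell_size = cell_size)
}

#' Straight low-resistance corridor fixture
#'
#' Uniform background resistance with one horizontal band of
#' `corridor_width` rows at `corridor_resistance`, centred vertically and
#' spanning the full grid width. Used to check that the circuit solver
#' concentrates current in planted corridors.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param corridor_width band width in cells (less than `min(n_rows, n_cols)`).
#' @param background_resistance,corridor_resistance resistances with
#'   `corridor_resistance <= background_resistance`.
#' @param cell_size cell edge length in metres.
#' @return `cs_raster` resistance surface.
#' @export
gen_corridor_fixture <- function(n_rows, n_cols, corridor_width,
                                 background_resistance, corridor_resistance,
                                 cell_size = 1000) {
  if (corridor_width >= min(n_rows, n_cols))
    stop("corridor_width must be smaller than the grid")
  if (corridor_resistance > background_resistance)
    stop("corridor_resistance must not exceed background_resistance")
  m <- matrix(background_resistance, n_rows, n_cols)
  top <- floor((n_rows - corridor_width) / 2) + 1
  m[top:(top + corridor_width - 1), ] <- corridor_resistance
  cs_raster(m, cell_size = cell_size)
}
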