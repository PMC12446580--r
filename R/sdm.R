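#' @title Species distribution modelling
#' @description Record gridding, pseudo-absence sampling, hexagonal spatial
#'   block cross-validation folds, logistic learner fitting, TSS/ROC
#'   evaluation, committee-average and weighted-mean ensembling, scenario
#'   projection, and in-range (MESS-count) extrapolation diagnostics.
#' @name sdm
NULL

#' Thin occurrence records to one per grid cell
#'
#' Duplicates within a cell are collapsed to a single record snapped to the
#' cell centre (a cell with any presence record becomes a presence). Output
#' rows are in row-major cell order, so the result is deterministic
#' regardless of input ordering. Points outside the grid are dropped.
#'
#' @param points occurrence data.frame (`x`, `y`, `presence`).
#' @param grid `cs_raster` defining the cell geometry.
#' @return thinned occurrence data.frame.
#' @export
grid_records <- function(points, grid) {
  rc <- point_to_cell(grid, points$x, points$y)
  inside <- !is.na(rc$row)
  if (!any(inside)) stop("grid_records: all points fall outside the grid")
  nc <- ncol(grid$values)
  cell <- (rc$row[inside] - 1) * nc + rc$col[inside]  # row-major cell index
  pres <- tapply(points$presence[inside], cell, max)
  cells <- sort(as.integer(names(pres)))
  pres <- pres[as.character(cells)]
  row <- (cells - 1) %/% nc + 1
  col <- (cells - 1) %% nc + 1
  nr <- nrow(grid$values)
  data.frame(
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (nr - row + 0.5) * grid$cell_size,
    presence = as.numeric(pres),
    fold = NA_integer_)
}

#' Sample pseudo-absences
#'
#' Draws `ratio` pseudo-absence cells per presence record, uniformly without
#' replacement from grid cells holding no presence, snapped to cell centres.
#' No exclusion buffer beyond the presence cells themselves is applied.
#'
#' @param presences presence occurrence data.frame (gridded).
#' @param grid `cs_raster` defining candidate cells.
#' @param ratio non-negative integer: absences per presence.
#' @param seed integer RNG seed.
#' @return occurrence data.frame of absences (`presence = 0`).
#' @export
sample_pseudo_absences <- function(presences, grid, ratio = 3, seed = 1) {
  if (ratio < 0 || ratio != round(ratio)) stop("ratio must be a non-negative integer")
  n_abs <- as.integer(ratio) * nrow(presences)
  if (n_abs == 0)
    return(data.frame(x = numeric(0), y = numeric(0), presence = numeric(0),
                      fold = integer(0)))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rc <- point_to_cell(grid, presences$x, presences$y)
  pres_cell <- (rc$row - 1) * nc + rc$col
  candidates <- setdiff(seq_len(nr * nc), pres_cell)
  if (length(candidates) < n_abs)
    stop(sprintf("only %d candidate cells for %d pseudo-absences",
                 length(candidates), n_abs))
  idx <- with_seed(seed, sort(sample(candidates, n_abs)))
  row <- (idx - 1) %/% nc + 1
  col <- (idx - 1) %% nc + 1
  data.frame(
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (nr - row + 0.5) * grid$cell_size,
    presence = 0,
    fold = NA_integer_)
}

# Axial hexagon index (pointy-top) for points at a given hex size
# (circumradius); standard cube-rounding.
hex_index <- function(x, y, size) {
  q <- (sqrt(3) / 3 * x - y / 3) / size
  r <- (2 / 3 * y) / size
  cx <- q; cz <- r; cy <- -cx - cz
  rx <- round(cx); ry <- round(cy); rz <- round(cz)
  dx <- abs(rx - cx); dy <- abs(ry - cy); dz <- abs(rz - cz)
  fx <- dx > dy & dx > dz
  fz <- !fx & dz > dy
  rx[fx] <- -ry[fx] - rz[fx]
  rz[fz] <- -rx[fz] - ry[fz]
  paste(rx, rz, sep = ":")
}

#' Assign records to hexagonal spatial blocks and cross-validation folds
#'
#' The extent is tessellated with hexagons whose edge length starts at
#' 1/20 of the square root of the extent area and is rescaled (bisection on
#' the edge length) until approximately `n_blocks` hexagons contain records.
#' Occupied blocks are then shuffled and dealt round-robin into `n_folds`
#' folds, so folds are balanced in blocks and every record inherits its
#' block's fold. Spatially separated folds mitigate the optimistic bias that
#' random record-level folds suffer under spatial autocorrelation.
#'
#' @param records occurrence data.frame.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` or a `cs_raster`.
#' @param n_blocks target number of occupied blocks.
#' @param n_folds number of folds (at most the occupied block count).
#' @param seed integer RNG seed.
#' @return data.frame with one row per record: `block_id`, `fold_id`; the
#'   block-to-fold table is attached as attribute `block_folds`, and the hex
#'   edge length used as attribute `hex_size`.
#' @export
assign_spatial_blocks <- function(records, extent, n_blocks = 40, n_folds = 5,
                                  seed = 1) {
  if (n_folds > n_blocks) stop("n_folds must not exceed n_blocks")
  if (inherits(extent, "cs_raster")) {
    d <- dim(extent$values)
    extent <- c(extent$origin[1], extent$origin[1] + d[2] * extent$cell_size,
                extent$origin[2], extent$origin[2] + d[1] * extent$cell_size)
  }
  area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  a0 <- sqrt(area) / 20
  n_occupied <- function(size)
    length(unique(hex_index(records$x, records$y, size)))
  # occupied-block count decreases as hexes grow; bisection to ~n_blocks,
  # bounded to a modest range around the canonical edge length so degenerate
  # record clusters are reported rather than chased with vanishing hexes
  lo <- a0 / 4; hi <- a0 * 4
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (n_occupied(mid) > n_blocks) lo <- mid else hi <- mid
  }
  size <- if (abs(n_occupied(lo) - n_blocks) < abs(n_occupied(hi) - n_blocks))
    lo else hi
  block_key <- hex_index(records$x, records$y, size)
  blocks <- unique(block_key)
  if (length(blocks) < n_folds)
    stop(sprintf("only %d occupied blocks for %d folds",
                 length(blocks), n_folds))
  fold_of <- with_seed(seed, {
    shuffled <- sample(blocks)
    stats::setNames(rep_len(seq_len(n_folds), length(blocks)),
                    shuffled)
  })
  block_id <- match(block_key, blocks)
  out <- data.frame(block_id = block_id,
                    fold_id = as.integer(fold_of[block_key]))
  attr(out, "block_folds") <- data.frame(
    block_id = match(names(fold_of), blocks),
    fold_id = as.integer(fold_of))
  attr(out, "hex_size") <- size
  out
}

# ---- learners --------------------------------------------------------------

#' Construct a fitted-learner object
#'
#' The pluggable learner contract: any model exposing a `predict` closure
#' mapping a predictor matrix (named columns) to probabilities in `[0, 1]`
#' can join an ensemble.
#'
#' @param kind character identifier.
#' @param predict function(matrix) -> numeric probabilities.
#' @param state opaque fitted state.
#' @return object of class `cs_learner`.
#' @export
new_learner <- function(kind, predict, state = NULL) {
  structure(list(kind = kind, predict = predict, state = state),
            class = "cs_learner")
}

# Design matrix for the logistic learner: linear terms, optional squares.
logistic_design <- function(x, quadratic) {
  out <- x
  if (quadratic) {
    sq <- x^2
    colnames(sq) <- paste0(colnames(x), "_sq")
    out <- cbind(out, sq)
  }
  out
}

# Ridge-penalised IRLS fallback for (quasi-)separated data; intercept
# unpenalised, lambda = 1e-6.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-8) {
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  ll_old <- -Inf
  for (i in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z)))
    ll <- sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(beta[-1]^2)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  stats::setNames(beta, colnames(Xd))
}

#' Fit the native logistic learner
#'
#' Binomial GLM (logit link) on linear and, optionally, squared predictor
#' terms, fitted by iteratively reweighted least squares (convergence on a
#' log-likelihood change below 1e-8, at most 100 iterations). Perfectly
#' separated data, which sends maximum-likelihood coefficients to infinity,
#' is detected and refitted with a tiny ridge penalty (1e-6); the returned
#' learner carries a `separation` flag.
#'
#' @param train occurrence data.frame with both classes present.
#' @param predictors `cs_stack`; predictor values are read at each record's
#'   cell.
#' @param quadratic add squared terms?
#' @return `cs_learner` of kind `"logistic"` with `state` holding
#'   coefficients, layer names and the separation flag.
#' @export
fit_logistic <- function(train, predictors, quadratic = FALSE) {
  y <- train$presence
  if (length(unique(y)) < 2)
    stop("fit_logistic: training data must contain both classes")
  X <- extract_predictors(predictors, train$x, train$y)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2)
    stop("fit_logistic: both classes required after dropping nodata cells")
  Xd <- logistic_design(X, quadratic)
  dat <- data.frame(.y = y, Xd, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- if (separated || !fit$converged) {
    separated <- TRUE
    ridge_logistic(Xd, y)
  } else {
    b <- stats::coef(fit)
    b[is.na(b)] <- 0  # aliased (perfectly collinear) terms drop out
    names(b) <- c("(Intercept)", colnames(Xd))
    b
  }
  layer_names <- stack_names(predictors)
  new_learner(
    kind = "logistic",
    predict = function(xmat) {
      Z <- logistic_design(xmat[, layer_names, drop = FALSE], quadratic)
      stats::plogis(drop(cbind(1, Z) %*% beta[c("(Intercept)", colnames(Z))]))
    },
    state = list(coefficients = beta, layers = layer_names,
                 quadratic = quadratic, separation = separated))
}

stack_names <- function(stack) stack$names

# Predictor values at point locations, one named column per layer.
extract_predictors <- function(stack, px, py) {
  template <- stack$layers[[1]]
  rc <- point_to_cell(template, px, py)
  m <- vapply(stack$layers, function(l) {
    v <- rep(NA_real_, length(px))
    ok <- !is.na(rc$row)
    v[ok] <- l$values[cbind(rc$row[ok], rc$col[ok])]
    v
  }, numeric(length(px)))
  if (length(px) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, stack$names))
  colnames(m) <- stack$names
  m
}

# ---- evaluation ------------------------------------------------------------

#' TSS and ROC evaluation of presence/absence predictions
#'
#' ROC AUC uses the rank (Mann-Whitney) formulation with mid-rank tie
#' correction. TSS is the maximum of sensitivity + specificity - 1 over all
#' observed prediction values used as thresholds (vote rule: predicted
#' presence when probability >= threshold); the maximising threshold is
#' returned for downstream committee binarisation.
#'
#' @param pred numeric probabilities.
#' @param truth 0/1 labels, both classes present.
#' @return list with `tss`, `roc_auc`, `best_threshold`.
#' @export
evaluate <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(unique(truth)) < 2)
    stop("evaluate: truth must contain both classes")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  r <- rank(pred)  # mid-ranks correct for ties
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(pred))
  tss_at <- vapply(thresholds, function(t) {
    vote <- pred >= t
    sens <- sum(vote & truth == 1) / n1
    spec <- sum(!vote & truth == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which.max(tss_at)
  list(tss = tss_at[best], roc_auc = auc,
       best_threshold = thresholds[best])
}

# ---- ensembles -------------------------------------------------------------

#' Fit a cross-validated ensemble
#'
#' One learner is fitted per fold on the records outside the fold and
#' evaluated on the held-out fold. Members with held-out ROC AUC at or above
#' `retention` are retained ("greater than 0.70" applied inclusively; see the
#' methods vignette). Folds whose training or test split lacks a class are
#' skipped with a message.
#'
#' @param occ occurrence data.frame with a `fold` column.
#' @param predictors `cs_stack` of training predictors.
#' @param quadratic passed to the learner.
#' @param retention minimum held-out ROC AUC for retention.
#' @param mode `"committee"` or `"weighted_mean"` (default committee, the
#'   projection rule).
#' @param learner fitting function with the signature of [fit_logistic()].
#' @return object of class `cs_ensemble`: retained members (learner +
#'   scores + fold), all-member score table, retention rule and mode.
#' @export
fit_ensemble <- function(occ, predictors, quadratic = TRUE, retention = 0.70,
                         mode = c("committee", "weighted_mean"),
                         learner = fit_logistic) {
  mode <- match.arg(mode)
  if (is.null(occ$fold) || all(is.na(occ$fold)))
    stop("fit_ensemble: records need fold assignments")
  folds <- sort(unique(occ$fold))
  members <- list()
  scores <- data.frame()
  for (f in folds) {
    train <- occ[occ$fold != f, ]
    test <- occ[occ$fold == f, ]
    if (length(unique(train$presence)) < 2 ||
        length(unique(test$presence)) < 2) {
      message(sprintf("fold %d skipped: single-class split", f))
      next
    }
    m <- learner(train, predictors, quadratic = quadratic)
    x <- extract_predictors(predictors, test$x, test$y)
    ok <- stats::complete.cases(x)
    if (length(unique(test$presence[ok])) < 2) {
      message(sprintf("fold %d skipped: single-class split", f))
      next
    }
    ev <- evaluate(m$predict(x[ok, , drop = FALSE]), test$presence[ok])
    scores <- rbind(scores, data.frame(
      fold = f, tss = ev$tss, roc_auc = ev$roc_auc,
      threshold = ev$best_threshold,
      retained = ev$roc_auc >= retention))
    if (ev$roc_auc >= retention)
      members[[length(members) + 1]] <- list(learner = m, scores = ev, fold = f)
  }
  structure(list(members = members, scores = scores,
                 retention = retention, mode = mode),
            class = "cs_ensemble")
}

#' @export
print.cs_ensemble <- function(x, ...) {
  cat(sprintf("<cs_ensemble> %d retained member(s) (ROC >= %.2f), mode = %s\n",
              length(x$members), x$retention, x$mode))
  if (nrow(x$scores)) print(x$scores, row.names = FALSE)
  invisible(x)
}

# Member probability predictions over a stack: cells x members matrix
# (NA rows where any predictor is nodata).
member_predictions <- function(ensemble, predictors) {
  if (length(ensemble$members) == 0)
    stop("ensemble has no retained members")
  m <- stack_matrix(predictors)
  ok <- stats::complete.cases(m)
  p <- matrix(NA_real_, nrow(m), length(ensemble$members))
  for (j in seq_along(ensemble$members))
    p[ok, j] <- ensemble$members[[j]]$learner$predict(m[ok, , drop = FALSE])
  p
}

vector_to_raster <- function(v, template) {
  raster_like(template,
              matrix(v, nrow(template$values), ncol(template$values),
                     byrow = TRUE))
}

#' Committee-average suitability surface
#'
#' Each retained member's probability map is binarised at that member's own
#' best TSS threshold (vote when probability >= threshold); the surface is
#' the fraction of members voting presence, i.e. the committee agreement in
#' `{0, 1/m, ..., 1}`.
#'
#' @param ensemble `cs_ensemble` with at least one retained member.
#' @param predictors `cs_stack` to predict over.
#' @return suitability `cs_raster` in `[0, 1]`.
#' @export
committee_average <- function(ensemble, predictors) {
  p <- member_predictions(ensemble, predictors)
  votes <- vapply(seq_along(ensemble$members), function(j)
    as.numeric(p[, j] >= ensemble$members[[j]]$scores$best_threshold),
    numeric(nrow(p)))
  vector_to_raster(rowMeans(votes), predictors$layers[[1]])
}

#' TSS-weighted mean suitability surface
#'
#' Member probabilities averaged with weights proportional to their held-out
#' TSS (negative weights floored at zero); weights normalised to sum to one.
#'
#' @inheritParams committee_average
#' @return suitability `cs_raster` in `[0, 1]`.
#' @export
weighted_mean_ensemble <- function(ensemble, predictors) {
  p <- member_predictions(ensemble, predictors)
  w <- vapply(ensemble$members, function(m) m$scores$tss, numeric(1))
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("all member weights are non-positive")
  vector_to_raster(drop(p %*% (w / sum(w))), predictors$layers[[1]])
}

#' Project an ensemble onto a scenario predictor stack
#'
#' Applies the ensemble's mode (committee average by default) to a stack in
#' which the climate layers carry a scenario's values while static layers
#' (distances, TPI, landcover) are unchanged. Cells with any nodata
#' predictor project to nodata.
#'
#' @param ensemble `cs_ensemble`.
#' @param scenario_stack `cs_stack` containing every training predictor.
#' @return suitability `cs_raster`.
#' @export
project_ensemble <- function(ensemble, scenario_stack) {
  if (length(ensemble$members) == 0) stop("ensemble has no retained members")
  need <- ensemble$members[[1]]$learner$state$layers
  missing <- setdiff(need, scenario_stack$names)
  if (length(missing))
    stop("scenario stack missing predictor layer(s): ",
         paste(missing, collapse = ", "))
  stack <- stack_subset(scenario_stack, need)
  if (ensemble$mode == "committee") committee_average(ensemble, stack)
  else weighted_mean_ensemble(ensemble, stack)
}

#' Count of in-range predictors (MESS-style map)
#'
#' For each cell, the number of listed climate layers whose scenario value
#' lies within the training range `[min, max]`. Low counts flag
#' extrapolation beyond the model's calibration domain. (This is the
#' count-of-in-range-variables map, not the continuous multivariate
#' similarity statistic.)
#'
#' @param training_ranges data.frame `layer, min, max` (one row per climate
#'   layer), e.g. from [training_range_table()].
#' @param scenario_stack `cs_stack` containing those layers.
#' @return `cs_raster` of integer counts.
#' @export
mess_count <- function(training_ranges, scenario_stack) {
  if (nrow(training_ranges) == 0) stop("empty training range table")
  missing <- setdiff(training_ranges$layer, scenario_stack$names)
  if (length(missing))
    stop("scenario stack missing layer(s): ", paste(missing, collapse = ", "))
  template <- scenario_stack$layers[[1]]
  count <- rep(0, length(template$values))
  anyna <- rep(FALSE, length(template$values))
  for (i in seq_len(nrow(training_ranges))) {
    v <- as.vector(t(scenario_stack$layers[[training_ranges$layer[i]]]$values))
    anyna <- anyna | is.na(v)
    count <- count + as.numeric(!is.na(v) &
                                  v >= training_ranges$min[i] &
                                  v <= training_ranges$max[i])
  }
  count[anyna] <- NA
  vector_to_raster(count, template)
}

#' Per-layer training min/max table
#'
#' @param stack `cs_stack` of training predictors.
#' @param layers layer names to include (default all).
#' @return data.frame `layer, min, max`.
#' @export
training_range_table <- function(stack, layers = stack$names) {
  data.frame(
    layer = layers,
    min = vapply(layers, function(n) min(stack$layers[[n]]$values, na.rm = TRUE),
                 numeric(1)),
    max = vapply(layers, function(n) max(stack$layers[[n]]$values, na.rm = TRUE),
                 numeric(1)),
    row.names = NULL)
}

#' Write a fold-level evaluation report CSV
#'
#' Columns `species, learner, fold, tss, roc_auc, threshold`.
#'
#' @param ensemble `cs_ensemble`.
#' @param species species identifier for the report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(ensemble, species, path) {
  s <- ensemble$scores
  out <- data.frame(species = species, learner = "logistic",
                    fold = s$fold, tss = s$tss, roc_auc = s$roc_auc,
                    threshold = s$threshold)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
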