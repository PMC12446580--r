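grid10 <- cs_raster(matrix(0, 10, 10), cell_size = 100)

test_that("record gridding thins to one record per cell, row-major", {
  pts <- data.frame(x = c(55, 51, 58, 155, 355), y = c(955, 951, 958, 955, 455),
                    presence = 1)
  g <- grid_records(pts, grid10)
  expect_equal(nrow(g), 3)          # 3 distinct cells from 5 points
  expect_equal(g$x, c(50, 150, 350))  # snapped to centres, row-major order
  set.seed(2)
  many <- data.frame(x = runif(1000, 0, 1000), y = runif(1000, 0, 1000),
                     presence = 1)
  expect_lte(nrow(grid_records(many, grid10)), 100)  # pigeonhole
  expect_error(grid_records(data.frame(x = -5, y = -5, presence = 1), grid10),
               "outside")
})

test_that("pseudo-absence sampling yields exactly ratio x presences, off presence cells", {
  # the published worked ratio: 262 presences, three absences per presence
  big <- cs_raster(matrix(0, 40, 40), cell_size = 100)
  set.seed(9)
  pres262 <- grid_records(data.frame(
    x = runif(600, 0, 4000), y = runif(600, 0, 4000), presence = 1), big)
  pres262 <- pres262[seq_len(262), ]
  pa <- sample_pseudo_absences(pres262, big, ratio = 3, seed = 4)
  expect_equal(nrow(pa), 786)

  expect_equal(nrow(sample_pseudo_absences(pres262, big, ratio = 0)), 0)

  pres10 <- grid_records(data.frame(
    x = seq(50, 950, 100), y = rep(50, 10), presence = 1), grid10)
  pa30 <- sample_pseudo_absences(pres10, grid10, ratio = 3, seed = 11)
  expect_equal(nrow(pa30), 30)
  expect_equal(nrow(merge(pa30[c("x", "y")], pres10[c("x", "y")])), 0)
  expect_identical(sample_pseudo_absences(pres10, grid10, 3, seed = 5),
                   sample_pseudo_absences(pres10, grid10, 3, seed = 5))
  expect_error(sample_pseudo_absences(pres10, grid10, ratio = 10, seed = 1),
               "candidate cells")
})

test_that("spatial blocks give spatially coherent folds", {
  set.seed(14)
  rec <- data.frame(x = runif(500, 0, 1000), y = runif(500, 0, 1000),
                    presence = 1)
  fa <- assign_spatial_blocks(rec, c(0, 1000, 0, 1000), n_blocks = 40,
                              n_folds = 5, seed = 9)
  expect_equal(sort(unique(fa$fold_id)), 1:5)       # every fold non-empty
  # all records of one block share one fold
  expect_true(all(tapply(fa$fold_id, fa$block_id,
                         function(f) length(unique(f))) == 1))

  one_fold <- assign_spatial_blocks(rec, c(0, 1000, 0, 1000), 40, 1, seed = 2)
  expect_true(all(one_fold$fold_id == 1))

  clustered <- data.frame(x = runif(30, 490, 510), y = runif(30, 490, 510),
                          presence = 1)
  # a tight cluster cannot fill enough blocks for spatially separated folds
  expect_error(assign_spatial_blocks(clustered, c(0, 1000, 0, 1000),
                                     n_blocks = 40, n_folds = 5, seed = 1),
               "occupied blocks")
  # with a single fold it degenerates gracefully: everyone shares fold 1
  clus1 <- assign_spatial_blocks(clustered, c(0, 1000, 0, 1000),
                                 n_blocks = 40, n_folds = 1, seed = 1)
  expect_true(all(clus1$fold_id == 1))
  expect_lte(length(unique(clus1$block_id)), 4)
})

test_that("logistic learner recovers closed-form and simulated truths", {
  stack1 <- raster_stack(list(cs_raster(matrix(0, 12, 10), cell_size = 1)),
                         names = "z")
  cc <- cell_centres(stack1$layers[[1]])
  train <- data.frame(x = cc$x, y = cc$y,
                      presence = c(rep(1, 30), rep(0, 90)))
  fit <- fit_logistic(train, stack1, quadratic = FALSE)
  expect_equal(unname(fit$state$coefficients["(Intercept)"]), log(30 / 90),
               tolerance = 1e-6)

  expect_error(fit_logistic(transform(train, presence = 1), stack1),
               "both classes")
})

test_that("slope recovery improves with sample size", {
  make_data <- function(n, seed) {
    set.seed(seed)
    nr <- 50; nc <- 40
    x <- matrix(rnorm(nr * nc), nr, nc)
    stack <- raster_stack(list(cs_raster(x, cell_size = 1)), names = "x1")
    cc <- cell_centres(stack$layers[[1]])
    idx <- sample(nr * nc, n, replace = TRUE)
    eta <- 0 + 2 * as.vector(t(x))[idx]
    y <- rbinom(n, 1, plogis(eta))
    list(occ = data.frame(x = cc$x[idx], y = cc$y[idx], presence = y),
         stack = stack)
  }
  d <- make_data(2000, seed = 31)
  fit <- fit_logistic(d$occ, d$stack, quadratic = FALSE)
  slope <- unname(fit$state$coefficients["x1"])
  expect_lt(abs(slope - 2), 0.3)

  bias_at <- function(n, seed) {
    d <- make_data(n, seed)
    f <- fit_logistic(d$occ, d$stack, quadratic = FALSE)
    abs(unname(f$state$coefficients["x1"]) - 2)
  }
  b500 <- mean(vapply(1:5, function(s) bias_at(500, 40 + s), numeric(1)))
  b5000 <- mean(vapply(1:5, function(s) bias_at(5000, 50 + s), numeric(1)))
  expect_lt(b5000, b500)
})

test_that("separated data falls back to a finite ridge fit", {
  stack <- raster_stack(list(cs_raster(matrix(seq(-3, 3, length.out = 100),
                                              10, 10), cell_size = 1)),
                        names = "x1")
  cc <- cell_centres(stack$layers[[1]])
  v <- as.vector(t(raster_values(stack$layers[[1]])))
  occ <- data.frame(x = cc$x, y = cc$y, presence = as.numeric(v > 0))
  fit <- fit_logistic(occ, stack, quadratic = FALSE)
  expect_true(fit$state$separation)
  expect_true(all(is.finite(fit$state$coefficients)))
  p <- fit$predict(matrix(c(-3, 3), ncol = 1, dimnames = list(NULL, "x1")))
  expect_lt(p[1], 0.05); expect_gt(p[2], 0.95)
})

test_that("evaluation matches exhaustive pair counting and known cases", {
  # perfectly separated
  ev <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$tss, 1); expect_equal(ev$roc_auc, 1)
  # uninformative constant predictions
  ev0 <- evaluate(rep(0.4, 10), rep(c(1, 0), 5))
  expect_equal(ev0$tss, 0); expect_equal(ev0$roc_auc, 0.5)
  # 3 of 4 pairs concordant
  expect_equal(evaluate(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))$roc_auc, 0.75)

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    pred <- round(runif(n), 2)  # ties likely
    ev <- evaluate(pred, truth)
    expect_equal(ev$roc_auc, pairwise_auc_oracle(pred, truth),
                 tolerance = 1e-12)
    expect_equal(ev$roc_auc,
                 as.numeric(pROC::auc(truth, pred, quiet = TRUE,
                                      levels = c(0, 1), direction = "<")),
                 tolerance = 1e-12)
    expect_gte(ev$tss, -1); expect_lte(ev$tss, 1)
    # per-threshold TSS of reversed labels is the negation of the original
    tss_curve <- function(pred, truth) vapply(sort(unique(pred)), function(t) {
      vote <- pred >= t
      sum(vote & truth == 1) / sum(truth == 1) +
        sum(!vote & truth == 0) / sum(truth == 0) - 1
    }, numeric(1))
    expect_equal(tss_curve(pred, 1 - truth), -tss_curve(pred, truth),
                 tolerance = 1e-12)
    expect_equal(ev$tss, max(tss_curve(pred, truth)), tolerance = 1e-12)
  }
  expect_error(evaluate(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("committee averages live on the vote lattice; weighted means are affine", {
  stack <- gen_climate_stack(12, 12, 2, seed = 3)
  mk_member <- function(const, thr, tss) list(
    learner = new_learner("const", function(x) rep(const, nrow(x))),
    scores = list(tss = tss, roc_auc = 0.9, best_threshold = thr), fold = 1)
  ens <- structure(list(members = list(mk_member(0.8, 0.5, 1),
                                       mk_member(0.2, 0.5, 1),
                                       mk_member(0.9, 0.5, 1),
                                       mk_member(0.1, 0.5, 1)),
                        retention = 0.7, mode = "committee"),
                   class = "cs_ensemble")
  ca <- raster_values(committee_average(ens, stack))
  expect_true(all(ca == 0.5))        # 2 of 4 vote presence
  ens1 <- structure(list(members = list(mk_member(0.8, 0.5, 1)),
                         retention = 0.7, mode = "committee"),
                    class = "cs_ensemble")
  expect_true(all(raster_values(committee_average(ens1, stack)) == 1))

  # m members: committee values confined to {0, 1/m, ..., 1}
  set.seed(6)
  members <- lapply(1:5, function(i) {
    b <- rnorm(3)
    list(learner = new_learner("lin", function(x)
      plogis(b[1] + x[, "clim1"] * b[2] + x[, "clim2"] * b[3])),
      scores = list(tss = runif(1, 0.3, 0.9), roc_auc = 0.9,
                    best_threshold = runif(1, 0.3, 0.7)), fold = i)
  })
  ens5 <- structure(list(members = members, retention = 0.7,
                         mode = "committee"), class = "cs_ensemble")
  ca5 <- raster_values(committee_average(ens5, stack))
  expect_true(all(abs(ca5 * 5 - round(ca5 * 5)) < 1e-12))

  wm <- structure(list(members = list(mk_member(1, 0.5, 3), mk_member(0, 0.5, 1)),
                       retention = 0.7, mode = "weighted_mean"),
                  class = "cs_ensemble")
  expect_true(all(raster_values(weighted_mean_ensemble(wm, stack)) == 0.75))
  wm2 <- structure(list(members = list(mk_member(0.2, 0.5, 1),
                                       mk_member(0.8, 0.5, 1)),
                        retention = 0.7, mode = "weighted_mean"),
                   class = "cs_ensemble")
  expect_true(all(raster_values(weighted_mean_ensemble(wm2, stack)) == 0.5))
})

test_that("projection responds to climate shifts and respects nodata", {
  stack <- gen_climate_stack(40, 40, 2, seed = 17)
  tm <- true_model(c("(Intercept)" = 0, clim1 = 2, clim2 = 0.5))
  occ <- gen_occurrences(tm, stack, 300, seed = 3)
  pres <- grid_records(occ, stack$layers[[1]])
  pa <- sample_pseudo_absences(pres, stack$layers[[1]], 3, seed = 4)
  rec <- rbind(pres, pa)
  rec$fold <- rep_len(1:4, nrow(rec))   # plain folds suffice here
  ens <- fit_ensemble(rec, stack, quadratic = FALSE, retention = 0.5)
  expect_gt(length(ens$members), 0)

  base <- project_ensemble(ens, stack)
  shifted <- gen_climate_stack(40, 40, 2, scenario_shift = c(1.5, 0), seed = 17)
  up <- project_ensemble(ens, shifted)
  # fitted slope on clim1 is positive, so warming raises mean suitability
  expect_gte(mean(raster_values(up)), mean(raster_values(base)))

  holed <- stack
  holed$layers$clim1$values[3, 4] <- NA
  p <- project_ensemble(ens, holed)
  expect_true(is.na(raster_values(p)[3, 4]))
  expect_error(project_ensemble(ens, stack_subset(stack, "clim2")), "missing")
})

test_that("in-range predictor counts match a brute-force range check", {
  stack <- gen_climate_stack(20, 20, 3, seed = 23)
  ranges <- training_range_table(stack)
  same <- mess_count(ranges, stack)
  expect_true(all(raster_values(same) == 3))

  shifted_all <- gen_climate_stack(20, 20, 3,
                                   scenario_shift = c(100, 0, 0), seed = 23)
  expect_true(all(raster_values(mess_count(ranges, shifted_all)) == 2))

  mixed <- gen_climate_stack(20, 20, 3, scenario_shift = c(1.2, -0.8, 0.3),
                             seed = 29)
  got <- as.vector(t(raster_values(mess_count(ranges, mixed))))
  m <- stack_matrix(mixed)
  want <- rowSums(sapply(1:3, function(k)
    m[, ranges$layer[k]] >= ranges$min[k] & m[, ranges$layer[k]] <= ranges$max[k]))
  expect_equal(got, unname(want))
  expect_error(mess_count(ranges[0, ], stack), "empty")
})
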