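test_that("the calibration/validation split is a deterministic partition", {
  ids <- sprintf("S%03d", 1:154)
  sp <- split_dataset(ids, 0.7, seed = 5)
  expect_length(sp$train, 108) # ceiling(0.7 * 154)
  expect_length(sp$validation, 46)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(split_dataset(ids, 0.7, seed = 5), sp)
  other <- split_dataset(ids, 0.7, seed = 6)
  expect_false(identical(other$train, sp$train))
  expect_setequal(c(other$train, other$validation), ids)
  expect_error(split_dataset(ids[1:5], 0.7, 1), ">= 10")
  expect_error(split_dataset(ids, 1.0, 1), "train_fraction")
})

test_that("evaluation metrics match a from-scratch oracle", {
  y <- c(70, 75, 80, 85)
  yhat <- c(72, 74, 81, 83)
  got <- evaluate_predictions(y, yhat)
  # independent direct evaluation of the three formulas
  r2 <- (sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2)))^2
  rmse <- sqrt(sum((y - yhat)^2) / length(y))
  resid <- y - yhat
  sep <- sqrt(sum((resid - mean(resid))^2) / (length(y) - 1))
  sdy <- sqrt(sum((y - mean(y))^2) / (length(y) - 1))
  expect_equal(got$r_squared, r2, tolerance = 1e-12)
  expect_equal(got$rmse, rmse, tolerance = 1e-12)
  expect_equal(got$rpd, sdy / sep, tolerance = 1e-12)
})

test_that("evaluation handles perfect, mean and constant predictors", {
  y <- c(70, 75, 80, 85)
  perfect <- evaluate_predictions(y, y)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  expect_identical(perfect$rpd, Inf)
  expect_identical(perfect$rpd_class, "better")

  mean_pred <- evaluate_predictions(y, rep(mean(y), 4))
  expect_equal(mean_pred$r_squared, 0)
  expect_equal(mean_pred$rmse, sqrt(mean((y - mean(y))^2)))

  expect_error(evaluate_predictions(rep(80, 4), y), "constant")
})

test_that("RPD decreases monotonically with RMSE for fixed observations", {
  set.seed(61)
  y <- rnorm(40, 78, 3.5)
  resid <- rnorm(40)
  rpds <- sapply(c(0.5, 1, 2, 4), function(s) {
    evaluate_predictions(y, y - s * resid)$rpd
  })
  expect_true(all(diff(rpds) < 0))
})

test_that("RPD class bands are respected", {
  expect_identical(lwcspec:::rpd_class(c(2.5, 1.7, 1.0)), c("better", "general", "poor"))
})

test_that("KNN limiting cases behave as the averaging definition implies", {
  set.seed(62)
  X <- matrix(rnorm(60), ncol = 2)
  y <- rnorm(30, 78, 3)
  cfg1 <- model_config("knn", k_grid = 1L)
  self_fit <- fit_predict(X, y, X, cfg1)
  expect_equal(self_fit$predictions, y)
  expect_equal(evaluate_predictions(y, self_fit$predictions)$rmse, 0)

  cfgn <- model_config("knn", k_grid = nrow(X))
  all_fit <- fit_predict(X, y, X[1:3, ], cfgn)
  expect_equal(all_fit$predictions, rep(mean(y), 3))

  expect_error(
    fit_predict(X, y, X, model_config("knn", k_grid = 31L)),
    "k_grid"
  )
})

test_that("SVR recovers a noiseless linear relationship", {
  set.seed(63)
  x <- matrix(runif(100, 0, 1), ncol = 1)
  y <- 70 + 15 * x[, 1]
  hold <- 71:100
  cfg <- model_config("svr", kernel = "linear", epsilon_grid = 0.01, cost_grid = c(10, 100))
  fit <- fit_predict(x[-hold, , drop = FALSE], y[-hold], x[hold, , drop = FALSE], cfg)
  ev <- evaluate_predictions(y[hold], fit$predictions)
  expect_gte(ev$r_squared, 0.99)
})

test_that("learners are deterministic given their seed and impute NAs", {
  set.seed(64)
  X <- matrix(rnorm(120), ncol = 3)
  X[c(2, 17), 2] <- NA
  y <- rnorm(40, 78, 3)
  for (m in c("knn", "svr", "ann")) {
    cfg <- model_config(m, seed = 9L)
    p1 <- fit_predict(X, y, X, cfg)$predictions
    p2 <- fit_predict(X, y, X, cfg)$predictions
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
  }
})

test_that("band selection ignores validation samples entirely", {
  ds <- make_dataset(small_config(seed = 71))
  pre <- preprocess_spectra(ds$spectra)
  split <- split_dataset(spectra_ids(pre), 0.7, seed = 71)
  stack <- fod_stack(pre, c(0, 0.8))
  # a permissive screen keeps the small fixture from emptying the band sets
  args <- list(
    spectra = pre, stack = stack, train_ids = split$train,
    alpha = 0.2, two_band_stride = 10, three_band_range = c(450, 900),
    three_band_stride = 25, max_bands = 20L
  )
  s1 <- do.call(optimize_lwc_features, c(args, list(traits = ds$traits)))
  # perturb the validation samples' trait values only
  mangled <- ds$traits
  vidx <- mangled$sample_id %in% split$validation
  mangled$lwc_percent[vidx] <- rev(mangled$lwc_percent[vidx]) + 3
  s2 <- do.call(optimize_lwc_features, c(args, list(traits = mangled)))
  expect_identical(s1$raw_sensitive, s2$raw_sensitive)
  expect_identical(s1$fod_sensitive, s2$fod_sensitive)
  expect_identical(s1$fod_order, s2$fod_order)
  expect_equal(s1$two_band_raw, s2$two_band_raw)
  expect_equal(s1$two_band_fod, s2$two_band_fod)
  expect_equal(s1$three_band, s2$three_band)
})

test_that("run_model_grid reports every cell with the expected schema", {
  set.seed(65)
  ids <- sprintf("S%02d", 1:40)
  traits <- tibble::tibble(sample_id = ids, lwc_percent = rnorm(40, 78, 3.5))
  feats <- list(
    informative = tibble::tibble(
      sample_id = ids,
      f1 = traits$lwc_percent + rnorm(40, 0, 0.5),
      f2 = rnorm(40)
    ),
    noise = tibble::tibble(sample_id = ids, g1 = rnorm(40), g2 = rnorm(40))
  )
  split <- split_dataset(ids, 0.7, seed = 66)
  grid <- run_model_grid(feats, traits, split,
    configs = list(model_config("knn"), model_config("svr")), seed = 66
  )
  tbl <- tidy(grid)
  expect_equal(nrow(tbl), 4)
  expect_setequal(tbl$data_type, c("informative", "noise"))
  expect_true(all(c("r2_cal", "rmse_cal", "r2_val", "rmse_val", "rpd", "rpd_class") %in% names(tbl)))
  expect_true(all(tbl$rmse_val >= 0))
  expect_true(all(tbl$r2_val <= 1))
  # signal set clearly beats noise set
  expect_gt(max(tbl$r2_val[tbl$data_type == "informative"]),
            max(tbl$r2_val[tbl$data_type == "noise"]))
  g <- glance(grid)
  expect_equal(g$n_models, 4L)
  expect_identical(g$best_data_type, "informative")
})
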