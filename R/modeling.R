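#' Calibration / validation split
#'
#' Random partition of the sample ids into a calibration (modeling) set of
#' size `ceiling(train_fraction * n)` and a validation set with the rest.
#' Deterministic given the seed.
#'
#' @param ids character vector of sample ids (>= 10).
#' @param train_fraction fraction in (0, 1), default 0.70.
#' @param seed integer seed.
#' @return list with `train` and `validation` id vectors (original order).
#' @export
split_dataset <- function(ids, train_fraction = 0.7, seed = 1L) {
  if (length(ids) < 10L) stop_lwc("need >= 10 samples to split, got %d", length(ids))
  if (anyDuplicated(ids)) stop_lwc("sample ids must be unique")
  if (train_fraction <= 0 || train_fraction >= 1) stop_lwc("train_fraction must be in (0, 1)")
  n_train <- ceiling(train_fraction * length(ids))
  take <- with_local_seed(seed, sample(seq_along(ids), n_train))
  list(
    train = ids[sort(take)],
    validation = ids[sort(setdiff(seq_along(ids), take))]
  )
}

#' Regression evaluation metrics: R-squared, RMSE, RPD
#'
#' `r_squared` is the squared Pearson correlation between observed and
#' predicted (0 when the correlation is undefined, e.g. a constant
#' predictor); `rmse = sqrt(mean((y - yhat)^2))` in trait units; `sep` is
#' the bias-corrected standard deviation of the residuals (standard error of
#' prediction, chemometrics convention) and `rpd = sd(y) / sep`. A perfect
#' fit has `sep = 0` and is reported as `rpd = Inf`. RPD classes: above 2.0
#' "better", 1.4--2.0 "general", below 1.4 "poor".
#'
#' @param observed,predicted aligned numeric vectors, >= 3 pairs; `observed`
#'   must not be constant.
#' @return one-row tibble `r_squared, rmse, sep, rpd, rpd_class`.
#' @export
evaluate_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop_lwc("observed/predicted length mismatch")
  if (length(observed) < 3L) stop_lwc("need >= 3 pairs")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) stop_lwc("non-finite values")
  if (stats::sd(observed) == 0) stop_lwc("observed values are constant")
  r2 <- if (stats::sd(predicted) == 0) 0 else stats::cor(observed, predicted)^2
  resid <- observed - predicted
  rmse <- sqrt(mean(resid^2))
  sep <- stats::sd(resid)
  rpd <- if (sep == 0) Inf else stats::sd(observed) / sep
  tibble::tibble(
    r_squared = r2, rmse = rmse, sep = sep, rpd = rpd,
    rpd_class = rpd_class(rpd)
  )
}

rpd_class <- function(rpd) {
  dplyr::case_when(
    rpd > 2.0 ~ "better",
    rpd >= 1.4 ~ "general",
    TRUE ~ "poor"
  )
}

#' Learner configuration
#'
#' Hyperparameter defaults: KNN tunes `k` over \{3, 5, 7, 9\} by 5-fold CV
#' on the calibration set; SVR (RBF kernel) tunes cost over \{1, 10, 100\}
#' and epsilon over \{0.01, 0.1\} the same way; the ANN is a single hidden
#' layer of 16 units trained for up to 2000 epochs with a small weight decay
#' and a seeded initialization. Features are standardized to the calibration
#' mean/sd for all learners.
#'
#' @param method `"knn"`, `"svr"` or `"ann"`.
#' @param ... overrides of the method's defaults (`k_grid`, `cv_folds`;
#'   `cost_grid`, `epsilon_grid`, `kernel`; `size`, `maxit`, `decay`), plus
#'   `scale` and `seed` for any method.
#' @return object of class `"lwc_model_config"`.
#' @export
model_config <- function(method = c("knn", "svr", "ann"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    knn = list(k_grid = c(3L, 5L, 7L, 9L), cv_folds = 5L),
    svr = list(kernel = "radial", cost_grid = c(1, 10, 100), epsilon_grid = c(0.01, 0.1), cv_folds = 5L),
    ann = list(size = 16L, maxit = 2000L, decay = 0.1)
  )
  cfg <- utils::modifyList(c(defaults, list(scale = TRUE, seed = 1L)), list(...))
  cfg$method <- method
  structure(cfg, class = "lwc_model_config")
}

# standardization fitted on the training rows only
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

knn_regress <- function(X_train, y_train, X_eval, k) {
  if (k > nrow(X_train)) stop_lwc("k = %d exceeds the %d training samples", k, nrow(X_train))
  d2 <- outer(rowSums(X_eval^2), rowSums(X_train^2), "+") - 2 * X_eval %*% t(X_train)
  apply(d2, 1, function(row) mean(y_train[order(row)[seq_len(k)]]))
}

cv_folds_idx <- function(n, folds, seed) {
  with_local_seed(seed, split(sample(seq_len(n)), rep_len(seq_len(folds), n)))
}

tune_by_cv <- function(grid, X, y, folds, seed, fit_fun) {
  idx <- cv_folds_idx(nrow(X), folds, seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(idx, function(hold) {
      pred <- fit_fun(grid[g, , drop = FALSE], X[-hold, , drop = FALSE], y[-hold], X[hold, , drop = FALSE])
      sqrt(mean((y[hold] - pred)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[which.min(scores), , drop = FALSE]
}

#' Fit a learner on calibration data and predict
#'
#' Standardizes features on the calibration set (when `scale` is on),
#' imputes missing feature values by the calibration column median, tunes
#' hyperparameters by cross-validation on the calibration set only, and
#' predicts for the evaluation rows. KNN averages the targets of the `k`
#' nearest calibration samples in scaled Euclidean space; SVR uses
#' [e1071::svm()] in epsilon-regression mode; the ANN is a seeded
#' single-hidden-layer [nnet::nnet()] on a standardized response.
#'
#' @param X_train,X_eval numeric feature matrices (rows = samples).
#' @param y_train calibration trait values.
#' @param config an [model_config()].
#' @return list `predictions` (numeric, one per eval row), `tuned`
#'   (chosen hyperparameters), `model` (fitted object or NULL for KNN).
#' @export
fit_predict <- function(X_train, y_train, X_eval, config) {
  stopifnot(inherits(config, "lwc_model_config"))
  X_train <- as.matrix(X_train)
  X_eval <- as.matrix(X_eval)
  med <- apply(X_train, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X_train))) {
    X_train[is.na(X_train[, j]), j] <- med[j]
    X_eval[is.na(X_eval[, j]), j] <- med[j]
  }
  if (any(!is.finite(X_train)) || any(!is.finite(X_eval))) stop_lwc("non-finite features after imputation")
  if (isTRUE(config$scale)) {
    sc <- fit_scaler(X_train)
    X_train <- apply_scaler(X_train, sc)
    X_eval <- apply_scaler(X_eval, sc)
  }
  switch(config$method,
    knn = {
      ks <- config$k_grid[config$k_grid <= nrow(X_train)]
      if (!length(ks)) stop_lwc("k_grid entirely above n_train = %d", nrow(X_train))
      tuned <- if (length(ks) == 1L) {
        data.frame(k = ks)
      } else {
        tune_by_cv(
          data.frame(k = ks), X_train, y_train, config$cv_folds, config$seed,
          function(g, Xtr, ytr, Xev) knn_regress(Xtr, ytr, Xev, g$k)
        )
      }
      list(
        predictions = knn_regress(X_train, y_train, X_eval, tuned$k),
        tuned = tuned, model = NULL
      )
    },
    svr = {
      grid <- expand.grid(cost = config$cost_grid, epsilon = config$epsilon_grid)
      svr_fit <- function(g, Xtr, ytr, Xev) {
        fit <- e1071::svm(Xtr, ytr,
          type = "eps-regression", kernel = config$kernel,
          cost = g$cost, epsilon = g$epsilon, scale = FALSE
        )
        as.numeric(stats::predict(fit, Xev))
      }
      tuned <- if (nrow(grid) == 1L) grid else {
        tune_by_cv(grid, X_train, y_train, config$cv_folds, config$seed, svr_fit)
      }
      fit <- e1071::svm(X_train, y_train,
        type = "eps-regression", kernel = config$kernel,
        cost = tuned$cost, epsilon = tuned$epsilon, scale = FALSE
      )
      list(
        predictions = as.numeric(stats::predict(fit, X_eval)),
        tuned = tuned, model = fit
      )
    },
    ann = {
      mu_y <- mean(y_train)
      sd_y <- stats::sd(y_train)
      if (sd_y == 0) sd_y <- 1
      fit <- with_local_seed(config$seed, nnet::nnet(
        X_train, (y_train - mu_y) / sd_y,
        size = config$size, linout = TRUE, maxit = config$maxit,
        decay = config$decay, trace = FALSE,
        MaxNWts = (ncol(X_train) + 2L) * config$size + config$size + 1L + 10L
      ))
      list(
        predictions = as.numeric(stats::predict(fit, X_eval)) * sd_y + mu_y,
        tuned = data.frame(size = config$size, decay = config$decay),
        model = fit
      )
    }
  )
}

features_matrix <- function(features, ids) {
  pos <- match(ids, features$sample_id)
  if (anyNA(pos)) stop_lwc("feature table missing sample(s): %s", paste(ids[is.na(pos)], collapse = ", "))
  as.matrix(features[pos, -1, drop = FALSE])
}

#' Fit the full data-type x learner model grid
#'
#' Fits every learner configuration on every feature set using the given
#' calibration/validation split and evaluates both subsets with
#' [evaluate_predictions()]; RPD is reported for the validation set. The
#' result mirrors the standard 9 x 3 accuracy table; per data type the
#' learner with the highest validation R-squared is flagged `best`.
#'
#' @param features named list of feature tibbles (`sample_id` + columns),
#'   e.g. from [assemble_all_features()].
#' @param traits trait tibble for all samples.
#' @param split list with `train` / `validation` ids, from [split_dataset()].
#' @param configs list of [model_config()]s; default KNN + SVR + ANN.
#' @param seed base seed; learner c gets `seed + c` unless its config sets
#'   one explicitly.
#' @return object of class `"lwc_model_grid"`; `tidy()` returns the report
#'   table, `glance()` the overall best model.
#' @export
run_model_grid <- function(features, traits, split, configs = NULL, seed = 1L) {
  configs <- configs %||% list(
    model_config("knn"), model_config("svr"), model_config("ann")
  )
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    stop_lwc("features must be a named list of feature tibbles")
  }
  y_tr <- traits$lwc_percent[match(split$train, traits$sample_id)]
  y_va <- traits$lwc_percent[match(split$validation, traits$sample_id)]
  if (anyNA(y_tr) || anyNA(y_va)) stop_lwc("split ids missing from traits")
  reports <- purrr::imap_dfr(features, function(ft, kind) {
    X_tr <- features_matrix(ft, split$train)
    X_va <- features_matrix(ft, split$validation)
    purrr::imap_dfr(configs, function(cfg, ci) {
      cfg$seed <- cfg$seed %||% 1L
      cfg$seed <- as.integer(cfg$seed + seed + ci)
      fit_tr <- tryCatch(
        fit_predict(X_tr, y_tr, X_tr, cfg),
        error = function(e) stop_lwc("model grid cell (%s, %s) failed: %s", kind, cfg$method, conditionMessage(e))
      )
      fit_va <- fit_predict(X_tr, y_tr, X_va, cfg)
      cal <- evaluate_predictions(y_tr, fit_tr$predictions)
      val <- evaluate_predictions(y_va, fit_va$predictions)
      tibble::tibble(
        data_type = kind, method = cfg$method,
        r2_cal = cal$r_squared, rmse_cal = cal$rmse,
        r2_val = val$r_squared, rmse_val = val$rmse,
        rpd = val$rpd, rpd_class = val$rpd_class
      )
    })
  })
  reports <- dplyr::mutate(
    dplyr::group_by(reports, .data$data_type),
    best = .data$r2_val == max(.data$r2_val)
  )
  reports <- dplyr::ungroup(reports)
  structure(
    list(reports = reports, split = split, seed = seed,
         methods = vapply(configs, `[[`, "", "method")),
    class = "lwc_model_grid"
  )
}

#' @export
print.lwc_model_grid <- function(x, ...) {
  cat(sprintf(
    "LWC model grid: %d feature sets x %d learners = %d models (train %d / validation %d)\n",
    length(unique(x$reports$data_type)), length(x$methods), nrow(x$reports),
    length(x$split$train), length(x$split$validation)
  ))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.lwc_model_grid <- function(x, ...) x$reports

#' @export
glance.lwc_model_grid <- function(x, ...) {
  best <- x$reports[which.max(x$reports$r2_val), ]
  tibble::tibble(
    n_models = nrow(x$reports),
    best_data_type = best$data_type, best_method = best$method,
    r2_val = best$r2_val, rmse_val = best$rmse_val,
    rpd = best$rpd, rpd_class = best$rpd_class
  )
}
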