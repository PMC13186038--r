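#' Fit a carbon inversion model
#'
#' Fits random forest regression (RFR) or support vector machine regression
#' (SVMR) to a training set restricted to a selected variable set. RFR uses
#' bootstrap-aggregated trees (500 by default, `floor(sqrt(p))` candidate
#' variables per split); SVMR uses a radial-basis kernel with cost and gamma
#' chosen by seeded 5-fold grid search on the training data.
#'
#' @param method `"RFR"` or `"SVMR"`.
#' @param train a [paired_samples()] training set.
#' @param selection a `selection_result` (or character vector of names)
#'   restricting the predictors.
#' @param hyper optional named list overriding defaults (`ntree`, `mtry` for
#'   RFR; `kernel`, `cost_grid`, `gamma_grid`, `cost`, `gamma` for SVMR).
#' @param seed integer seed controlling all randomness in the fit.
#' @return Object of class `carbon_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
fit_carbon_model <- function(method = c("RFR", "SVMR"), train, selection,
                             hyper = list(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(train, "paired_samples"))
  vars <- if (inherits(selection, "selection_result")) selection$selected
          else as.character(selection)
  if (length(vars) == 0L) stop("empty variable selection")
  missing_vars <- setdiff(vars, train$names)
  if (length(missing_vars))
    stop("selection names absent from training data: ",
         paste(missing_vars, collapse = ", "))
  X <- train$X[, vars, drop = FALSE]
  y <- train$y
  if (nrow(X) < 10L) stop("need at least 10 training samples")
  set.seed(seed)
  if (method == "RFR") {
    ntree <- hyper$ntree %||% 500L
    mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(X))))
    fit <- randomForest::randomForest(x = X, y = y, ntree = ntree, mtry = mtry)
    used <- list(ntree = ntree, mtry = mtry)
  } else {
    kernel <- hyper$kernel %||% "radial"
    if (!is.null(hyper$cost) && (!is.null(hyper$gamma) || kernel == "linear")) {
      cost <- hyper$cost; gamma <- hyper$gamma %||% (1 / ncol(X))
    } else {
      cost_grid <- hyper$cost_grid %||% 2^(0:6)
      gamma_grid <- hyper$gamma_grid %||% ((1 / ncol(X)) * 2^(-2:2))
      if (kernel == "linear") gamma_grid <- 1 / ncol(X)
      fold <- make_folds(nrow(X), 5L, seed + 7L)
      grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
      cv_err <- vapply(seq_len(nrow(grid)), function(g) {
        sse <- 0
        for (f in seq_len(5L)) {
          tr <- fold != f
          m <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                          kernel = kernel, cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = TRUE)
          pr <- stats::predict(m, X[!tr, , drop = FALSE])
          sse <- sse + sum((y[!tr] - pr)^2)
        }
        sqrt(sse / nrow(X))
      }, numeric(1))
      gbest <- which.min(cv_err)
      cost <- grid$cost[gbest]; gamma <- grid$gamma[gbest]
    }
    fit <- e1071::svm(x = X, y = y, kernel = kernel, cost = cost,
                      gamma = gamma, scale = TRUE)
    used <- list(kernel = kernel, cost = cost, gamma = gamma)
  }
  structure(list(method = method, fit = fit, variables = vars,
                 hyperparameters = used, seed = seed,
                 response_range = range(y)),
            class = "carbon_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.carbon_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "paired_samples")) newdata$X else as.matrix(newdata)
  missing_vars <- setdiff(object$variables, colnames(X))
  if (length(missing_vars))
    stop("missing predictor(s): ", paste(missing_vars, collapse = ", "))
  as.numeric(stats::predict(object$fit,
                            X[, object$variables, drop = FALSE]))
}

#' @export
print.carbon_model <- function(x, ...) {
  cat(sprintf("<carbon_model> %s on %d variable(s), seed %d\n",
              x$method, length(x$variables), x$seed))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.carbon_model <- function(object, ...) print(object)

#' Regression accuracy metrics
#'
#' The coefficient of determination R² = 1 − Σ(zᵢ−ẑᵢ)²/Σ(zᵢ−z̄)², the root
#' mean square error RMSE = √(Σ(zᵢ−ẑᵢ)²/n), the standard deviation of the
#' observations SD (n−1 divisor), and the relative percent deviation
#' RPD = SD/RMSE. RPD bands qualify estimation quality: below 1.4 poor,
#' 1.4 to 2 rough, 2 or more strong.
#'
#' @param observed,predicted numeric vectors of equal length (n ≥ 2).
#' @return Named list: `r2`, `rmse`, `sd`, `rpd`, `n`, `rpd_band`.
#' @export
regression_metrics <- function(observed, predicted) {
  n <- length(observed)
  if (n < 2L || length(predicted) != n)
    stop("need two equal-length vectors with n >= 2")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / n)
  sdv <- sqrt(sst / (n - 1))
  rpd <- if (rmse > 0) sdv / rmse else {
    message("RMSE is zero; RPD reported as +Inf")
    Inf
  }
  band <- if (rpd < 1.4) "poor" else if (rpd < 2) "rough" else "strong"
  list(r2 = r2, rmse = rmse, sd = sdv, rpd = rpd, n = n, rpd_band = band)
}

#' Evaluate a fitted model on a sample set
#'
#' @param model a `carbon_model`.
#' @param data a [paired_samples()].
#' @param split label recorded in the report (`"train"` or `"validation"`).
#' @return List of class `evaluation_report` (see [regression_metrics()]).
#' @export
evaluate_model <- function(model, data, split = "validation") {
  pred <- predict(model, data)
  out <- regression_metrics(data$y, pred)
  out$split <- split
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: n=%d R2=%.3f RMSE=%.4g RPD=%.3f (%s)\n",
              x$split, x$n, x$r2, x$rmse, x$rpd, x$rpd_band))
  invisible(x)
}

#' Observed-vs-predicted table for 1:1-line diagnostics
#'
#' @param model a `carbon_model`.
#' @param data a [paired_samples()].
#' @return Data frame with columns `observed`, `predicted`, `deviation`.
#' @export
one_to_one_table <- function(model, data) {
  pred <- predict(model, data)
  data.frame(observed = data$y, predicted = pred, deviation = pred - data$y)
}

#' Invert a fitted model over a predictor stack
#'
#' Predicts per cell on all unmasked cells, propagates nodata, and clips
#' predictions below `min_value` (physical non-negativity) with a logged
#' count of clipped cells.
#'
#' @param model a `carbon_model`.
#' @param predictors named list of `oc_raster` layers covering the model's
#'   variables.
#' @param min_value lower physical bound; default 0.
#' @return Continuous `oc_raster`; attribute `clipped` counts clipped cells.
#' @export
invert_raster <- function(model, predictors, min_value = 0) {
  missing_layer <- setdiff(model$variables, names(predictors))
  if (length(missing_layer))
    stop("predictor stack lacks layer(s): ",
         paste(missing_layer, collapse = ", "))
  do.call(check_same_grid, unname(predictors[model$variables]))
  ref <- predictors[[model$variables[1L]]]
  n <- length(ref)
  X <- vapply(model$variables, function(nm) as.vector(unclass(predictors[[nm]])),
              numeric(n))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, n)
  if (any(ok)) {
    Xok <- X[ok, , drop = FALSE]
    colnames(Xok) <- model$variables
    out[ok] <- predict(model, Xok)
  }
  clipped <- sum(out < min_value, na.rm = TRUE)
  if (clipped > 0) message(clipped, " cell(s) clipped to ", min_value)
  out[!is.na(out) & out < min_value] <- min_value
  r <- oc_raster(matrix(out, nrow(ref), ncol(ref)), cell_size = cell_size(ref))
  attr(r, "clipped") <- clipped
  r
}

#' Compare models across variable combinations
#'
#' Fits every (variable set, method) pair, evaluates on training and
#' validation splits, and picks the winner by validation R² (ties broken by
#' lower validation RMSE) — the selection logic used for the inversion stage.
#'
#' @param train,val [paired_samples()] splits.
#' @param selections named list of `selection_result`s.
#' @param methods character vector among `"RFR"`, `"SVMR"`.
#' @param seed integer seed forwarded to every fit.
#' @param hyper optional list of per-method hyperparameter overrides.
#' @return List of class `model_comparison`: `table` (one row per pair),
#'   `models` (named list), `best` (name of the winning pair).
#' @export
compare_models <- function(train, val, selections, methods = c("RFR", "SVMR"),
                           seed = 1L, hyper = list()) {
  rows <- list(); models <- list()
  for (set_name in names(selections)) {
    sel <- selections[[set_name]]
    if (length(sel$selected) == 0L) next
    for (m in methods) {
      key <- paste(set_name, m, sep = "-")
      mod <- fit_carbon_model(m, train, sel, hyper = hyper[[m]] %||% list(),
                              seed = seed)
      tr <- evaluate_model(mod, train, "train")
      va <- evaluate_model(mod, val, "validation")
      rows[[key]] <- data.frame(
        set = set_name, method = m, n_vars = length(sel$selected),
        train_r2 = tr$r2, train_rmse = tr$rmse, train_rpd = tr$rpd,
        val_r2 = va$r2, val_rmse = va$rmse, val_rpd = va$rpd,
        val_band = va$rpd_band, stringsAsFactors = FALSE)
      models[[key]] <- mod
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$val_r2, tab$val_rmse)
  best <- rownames(tab)[ord[1L]]
  structure(list(table = tab, models = models, best = best),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> best:", x$best, "\n")
  print(x$table[order(-x$table$val_r2), c("set", "method", "n_vars",
                                          "train_r2", "val_r2", "val_rmse",
                                          "val_rpd", "val_band")],
        digits = 3)
  invisible(x)
}
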