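# closed-form metric oracle, coded independently of regression_metrics()
metric_oracle <- function(z, zhat) {
  n <- length(z)
  zbar <- sum(z) / n
  list(r2 = 1 - sum((z - zhat)^2) / sum((z - zbar)^2),
       rmse = sqrt(sum((z - zhat)^2) / n),
       sd = sqrt(sum((z - zbar)^2) / (n - 1)))
}

test_that("accuracy metrics agree with closed forms on random vectors", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:60, 1L)
    z <- stats::rnorm(n, sd = stats::runif(1, 0.5, 5))
    zhat <- z + stats::rnorm(n)
    m <- regression_metrics(z, zhat)
    o <- metric_oracle(z, zhat)
    expect_equal(m$r2, o$r2, tolerance = 1e-12)
    expect_equal(m$rmse, o$rmse, tolerance = 1e-12)
    expect_equal(m$sd, o$sd, tolerance = 1e-12)
    expect_equal(m$rpd, o$sd / o$rmse, tolerance = 1e-12)
  }
})

test_that("metric corner cases follow their definitions", {
  m <- regression_metrics(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(m$rmse, 0.5, tolerance = 1e-14)
  suppressMessages(perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_identical(perfect$rpd, Inf)
  expect_identical(perfect$rpd_band, "strong")
})

test_that("RPD bands follow the printed cutpoints", {
  mk <- function(rpd) { # observed/predicted pair with a target RPD
    z <- c(-1, 0, 1) * sqrt(3 / 2) # sd = sqrt(3/2)/... construct directly
    z <- c(0, 1, 2, 3)
    sdz <- stats::sd(z)
    rmse <- sdz / rpd
    zhat <- z + rmse * c(1, -1, 1, -1) # rmse exactly as requested
    regression_metrics(z, zhat)
  }
  expect_identical(mk(1.92)$rpd_band, "rough")
  expect_identical(mk(1.2)$rpd_band, "poor")
  expect_identical(mk(2.3)$rpd_band, "strong")
  expect_equal(mk(1.92)$rpd, 1.92, tolerance = 1e-12)
})

test_that("model fits are deterministic and capture planted structure", {
  d <- planted_design(seed = 21, p = 10L, noise_frac = 0.01)
  sel <- selnames <- d$samples$names
  m1 <- fit_carbon_model("RFR", d$samples, selnames, seed = 9L)
  m2 <- fit_carbon_model("RFR", d$samples, selnames, seed = 9L)
  expect_identical(predict(m1, d$samples), predict(m2, d$samples))
  ev <- evaluate_model(m1, d$samples, "train")
  expect_gt(ev$r2, 0.95)
})

test_that("an RBF kernel beats a linear kernel on planted nonlinear data", {
  set.seed(17)
  n <- 200L
  X <- matrix(stats::runif(n * 3, -2, 2), n, 3)
  colnames(X) <- c("a", "b", "c")
  y <- sin(2 * X[, 1]) + X[, 2]^2 + stats::rnorm(n, sd = 0.1)
  tr <- paired_samples(X[1:140, ], y[1:140])
  va <- paired_samples(X[141:200, ], y[141:200])
  rbf <- fit_carbon_model("SVMR", tr, colnames(X), seed = 4L)
  lin <- fit_carbon_model("SVMR", tr, colnames(X),
                          hyper = list(kernel = "linear"), seed = 4L)
  expect_gt(evaluate_model(rbf, va)$r2, evaluate_model(lin, va)$r2)
})

test_that("1:1 tables carry the signed deviation identity", {
  d <- planted_design(seed = 3, p = 8L)
  m <- fit_carbon_model("RFR", d$samples, d$samples$names, seed = 2L)
  tab <- one_to_one_table(m, d$samples)
  expect_identical(nrow(tab), length(d$samples$y))
  expect_equal(mean(tab$deviation), mean(tab$predicted) - mean(tab$observed),
               tolerance = 1e-12)
})

test_that("raster inversion matches tabular prediction and honours the mask", {
  sc <- small_scene()
  pts <- sample_points(sc, 120L, seed = 2L)
  X <- predictor_matrix(sc, pts)
  ps <- paired_samples(X, pts$agb)
  m <- fit_carbon_model("RFR", ps, grep("^inf_", colnames(X), value = TRUE),
                        seed = 6L)
  r <- invert_raster(m, sc$predictors)
  nr <- nrow(unclass(sc$latent_agb))
  idx <- (pts$col - 1L) * nr + pts$row
  expect_equal(unclass(r)[idx], predict(m, ps), tolerance = 1e-10)
  # nodata propagates through the stack
  preds <- sc$predictors
  masked <- unclass(preds[[1L]]); masked[1:5] <- NA
  preds[[1L]] <- oc_raster(masked, cell_size = attr(preds[[1L]], "cell_size"))
  r2 <- invert_raster(m, preds)
  expect_true(all(is.na(unclass(r2)[1:5])))
  expect_error(invert_raster(m, preds[-1L]), "lacks layer")
})

test_that("constant predictors give a constant inversion", {
  d <- planted_design(seed = 41, p = 4L, n = 50L, n_inf = 3L)
  m <- fit_carbon_model("RFR", d$samples, d$samples$names, seed = 1L)
  layers <- lapply(seq_len(4L), function(i) oc_raster(matrix(0.5, 6, 6)))
  names(layers) <- d$samples$names
  r <- invert_raster(m, layers)
  expect_equal(stats::sd(as.vector(unclass(r))), 0)
})

test_that("comparison harness ranks by validation R2 with RMSE tie-break", {
  d <- planted_design(seed = 71, p = 12L)
  sp <- spxy_split(d$samples, 0.7)
  tr <- oasiscarbon:::subset_samples(d$samples, sp$train_idx)
  va <- oasiscarbon:::subset_samples(d$samples, sp$val_idx)
  sels <- list(good = pcc_screen(tr),
               noisy = oasiscarbon:::selection_result(
                 "none", tr$names[10:12],
                 data.frame(name = tr$names[10:12])))
  cmp <- compare_models(tr, va, sels, methods = "RFR", seed = 3L)
  expect_identical(cmp$table[cmp$best, "set"], "good")
  expect_identical(order(-cmp$table$val_r2, cmp$table$val_rmse)[1L],
                   which(rownames(cmp$table) == cmp$best))
})
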