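#' Paired predictor/response samples
#'
#' @param X numeric matrix (n x p) of predictor values, no missing entries.
#' @param y numeric response vector of length n.
#' @param names optional predictor labels (defaults to `colnames(X)`).
#' @return Object of class `paired_samples`.
#' @export
paired_samples <- function(X, y, names = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(names)) names <- sprintf("x%02d", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (nrow(X) < 4L) stop("need at least 4 samples")
  if (ncol(X) < 1L) stop("need at least 1 predictor")
  colnames(X) <- names
  structure(list(X = X, y = as.numeric(y), names = names),
            class = "paired_samples")
}

selection_result <- function(method, selected, diagnostics, empty = FALSE) {
  structure(list(method = method, selected = selected,
                 diagnostics = diagnostics, empty = empty),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d variable(s) selected%s\n",
              x$method, length(x$selected),
              if (x$empty) " (explicit empty set)" else ""))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' SPXY sample set partitioning
#'
#' Splits samples into calibration and validation sets by the joint X-y
#' distance rule descended from Kennard-Stone: pairwise Euclidean distances
#' on min-max-scaled predictors and absolute response differences are each
#' normalised by their maximum, summed, and the training set is grown
#' greedily — seed with the two mutually most distant samples, then
#' repeatedly add the sample whose minimum distance to the chosen set is
#' largest — until `round(n * train_fraction)` samples are selected.
#'
#' @param data a [paired_samples()].
#' @param train_fraction real in (0, 1).
#' @return List of class `spxy_split` with `train_idx`, `val_idx`,
#'   `train_fraction`.
#' @export
spxy_split <- function(data, train_fraction = 0.7) {
  stopifnot(inherits(data, "paired_samples"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  n <- nrow(data$X)
  ntrain <- round(n * train_fraction)
  if (ntrain < 2L) stop("training fraction leaves fewer than 2 samples")
  rng <- apply(data$X, 2L, function(v) diff(range(v)))
  keep <- rng > 0
  Xs <- data$X[, keep, drop = FALSE]
  if (ncol(Xs) == 0L) stop("degenerate data: all predictors are constant")
  Xs <- sweep(sweep(Xs, 2L, apply(Xs, 2L, min)), 2L, rng[keep], "/")
  dx <- as.matrix(stats::dist(Xs))
  dy <- abs(outer(data$y, data$y, "-"))
  if (max(dx) == 0 && max(dy) == 0)
    stop("degenerate data: all samples are identical in X and y")
  D <- (if (max(dx) > 0) dx / max(dx) else dx) +
       (if (max(dy) > 0) dy / max(dy) else dy)
  seedpair <- which(D == max(D), arr.ind = TRUE)[1L, ]
  sel <- sort(unique(as.integer(seedpair)))
  if (length(sel) < 2L) stop("degenerate data: no distinct seed pair")
  while (length(sel) < ntrain) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- apply(D[cand, sel, drop = FALSE], 1L, min)
    sel <- c(sel, cand[which.max(dmin)])
  }
  structure(list(train_idx = sort(sel),
                 val_idx = sort(setdiff(seq_len(n), sel)),
                 train_fraction = train_fraction),
            class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> train %d / validation %d (fraction %.3g)\n",
              length(x$train_idx), length(x$val_idx), x$train_fraction))
  invisible(x)
}

subset_samples <- function(data, idx, vars = NULL) {
  X <- data$X[idx, , drop = FALSE]
  if (!is.null(vars)) X <- X[, vars, drop = FALSE]
  paired_samples(X, data$y[idx])
}

#' Pearson correlation screening
#'
#' Retains predictors whose Pearson correlation with the response is
#' significant under the two-sided t test at level `alpha`, or (if
#' `r_threshold` is given) whose |r| exceeds the threshold. Zero-variance
#' predictors are dropped with a warning.
#'
#' @param data a [paired_samples()].
#' @param alpha two-sided significance level; default 0.05.
#' @param r_threshold optional absolute-correlation cutoff overriding the
#'   significance rule.
#' @return A `selection_result`; diagnostics carry every r and p value.
#' @export
pcc_screen <- function(data, alpha = 0.05, r_threshold = NULL) {
  stopifnot(inherits(data, "paired_samples"))
  n <- nrow(data$X)
  sds <- apply(data$X, 2L, stats::sd)
  if (any(sds == 0))
    warning("dropping zero-variance predictor(s): ",
            paste(data$names[sds == 0], collapse = ", "))
  ok <- sds > 0
  r <- rep(NA_real_, ncol(data$X))
  r[ok] <- as.vector(stats::cor(data$X[, ok, drop = FALSE], data$y))
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!ok] <- NA_real_
  retained <- if (is.null(r_threshold)) !is.na(p) & p < alpha
              else !is.na(r) & abs(r) > r_threshold
  diagnostics <- data.frame(name = data$names, r = r, p = p,
                            retained = retained, stringsAsFactors = FALSE)
  selection_result("pcc", data$names[retained], diagnostics,
                   empty = !any(retained))
}

make_folds <- function(n, nfold, seed) {
  set.seed(seed)
  as.integer(sample(rep_len(seq_len(nfold), n)))
}

cv_rmse_subset <- function(X, y, vars, ncomp, fold) {
  Xi <- X[, vars, drop = FALSE]
  min(.pls_cv_rmse(Xi, y, min(ncomp, ncol(Xi)), fold))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo variable selection driven by partial-least-squares regression
#' coefficients: each run fits PLS on a random subset of samples, ranks
#' variables by absolute standardized coefficient, enforces an exponentially
#' decaying retention ratio (all variables at the first run, two at the
#' last), applies adaptive reweighted sampling among the survivors, and
#' scores the run's variable set by cross-validated RMSE. The set with the
#' smallest RMSECV wins.
#'
#' @param data a [paired_samples()] (normally already PCC-screened).
#' @param runs Monte-Carlo iterations; default 50.
#' @param seed integer seed; all randomness in the routine flows from it.
#' @param sample_ratio fraction of samples drawn per run; default 0.8.
#' @param nfold cross-validation folds; default 5.
#' @param max_ncomp PLS component ceiling; default 10.
#' @return A `selection_result`; diagnostics give per-variable retention
#'   frequency over runs and the RMSECV path.
#' @export
cars_select <- function(data, runs = 50L, seed = 1L, sample_ratio = 0.8,
                        nfold = 5L, max_ncomp = 10L) {
  stopifnot(inherits(data, "paired_samples"))
  if (runs < 10L) stop("`runs` must be at least 10")
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  if (p < 2L)
    return(selection_result("pcc+cars", data$names,
                            data.frame(name = data$names, frequency = 1,
                                       stringsAsFactors = FALSE)))
  set.seed(seed)
  fold <- make_folds(n, nfold, seed + 1L)
  # exponential decay of the retained fraction: p at run 1 -> 2 at run `runs`
  kdec <- log(p / 2) / (runs - 1)
  adec <- exp(kdec)
  active <- seq_len(p)
  m <- max(3L, floor(sample_ratio * n))
  sets <- vector("list", runs)
  rmse <- numeric(runs)
  hits <- integer(p)
  for (i in seq_len(runs)) {
    rows <- sample(n, m)
    beta <- .pls_coef(X[rows, active, drop = FALSE], y[rows],
                      min(max_ncomp, length(active)))
    w <- abs(as.vector(beta))
    keep_n <- max(2L, min(length(active), round(adec * exp(-kdec * i) * p)))
    if (keep_n < length(active)) {
      # forced removal of the clearly weak, then adaptive reweighted
      # sampling (weight-proportional, without replacement) among survivors
      pool_n <- min(length(active), max(keep_n + 1L, ceiling(1.25 * keep_n)))
      pool_ord <- order(w, decreasing = TRUE)[seq_len(pool_n)]
      wp <- pmax(w[pool_ord], 1e-12)
      active <- sort(active[sample(pool_ord, keep_n, prob = wp)])
    } else {
      active <- sort(active)
    }
    sets[[i]] <- active
    rmse[i] <- cv_rmse_subset(X, y, active, max_ncomp, fold)
    hits[active] <- hits[active] + 1L
    if (length(active) <= 2L && i < runs) {
      sets[(i + 1L):runs] <- list(active)
      rmse[(i + 1L):runs] <- rmse[i]
      break
    }
  }
  best <- which.min(rmse)
  sel <- sets[[best]]
  diagnostics <- data.frame(name = data$names,
                            frequency = hits / max(1L, best),
                            stringsAsFactors = FALSE)
  attr(diagnostics, "rmsecv_path") <- rmse
  selection_result("pcc+cars", data$names[sel], diagnostics,
                   empty = length(sel) == 0L)
}

#' Iterative retained information variable selection (IRIV)
#'
#' Rounds of a binary matrix shuffling filter: random variable-inclusion
#' models are fitted by PLS with cross-validation; for each variable the
#' paired difference in RMSECV between models without and with it classifies
#' it as strongly informative, weakly informative, uninformative, or
#' interfering. Uninformative and interfering variables are removed each
#' round until none remain, then a backward elimination on RMSECV returns
#' the final set.
#'
#' @param data a [paired_samples()] (normally already PCC-screened).
#' @param seed integer seed.
#' @param n_models rows of the binary inclusion matrix per round; default 500.
#' @param alpha classification level for the paired comparison; default 0.05.
#' @param nfold cross-validation folds; default 5.
#' @param max_ncomp PLS component ceiling; default 10.
#' @param max_rounds safety cap on filtering rounds; default 15.
#' @return A `selection_result`; diagnostics carry the last-round
#'   classification of every input variable.
#' @export
iriv_select <- function(data, seed = 1L, n_models = 500L, alpha = 0.05,
                        nfold = 5L, max_ncomp = 10L, max_rounds = 15L) {
  stopifnot(inherits(data, "paired_samples"))
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  fold <- make_folds(n, nfold, seed + 1L)
  active <- seq_len(p)
  class_last <- rep("uninformative", p)
  for (round in seq_len(max_rounds)) {
    pa <- length(active)
    if (pa <= 2L) break
    M <- matrix(stats::rbinom(n_models * pa, 1L, 0.5), n_models, pa)
    bad <- rowSums(M) < 2L
    if (any(bad)) M[bad, ] <- 1L
    Xa <- X[, active, drop = FALSE]
    rmse0 <- .pls_cv_rmse_rows(Xa, y, M, max_ncomp, fold)
    classes <- character(pa)
    dmean <- numeric(pa)
    for (j in seq_len(pa)) {
      Mj <- M
      Mj[, j] <- 1L - Mj[, j]
      ok <- rowSums(Mj) >= 2L
      rmse1 <- rep(NA_real_, n_models)
      rmse1[ok] <- .pls_cv_rmse_rows(Xa, y, Mj[ok, , drop = FALSE],
                                     max_ncomp, fold)
      with_j <- ifelse(M[, j] == 1L, rmse0, rmse1)
      without_j <- ifelse(M[, j] == 1L, rmse1, rmse0)
      keep <- is.finite(with_j) & is.finite(without_j)
      d <- without_j[keep] - with_j[keep]
      dmean[j] <- mean(d)
      pval <- tryCatch(stats::t.test(d)$p.value, error = function(e) 1)
      classes[j] <- if (dmean[j] > 0 && pval < alpha) "strong"
        else if (dmean[j] > 0) "weak"
        else if (pval < alpha) "interfering"
        else "uninformative"
    }
    class_last[active] <- classes
    drop_j <- classes %in% c("uninformative", "interfering")
    if (!any(drop_j)) break
    if (all(drop_j)) {
      # nothing informative survives this round
      active <- integer(0)
      break
    }
    active <- active[!drop_j]
  }
  # backward elimination on RMSECV
  if (length(active) > 1L) {
    current <- active
    best_rmse <- cv_rmse_subset(X, y, current, max_ncomp, fold)
    repeat {
      if (length(current) <= 1L) break
      trial <- vapply(seq_along(current), function(j)
        cv_rmse_subset(X, y, current[-j], max_ncomp, fold), numeric(1))
      jbest <- which.min(trial)
      if (trial[jbest] < best_rmse) {
        best_rmse <- trial[jbest]
        current <- current[-jbest]
      } else break
    }
    active <- current
  }
  diagnostics <- data.frame(name = data$names, classification = class_last,
                            retained = seq_len(p) %in% active,
                            stringsAsFactors = FALSE)
  selection_result("pcc+iriv", data$names[sort(active)], diagnostics,
                   empty = length(active) == 0L)
}

#' Build the four standard variable combinations
#'
#' Set I is all variables; set II the PCC screen; set III PCC+CARS; set IV
#' PCC+IRIV — the combinations compared in the model-selection harness.
#'
#' @param data training-set [paired_samples()].
#' @param seed integer seed shared by the stochastic selectors.
#' @param alpha PCC screening level.
#' @param cars_runs,iriv_models forwarded to [cars_select()] / [iriv_select()].
#' @return Named list of `selection_result`s (`set_I` .. `set_IV`).
#' @export
variable_combinations <- function(data, seed = 1L, alpha = 0.05,
                                  cars_runs = 50L, iriv_models = 500L) {
  all_sel <- selection_result("none", data$names,
                              data.frame(name = data$names,
                                         stringsAsFactors = FALSE))
  pcc <- pcc_screen(data, alpha = alpha)
  screened_names <- if (length(pcc$selected)) pcc$selected else data$names
  screened <- subset_samples(data, seq_len(nrow(data$X)), screened_names)
  cars <- cars_select(screened, runs = cars_runs, seed = seed)
  cars$method <- "pcc+cars"
  iriv <- iriv_select(screened, seed = seed, n_models = iriv_models)
  iriv$method <- "pcc+iriv"
  list(set_I = all_sel, set_II = pcc, set_III = cars, set_IV = iriv)
}
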