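#' Discretize a continuous variable into strata
#'
#' The five classification methods used when optimising geodetector
#' parameters: equal-width intervals, equal-frequency quantiles,
#' Fisher-Jenks natural breaks (exact dynamic program), a geometric
#' progression of interval widths, and mean ± standard-deviation bands.
#'
#' @param values numeric vector (no NA).
#' @param method one of `"equal"`, `"quantile"`, `"natural_breaks"`,
#'   `"geometric"`, `"sd"`.
#' @param k number of classes (k ≥ 2).
#' @param jenks_sample natural-breaks inputs longer than this are thinned to
#'   this many quantile-spaced points before the exact dynamic program;
#'   default 1024.
#' @return Integer stratum labels in 1..k (empty classes collapsed), with
#'   attribute `breaks` (interior cut points, strictly increasing).
#' @export
discretize <- function(values, method = c("equal", "quantile",
                                          "natural_breaks", "geometric", "sd"),
                       k, jenks_sample = 1024L) {
  method <- match.arg(method)
  if (k < 2L) stop("k must be at least 2")
  if (anyNA(values)) stop("values must not contain NA")
  ux <- unique(values)
  if (length(ux) < k)
    stop(sprintf("only %d distinct values; choose k <= %d",
                 length(ux), length(ux)))
  rng <- range(values)
  breaks <- switch(method,
    equal = seq(rng[1L], rng[2L], length.out = k + 1L)[2L:k],
    quantile = {
      b <- stats::quantile(values, probs = seq_len(k - 1L) / k, names = FALSE)
      unique(b)
    },
    natural_breaks = {
      x <- sort(values)
      if (length(x) > jenks_sample)
        x <- stats::quantile(x, probs = seq(0, 1, length.out = jenks_sample),
                             names = FALSE, type = 7)
      ends <- .fisher_jenks(x, k)
      ends <- ends[-length(ends)]
      unique((x[ends] + x[pmin(ends + 1L, length(x))]) / 2)
    },
    geometric = {
      lo <- rng[1L]; hi <- rng[2L]
      shift <- if (lo <= 0) 1 - lo else 0
      g <- (lo + shift) * ((hi + shift) / (lo + shift))^(seq_len(k - 1L) / k)
      unique(g - shift)
    },
    sd = {
      m <- mean(values); s <- stats::sd(values)
      b <- m + s * (seq_len(k - 1L) - k / 2)
      unique(b[b > rng[1L] & b < rng[2L]])
    })
  breaks <- sort(unique(breaks))
  if (length(breaks) < 1L)
    stop("method '", method, "' produced no usable breaks; try smaller k")
  lab <- findInterval(values, breaks) + 1L
  lab <- as.integer(factor(lab)) # collapse empty classes
  attr(lab, "breaks") <- breaks
  lab
}

#' Geodetector q statistic
#'
#' The explanatory power of a stratification for a response's spatial
#' heterogeneity: q = 1 − Σ A_i σ_i² / (A σ²) over strata i, with
#' population (divisor N) variances — equivalently 1 − SSW/SST.
#'
#' @param response numeric vector.
#' @param strata stratum labels (coercible to factor), same length.
#' @return List of class `q_computation`: `q`, `n_strata`, `stratum_counts`,
#'   `stratum_variances` (population), `overall_count`, `overall_variance`,
#'   `p_value` (NA until [q_significance()]), plus the data for permutation.
#' @export
q_statistic <- function(response, strata) {
  if (length(response) != length(strata)) stop("length mismatch")
  f <- factor(strata)
  if (nlevels(f) < 2L) stop("need at least 2 strata")
  n <- length(response)
  mu <- mean(response)
  sst <- sum((response - mu)^2)
  if (sst == 0) stop("q undefined: overall variance is zero")
  cnt <- as.vector(table(f))
  ssw_i <- as.vector(tapply(response, f,
                            function(v) sum((v - mean(v))^2)))
  q <- 1 - sum(ssw_i) / sst
  structure(list(q = q, n_strata = nlevels(f), stratum_counts = cnt,
                 stratum_variances = ssw_i / cnt,
                 overall_count = n, overall_variance = sst / n,
                 p_value = NA_real_,
                 response = response, strata = f),
            class = "q_computation")
}

#' @export
print.q_computation <- function(x, ...) {
  cat(sprintf("<q_computation> q=%.4f over %d strata (n=%d)%s\n",
              x$q, x$n_strata, x$overall_count,
              if (!is.na(x$p_value)) sprintf(", p=%.4g", x$p_value) else ""))
  invisible(x)
}

#' Permutation significance of a q statistic
#'
#' Permutes stratum labels (fixed stratum sizes) and recomputes q;
#' p = (1 + #{q* ≥ q}) / (1 + permutations).
#'
#' @param comp a [q_statistic()] result.
#' @param permutations number of label permutations (≥ 99); default 999.
#' @param seed integer seed.
#' @return The `q_computation` with `p_value` filled in.
#' @export
q_significance <- function(comp, permutations = 999L, seed = 1L) {
  stopifnot(inherits(comp, "q_computation"))
  if (permutations < 99L) stop("use at least 99 permutations")
  y <- comp$response
  f <- comp$strata
  n <- length(y)
  mu <- mean(y)
  sst <- sum((y - mu)^2)
  cnt <- comp$stratum_counts
  set.seed(seed)
  idx <- as.integer(f)
  exceed <- 0L
  y2 <- y^2
  for (b in seq_len(permutations)) {
    pi <- idx[sample.int(n)]
    gs <- rowsum(y, pi)
    g2 <- rowsum(y2, pi)
    ssw <- sum(g2 - gs^2 / cnt[as.integer(rownames(gs))])
    if (1 - ssw / sst >= comp$q - 1e-12) exceed <- exceed + 1L
  }
  comp$p_value <- (1 + exceed) / (1 + permutations)
  comp
}

#' Optimise the discretization of a driver
#'
#' Evaluates every (method, k) pair on the grid, computes q against the
#' response for each, and returns the spec with the largest q (ties: smaller
#' k, then method order as supplied).
#'
#' @param driver numeric vector (continuous driver values).
#' @param response numeric response vector, same length.
#' @param methods candidate methods; default all five.
#' @param k_range candidate class counts; default 3:8.
#' @return List of class `discretization_spec`: `method`, `k`, `breaks`,
#'   `q`, `labels`, and the full `grid` of attempted pairs.
#' @export
optimize_discretization <- function(driver, response,
                                    methods = c("equal", "quantile",
                                                "natural_breaks", "geometric",
                                                "sd"),
                                    k_range = 3:8) {
  grid <- expand.grid(method = methods, k = k_range,
                      stringsAsFactors = FALSE)
  grid$q <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    lab <- tryCatch(discretize(driver, grid$method[g], grid$k[g]),
                    error = function(e) NULL)
    if (is.null(lab) || length(unique(lab)) < 2L) next
    qc <- tryCatch(q_statistic(response, lab), error = function(e) NULL)
    if (is.null(qc)) next
    grid$q[g] <- qc$q
    better <- is.null(best) || qc$q > best$q + 1e-15 ||
      (abs(qc$q - best$q) <= 1e-15 &&
         (grid$k[g] < best$k ||
            (grid$k[g] == best$k &&
               match(grid$method[g], methods) < match(best$method, methods))))
    if (better)
      best <- list(method = grid$method[g], k = grid$k[g],
                   breaks = attr(lab, "breaks"), q = qc$q, labels = lab)
  }
  if (is.null(best)) stop("no feasible (method, k) pair on the grid")
  best$grid <- grid
  class(best) <- "discretization_spec"
  best
}

#' @export
print.discretization_spec <- function(x, ...) {
  cat(sprintf("<discretization_spec> %s, k=%d, q=%.4f\n",
              x$method, x$k, x$q))
  invisible(x)
}

band_q <- function(q) {
  ifelse(q >= 0.3, "main",
         ifelse(q >= 0.2, "strong",
                ifelse(q >= 0.1, "medium", "weak")))
}

driver_values <- function(d, idx) {
  if (inherits(d, "oc_raster")) as.vector(unclass(d))[idx] else d[idx]
}

#' Factor detection over a set of drivers
#'
#' For each driver, continuous drivers are discretized by
#' [optimize_discretization()] and categorical drivers used as-is; the q
#' statistic against the response is computed with permutation significance,
#' banded by the standard cutpoints (q ≥ 0.3 main, ≥ 0.2 strong, ≥ 0.1
#' medium, else weak influence) and ranked by q.
#'
#' @param response continuous `oc_raster` (or numeric vector).
#' @param drivers named list of `oc_raster`s (or vectors).
#' @param categorical names of drivers to use as pre-stratified classes.
#' @param methods,k_range forwarded to [optimize_discretization()].
#' @param permutations,seed forwarded to [q_significance()].
#' @param stride sample every `stride`-th cell of the analysis grid;
#'   default 1 (every cell).
#' @return List of class `factor_detection`: `table` (name, q, p, band,
#'   method, k, ranked by q descending) and `strata` (named list of the
#'   stratum labels used, for interaction detection).
#' @export
factor_detect <- function(response, drivers, categorical = "ST",
                          methods = c("equal", "quantile", "natural_breaks",
                                      "geometric", "sd"),
                          k_range = 3:8, permutations = 999L, seed = 1L,
                          stride = 1L) {
  yv <- if (inherits(response, "oc_raster")) as.vector(unclass(response))
        else as.numeric(response)
  idx <- which(!is.na(yv))
  if (stride > 1L) idx <- idx[seq(1L, length(idx), by = stride)]
  y <- yv[idx]
  rows <- list(); strata <- list()
  for (nm in names(drivers)) {
    dv <- driver_values(drivers[[nm]], idx)
    ok <- !is.na(dv)
    if (nm %in% categorical) {
      lab <- as.integer(factor(dv[ok]))
      method <- "categorical"; kk <- length(unique(lab))
      if (kk < 2L) {
        warning("driver ", nm, " has a single stratum; excluded")
        next
      }
      qc <- q_statistic(y[ok], lab)
    } else {
      spec <- tryCatch(
        optimize_discretization(dv[ok], y[ok], methods, k_range),
        error = function(e) NULL)
      if (is.null(spec)) {
        warning("driver ", nm, " could not be discretized; excluded")
        next
      }
      lab <- spec$labels; method <- spec$method; kk <- spec$k
      qc <- q_statistic(y[ok], lab)
    }
    qc <- q_significance(qc, permutations = permutations,
                         seed = seed + match(nm, names(drivers)))
    rows[[nm]] <- data.frame(name = nm, q = qc$q, p = qc$p_value,
                             band = band_q(qc$q), method = method, k = kk,
                             stringsAsFactors = FALSE)
    full <- rep(NA_integer_, length(y))
    full[ok] <- lab
    strata[[nm]] <- full
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$q), ]
  rownames(tab) <- NULL
  structure(list(table = tab, strata = strata, response = y),
            class = "factor_detection")
}

#' @export
print.factor_detection <- function(x, ...) {
  cat("<factor_detection>\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

classify_interaction <- function(q1, q2, q12, eps = 1e-9) {
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (abs(q12 - (q1 + q2)) <= eps) "independent"
  else if (q12 > q1 + q2) "nonlinear_enhance"
  else if (q12 > hi + eps) "bivariate_enhance"
  else if (q12 >= lo - eps) "univariate_weaken"
  else "nonlinear_weaken"
}

#' Interaction detection for a driver pair
#'
#' Computes q on the cross-product strata of two (discretized) drivers and
#' categorises the joint explanatory power against the single-factor q
#' values: below both weakens nonlinearly; between them weakens one factor;
#' above both but below their sum enhances bivariately; equal to the sum is
#' independence; above the sum enhances nonlinearly. Empty cross strata are
#' dropped.
#'
#' @param response numeric response vector.
#' @param s1,s2 stratum label vectors for the two drivers (same length as
#'   response), e.g. from [factor_detect()]'s `strata`.
#' @param eps boundary tolerance; default 1e-9.
#' @return List of class `interaction_result`: `q1`, `q2`, `q12`, `category`.
#' @export
interaction_detect <- function(response, s1, s2, eps = 1e-9) {
  ok <- !is.na(s1) & !is.na(s2) & !is.na(response)
  y <- response[ok]
  q1 <- q_statistic(y, s1[ok])$q
  q2 <- q_statistic(y, s2[ok])$q
  cross <- interaction(factor(s1[ok]), factor(s2[ok]), drop = TRUE)
  q12 <- q_statistic(y, cross)$q
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 category = classify_interaction(q1, q2, q12, eps)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> q1=%.4f q2=%.4f q12=%.4f -> %s\n",
              x$q1, x$q2, x$q12, x$category))
  invisible(x)
}

#' All pairwise interactions from a factor-detection result
#'
#' @param detection a [factor_detect()] result.
#' @return Data frame: `d1`, `d2`, `q1`, `q2`, `q12`, `category` for every
#'   unordered driver pair.
#' @export
interaction_matrix <- function(detection) {
  stopifnot(inherits(detection, "factor_detection"))
  nms <- names(detection$strata)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    ir <- interaction_detect(detection$response,
                             detection$strata[[nms[i]]],
                             detection$strata[[nms[j]]])
    rows[[paste(nms[i], nms[j])]] <- data.frame(
      d1 = nms[i], d2 = nms[j], q1 = ir$q1, q2 = ir$q2, q12 = ir$q12,
      category = ir$category, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
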