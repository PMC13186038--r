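#' Configuration for a synthetic oasis scene
#'
#' Defines the study conditions the generator emulates: grid geometry, epochs
#' and scenarios, target land-use areal fractions, the marginal ranges and
#' per-class means of aboveground biomass (AGB, g·m⁻²) and soil organic
#' carbon (SOC, g·kg⁻¹), the predictor-stack layout, observation noise, and
#' the seed. Defaults follow the statistical structure of an arid fan-shaped
#' oasis: a vegetated core grading into desert, strongly right-skewed AGB
#' with a prevalence of low values, and per-class mean ordering
#' garden > arable > forest-grassland > unused for both AGB and SOC.
#'
#' @param grid_rows,grid_cols positive integers; default 200 x 200.
#' @param cell_size metres per pixel edge; default 10.
#' @param years character vector of historical epoch labels.
#' @param scenarios named character vector: scenario label -> projected epoch.
#' @param lu_fractions named numeric vector over AR, GA, FO, CO, WA, UN
#'   summing to 1: target areal fractions of the base (first-epoch) map.
#' @param agb_range,soc_range length-2 positive increasing numeric vectors.
#' @param lu_mean_agb,lu_mean_soc named numeric vectors of per-class target
#'   means (g·m⁻² and g·kg⁻¹).
#' @param n_predictors,n_informative predictor stack layout; informative
#'   layers are transforms of the latent AGB field.
#' @param noise_sd relative observation noise (coefficient of variation) on
#'   sampled AGB/SOC; default 0.10.
#' @param epoch_drift per-epoch areal drift applied cumulatively to
#'   `lu_fractions` for successive historical years (named over classes).
#' @param scenario_drift named list: per-scenario areal drift applied to the
#'   final historical epoch's fractions for the projected year.
#' @param seed integer master seed.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 200L, grid_cols = 200L, cell_size = 10,
                         years = c("2010", "2013", "2016", "2019", "2022"),
                         scenarios = c(EPS = "2028", NDS = "2028",
                                       CDS = "2028", EDS = "2028"),
                         lu_fractions = c(AR = 0.30, GA = 0.10, FO = 0.20,
                                          CO = 0.05, WA = 0.03, UN = 0.32),
                         agb_range = c(5.83, 3416.5),
                         soc_range = c(0.67, 10.20),
                         lu_mean_agb = c(AR = 750, GA = 1100, FO = 450,
                                         CO = 180, WA = 8, UN = 120),
                         lu_mean_soc = c(AR = 5.0, GA = 7.0, FO = 4.0,
                                         CO = 3.0, WA = 1.5, UN = 2.3),
                         n_predictors = 44L, n_informative = 5L,
                         noise_sd = 0.10,
                         epoch_drift = c(AR = 0.010, GA = 0.006, FO = -0.004,
                                         CO = 0.002, WA = 0, UN = -0.014),
                         scenario_drift = list(
                           EPS = c(AR = 0.00, GA = 0.00, FO = 0.030,
                                   CO = 0.005, WA = 0, UN = -0.035),
                           NDS = c(AR = 0.010, GA = 0.006, FO = -0.004,
                                   CO = 0.008, WA = 0, UN = -0.020),
                           CDS = c(AR = 0.040, GA = 0.005, FO = -0.025,
                                   CO = 0.005, WA = 0, UN = -0.025),
                           EDS = c(AR = 0.005, GA = 0.000, FO = -0.020,
                                   CO = 0.030, WA = 0, UN = -0.015)),
                         seed = 42L) {
  cls <- lu_names()
  stopifnot(grid_rows >= 10, grid_cols >= 10, cell_size > 0)
  if (!setequal(names(lu_fractions), cls))
    stop("`lu_fractions` must be named over ", paste(cls, collapse = ", "))
  lu_fractions <- lu_fractions[cls]
  if (abs(sum(lu_fractions) - 1) > 1e-9)
    stop("`lu_fractions` must sum to 1 (got ", sum(lu_fractions), ")")
  if (any(lu_fractions < 0)) stop("`lu_fractions` must be non-negative")
  for (rg in list(agb_range, soc_range))
    if (length(rg) != 2L || any(rg <= 0) || rg[1L] >= rg[2L])
      stop("ranges must be positive and increasing")
  if (!all(cls %in% names(lu_mean_agb)) || !all(cls %in% names(lu_mean_soc)))
    stop("per-class means must cover all six classes")
  zero_cls <- cls[lu_fractions == 0]
  veg <- c("AR", "GA", "FO", "UN")
  if (any(zero_cls %in% veg) && any(lu_mean_agb[intersect(zero_cls, veg)] > 0))
    stop("configuration error: zero-area class ",
         paste(intersect(zero_cls, veg), collapse = ","),
         " requested with nonzero mean constraints")
  if (n_informative > n_predictors)
    stop("`n_informative` must not exceed `n_predictors`")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, years = years, scenarios = scenarios,
                 lu_fractions = lu_fractions,
                 agb_range = agb_range, soc_range = soc_range,
                 lu_mean_agb = lu_mean_agb[cls], lu_mean_soc = lu_mean_soc[cls],
                 n_predictors = as.integer(n_predictors),
                 n_informative = as.integer(n_informative),
                 noise_sd = noise_sd, epoch_drift = epoch_drift[cls],
                 scenario_drift = scenario_drift, seed = as.integer(seed)),
            class = "scene_config")
}

# Smooth a white-noise matrix with a separable Gaussian kernel (edge-renormalised).
smooth_field <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], half), v, rep(v[n], half))
    stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
  }
  m <- apply(m, 2L, pad_filter)
  t(apply(t(m), 2L, pad_filter))
}

standardize_mat <- function(m) {
  v <- as.vector(m)
  (m - mean(v)) / stats::sd(v)
}

# Assign classes along a suitability ranking so areal fractions are exact
# (up to integer rounding). High suitability -> oasis-interior classes.
assign_lu <- function(suit, fractions) {
  cls_order <- c("GA", "AR", "CO", "FO", "WA", "UN") # interior -> fringe
  n <- length(suit)
  counts <- floor(fractions[cls_order] * n)
  rem <- n - sum(counts)
  if (rem > 0) { # distribute remainder by largest fractional part
    fp <- fractions[cls_order] * n - counts
    add <- order(fp, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  rk <- rank(-suit, ties.method = "first") # 1 = most suitable
  lu <- integer(n)
  lo <- 0L
  for (cl in cls_order) {
    k <- counts[[cl]]
    if (k > 0L) lu[rk > lo & rk <= lo + k] <- lu_codes()[[cl]]
    lo <- lo + k
  }
  lu
}

#' Generate a synthetic oasis scene
#'
#' Builds a seeded, fully deterministic scene: multi-epoch land-use maps with
#' controlled areal fractions and fringe transitions, latent AGB and SOC
#' fields with an oasis-core-to-desert gradient and right-skewed AGB
#' marginals, a named predictor stack, a regional climate series, and nine
#' driver rasters (AAT, AP, PET, EL, SL, VC, ST, PD, GDP; ST categorical).
#' Vegetation cover (VC) is constructed as the driver most strongly coupled
#' to the latent carbon field, so downstream driver detection has a known
#' planted answer.
#'
#' @param config a [scene_config()].
#' @return A list of class `synthetic_scene` with elements `lu_maps` (named
#'   list of categorical `oc_raster`s; projected epochs keyed
#'   `"<year>_<scenario>"`), `latent_agb`, `latent_soc` (`oc_raster`),
#'   `predictors` (named list of `oc_raster` layers), `climate` (data frame:
#'   epoch, temperature_c, precipitation_mm, scenario), `drivers` (named list
#'   of `oc_raster`), and `provenance` (the config).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  cls <- lu_names()
  set.seed(config$seed)

  # oasis gradient: elliptical core offset to the upper (fan apex) side
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy <- 0.42 * nr; cx <- 0.50 * nc
  d2 <- ((rows - cy) / (0.55 * nr))^2 + ((cols - cx) / (0.50 * nc))^2
  gradient <- exp(-1.6 * d2) # 1 at core, ->0 in desert

  field_u <- standardize_mat(smooth_field(matrix(stats::rnorm(n), nr, nc),
                                          sigma = max(2, nr / 28)))
  suit <- standardize_mat(0.85 * standardize_mat(gradient) + 0.35 * field_u)

  lu_base <- assign_lu(as.vector(suit), config$lu_fractions)

  # multi-epoch LU maps: drift class-area targets along the suitability
  # ranking with small seeded boundary noise -> fringe transitions
  clamp_fractions <- function(f) {
    f <- pmax(f, 0)
    f / sum(f)
  }
  epochs <- config$years
  lu_maps <- vector("list", length(epochs))
  names(lu_maps) <- epochs
  fr <- config$lu_fractions
  for (i in seq_along(epochs)) {
    if (i > 1L) fr <- clamp_fractions(fr + config$epoch_drift)
    wob <- standardize_mat(smooth_field(matrix(stats::rnorm(n), nr, nc),
                                        sigma = max(2, nr / 40)))
    suit_t <- as.vector(suit) + 0.06 * as.vector(wob)
    lu_maps[[i]] <- oc_raster(matrix(assign_lu(suit_t, fr), nr, nc),
                              cell_size = config$cell_size, categorical = TRUE)
  }
  fr_last <- fr
  for (sc in names(config$scenarios)) {
    yr <- config$scenarios[[sc]]
    frs <- clamp_fractions(fr_last + config$scenario_drift[[sc]])
    wob <- standardize_mat(smooth_field(matrix(stats::rnorm(n), nr, nc),
                                        sigma = max(2, nr / 40)))
    suit_t <- as.vector(suit) + 0.06 * as.vector(wob)
    key <- paste0(yr, "_", sc)
    lu_maps[[key]] <- oc_raster(matrix(assign_lu(suit_t, frs), nr, nc),
                                cell_size = config$cell_size, categorical = TRUE)
  }

  # latent AGB: per-class lognormal multiplied onto the class target mean,
  # spatially correlated through a shared standardized field; right-skewed
  ref_year <- config$years[which(config$years == "2019")]
  if (length(ref_year) == 0L) ref_year <- config$years[length(config$years)]
  lu_ref <- as.vector(unclass(lu_maps[[ref_year]]))
  zf <- 0.6 * as.vector(standardize_mat(
    smooth_field(matrix(stats::rnorm(n), nr, nc), sigma = max(2, nr / 35)))) +
    0.8 * stats::rnorm(n)
  zf <- (zf - mean(zf)) / stats::sd(zf)
  sdlog <- 0.85
  mult <- exp(sdlog * zf - sdlog^2 / 2)
  mean_agb <- config$lu_mean_agb[cls][lu_ref]
  agb <- pmin(pmax(mean_agb * mult, config$agb_range[1L]), config$agb_range[2L])
  latent_agb <- oc_raster(matrix(agb, nr, nc), cell_size = config$cell_size)

  # latent SOC: truncated normal per class, correlated with the AGB field
  zs <- 0.7 * zf + sqrt(1 - 0.7^2) * stats::rnorm(n)
  mean_soc <- config$lu_mean_soc[cls][lu_ref]
  soc <- pmin(pmax(mean_soc + 1.3 * zs, config$soc_range[1L]),
              config$soc_range[2L])
  latent_soc <- oc_raster(matrix(soc, nr, nc), cell_size = config$cell_size)

  climate <- default_climate(config)

  scene <- structure(list(lu_maps = lu_maps, latent_agb = latent_agb,
                          latent_soc = latent_soc, predictors = NULL,
                          climate = climate, drivers = NULL,
                          provenance = config),
                     class = "synthetic_scene")
  scene$predictors <- make_predictors(scene, config)
  scene$drivers <- make_drivers(scene, config)
  scene
}

# Regional mean climate per epoch; projected epochs follow their matched SSP.
default_climate <- function(config) {
  hist_t <- c(11.0, 11.2, 11.4, 11.6, 11.9)
  hist_p <- c(62, 58, 73, 70, 66)
  ny <- length(config$years)
  tt <- hist_t[seq_len(min(ny, 5L))]
  pp <- hist_p[seq_len(min(ny, 5L))]
  if (ny > 5L) { tt <- c(tt, rep(11.9, ny - 5L)); pp <- c(pp, rep(66, ny - 5L)) }
  out <- data.frame(epoch = config$years, temperature_c = tt,
                    precipitation_mm = pp, scenario = "historical",
                    stringsAsFactors = FALSE)
  ssp_t <- c(SSP126 = 12.1, SSP245 = 12.3, SSP370 = 12.6, SSP585 = 12.9)
  ssp_p <- c(SSP126 = 78, SSP245 = 74, SSP370 = 70, SSP585 = 64)
  for (sc in names(config$scenarios)) {
    ssp <- scenario_match(sc)
    out <- rbind(out, data.frame(
      epoch = paste0(config$scenarios[[sc]], "_", sc),
      temperature_c = ssp_t[[ssp]], precipitation_mm = ssp_p[[ssp]],
      scenario = ssp, stringsAsFactors = FALSE))
  }
  out
}

#' Build the predictor raster stack
#'
#' Produces `n_predictors` named layers. The first `n_informative` are
#' monotone or smooth transforms of the latent AGB field with additive noise
#' (`noise_sd` relative to each layer's spread); an equally sized block
#' carries transforms of the latent SOC field (the stack serves both
#' inversions, as soil-relevant covariates do in practice); a further block
#' is nuisance correlated with the oasis gradient, and the remainder is pure
#' spatial noise. Layer names encode the block (`inf_*`, `sol_*`, `nui_*`,
#' `rnd_*`).
#'
#' @param scene a `synthetic_scene` (latent fields present).
#' @param config the matching [scene_config()].
#' @return Named list of `oc_raster` layers.
#' @export
make_predictors <- function(scene, config = scene$provenance) {
  agb <- as.vector(unclass(scene$latent_agb))
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  p <- config$n_predictors; ni <- config$n_informative
  transforms <- list(function(a) a,
                     function(a) sqrt(a),
                     function(a) log(a),
                     function(a) a^0.7,
                     function(a) -a,
                     function(a) a + 0.3 * sqrt(a) * stats::sd(a) / stats::sd(sqrt(a)),
                     function(a) log1p(a)^2,
                     function(a) -sqrt(a))
  layers <- vector("list", p)
  nms <- character(p)
  for (j in seq_len(ni)) {
    f <- transforms[[((j - 1L) %% length(transforms)) + 1L]]
    v <- f(agb)
    v <- v + stats::rnorm(n, sd = config$noise_sd * stats::sd(v))
    layers[[j]] <- oc_raster(matrix(v, nr, nc), cell_size = config$cell_size)
    nms[j] <- sprintf("inf_%02d", j)
  }
  soc <- as.vector(unclass(scene$latent_soc))
  ns <- min(ni, p - ni)
  if (ns > 0L) for (j in seq_len(ns)) {
    f <- transforms[[((j - 1L) %% length(transforms)) + 1L]]
    v <- f(soc)
    v <- v + stats::rnorm(n, sd = config$noise_sd * stats::sd(v))
    layers[[ni + j]] <- oc_raster(matrix(v, nr, nc), cell_size = config$cell_size)
    nms[ni + j] <- sprintf("sol_%02d", j)
  }
  ni <- ni + ns
  n_nui <- min(p - ni, max(0L, (p - ni) %/% 2L))
  grad <- standardize_mat(smooth_field(matrix(stats::rnorm(n), nr, nc),
                                       sigma = max(2, nr / 30)))
  if (n_nui > 0L) for (j in seq_len(n_nui)) {
    v <- 0.6 * as.vector(grad) + stats::rnorm(n, sd = 0.8)
    layers[[ni + j]] <- oc_raster(matrix(v, nr, nc), cell_size = config$cell_size)
    nms[ni + j] <- sprintf("nui_%02d", j)
  }
  n_rnd <- p - ni - n_nui
  if (n_rnd > 0L) for (j in seq_len(n_rnd)) {
    v <- stats::rnorm(n)
    layers[[ni + n_nui + j]] <- oc_raster(matrix(v, nr, nc),
                                          cell_size = config$cell_size)
    nms[ni + n_nui + j] <- sprintf("rnd_%02d", j)
  }
  names(layers) <- nms
  layers
}

# Nine driver rasters; vegetation cover (VC) is the planted dominant driver.
make_drivers <- function(scene, config = scene$provenance) {
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  agb <- as.vector(unclass(scene$latent_agb))
  carbon_proxy <- standardize_mat(matrix(log(agb), nr, nc))
  smooth01 <- function(sigma) standardize_mat(
    smooth_field(matrix(stats::rnorm(n), nr, nc), sigma = sigma))
  mk <- function(m) oc_raster(m, cell_size = config$cell_size)

  vc_raw <- 0.95 * as.vector(carbon_proxy) + 0.25 * stats::rnorm(n)
  vc <- (vc_raw - min(vc_raw)) / (max(vc_raw) - min(vc_raw)) # fractional cover

  mix <- function(w, sigma) {
    w * as.vector(carbon_proxy) + sqrt(max(0, 1 - w^2)) * as.vector(smooth01(sigma))
  }
  aat <- 11.5 - 1.2 * mix(0.30, nr / 20)          # degC, cooler in the core
  ap  <- 65 + 9 * mix(0.35, nr / 22)              # mm
  pet <- 1450 - 110 * mix(0.40, nr / 25)          # mm
  el  <- 1000 - 45 * mix(0.25, nr / 15)           # m
  sl  <- pmax(0, 1.8 + 1.1 * mix(-0.15, nr / 18)) # degrees
  pd  <- exp(1.2 * mix(0.40, nr / 24))            # persons km^-2 (relative)
  gdp <- exp(1.1 * mix(0.35, nr / 26))            # CNY km^-2 (relative)
  st_cont <- mix(0.30, nr / 16)
  st <- findInterval(st_cont, stats::quantile(st_cont, c(0.2, 0.4, 0.6, 0.8))) + 1L

  list(AAT = mk(matrix(aat, nr, nc)), AP = mk(matrix(ap, nr, nc)),
       PET = mk(matrix(pet, nr, nc)), EL = mk(matrix(el, nr, nc)),
       SL = mk(matrix(sl, nr, nc)), VC = mk(matrix(vc, nr, nc)),
       ST = oc_raster(matrix(st, nr, nc), cell_size = config$cell_size,
                      categorical = TRUE),
       PD = mk(matrix(pd, nr, nc)), GDP = mk(matrix(gdp, nr, nc)))
}

#' Sample field points from a scene
#'
#' Draws `n` distinct unmasked cells uniformly at random and reads AGB and
#' SOC from the latent fields with multiplicative Gaussian observation noise
#' (`noise_sd` of the config, a coefficient of variation).
#'
#' @param scene a `synthetic_scene`.
#' @param n number of points.
#' @param seed integer seed for this draw.
#' @return Data frame with columns `x`, `y` (cell-centre metres), `row`,
#'   `col`, `lu` (class label), `agb`, `soc`.
#' @export
sample_points <- function(scene, n, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  config <- scene$provenance
  lu_ref_name <- if ("2019" %in% names(scene$lu_maps)) "2019" else
    names(scene$lu_maps)[1L]
  lu <- unclass(scene$lu_maps[[lu_ref_name]])
  ok <- which(!is.na(lu))
  if (n > length(ok)) stop("n exceeds the number of unmasked cells")
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), row = integer(0),
                      col = integer(0), lu = character(0),
                      agb = numeric(0), soc = numeric(0)))
  set.seed(seed)
  idx <- sort(sample(ok, n))
  nr <- nrow(lu)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  agb0 <- unclass(scene$latent_agb)[idx]
  soc0 <- unclass(scene$latent_soc)[idx]
  cv <- config$noise_sd
  agb <- pmax(config$agb_range[1L], agb0 * (1 + stats::rnorm(n, sd = cv)))
  soc <- pmax(config$soc_range[1L], soc0 * (1 + stats::rnorm(n, sd = cv)))
  cs <- cell_size(scene$latent_agb)
  data.frame(x = (cc - 0.5) * cs, y = (nr - rr + 0.5) * cs,
             row = rr, col = cc,
             lu = lu_names()[lu[idx]], agb = agb, soc = soc,
             stringsAsFactors = FALSE)
}

#' Read predictor values at sampled points
#'
#' @param scene a `synthetic_scene`.
#' @param points data frame from [sample_points()] (needs `row`, `col`).
#' @return Numeric matrix, one column per predictor layer.
#' @export
predictor_matrix <- function(scene, points) {
  nr <- nrow(unclass(scene$latent_agb))
  idx <- (points$col - 1L) * nr + points$row
  X <- vapply(scene$predictors, function(r) unclass(r)[idx],
              numeric(length(idx)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  colnames(X) <- names(scene$predictors)
  X
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cfg <- x$provenance
  cat(sprintf("<synthetic_scene> %d x %d cells (%g m), %d epochs, %d scenarios\n",
              cfg$grid_rows, cfg$grid_cols, cfg$cell_size,
              length(cfg$years), length(cfg$scenarios)))
  cat(sprintf("  predictors: %d (%d informative); drivers: %s\n",
              cfg$n_predictors, cfg$n_informative,
              paste(names(x$drivers), collapse = ", ")))
  invisible(x)
}
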