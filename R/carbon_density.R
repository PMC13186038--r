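#' Carbon pool parameters
#'
#' Constants of the four-pool density assembly: the biomass-to-carbon
#' conversion coefficient (0.45), per-class root-to-shoot ratios (arable
#' 0.10, garden 0.30, forest-grassland 3.70, unused 4.50), field soil bulk
#' densities (g·cm⁻³: arable 1.53, garden 1.48, forest-grassland 1.71,
#' unused 1.24), the 0-20 cm accounting depth, the dead-organic fraction
#' (one tenth of the aboveground pool), and the construction-land green
#' coverage rate (41.4%).
#'
#' @param carbon_conversion unitless biomass-to-carbon factor.
#' @param root_shoot named ratios over AR, GA, FO, UN.
#' @param bulk_density named g·cm⁻³ over AR, GA, FO, UN.
#' @param soil_depth_cm accounting depth (cm).
#' @param dead_fraction dead-organic fraction of aboveground carbon.
#' @param green_coverage construction-land green coverage rate in (0, 1).
#' @return Validated list of class `pool_parameters`.
#' @export
pool_parameters <- function(carbon_conversion = 0.45,
                            root_shoot = c(AR = 0.10, GA = 0.30,
                                           FO = 3.70, UN = 4.50),
                            bulk_density = c(AR = 1.53, GA = 1.48,
                                             FO = 1.71, UN = 1.24),
                            soil_depth_cm = 20,
                            dead_fraction = 0.1,
                            green_coverage = 0.414) {
  veg <- c("AR", "GA", "FO", "UN")
  stopifnot(carbon_conversion > 0, soil_depth_cm > 0,
            dead_fraction > 0, dead_fraction < 1,
            green_coverage > 0, green_coverage < 1)
  if (!all(veg %in% names(root_shoot)) || !all(veg %in% names(bulk_density)))
    stop("`root_shoot` and `bulk_density` must cover AR, GA, FO, UN")
  if (any(root_shoot[veg] <= 0) || any(bulk_density[veg] <= 0))
    stop("ratios and bulk densities must be positive")
  structure(list(carbon_conversion = carbon_conversion,
                 root_shoot = root_shoot[veg],
                 bulk_density = bulk_density[veg],
                 soil_depth_cm = soil_depth_cm,
                 dead_fraction = dead_fraction,
                 green_coverage = green_coverage),
            class = "pool_parameters")
}

#' Assemble the four carbon pools
#'
#' On vegetated classes (AR, GA, FO, UN): aboveground carbon = 0.45 × AGB;
#' underground carbon = aboveground × root-to-shoot ratio; soil carbon from
#' SCD = S × B × G × 0.01 (kg·m⁻², SOC in g·kg⁻¹, bulk density in g·cm⁻³,
#' depth in cm), converted to g·m⁻²; dead organic carbon = one tenth of the
#' aboveground pool. Water cells carry zero in all pools. Construction cells
#' take the green coverage rate times the scene's per-class mean
#' forest-grassland pool values.
#'
#' @param agb continuous `oc_raster`, g·m⁻².
#' @param soc continuous `oc_raster`, g·kg⁻¹.
#' @param lu categorical `oc_raster` of land-use codes.
#' @param params a [pool_parameters()].
#' @return List of class `carbon_pools` with `above`, `below`, `soil`,
#'   `dead` rasters (g·m⁻²).
#' @export
assemble_pools <- function(agb, soc, lu, params = pool_parameters()) {
  check_same_grid(agb, soc, lu)
  codes <- lu_codes()
  luv <- as.vector(unclass(lu))
  known <- is.na(luv) | luv %in% codes
  if (!all(known))
    stop("unknown LU code(s): ", paste(unique(luv[!known]), collapse = ", "))
  agbv <- as.vector(unclass(agb))
  socv <- as.vector(unclass(soc))
  n <- length(luv)
  above <- below <- soil <- dead <- rep(NA_real_, n)
  veg <- c("AR", "GA", "FO", "UN")
  for (cl in veg) {
    i <- which(!is.na(luv) & luv == codes[[cl]])
    if (!length(i)) next
    above[i] <- params$carbon_conversion * agbv[i]
    below[i] <- above[i] * params$root_shoot[[cl]]
    # SCD (kg·m⁻²) = S × B × G × 0.01; ×1000 -> g·m⁻²
    soil[i] <- socv[i] * params$bulk_density[[cl]] *
      params$soil_depth_cm * 0.01 * 1000
    dead[i] <- params$dead_fraction * above[i]
  }
  i_wa <- which(!is.na(luv) & luv == codes[["WA"]])
  above[i_wa] <- below[i_wa] <- soil[i_wa] <- dead[i_wa] <- 0
  i_co <- which(!is.na(luv) & luv == codes[["CO"]])
  if (length(i_co)) {
    i_fo <- which(!is.na(luv) & luv == codes[["FO"]])
    if (!length(i_fo))
      stop("construction cells present but no forest-grassland cells to scale from")
    g <- params$green_coverage
    above[i_co] <- g * mean(above[i_fo])
    below[i_co] <- g * mean(below[i_fo])
    soil[i_co] <- g * mean(soil[i_fo])
    dead[i_co] <- g * mean(dead[i_fo])
  }
  cs <- cell_size(lu)
  dims <- dim(unclass(lu))
  wrap <- function(v) oc_raster(matrix(v, dims[1L], dims[2L]), cell_size = cs)
  structure(list(above = wrap(above), below = wrap(below),
                 soil = wrap(soil), dead = wrap(dead)),
            class = "carbon_pools")
}

#' Per-class mean carbon density table
#'
#' Arithmetic mean of each pool over every land-use class's unmasked cells,
#' with the pool total. Classes absent from the map are flagged and reported
#' as missing.
#'
#' @param pools a `carbon_pools`.
#' @param lu categorical `oc_raster`.
#' @param epoch label stored on the table.
#' @return Data frame of class `carbon_density_table`: one row per class,
#'   columns `lu`, `above`, `below`, `soil`, `dead`, `total`, `n_cells`.
#' @export
zonal_density_table <- function(pools, lu, epoch = "reference") {
  check_same_grid(pools$above, lu)
  luv <- as.vector(unclass(lu))
  codes <- lu_codes()
  rows <- lapply(names(codes), function(cl) {
    i <- which(!is.na(luv) & luv == codes[[cl]])
    if (!length(i)) {
      data.frame(lu = cl, above = NA_real_, below = NA_real_,
                 soil = NA_real_, dead = NA_real_, total = NA_real_,
                 n_cells = 0L, stringsAsFactors = FALSE)
    } else {
      a <- mean(unclass(pools$above)[i]); b <- mean(unclass(pools$below)[i])
      s <- mean(unclass(pools$soil)[i]); d <- mean(unclass(pools$dead)[i])
      data.frame(lu = cl, above = a, below = b, soil = s, dead = d,
                 total = a + b + s + d, n_cells = length(i),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(out$n_cells == 0L))
    warning("class(es) absent from map: ",
            paste(out$lu[out$n_cells == 0L], collapse = ", "))
  structure(out, epoch = epoch,
            class = c("carbon_density_table", "data.frame"))
}

#' Regional climate state for one epoch
#'
#' @param epoch label.
#' @param temperature_c mean annual temperature, °C.
#' @param precipitation_mm mean annual precipitation, mm (non-negative).
#' @param scenario one of `historical`, `SSP126`, `SSP245`, `SSP370`,
#'   `SSP585`.
#' @return List of class `climate_state`.
#' @export
climate_state <- function(epoch, temperature_c, precipitation_mm,
                          scenario = "historical") {
  if (precipitation_mm < 0) stop("precipitation must be non-negative")
  scenario <- match.arg(scenario, c("historical", "SSP126", "SSP245",
                                    "SSP370", "SSP585"))
  structure(list(epoch = epoch, temperature_c = temperature_c,
                 precipitation_mm = precipitation_mm, scenario = scenario),
            class = "climate_state")
}

#' Climate correction coefficients between two epochs
#'
#' Literature regressions link carbon density to regional climate:
#' soil density to precipitation through D_SP = 3.3968·P + 3996.1, biomass
#' density to precipitation through D_BP = 6.798·e^(0.0054·P) and to
#' temperature through D_BT = 28·T + 398. Only their ratios are used, so the
#' absolute units of the regression constants cancel: the soil coefficient
#' is D_SP(target)/D_SP(reference), the biomass precipitation coefficient
#' e^(0.0054·(P'−P″)), the biomass temperature coefficient
#' (28·T'+398)/(28·T″+398), and the combined biomass coefficient their
#' product (primes: target epoch; double primes: reference epoch).
#'
#' @param reference `climate_state` of the directly estimated epoch.
#' @param target `climate_state` of the epoch being corrected to.
#' @return List of class `correction_coefficients` with `c_soil`,
#'   `c_bio_precip`, `c_bio_temp`, `c_bio` and the two epoch labels.
#' @export
correction_coefficients <- function(reference, target) {
  stopifnot(inherits(reference, "climate_state"),
            inherits(target, "climate_state"))
  dsp <- function(p) 3.3968 * p + 3996.1
  dbt <- function(t) 28 * t + 398
  if (dsp(reference$precipitation_mm) <= 0 || dbt(reference$temperature_c) <= 0 ||
      dbt(target$temperature_c) <= 0)
    stop("unphysical climate: correction denominator is non-positive")
  c_soil <- dsp(target$precipitation_mm) / dsp(reference$precipitation_mm)
  c_bp <- exp(0.0054 * (target$precipitation_mm - reference$precipitation_mm))
  c_bt <- dbt(target$temperature_c) / dbt(reference$temperature_c)
  structure(list(c_soil = c_soil, c_bio_precip = c_bp, c_bio_temp = c_bt,
                 c_bio = c_bp * c_bt,
                 reference = reference$epoch, target = target$epoch),
            class = "correction_coefficients")
}

#' @export
print.correction_coefficients <- function(x, ...) {
  cat(sprintf("<correction_coefficients> %s -> %s: c_soil=%.4f c_bio=%.4f (P %.4f x T %.4f)\n",
              x$reference, x$target, x$c_soil, x$c_bio,
              x$c_bio_precip, x$c_bio_temp))
  invisible(x)
}

#' Apply climate correction to a density table
#'
#' Scales the soil pool by the soil coefficient and the three biomass-linked
#' pools (aboveground, underground, dead organic) by the combined biomass
#' coefficient; totals are recomputed and the water row stays zero.
#'
#' @param reference_table a `carbon_density_table` for the reference epoch.
#' @param coeffs a [correction_coefficients()].
#' @return A corrected `carbon_density_table` labelled with the target epoch.
#' @export
correct_table <- function(reference_table, coeffs) {
  stopifnot(inherits(reference_table, "carbon_density_table"),
            inherits(coeffs, "correction_coefficients"))
  out <- reference_table
  for (col in c("above", "below", "dead")) out[[col]] <- out[[col]] * coeffs$c_bio
  out$soil <- out$soil * coeffs$c_soil
  out$total <- out$above + out$below + out$soil + out$dead
  attr(out, "epoch") <- coeffs$target
  out
}

#' Match a land-use scenario to its CMIP6 SSP pathway
#'
#' EPS (ecological protection) pairs with SSP126, NDS (natural development)
#' with SSP245, CDS (cropland development) with SSP370, and EDS (economic
#' development) with SSP585.
#'
#' @param scenario one of `"EPS"`, `"NDS"`, `"CDS"`, `"EDS"`.
#' @return The SSP tag as a character scalar.
#' @export
scenario_match <- function(scenario) {
  map <- c(EPS = "SSP126", NDS = "SSP245", CDS = "SSP370", EDS = "SSP585")
  if (!scenario %in% names(map))
    stop("unknown scenario: ", scenario,
         " (expected EPS, NDS, CDS or EDS)")
  unname(map[[scenario]])
}
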