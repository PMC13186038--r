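#' Total carbon stock by land use
#'
#' InVEST-style accounting: per-class total density D_i (sum of the four
#' pools, g·m⁻²) times class area A_i, summed over classes,
#' S_total = Σ D_i·A_i. Stocks are reported in tonnes (1 g·m⁻² over 1 km²
#' is exactly 1 t), areas in km², and area/stock shares in percent of the
#' non-nodata map.
#'
#' @param lu categorical `oc_raster` of land-use codes.
#' @param table matching `carbon_density_table`.
#' @param cell_area cell area in m²; defaults to `cell_size(lu)^2`.
#' @return List of class `stock_report`: `table` (per-class data frame with
#'   `lu`, `area_km2`, `density`, `stock_t`, `area_share`, `stock_share`),
#'   `total_t`, `epoch`.
#' @export
total_carbon <- function(lu, table, cell_area = NULL) {
  stopifnot(inherits(table, "carbon_density_table"))
  if (is.null(cell_area)) cell_area <- cell_size(lu)^2
  luv <- as.vector(unclass(lu))
  codes <- lu_codes()
  counts <- vapply(codes, function(cd) sum(!is.na(luv) & luv == cd), integer(1))
  present <- names(codes)[counts > 0L]
  dens <- table$total[match(present, table$lu)]
  if (anyNA(dens))
    stop("density table lacks class(es): ",
         paste(present[is.na(dens)], collapse = ", "))
  area_m2 <- counts * cell_area
  dens_all <- table$total[match(names(codes), table$lu)]
  dens_all[counts == 0L & is.na(dens_all)] <- 0
  stock_t <- dens_all * area_m2 / 1e6 # g -> t
  stock_t[counts == 0L] <- 0
  total_area <- sum(area_m2)
  tab <- data.frame(lu = names(codes),
                    area_km2 = area_m2 / 1e6,
                    density = dens_all,
                    stock_t = stock_t,
                    area_share = if (total_area > 0) 100 * area_m2 / total_area
                                 else rep(NA_real_, length(codes)),
                    stock_share = if (sum(stock_t) > 0)
                                    100 * stock_t / sum(stock_t)
                                  else rep(NA_real_, length(codes)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, total_t = sum(stock_t),
                 epoch = attr(table, "epoch")),
            class = "stock_report")
}

#' @export
print.stock_report <- function(x, ...) {
  cat(sprintf("<stock_report> epoch %s: total %.6g t over %.6g km2\n",
              x$epoch, x$total_t, sum(x$table$area_km2)))
  print(x$table, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Per-cell carbon stock density raster
#'
#' Looks up each cell's class total density in the table; nodata propagates;
#' water cells carry zero by the table's water row.
#'
#' @inheritParams total_carbon
#' @return Continuous `oc_raster` in g·m⁻².
#' @export
stock_raster <- function(lu, table) {
  stopifnot(inherits(table, "carbon_density_table"))
  luv <- as.vector(unclass(lu))
  codes <- lu_codes()
  present <- names(codes)[codes %in% unique(luv[!is.na(luv)])]
  dens <- table$total[match(present, table$lu)]
  if (anyNA(dens))
    stop("density table lacks class(es): ",
         paste(present[is.na(dens)], collapse = ", "))
  lut <- rep(NA_real_, max(codes))
  lut[codes] <- table$total[match(names(codes), table$lu)]
  out <- rep(NA_real_, length(luv))
  ok <- !is.na(luv)
  out[ok] <- lut[luv[ok]]
  oc_raster(matrix(out, nrow(unclass(lu)), ncol(unclass(lu))),
            cell_size = cell_size(lu))
}

#' Classify per-cell carbon stock change
#'
#' Relative change (cs2 − cs1)/cs1 against a ±threshold (default 5%):
#' decrease, essentially unchanged, increase. Cells with cs1 = 0 are
#' unchanged when cs2 = 0 and an increase otherwise.
#'
#' @param cs1,cs2 co-registered continuous `oc_raster`s (earlier, later).
#' @param rel_threshold positive relative threshold; default 0.05.
#' @return List of class `change_map`: `raster` (categorical `oc_raster`,
#'   1 decrease / 2 unchanged / 3 increase), `areas_km2` (named),
#'   `rel_threshold`.
#' @export
change_classify <- function(cs1, cs2, rel_threshold = 0.05) {
  check_same_grid(cs1, cs2)
  if (rel_threshold <= 0) stop("`rel_threshold` must be positive")
  a <- as.vector(unclass(cs1)); b <- as.vector(unclass(cs2))
  out <- rep(NA_integer_, length(a))
  ok <- !is.na(a) & !is.na(b)
  rel <- (b[ok] - a[ok]) / a[ok]
  cls <- ifelse(a[ok] == 0,
                ifelse(b[ok] == 0, 2L, 3L),
                ifelse(rel < -rel_threshold, 1L,
                       ifelse(rel > rel_threshold, 3L, 2L)))
  out[ok] <- cls
  km2 <- cell_size(cs1)^2 / 1e6
  areas <- c(decrease = sum(out == 1L, na.rm = TRUE),
             unchanged = sum(out == 2L, na.rm = TRUE),
             increase = sum(out == 3L, na.rm = TRUE)) * km2
  structure(list(raster = oc_raster(matrix(out, nrow(unclass(cs1)),
                                           ncol(unclass(cs1))),
                                    cell_size = cell_size(cs1),
                                    categorical = TRUE),
                 areas_km2 = areas, rel_threshold = rel_threshold),
            class = "change_map")
}

#' Decompose carbon stock change over land-use transitions
#'
#' For cells converting from class i to class j between two epochs, the
#' stock change is (D_j under the later table − D_i under the earlier
#' table) × area, accumulated per (i, j) pair; stable cells contribute the
#' table change of their class. Conversion and stable components together
#' equal the difference of the two epochs' totals exactly.
#'
#' @param lu1,lu2 co-registered categorical `oc_raster`s (earlier, later).
#' @param table1,table2 the matching `carbon_density_table`s.
#' @param cell_area cell area in m²; defaults to `cell_size(lu1)^2`.
#' @return List of class `transition_report`: `matrix_area_km2` and
#'   `matrix_dcs_t` (6x6, from-rows to-columns), `stable_dcs_t` (named per
#'   class), `gross_increase_t`, `gross_decrease_t`, `net_t`.
#' @export
transition_analysis <- function(lu1, lu2, table1, table2, cell_area = NULL) {
  check_same_grid(lu1, lu2)
  stopifnot(inherits(table1, "carbon_density_table"),
            inherits(table2, "carbon_density_table"))
  if (is.null(cell_area)) cell_area <- cell_size(lu1)^2
  a <- as.vector(unclass(lu1)); b <- as.vector(unclass(lu2))
  ok <- !is.na(a) & !is.na(b)
  codes <- lu_codes(); k <- length(codes)
  d1 <- table1$total[match(names(codes), table1$lu)]
  d2 <- table2$total[match(names(codes), table2$lu)]
  used1 <- names(codes)[codes %in% unique(a[ok])]
  used2 <- names(codes)[codes %in% unique(b[ok])]
  if (anyNA(d1[match(used1, names(codes))]))
    stop("earlier table lacks class(es) present in map")
  if (anyNA(d2[match(used2, names(codes))]))
    stop("later table lacks class(es) present in map")
  cross <- table(factor(a[ok], levels = codes), factor(b[ok], levels = codes))
  area <- matrix(as.numeric(cross) * cell_area, k, k,
                 dimnames = list(from = names(codes), to = names(codes)))
  dcs <- matrix(0, k, k, dimnames = dimnames(area))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (area[i, j] > 0)
      dcs[i, j] <- (d2[j] - d1[i]) * area[i, j] / 1e6
  }
  stable <- diag(dcs)
  names(stable) <- names(codes)
  conv <- dcs; diag(conv) <- 0
  comp <- c(as.vector(conv)[as.vector(conv) != 0], stable[stable != 0])
  gross_inc <- sum(comp[comp > 0])
  gross_dec <- sum(comp[comp < 0])
  structure(list(matrix_area_km2 = area / 1e6, matrix_dcs_t = dcs,
                 stable_dcs_t = stable,
                 gross_increase_t = gross_inc, gross_decrease_t = gross_dec,
                 net_t = sum(dcs)),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report> net %+.6g t (gross +%.6g / %.6g t)\n",
              x$net_t, x$gross_increase_t, x$gross_decrease_t))
  cat("stock change by conversion (t):\n")
  print(round(x$matrix_dcs_t, 2))
  invisible(x)
}

#' Area share versus stock share
#'
#' Compares each class's share of carbon stock with its share of area; the
#' ratio (stock share / area share) is the class's relative carbon-fixation
#' capacity, with a ranking flag. Zero-area classes yield an undefined,
#' flagged ratio.
#'
#' @param report a `stock_report`.
#' @return Data frame: `lu`, `area_share`, `stock_share`, `ratio`,
#'   `capacity_rank` (1 = highest ratio; NA where undefined).
#' @export
share_comparison <- function(report) {
  stopifnot(inherits(report, "stock_report"))
  tab <- report$table
  ratio <- ifelse(tab$area_share > 0, tab$stock_share / tab$area_share,
                  NA_real_)
  rk <- rep(NA_integer_, length(ratio))
  ok <- !is.na(ratio)
  rk[ok] <- as.integer(rank(-ratio[ok], ties.method = "min"))
  data.frame(lu = tab$lu, area_share = tab$area_share,
             stock_share = tab$stock_share, ratio = ratio,
             capacity_rank = rk, stringsAsFactors = FALSE)
}
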