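uniform_table <- function(vals, epoch = "t") {
  d <- data.frame(lu = lu_names(), above = vals / 4, below = vals / 4,
                  soil = vals / 4, dead = vals / 4, total = vals,
                  n_cells = 1L, stringsAsFactors = FALSE)
  d$total[d$lu == "WA"] <- 0
  d[d$lu == "WA", c("above", "below", "soil", "dead")] <- 0
  structure(d, epoch = epoch, class = c("carbon_density_table", "data.frame"))
}

test_that("stock accounting honours the density-times-area identity", {
  # 1 g/m2 over 1 km2 is exactly 1 t: D = 1000 g/m2 on 1 km2 -> 1000 t
  lu <- oc_raster(matrix(1L, 100, 100), cell_size = 10, categorical = TRUE)
  tab <- uniform_table(rep(1000, 6))
  rep1 <- total_carbon(lu, tab)
  expect_equal(rep1$total_t, 1000, tolerance = 1e-9)
  expect_equal(rep1$table$area_km2[rep1$table$lu == "AR"], 1)
  # all-nodata map
  lu_na <- oc_raster(matrix(NA_integer_, 5, 5), categorical = TRUE)
  rep0 <- total_carbon(lu_na, tab)
  expect_equal(rep0$total_t, 0)
  expect_true(all(is.na(rep0$table$area_share)))
})

test_that("stock totals match a per-cell brute-force oracle", {
  sc <- small_scene()
  lu <- sc$lu_maps[["2016"]]
  tab <- zonal_density_table(
    assemble_pools(sc$latent_agb, sc$latent_soc, sc$lu_maps[["2019"]]),
    sc$lu_maps[["2019"]], "2019")
  rep1 <- total_carbon(lu, tab)
  luv <- as.vector(unclass(lu))
  dens <- tab$total[match(lu_names(), tab$lu)]
  acc <- 0
  for (i in seq_along(luv)) if (!is.na(luv[i]))
    acc <- acc + dens[luv[i]] * attr(lu, "cell_size")^2
  expect_equal(rep1$total_t, acc / 1e6, tolerance = 1e-6)
  expect_equal(sum(rep1$table$area_share), 100, tolerance = 1e-6)
  expect_equal(sum(rep1$table$stock_share), 100, tolerance = 1e-6)
  # additivity over a partition of the map
  top <- oc_raster(unclass(lu)[1:30, , drop = FALSE], cell_size = 10,
                   categorical = TRUE)
  bottom <- oc_raster(unclass(lu)[31:60, , drop = FALSE], cell_size = 10,
                      categorical = TRUE)
  expect_equal(total_carbon(top, tab)$total_t +
                 total_carbon(bottom, tab)$total_t,
               rep1$total_t, tolerance = 1e-9)
})

test_that("stock raster lookup is consistent with the report", {
  sc <- small_scene()
  lu <- sc$lu_maps[["2013"]]
  tab <- uniform_table(c(100, 200, 300, 400, 0, 600))
  tab$total <- c(100, 200, 300, 400, 0, 600)
  r <- stock_raster(lu, tab)
  rep1 <- total_carbon(lu, tab)
  expect_equal(mean(as.vector(unclass(r))) * 60 * 60 * 100 / 1e6,
               rep1$total_t, tolerance = 1e-9)
  expect_true(all(unclass(r)[unclass(lu) == 5L] == 0))
  lu_u <- oc_raster(matrix(2L, 4, 4), categorical = TRUE)
  expect_equal(stats::sd(unclass(stock_raster(lu_u, tab))), 0)
})

test_that("change classification applies the relative threshold", {
  cs1 <- oc_raster(matrix(c(100, 100, 100, 0, 0, 50), 2, 3))
  cs2 <- oc_raster(matrix(c(104, 110, 90, 0, 5, 50), 2, 3))
  cm <- change_classify(cs1, cs2)
  v <- as.vector(unclass(cm$raster))
  expect_identical(v, c(2L, 3L, 1L, 2L, 3L, 2L))
  expect_equal(sum(cm$areas_km2), 6 * 100 / 1e6, tolerance = 1e-12)
  expect_error(change_classify(cs1, oc_raster(matrix(0, 3, 2))), "mismatch")
  # identical rasters are all unchanged, at any threshold
  for (th in c(0.01, 0.05, 0.2)) {
    cm0 <- change_classify(cs1, cs1, th)
    expect_true(all(as.vector(unclass(cm0$raster)) == 2L))
  }
})

test_that("transition decomposition conserves the inter-epoch difference", {
  sc <- small_scene()
  lu1 <- sc$lu_maps[["2010"]]; lu2 <- sc$lu_maps[["2022"]]
  base <- zonal_density_table(
    assemble_pools(sc$latent_agb, sc$latent_soc, sc$lu_maps[["2019"]]),
    sc$lu_maps[["2019"]], "2019")
  ref <- climate_state("2019", 11.6, 70)
  t1 <- correct_table(base, correction_coefficients(
    ref, climate_state("2010", 11.0, 62)))
  t2 <- correct_table(base, correction_coefficients(
    ref, climate_state("2022", 11.9, 66)))
  tr <- transition_analysis(lu1, lu2, t1, t2)
  diff_totals <- total_carbon(lu2, t2)$total_t - total_carbon(lu1, t1)$total_t
  expect_equal(tr$net_t, diff_totals, tolerance = 1e-6)
  expect_equal(tr$gross_increase_t + tr$gross_decrease_t, tr$net_t,
               tolerance = 1e-9)
  # identical epochs, identical tables: all zero
  tr0 <- transition_analysis(lu1, lu1, t1, t1)
  expect_equal(tr0$net_t, 0)
  expect_true(all(tr0$matrix_dcs_t == 0))
})

test_that("a 1 km2 unused-to-forest conversion uses the density difference", {
  lu1 <- oc_raster(matrix(6L, 100, 100), cell_size = 10, categorical = TRUE)
  lu2 <- oc_raster(matrix(3L, 100, 100), cell_size = 10, categorical = TRUE)
  tab <- uniform_table(rep(0, 6))
  tab$total <- c(0, 0, 2386.31, 0, 0, 869.86)[match(tab$lu, tab$lu)]
  tab$total <- ifelse(tab$lu == "FO", 2386.31,
                      ifelse(tab$lu == "UN", 869.86, 0))
  tr <- transition_analysis(lu1, lu2, tab, tab)
  expect_equal(tr$matrix_dcs_t["UN", "FO"], 2386.31 - 869.86,
               tolerance = 1e-9) # +1516.45 t over 1 km2
})

test_that("share ratios behave as density contrasts", {
  lu <- small_scene()$lu_maps[["2019"]]
  tab_u <- uniform_table(rep(500, 6))
  tab_u$total <- rep(500, 6) # include water: uniform density everywhere
  rep_u <- total_carbon(lu, tab_u)
  sh <- share_comparison(rep_u)
  expect_all_close(sh$ratio, 1, 1e-9)
  # area-weighted mean of ratios is 1 by construction
  tab_v <- uniform_table(c(100, 900, 400, 50, 0, 20))
  tab_v$total <- c(100, 900, 400, 50, 0, 20)
  sh2 <- share_comparison(total_carbon(lu, tab_v))
  w <- sh2$area_share / 100
  expect_equal(sum(w * sh2$ratio, na.rm = TRUE), 1, tolerance = 1e-9)
})
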