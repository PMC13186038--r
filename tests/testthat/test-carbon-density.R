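make_square <- function(vals, cats = FALSE, n = NULL) {
  if (is.null(n)) n <- sqrt(length(vals))
  oc_raster(matrix(vals, n, n), categorical = cats)
}

test_that("pool assembly reproduces the printed-constant arithmetic", {
  lu <- make_square(c(3L, 3L, 5L, 4L), cats = TRUE, n = 2)
  agb <- make_square(rep(1000, 4), n = 2)
  soc <- make_square(rep(5, 4), n = 2)
  p <- assemble_pools(agb, soc, lu)
  # forest-grassland cell, AGB 1000: 0.45 conversion, 3.70 root-shoot, 0.1 dead
  expect_equal(unclass(p$above)[1L], 450)
  expect_equal(unclass(p$below)[1L], 1665)
  expect_equal(unclass(p$dead)[1L], 45)
  # water carries nothing
  expect_identical(unname(c(unclass(p$above)[3L], unclass(p$below)[3L],
                            unclass(p$soil)[3L], unclass(p$dead)[3L])),
                   rep(0, 4))
  # construction = green coverage x forest-grassland means
  expect_equal(unclass(p$above)[4L], 0.414 * 450, tolerance = 1e-12)
})

test_that("soil pool follows the depth-bulk-density closed form", {
  # SOC 5 g/kg, bulk density 1.5 g/cm3, 20 cm -> 1.5 kg/m2 = 1500 g/m2
  lu <- make_square(rep(1L, 4), cats = TRUE, n = 2)
  params <- pool_parameters(bulk_density = c(AR = 1.5, GA = 1.48,
                                             FO = 1.71, UN = 1.24))
  p <- assemble_pools(make_square(rep(100, 4), n = 2),
                      make_square(rep(5, 4), n = 2), lu, params)
  expect_equal(unclass(p$soil)[1L], 1500, tolerance = 1e-12)
})

test_that("pool identities hold cell-wise on random scenes", {
  sc <- small_scene()
  lu <- sc$lu_maps[["2019"]]
  p <- assemble_pools(sc$latent_agb, sc$latent_soc, lu)
  luv <- as.vector(unclass(lu))
  agb <- as.vector(unclass(sc$latent_agb))
  rs <- pool_parameters()$root_shoot
  for (cl in c("AR", "GA", "FO", "UN")) {
    i <- luv == lu_codes()[[cl]]
    expect_all_close(unclass(p$dead)[i] / unclass(p$above)[i], 0.1, 1e-9)
    expect_all_close(unclass(p$below)[i] / unclass(p$above)[i],
                     rs[[cl]], 1e-9)
    expect_all_close(unclass(p$above)[i] / agb[i], 0.45, 1e-9)
  }
  i_co <- luv == lu_codes()[["CO"]]
  i_fo <- luv == lu_codes()[["FO"]]
  for (pool in p)
    expect_all_close(unclass(pool)[i_co],
                     0.414 * mean(unclass(pool)[i_fo]), 1e-9)
})

test_that("zonal means equal a brute-force per-cell accumulation", {
  sc <- small_scene()
  lu <- sc$lu_maps[["2019"]]
  p <- assemble_pools(sc$latent_agb, sc$latent_soc, lu)
  tab <- zonal_density_table(p, lu, "2019")
  luv <- as.vector(unclass(lu))
  for (cl in lu_names()) {
    acc <- 0; cnt <- 0L
    av <- unclass(p$above)
    for (i in seq_along(luv)) if (!is.na(luv[i]) && luv[i] == lu_codes()[[cl]]) {
      acc <- acc + av[i]; cnt <- cnt + 1L
    }
    if (cnt > 0L)
      expect_equal(tab$above[tab$lu == cl], acc / cnt, tolerance = 1e-9)
  }
  expect_all_close(tab$total, rowSums(tab[, c("above", "below", "soil",
                                              "dead")]), 1e-9)
  expect_equal(tab$total[tab$lu == "WA"], 0)
})

test_that("correction coefficients follow the literature regressions", {
  ref <- climate_state("2019", 11.6, 70)
  expect_true(all(unlist(correction_coefficients(ref, ref)[1:4]) == 1))
  # precipitation +100 mm on biomass: e^0.54
  t1 <- climate_state("x", 11.6, 170)
  cc <- correction_coefficients(ref, t1)
  expect_equal(cc$c_bio_precip, exp(0.54), tolerance = 1e-12)
  # soil ratio closed form
  r0 <- climate_state("r", 10, 0)
  cc2 <- correction_coefficients(r0, climate_state("t", 10, 100))
  expect_equal(cc2$c_soil, (3.3968 * 100 + 3996.1) / 3996.1,
               tolerance = 1e-12)
  expect_equal(cc2$c_soil, 1.0850, tolerance = 1e-4)
  expect_equal(cc$c_bio, cc$c_bio_precip * cc$c_bio_temp, tolerance = 1e-12)
  expect_error(correction_coefficients(ref, climate_state("bad", -100, 10)),
               "denominator")
})

test_that("table correction scales pools and round-trips to identity", {
  sc <- small_scene()
  lu <- sc$lu_maps[["2019"]]
  tab <- zonal_density_table(assemble_pools(sc$latent_agb, sc$latent_soc, lu),
                             lu, "2019")
  ref <- climate_state("2019", 11.6, 70)
  tgt <- climate_state("2010", 11.0, 62)
  cc <- correction_coefficients(ref, tgt)
  out <- correct_table(tab, cc)
  expect_equal(out$above, tab$above * cc$c_bio, tolerance = 1e-12)
  expect_equal(out$soil, tab$soil * cc$c_soil, tolerance = 1e-12)
  expect_equal(out$total[out$lu == "WA"], 0)
  # reciprocal coefficients restore the original table
  back <- correct_table(out, correction_coefficients(tgt, ref))
  expect_all_close(back$total, tab$total, 1e-9)
  # identity coefficients change nothing
  same <- correct_table(tab, correction_coefficients(ref, ref))
  expect_equal(same$total, tab$total, tolerance = 1e-14)
})

test_that("scenario labels map to their CMIP6 pathways", {
  expect_identical(scenario_match("EPS"), "SSP126")
  expect_identical(scenario_match("NDS"), "SSP245")
  expect_identical(scenario_match("CDS"), "SSP370")
  expect_identical(scenario_match("EDS"), "SSP585")
  expect_error(scenario_match("XYZ"), "unknown scenario")
})
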