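# coarse climatology whose every band is the same analytic function of
# (x, y, elevation); returns both the climatology and the truth function
affine_coarse <- function(geometry, terrain, a = 2, cx = 0.01, cy = -0.003,
                          ce = -0.0065) {
  truth <- function(x, y, e) a + cx * x + cy * y + ce * e
  data <- terrain[c("cell", "row", "col", "x", "y")]
  z <- truth(terrain$x, terrain$y, terrain$elevation)
  for (col in isoclim:::clim_value_cols()) {
    data[[col]] <- if (grepl("^prcp", col)) pmax(z + 100, 0) else z
  }
  list(clim = clim_normal(data, geometry, period = "affine"), truth = truth)
}

test_that("GIDS reproduces affine fields exactly for any neighbourhood size", {
  gc <- grid_geometry(6, 6, 4000)
  coarse_tr <- make_terrain(gc, 900, seed = 21)
  af <- affine_coarse(gc, coarse_tr)
  # fine centres offset so none coincides with a coarse centre (the d = 0
  # short-circuit would otherwise return the coarse cell's own elevation)
  gf <- grid_geometry(15, 15, 1500, origin = gc$origin + c(100, -100))
  fine_tr <- make_terrain(gf, 0, seed = 1)
  set.seed(3)
  fine_tr$elevation <- stats::runif(nrow(fine_tr), -500, 1500)
  for (k in c(4, 8, 36)) {
    out <- gids_interpolate(af$clim, coarse_tr, fine_tr, gids_config(k))
    want <- af$truth(fine_tr$x, fine_tr$y, fine_tr$elevation)
    expect_equal(out$tmin_01, want, tolerance = 1e-8)
    expect_equal(out$tmax_07, want, tolerance = 1e-8)
    expect_equal(out$prcp_06, want + 100, tolerance = 1e-8)
  }
})

test_that("GIDS on a constant field over flat terrain returns the constant", {
  gc <- grid_geometry(5, 5, 4000)
  coarse_tr <- make_terrain(gc, 0, seed = 1)
  data <- coarse_tr[c("cell", "row", "col", "x", "y")]
  for (col in isoclim:::clim_value_cols()) data[[col]] <- 7.25
  coarse <- clim_normal(data, gc, period = "const")
  gf <- grid_geometry(10, 10, 2000, origin = gc$origin)
  fine_tr <- make_terrain(gf, 0, seed = 1)
  # flat elevation makes every neighbourhood singular: gradient-free fallback
  expect_warning(
    out <- gids_interpolate(coarse, coarse_tr, fine_tr, gids_config(8)),
    "fallback"
  )
  expect_true(all(abs(out$tmin_05 - 7.25) < 1e-12))
  expect_error(
    suppressWarnings(gids_interpolate(coarse, coarse_tr, fine_tr,
                                      gids_config(8, "error"))),
    "singular"
  )
})

test_that("GIDS at a coarse centre returns that centre's value, else the weighted sum", {
  gc <- grid_geometry(5, 5, 4000)
  coarse_tr <- make_terrain(gc, 1200, seed = 8)
  set.seed(12)
  data <- coarse_tr[c("cell", "row", "col", "x", "y")]
  for (m in 1:12) {
    tmin <- stats::runif(25, 0, 20)
    data[[sprintf("tmin_%02d", m)]] <- tmin
    data[[sprintf("tmax_%02d", m)]] <- tmin + stats::runif(25, 1, 8)
    data[[sprintf("prcp_%02d", m)]] <- stats::runif(25, 0, 150)
  }
  coarse <- clim_normal(data, gc, period = "random")

  # fine grid congruent with the coarse grid: d = 0 short-circuit everywhere
  out <- gids_interpolate(coarse, coarse_tr, coarse_tr, gids_config(25))
  expect_equal(out$tmin_03, coarse$tmin_03)
  expect_equal(out$prcp_11, coarse$prcp_11)

  # independent re-implementation of the GIDS weighted sum at one off-centre point
  target <- tibble::tibble(cell = 1L, row = 1L, col = 1L,
                           x = coarse_tr$x[7] + 700, y = coarse_tr$y[7] - 450,
                           elevation = 333)
  target <- structure(target, geometry = grid_geometry(1, 1, 100,
                                                       origin = c(target$x, target$y)))
  got <- gids_interpolate(coarse, coarse_tr, target, gids_config(25))
  z <- coarse$tmax_09
  fit <- stats::lm(z ~ x + y + elevation,
                   data = data.frame(x = coarse_tr$x, y = coarse_tr$y,
                                     elevation = coarse_tr$elevation, z = z))
  b <- stats::coef(fit)
  d2 <- (coarse_tr$x - target$x)^2 + (coarse_tr$y - target$y)^2
  adj <- z + (target$x - coarse_tr$x) * b["x"] +
    (target$y - coarse_tr$y) * b["y"] +
    (333 - coarse_tr$elevation) * b["elevation"]
  expect_equal(got$tmax_09, sum(adj / d2) / sum(1 / d2), tolerance = 1e-9)
})

test_that("bias correction matches reference moments and is idempotent", {
  g <- grid_geometry(4, 4, 1000)
  tr <- make_terrain(g, 600, seed = 2)
  reference <- make_climatology(tr, synthetic_climate_params())

  # identity when modeled equals reference
  bc0 <- bias_correct(reference, reference)
  expect_equal(tibble::as_tibble(bc0$corrected)[isoclim:::clim_value_cols()],
               tibble::as_tibble(reference)[isoclim:::clim_value_cols()],
               tolerance = 1e-12)

  # uniform +2 degC bias is removed exactly
  shifted <- make_future(reference, delta_t = 2, precip_scale = 1,
                         continentality_boost = 0)
  bc2 <- bias_correct(shifted, reference)
  expect_equal(bc2$corrected$tmin_04, reference$tmin_04, tolerance = 1e-12)
  expect_equal(bc2$corrected$tmax_10, reference$tmax_10, tolerance = 1e-12)

  # doubled anomaly spread: corrected monthly mean and SD match the reference
  doubled <- make_future(reference, 0, 1, continentality_boost = 0)
  dd <- tibble::as_tibble(doubled)
  for (v in c("tmin", "tmax")) {
    cols <- isoclim:::month_cols(v)
    z <- as.matrix(dd[cols])
    dd[cols] <- (z - rowMeans(z)) * 2 + rowMeans(z) + 1.5
  }
  doubled <- clim_normal(dd, g, check = "mask")
  bcd <- bias_correct(doubled, reference)
  for (v in c("tmin", "tmax", "prcp")) {
    zc <- as.matrix(tibble::as_tibble(bcd$corrected)[isoclim:::month_cols(v)])
    zr <- as.matrix(tibble::as_tibble(reference)[isoclim:::month_cols(v)])
    expect_equal(rowMeans(zc), rowMeans(zr), tolerance = 1e-9)
    expect_equal(apply(zc, 1, sd), apply(zr, 1, sd), tolerance = 1e-9)
  }

  # idempotence: correcting the corrected historical changes nothing
  bc_again <- bias_correct(bcd$corrected, reference)
  expect_equal(tibble::as_tibble(bc_again$corrected)[isoclim:::clim_value_cols()],
               tibble::as_tibble(bcd$corrected)[isoclim:::clim_value_cols()],
               tolerance = 1e-9)

  other <- make_climatology(make_terrain(grid_geometry(3, 3, 1000), 0, seed = 1))
  expect_error(bias_correct(reference, other), "grid mismatch")
})

test_that("three-step pipeline recovers an elevation-linear truth field", {
  # truth affine in elevation only; biased model = truth + 3 degC
  truth_clim <- function(geometry, terrain, bias = 0) {
    data <- terrain[c("cell", "row", "col", "x", "y")]
    for (m in 1:12) {
      z <- 15 - 0.006 * terrain$elevation + 5 * cos(2 * pi * (m - 7) / 12)
      data[[sprintf("tmin_%02d", m)]] <- z - 5 + bias
      data[[sprintf("tmax_%02d", m)]] <- z + 5 + bias
      data[[sprintf("prcp_%02d", m)]] <- 60 + 0.05 * terrain$elevation
    }
    clim_normal(data, geometry, period = "truth")
  }
  gc <- grid_geometry(6, 6, 12000)
  gm <- grid_geometry(18, 18, 4000, origin = gc$origin)
  gf <- grid_geometry(36, 36, 2000, origin = gc$origin)
  # one smooth truth terrain sampled at three resolutions
  elev_fun <- function(tr) 400 + 300 * sin(tr$x / 2e4) * cos(tr$y / 3e4)
  trc <- make_terrain(gc, 0, seed = 1); trc$elevation <- elev_fun(trc)
  trm <- make_terrain(gm, 0, seed = 1); trm$elevation <- elev_fun(trm)
  trf <- make_terrain(gf, 0, seed = 1); trf$elevation <- elev_fun(trf)

  coarse_model <- truth_clim(gc, trc, bias = 3)
  reference_mid <- truth_clim(gm, trm, bias = 0)
  res <- downscale_pipeline(coarse_model, trc, reference_mid, trm, trf)
  want <- truth_clim(gf, trf, bias = 0)
  expect_equal(res$historical$tmin_01, want$tmin_01, tolerance = 0.05)
  expect_equal(res$historical$tmax_07, want$tmax_07, tolerance = 0.05)
  expect_equal(res$historical$prcp_12, want$prcp_12, tolerance = 0.5)
  expect_equal(length(res$log), 3)

  # determinism: no randomness anywhere in the chain
  res2 <- downscale_pipeline(coarse_model, trc, reference_mid, trm, trf)
  expect_identical(res$historical$tmin_01, res2$historical$tmin_01)

  # a future run goes through the stored transform
  future_model <- truth_clim(gc, trc, bias = 3)
  fut <- make_future(future_model, delta_t = 2, precip_scale = 0.9,
                     continentality_boost = 0)
  res3 <- downscale_pipeline(coarse_model, trc, reference_mid, trm, trf,
                             future = fut)
  expect_false(is.null(res3$future))
  # warming survives the bias correction (approximately delta_t everywhere)
  expect_equal(mean(res3$future$tmax_07 - res$historical$tmax_07), 2,
               tolerance = 0.2)
})
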