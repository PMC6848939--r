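linear_samples <- function(n = 8) {
  w <- seq(0.1, 1, length.out = n)
  tibble::tibble(weight_g = w, area_mm2 = 400 * w)
}

test_that("the density model is the exact weight/area ratio", {
  m <- fit_weight_area_model(linear_samples(), "density")
  expect_equal(m$pars$rho, 1 / 400)
  expect_equal(m$train_rmse, 0, tolerance = 1e-9)

  # a single reference leaf defines the density exactly
  one <- tibble::tibble(weight_g = 0.3, area_mm2 = 1500)
  m1 <- fit_weight_area_model(one, "density")
  expect_equal(m1$pars$rho, 0.3 / 1500)
})

test_that("plug area prediction feeds the mean single-leaf weight", {
  m <- fit_weight_area_model(linear_samples(), "density")
  # 2 g over 10 leaves -> 0.2 g/leaf -> 80 mm^2
  expect_equal(area_from_weight(m, 2, 10), 80)
  # one leaf: the model applies to the weight directly
  expect_equal(area_from_weight(m, 0.5, 1), 200)
  expect_warning(area_from_weight(m, 50, 1), "extrapolating")
})

test_that("inversion recovers weights from areas", {
  m <- fit_weight_area_model(linear_samples(), "density")
  expect_equal(weight_from_area(m, 80), 0.2)
  # density model: weight = rho * area, exactly
  expect_equal(weight_from_area(m, 160), m$pars$rho * 160)

  # round trip on the nonlinear network model
  set.seed(16)
  w <- seq(0.1, 1, length.out = 8)
  s2 <- tibble::tibble(weight_g = w, area_mm2 = 100 + 500 * w^2)
  mm <- fit_weight_area_model(s2, "mlp")
  for (w0 in c(0.2, 0.55, 0.9)) {
    rt <- weight_from_area(mm, area_from_weight(mm, w0))
    expect_lt(abs(rt - w0) / w0, 1e-6)
  }
  expect_error(weight_from_area(mm, 1e6), "attainable range")
})

test_that("the two-layer network has capacity for a quadratic relation", {
  w <- seq(0.1, 1, length.out = 8)
  s2 <- tibble::tibble(weight_g = w, area_mm2 = 100 + 500 * w^2)
  mm <- fit_weight_area_model(s2, "mlp", seed = 42)
  expect_lt(mm$train_rmse / mean(s2$area_mm2), 0.01)
})

test_that("non-monotone fits are rejected with advice", {
  w <- seq(0.1, 1, length.out = 9)
  dec <- tibble::tibble(weight_g = w, area_mm2 = 500 - 380 * w)
  expect_error(fit_weight_area_model(dec, "polynomial", degree = 1),
               "simpler")
})

test_that("leaf density is recovered within 2% at 5% noise", {
  cfg <- scene_config(seed = 5)
  smp <- phenotray:::with_scene_rng(5L, 0L,
                                    generate_leaf_samples(cfg, 50, 0.05))
  md <- fit_weight_area_model(smp, "density")
  expect_lt(abs(md$pars$rho - cfg$rho_bl) / cfg$rho_bl, 0.02)
})

test_that("growth curves interpolate unmeasured days", {
  # exact line
  lin <- tibble::tibble(das = c(18, 21, 24, 28), value = 2 * c(18, 21, 24, 28))
  g1 <- fit_growth_curve(lin, degree = 1, predict_das = 19:27)
  expect_equal(max(abs(g1$fitted$residual)), 0, tolerance = 1e-9)
  expect_equal(g1$predicted$value, 2 * (19:27), tolerance = 1e-9)

  # quadratic coefficients recovered exactly by least squares
  qd <- tibble::tibble(das = 10:20)
  qd$value <- 3 + 0.5 * qd$das - 0.02 * qd$das^2
  g2 <- fit_growth_curve(qd, degree = 2)
  expect_equal(g2$coef, c(3, 0.5, -0.02), tolerance = 1e-9)

  expect_error(fit_growth_curve(lin[1:2, ], degree = 2), "under-determined")
})

test_that("models serialize to JSON and back", {
  m <- fit_weight_area_model(linear_samples(), "density")
  f <- withr::local_tempfile(fileext = ".json")
  write_weight_area_model(m, f)
  back <- read_weight_area_model(f)
  expect_equal(back$pars$rho, m$pars$rho)
  expect_equal(weight_from_area(back, 80), 0.2)

  set.seed(16)
  w <- seq(0.1, 1, length.out = 8)
  mm <- fit_weight_area_model(
    tibble::tibble(weight_g = w, area_mm2 = 100 + 500 * w^2), "mlp")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_weight_area_model(mm, f2)
  back2 <- read_weight_area_model(f2)
  expect_equal(area_from_weight(back2, 0.4), area_from_weight(mm, 0.4),
               tolerance = 1e-9)
})

test_that("tidy and glance summarize fitted models", {
  m <- fit_weight_area_model(linear_samples(), "density")
  td <- tidy(m)
  expect_equal(td$term, "rho")
  gl <- glance(m)
  expect_equal(gl$kind, "density")
  expect_equal(gl$n, 8L)

  smp_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(species = "Ya", linear_samples()), smp_csv,
                   row.names = FALSE)
  expect_equal(nrow(read_leaf_samples(smp_csv)), 8)
})
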