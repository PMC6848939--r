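test_that("the Gaussian Bhattacharyya distance matches its closed form", {
  # identical distributions
  expect_equal(bhattacharyya_distance(5, 5, sigma_p = 2, sigma_m = 2), 0)
  # unit variances two means apart: log term 0, mean term 4/8
  expect_equal(bhattacharyya_distance(0, 2, sigma_p = 1, sigma_m = 1), 0.5)

  # symmetry
  set.seed(17)
  for (i in 1:10) {
    mu <- rnorm(2, 50, 20); s <- runif(2, 0.5, 8)
    expect_equal(bhattacharyya_distance(mu[1], mu[2], sigma_p = s[1],
                                        sigma_m = s[2]),
                 bhattacharyya_distance(mu[2], mu[1], sigma_p = s[2],
                                        sigma_m = s[1]))
  }

  # invariant to a common affine rescaling (mm -> cm)
  d_mm <- bhattacharyya_distance(120, 135, sigma_p = 6, sigma_m = 9)
  d_cm <- bhattacharyya_distance(12, 13.5, sigma_p = 0.6, sigma_m = 0.9)
  expect_equal(d_mm, d_cm)

  # monotone in the mean gap at fixed variances, and in the variance
  # ratio away from 1 at fixed means
  gaps <- bhattacharyya_distance(c(0, 1, 2, 4), 0, sigma_p = 1, sigma_m = 1)
  expect_true(all(diff(gaps) > 0))
  ratios <- bhattacharyya_distance(0, 0, sigma_p = c(1, 2, 4, 8),
                                   sigma_m = 1)
  expect_true(all(diff(ratios) > 0))

  expect_error(bhattacharyya_distance(0, 0, sigma_p = 0, sigma_m = 1),
               "variance")
  # gaussian_summary objects are accepted directly
  expect_equal(bhattacharyya_distance(gaussian_summary(0, 1),
                                      gaussian_summary(2, 1)), 0.5)
})

test_that("predicted equals measured gives a zero-distance report", {
  set.seed(18)
  rec <- tibble::tibble(rack_id = rep(c("r7", "r8"), each = 40),
                        das = rep(c(21, 24), 40),
                        height_mm = rnorm(80, 120, 6))
  rep0 <- compare_to_ground_truth(rec, rec, "height_mm")
  expect_true(all(rep0$DB == 0))
  expect_equal(nrow(rep0), 4)

  # shifting every prediction strictly increases every distance
  shifted <- rec; shifted$height_mm <- shifted$height_mm + 10
  rep1 <- compare_to_ground_truth(shifted, rec, "height_mm")
  expect_true(all(rep1$DB > 0))

  # a (rack, DAS) present on one side only is absent, not zero
  rep2 <- compare_to_ground_truth(rec[rec$rack_id == "r7", ], rec,
                                  "height_mm")
  expect_true(all(is.na(rep2$DB[rep2$rack_id == "r8"])))
  expect_true(all(!is.na(rep2$DB[rep2$rack_id == "r7"])))

  expect_error(compare_to_ground_truth(rec[0, ], rec, "height_mm"),
               "non-empty")

  # broom-style accessors and CSV export
  expect_s3_class(tidy(rep0), "tbl_df")
  expect_equal(glance(rep0)$max_DB, 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(rep0, f)
  expect_equal(nrow(utils::read.csv(f)), 4)
})

test_that("pipeline heights match scene truth distributions closely", {
  sc <- cached_scene(24)
  hs <- cached_height(24)
  g <- cached_grid()
  cells <- suppressWarnings(cell_stats(hs, g))
  pred <- tibble::tibble(rack_id = "sim", das = 24,
                         height_mm = cells$h_mean_mm[cells$n_pixels > 0])
  truth <- tibble::tibble(rack_id = "sim", das = 24,
                          height_mm = sc$truth$cells$h_mean_mm)
  rep <- compare_to_ground_truth(pred, truth, "height_mm")
  expect_lt(max(rep$DB), 0.05)
})

test_that("density classes separate in the three phenotype features", {
  set.seed(19)
  n <- 200
  recs <- tibble::tibble(
    density_class = rep(c("high", "low"), each = n),
    height_mm = c(rnorm(n, 130, 5), rnorm(n, 115, 5)),     # 3 sd apart
    leaf_area_mm2 = c(rnorm(n, 150, 25), rnorm(n, 150, 25)),
    leaf_weight_g = c(rnorm(n, 0.030, 0.005), rnorm(n, 0.030, 0.005)))
  dd <- density_discrimination_summary(recs)
  expect_equal(nrow(dd$separation), 3)
  sep_h <- dd$separation$smd[dd$separation$feature == "height_mm"]
  expect_gt(sep_h, 2)
  # identically distributed features show no separation
  sep_a <- dd$separation$smd[dd$separation$feature == "leaf_area_mm2"]
  expect_lt(sep_a, 0.3)
  # pairwise table covers the three feature pairs
  expect_equal(nrow(dplyr::distinct(dd$pairs, feature_x, feature_y)), 3)

  expect_error(density_discrimination_summary(
    recs[recs$density_class == "high", ]), "both density classes")
})
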