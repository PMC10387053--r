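ref_tf <- function() {
  r <- reference_depth_means()
  r <- r[r$ecosystem == "terra_firme", ]
  depth_means_profile(mean = r$mean, se = r$se,
                      midpoint_cm = r$midpoint_cm)
}

test_that("LOESS reproduces constants and is exact on linear data", {
  const <- depth_means_profile(mean = rep(4, 5))
  g <- predict_depth_grid(fit_depth_loess(const))
  expect_equal(g$frp_mean, rep(4, 40), tolerance = 1e-9)

  lin <- depth_means_profile(mean = 30 - 0.25 * (c(0, 6, 16, 36, 71) + 1.25))
  gl <- predict_depth_grid(fit_depth_loess(lin, degree = 1))
  expect_equal(gl$frp_mean, 30 - 0.25 * gl$midpoint_cm, tolerance = 1e-7)
})

test_that("predictions match the closed-form tricube weighted line solve", {
  prof <- ref_tf()
  g <- predict_depth_grid(fit_depth_loess(prof, span = 1, degree = 1))
  oracle <- tricube_line_predict(prof$midpoint_cm, prof$mean,
                                 g$midpoint_cm)
  expect_equal(g$frp_mean, pmax(oracle, 0), tolerance = 1e-6)
})

test_that("grid predictions are clamped, bounded and 40 windows long", {
  prof <- ref_tf()
  g <- predict_depth_grid(fit_depth_loess(prof))
  expect_identical(nrow(g), 40L)
  expect_identical(g$top_cm, seq(0, 97.5, by = 2.5))
  expect_true(all(g$frp_mean >= 0))
  expect_lte(max(g$frp_mean), max(prof$mean))

  # monotone decreasing inputs: no prediction exceeds the surface mean
  mono <- depth_means_profile(mean = c(20, 12, 6, 2, 0.5))
  gm <- predict_depth_grid(fit_depth_loess(mono))
  expect_lte(max(gm$frp_mean), 20)

  # a hardwood-like profile decays to ~0 in the deepest windows
  r <- reference_depth_means()
  hw <- r[r$ecosystem == "hardwood_peat", ]
  gh <- predict_depth_grid(fit_depth_loess(
    depth_means_profile(hw$mean, hw$se, hw$midpoint_cm)))
  expect_lt(max(gh$frp_mean[gh$top_cm >= 77.5]), 0.5)
})

test_that("smoothing is shift-equivariant before clamping", {
  prof <- ref_tf()
  g0 <- predict_depth_grid(fit_depth_loess(prof))
  shifted <- depth_means_profile(prof$mean + 50, prof$se,
                                 prof$midpoint_cm)
  g1 <- predict_depth_grid(fit_depth_loess(shifted))
  # +50 keeps every prediction positive, so clamping is inactive
  expect_equal(g1$frp_mean, g0$frp_mean + 50, tolerance = 1e-6)
})

test_that("infeasible spans error with the minimum feasible span", {
  prof <- ref_tf()
  expect_error(fit_depth_loess(prof, span = 0.3, degree = 1),
               "minimum feasible span")
  expect_error(fit_depth_loess(prof, span = 0.5, degree = 2),
               "minimum feasible span")
  # a feasible but small span is accepted (loess itself grumbles about
  # the tiny neighbourhoods; that is expected here)
  expect_s3_class(suppressWarnings(
    fit_depth_loess(prof, span = 0.5, degree = 1)),
    "frp_depth_smoother")
})

test_that("binning averages windows and conserves the grid average", {
  prof <- ref_tf()
  g <- predict_depth_grid(fit_depth_loess(prof))
  b <- bin_depth_profile(g)
  expect_identical(nrow(b), 10L)
  expect_identical(b$section_top_cm, seq(0, 90, by = 10))
  expect_equal(mean(b$frp_mean), mean(g$frp_mean), tolerance = 1e-12)
  # hand-check one bin
  expect_equal(b$frp_mean[3], mean(g$frp_mean[9:12]), tolerance = 1e-12)

  gc <- g; gc$frp_mean <- rep(4, 40)
  expect_equal(bin_depth_profile(gc)$frp_mean, rep(4, 10))
  gw <- g; gw$frp_mean[1:4] <- c(8, 6, 4, 2)
  expect_equal(bin_depth_profile(gw)$frp_mean[1], 5)
})

test_that("depth-weighted 0-75 cm means use the midpoint partition and match the references", {
  r <- reference_depth_means()
  prof <- function(e) {
    d <- r[r$ecosystem == e, ]
    depth_means_profile(d$mean, d$se, d$midpoint_cm)
  }
  w <- depth_weighted_mean(prof("terra_firme"))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_equal(w$weights * 75, c(4.25, 8, 15, 27.5, 20.25),
               tolerance = 1e-12)
  # independent arithmetic oracle
  tf <- r[r$ecosystem == "terra_firme", ]
  expect_equal(w$mean,
               sum(c(4.25, 8, 15, 27.5, 20.25) * tf$mean) / 75,
               tolerance = 1e-12)
  expect_equal(round(w$mean, 1), 4.1)
  expect_equal(round(depth_weighted_mean(prof("hardwood_peat"))$mean, 1),
               4.6)
  expect_equal(round(depth_weighted_mean(prof("palm_peat"))$mean, 1), 6.5)
  # constant profile: invariant to weighting
  cw <- depth_weighted_mean(depth_means_profile(rep(7, 5)))
  expect_equal(cw$mean, 7, tolerance = 1e-12)
  expect_error(depth_weighted_mean(prof("terra_firme"), max_depth_cm = 60),
               "deepest midpoint")
})
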