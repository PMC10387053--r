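test_that("constant responses with an intercept-only model recover log(c) exactly", {
  obs <- make_complete_design(n_tubes = 2, value = 3.5)
  fit <- fit_frp(obs, model_spec(~ 1, power_grid = c(1.4, 1.6)))
  expect_equal(unname(fit$beta_hat), log(3.5), tolerance = 1e-12)
})

test_that("the fit is deterministic and degenerate inputs error clearly", {
  obs <- generate_study(default_generator_spec(seed = 21, tube_sd = 0))
  f1 <- fit_frp(obs, model_spec(power_grid = 1.6))
  f2 <- fit_frp(obs, model_spec(power_grid = 1.6))
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-12)
  expect_equal(f1$phi_hat, f2$phi_hat, tolerance = 1e-8)

  zero <- make_complete_design(n_tubes = 1, value = 0)
  expect_error(fit_frp(zero), "all responses are zero")

  # season perfectly confounded with ecosystem: aliased coefficients
  conf <- as.data.frame(make_complete_design(n_tubes = 2))
  keep <- paste(conf$ecosystem, conf$season) %in%
    c("terra_firme short_wet", "hardwood_peat long_wet",
      "palm_peat long_dry")
  obs1 <- observation_set(conf[keep, ], provenance = "fixture")
  expect_error(fit_frp(obs1, model_spec(~ ecosystem + season,
                                        power_grid = 1.6)),
               "aliased")
})

test_that("fitted likelihood beats a coarse brute-force grid on small samples", {
  # intercept + one factor, n = 15; compare profile ML against a direct
  # grid over (intercept, effect, phi) at the fitted power
  set.seed(8)
  g <- expand.grid(depth_top_cm = c(0, 6, 16), season = "long_dry",
                   tube_id = 1:5, ecosystem = "terra_firme",
                   stringsAsFactors = FALSE)
  g$frp_length <- rtweedie(nrow(g), mu = c(8, 3, 1), power = 1.5, phi = 2)
  obs <- observation_set(g, provenance = "fixture")
  fit <- fit_frp(obs, model_spec(~ depth, power_grid = 1.5))
  X <- rootprod:::frp_model_matrix(~ depth, obs)
  ll <- function(beta, phi)
    sum(dtweedie(obs$frp_length, exp(drop(X %*% beta)), 1.5, phi,
                 log = TRUE))
  grid <- expand.grid(b0 = seq(-1, 3, length.out = 9),
                      b1 = seq(-2, 2, length.out = 9),
                      b2 = seq(-2, 2, length.out = 9),
                      phi = c(0.5, 1, 2, 4, 8))
  brute <- max(apply(grid, 1, function(r)
    ll(c(r["b0"], r["b1"], r["b2"]), r["phi"])))
  expect_gte(fit$loglik + 1e-8, brute)
})

test_that("fixed-effects ML agrees with an independent mixed-model engine", {
  skip_if_not_installed("glmmTMB")
  obs <- generate_study(default_generator_spec(seed = 31, tube_sd = 0))
  fit <- fit_frp(obs, model_spec(~ ecosystem + depth,
                                 power_grid = seq(1.2, 1.9, by = 0.05)))
  md <- as.data.frame(obs)
  md$depth <- factor(md$depth_top_cm)
  ref <- glmmTMB::glmmTMB(
    frp_length ~ ecosystem + depth, data = md,
    family = glmmTMB::tweedie(link = "log"),
    contrasts = list(ecosystem = "contr.sum", depth = "contr.sum"))
  expect_equal(unname(fit$beta_hat),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(fit$power_hat,
               unname(glmmTMB::family_params(ref)["Tweedie power"]),
               tolerance = 0.05)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-3)
})

test_that("tube random-intercept fit runs and reports a sensible SD", {
  skip_if_not_installed("glmmTMB")
  obs <- generate_study(default_generator_spec(seed = 41, tube_sd = 0.5,
                                               n_tubes = 8))
  fit <- suppressWarnings(
    fit_frp(obs, model_spec(~ ecosystem + depth,
                            include_tube_intercept = TRUE)))
  expect_s3_class(fit, "frp_fit")
  expect_true(fit$random$tube_sd >= 0 && fit$random$tube_sd < 2)
  expect_true(fit$power_hat > 1 && fit$power_hat < 2)
  an <- type3_anova(fit)
  expect_true("depth" %in% an$term)
})

test_that("Type-III table has product degrees of freedom and is invariant to level order", {
  obs <- generate_study(default_generator_spec(seed = 13, tube_sd = 0))
  fit <- fit_frp(obs, model_spec(power_grid = 1.6))
  an <- type3_anova(fit, include_intercept = FALSE)
  expect_identical(an$term, c("ecosystem", "season", "depth",
                              "ecosystem:season", "ecosystem:depth",
                              "season:depth"))
  expect_identical(an$df, c(2L, 2L, 4L, 4L, 8L, 8L))
  expect_true(all(an$p_value >= 0 & an$p_value <= 1))

  # reorder factor levels: chi-squares must not change
  df2 <- as.data.frame(obs)
  df2$ecosystem <- as.character(df2$ecosystem)
  perm <- observation_set(df2[order(rev(df2$ecosystem)), ],
                          provenance = "fixture")
  an2 <- type3_anova(fit_frp(perm, model_spec(power_grid = 1.6)),
                     include_intercept = FALSE)
  expect_equal(an$chi_square, an2$chi_square, tolerance = 1e-6)

  # a model without the depth term has no depth row
  an3 <- type3_anova(fit_frp(obs, model_spec(~ ecosystem + season,
                                             power_grid = 1.6)))
  expect_false("depth" %in% an3$term)
})

test_that("marginal means: cell reproduction, constant invariance, SE scaling", {
  obs <- generate_study(default_generator_spec(seed = 17, tube_sd = 0))
  fit <- fit_frp(obs, model_spec(power_grid = 1.6))
  # joint means over all factors = fitted cell means, exactly
  mm_all <- marginal_means(fit, by = c("ecosystem", "season", "depth"))
  key_mm <- paste(mm_all$ecosystem, mm_all$season, mm_all$depth)
  key_obs <- paste(obs$ecosystem, obs$season, obs$depth_top_cm)
  expect_equal(mm_all$mean[match(key_obs, key_mm)],
               unname(fit$fitted), tolerance = 1e-8)

  # constant data: every marginal mean equals the constant
  cobs <- make_complete_design(n_tubes = 2, value = 4.2)
  cfit <- fit_frp(cobs, model_spec(power_grid = 1.6))
  for (by in list(NULL, "depth", c("ecosystem", "season"))) {
    m <- marginal_means(cfit, by = by)$mean
    expect_true(all(abs(m - 4.2) < 1e-8))
  }

  expect_error(marginal_means(fit, by = "orientation"), "unknown factor")

  # link-scale SEs shrink roughly as 1/sqrt(n_tubes); quadrupling the
  # tubes should halve them (up to sampling wobble in the weights)
  se16 <- marginal_means(fit, by = "depth")$link_se
  obs64 <- generate_study(default_generator_spec(seed = 17, tube_sd = 0,
                                                 n_tubes = 64))
  fit64 <- fit_frp(obs64, model_spec(power_grid = 1.6))
  se64 <- marginal_means(fit64, by = "depth")$link_se
  ratio <- se16 / se64
  expect_gt(mean(ratio), 1.6)
  expect_lt(mean(ratio), 2.4)
  expect_true(all(ratio > 1.2 & ratio < 3.2))
})

test_that("pairwise Tukey comparisons: combinatorics and identical-level edge", {
  obs <- generate_study(default_generator_spec(seed = 19, tube_sd = 0))
  fit <- fit_frp(obs, model_spec(power_grid = 1.6))
  for (by in list("season", "depth")) {
    mm <- marginal_means(fit, by = by)
    k <- nrow(mm)
    tk <- pairwise_tukey(mm)
    expect_identical(nrow(tk), as.integer(k * (k - 1) / 2))
    expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  }
  # hand-built table with two identical levels
  mm2 <- structure(
    data.frame(season = c("a", "b"), mean = c(2, 2), se = c(0.1, 0.1),
               link_est = c(log(2), log(2)), link_se = c(0.05, 0.05)),
    link_vcov = matrix(c(0.0025, 0, 0, 0.0025), 2),
    df = 100, by = "season", class = c("frp_emm", "data.frame"))
  tk2 <- pairwise_tukey(mm2)
  expect_equal(tk2$difference, 0)
  expect_equal(tk2$p_adj, 1, tolerance = 1e-10)
  # single level: empty table
  mm1 <- mm2[1, ]
  attr(mm1, "link_vcov") <- matrix(0.0025)
  attr(mm1, "df") <- 100; attr(mm1, "by") <- "season"
  class(mm1) <- c("frp_emm", "data.frame")
  expect_identical(nrow(pairwise_tukey(mm1)), 0L)
})

test_that("AICc ranking: identical fits tie, simpler model wins on null data, divergence flagged", {
  obs <- generate_study(default_generator_spec(seed = 23, tube_sd = 0))
  f <- fit_frp(obs, model_spec(~ ecosystem + depth, power_grid = 1.6))
  cmp <- aicc_compare(list(a = f, b = f))
  expect_equal(cmp$delta_aicc, c(0, 0))

  # a spurious season term on season-null data loses most of the time
  wins <- vapply(1:30, function(s) {
    cells <- rootprod:::default_cell_means()
    cells$mu <- ave(cells$mu, cells$ecosystem, cells$depth_top_cm)
    beta <- beta_from_cell_means(cells)
    spec <- generator_spec(beta, power_p = 1.6, phi = 5, tube_sd = 0,
                           n_tubes = 8, seed = 3000 + s)
    o <- generate_study(spec)
    small <- fit_frp(o, model_spec(~ ecosystem + depth, power_grid = 1.6))
    big <- fit_frp(o, model_spec(~ ecosystem + depth + season,
                                 power_grid = 1.6))
    aicc_compare(list(small = small, big = big))$model[1] == "small"
  }, TRUE)
  expect_gt(mean(wins), 0.5)

  o4 <- observation_set(as.data.frame(
    make_complete_design(n_tubes = 1))[1:4, ], provenance = "fixture")
  fit4 <- fit_frp(o4, model_spec(~ 1, power_grid = 1.6))
  cmp4 <- aicc_compare(list(tiny = fit4))
  expect_true(cmp4$diverged)

  o5 <- generate_study(default_generator_spec(seed = 2, n_tubes = 4))
  f5 <- fit_frp(o5, model_spec(~ 1, power_grid = 1.6))
  expect_error(aicc_compare(list(f, f5)), "different numbers")
})
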