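# Shared fixtures and simulation helpers for the test suite.

# complete 720-row deterministic design with a simple mean pattern
make_complete_design <- function(n_tubes = 16, value = NULL) {
  g <- expand.grid(depth_top_cm = c(0, 6, 16, 36, 71),
                   season = c("short_wet", "long_wet", "long_dry"),
                   tube_id = seq_len(n_tubes),
                   ecosystem = c("terra_firme", "hardwood_peat",
                                 "palm_peat"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$frp_length <- if (is.null(value)) seq_len(nrow(g)) / 7 else value
  observation_set(g, provenance = "fixture")
}

# generator with a strong depth gradient, no ecosystem effect, mild
# seasonality: the generating truth for the recovery / power / size
# simulations. Cell means are the grand per-depth means of the
# reference table, identical across ecosystems.
null_ecosystem_spec <- function(seed, n_tubes = 16, power_p = 1.6) {
  ref <- reference_depth_means()
  depth_means <- tapply(ref$mean, ref$depth_top_cm, mean)
  seas <- c(short_wet = 3.9, long_wet = 5.4, long_dry = 6.2)
  seas <- seas / mean(seas)
  cells <- expand.grid(depth_top_cm = c(0, 6, 16, 36, 71),
                       season = names(seas),
                       ecosystem = c("terra_firme", "hardwood_peat",
                                     "palm_peat"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$mu <- depth_means[as.character(cells$depth_top_cm)] *
    seas[cells$season]
  beta <- beta_from_cell_means(cells)
  f <- function(phi) mean(exp(-cells$mu^(2 - power_p) /
                                (phi * (2 - power_p)))) - 0.75
  phi <- stats::uniroot(f, c(1e-3, 1e4), tol = 1e-10)$root
  generator_spec(beta, power_p = power_p, phi = phi, tube_sd = 0,
                 n_tubes = n_tubes, seed = seed)
}

# run `n_rep` replicate fits under the null-ecosystem truth and collect
# depth-coefficient estimates/SEs and the Type-III p-values. The truth
# is additive (no interactions), so the fitted recovery model is the
# generating one: ecosystem + season + depth.
run_recovery_sims <- function(n_rep, power_grid = c(1.4, 1.6, 1.8)) {
  spec0 <- null_ecosystem_spec(seed = 1)
  form <- ~ ecosystem + season + depth
  cells <- rootprod:::design_grid(1)
  Xfull <- rootprod:::frp_model_matrix(rootprod:::FULL_FIXED_FORMULA,
                                       cells)
  X <- rootprod:::frp_model_matrix(form, cells)
  true_beta <- qr.coef(qr(X), drop(Xfull %*% spec0$beta))
  depth_idx <- which(attr(X, "assign") ==
                       match("depth", attr(stats::terms(form),
                                           "term.labels")))
  true_depth <- true_beta[depth_idx]
  ms <- model_spec(form, power_grid = power_grid)
  res <- lapply(seq_len(n_rep), function(r) {
    spec <- null_ecosystem_spec(seed = 1000 + r)
    obs <- generate_study(spec)
    fit <- fit_frp(obs, ms)
    an <- type3_anova(fit)
    est <- fit$beta_hat[depth_idx]
    se <- sqrt(diag(fit$cov_beta))[depth_idx]
    list(est = est, se = se,
         covered = abs(est - true_depth) <= 1.96 * se,
         p_depth = an$p_value[an$term == "depth"],
         p_eco = an$p_value[an$term == "ecosystem"])
  })
  list(true_depth = true_depth,
       est = do.call(rbind, lapply(res, `[[`, "est")),
       covered = do.call(rbind, lapply(res, `[[`, "covered")),
       p_depth = vapply(res, `[[`, 0, "p_depth"),
       p_eco = vapply(res, `[[`, 0, "p_eco"))
}

# closed-form local tricube weighted least squares line, the
# independent oracle for the LOESS path (span 1, degree 1, direct
# surface): bandwidth is the largest distance from the target times
# span^(1/d) for span >= 1 (here = d_max)
tricube_line_predict <- function(x, y, x0) {
  vapply(x0, function(t) {
    d <- abs(x - t)
    h <- max(d)
    w <- pmax(1 - (d / h)^3, 0)^3
    W <- diag(w)
    Xl <- cbind(1, x - t)
    b <- solve(t(Xl) %*% W %*% Xl, t(Xl) %*% W %*% y)
    b[1]
  }, 0.0)
}
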