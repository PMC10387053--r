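# End-to-end orchestration: simulate (or read) observations, fit the
# Tweedie regression, extrapolate depth profiles, convert to carbon,
# and write CSV/JSON artifacts; plus the arithmetic reproduction report
# computed from the packaged reference tables.

#' Assemble a pipeline run configuration
#'
#' All defaults are resolvable without any external file; any subset can
#' be overridden, including from a YAML config via [read_run_config()].
#'
#' @param input_csv optional path to an observation CSV; when `NULL`
#'   (default) observations are simulated from `generator`.
#' @param generator an `frp_generator_spec`; defaults to
#'   [default_generator_spec()] with `seed`.
#' @param model an `frp_model_spec`.
#' @param span,degree LOESS options for the depth extrapolation.
#' @param constants an `frp_constants` object.
#' @param seed integer seed for the simulation stage.
#' @param outdir output directory; `NULL` disables file output.
#' @return object of class `frp_run_config`.
#' @export
run_config <- function(input_csv = NULL, generator = NULL, model = NULL,
                       span = 1, degree = 1, constants = NULL,
                       seed = 1L, outdir = NULL) {
  structure(list(
    input_csv = input_csv,
    generator = generator %||% default_generator_spec(seed = seed),
    model = model %||% model_spec(),
    span = span, degree = degree,
    constants = constants %||% conversion_constants(),
    seed = as.integer(seed), outdir = outdir),
    class = "frp_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `input_csv`, `seed`, `outdir`, `span`,
#' `degree`, `generator` (keys `tube_sd`, `n_tubes`, `power_p`,
#' `target_zero_fraction`), `model` (keys `power_grid`,
#' `include_tube_intercept`), `constants` (keys as in
#' [conversion_constants()]). Missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return an `frp_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- as.integer(cfg$seed %||% 1L)
  gen <- do.call(default_generator_spec,
                 c(cfg$generator, list(seed = seed)))
  mod <- do.call(model_spec, cfg$model %||% list())
  cons <- do.call(conversion_constants, cfg$constants %||% list())
  run_config(input_csv = cfg$input_csv, generator = gen, model = mod,
             span = cfg$span %||% 1, degree = cfg$degree %||% 1,
             constants = cons, seed = seed, outdir = cfg$outdir)
}

#' Run the full FRP estimation pipeline
#'
#' Stages: obtain observations (simulate or read), validate the design,
#' fit the Tweedie regression, compute marginal means per ecosystem and
#' depth (averaged over seasons), LOESS-extrapolate each ecosystem's
#' depth profile to 1 m, bin to 10-cm sections and convert to carbon
#' flux. Deterministic given the seed. When `config$outdir` is set the
#' observations, marginal means, depth grids and carbon table are
#' written as CSV and a combined JSON report.
#'
#' @param config an `frp_run_config`.
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list with `observations`, `design_report`,
#'   `fit`, `marginal_means`, `grids`, `binned`, `carbon`, `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "frp_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  obs <- stage("observations", {
    if (!is.null(config$input_csv)) read_observations(config$input_csv)
    else generate_study(config$generator)
  })
  say("observations: %d rows (%s, seed %d)", nrow(obs),
      attr(obs, "provenance"), config$seed)
  report <- validate_design(obs)
  if (!report$full_design)
    say("design: reduced or incomplete (%d tubes, %d missing keys)",
        report$n_tubes, nrow(report$missing_keys))
  fit <- stage("fit", fit_frp(obs, config$model))
  say("fit: power %.2f, phi %.3f, logLik %.1f", fit$power_hat,
      fit$phi_hat, fit$loglik)
  mm <- stage("marginal_means",
              marginal_means(fit, by = c("ecosystem", "depth")))
  ecos <- unique(mm$ecosystem)
  grids <- stage("depth_profile", lapply(stats::setNames(ecos, ecos),
    function(e) {
      d <- mm[mm$ecosystem == e, ]
      prof <- depth_means_profile(
        mean = d$mean[order(as.numeric(d$depth))],
        se = d$se[order(as.numeric(d$depth))],
        midpoint_cm = sort(as.numeric(d$depth)) + WINDOW_SPAN_CM / 2)
      predict_depth_grid(fit_depth_loess(prof, span = config$span,
                                         degree = config$degree))
    }))
  binned <- lapply(grids, bin_depth_profile)
  carbon <- stage("carbon", assemble_carbon_table(binned,
                                                  config$constants))
  say("carbon: totals %s", paste(sprintf("%s %.2f",
      attr(carbon, "totals")$ecosystem,
      attr(carbon, "totals")$total), collapse = ", "))
  res <- list(observations = obs, design_report = report, fit = fit,
              marginal_means = mm, grids = grids, binned = binned,
              carbon = carbon, config = config)
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  invisible(res)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_observations(res$observations, file.path(outdir, "observations.csv"))
  utils::write.csv(as.data.frame(res$marginal_means),
                   file.path(outdir, "marginal_means.csv"),
                   row.names = FALSE)
  grids <- do.call(rbind, lapply(names(res$grids), function(e)
    cbind(ecosystem = e, as.data.frame(res$grids[[e]]))))
  utils::write.csv(grids, file.path(outdir, "depth_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$carbon),
                   file.path(outdir, "carbon_table.csv"),
                   row.names = FALSE)
  json <- list(
    provenance = attr(res$observations, "provenance"),
    seed = res$config$seed,
    design = list(n = res$design_report$n,
                  n_tubes = res$design_report$n_tubes,
                  zero_fraction = res$design_report$zero_fraction,
                  full_design = res$design_report$full_design,
                  missing_keys = nrow(res$design_report$missing_keys)),
    fit = list(power = res$fit$power_hat, phi = res$fit$phi_hat,
               loglik = res$fit$loglik, aicc = res$fit$aicc),
    totals = attr(res$carbon, "totals"))
  jsonlite::write_json(json, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Recompute the published headline arithmetic from the reference tables
#'
#' Pure arithmetic on the packaged reference tables — no model fitting
#' and no randomness, so re-runs are bit-identical. Checks: the grand
#' per-depth marginal means (average of the three ecosystem means per
#' depth row), within-ecosystem percentages of surface FRP at 16-18.5
#' and 71-73.5 cm, 0-30 cm carbon sums, totals and root-sum-of-squares
#' total SEs of the carbon table, and the depth-weighted 0-75 cm
#' profile means via the midpoint-partition weights.
#'
#' Each check records the rounding band it is compared at: agreement at
#' the printed decimal for directly printed arithmetic, and a slightly
#' wider band for quantities whose published inputs are themselves
#' rounded (the palm total SE, the printed totals, and the
#' depth-weighted means for hardwood and palm, which reconstruct to 4.6
#' and 6.5 against printed 4.7 and 6.6).
#'
#' @return data.frame of class `frp_repro_report` with columns `check`,
#'   `computed`, `printed`, `tolerance`, `pass`.
#' @export
reproduce_reference <- function() {
  ref <- reference_depth_means()
  carb <- reference_carbon_profile()
  val <- c()
  # grand per-depth means across the three ecosystems
  for (d in MEASURED_DEPTHS)
    val[paste0("grand_mean_depth_", d)] <-
      mean(ref$mean[ref$depth_top_cm == d])
  short <- c(terra_firme = "terra_firme", hardwood_peat = "hardwood",
             palm_peat = "palm")
  # percentage of the 0-2.5 cm FRP found at 16-18.5 and 71-73.5 cm
  for (e in ECOSYSTEMS) {
    m <- ref[ref$ecosystem == e, ]
    surf <- m$mean[m$depth_top_cm == 0]
    val[paste0("ratio_", short[e], "_16_vs_0_pct")] <-
      100 * m$mean[m$depth_top_cm == 16] / surf
    val[paste0("ratio_", short[e], "_71_vs_0_pct")] <-
      100 * m$mean[m$depth_top_cm == 71] / surf
  }
  # carbon sums, totals, propagated SEs
  for (e in ECOSYSTEMS) {
    cc <- carb[carb$ecosystem == e, ]
    val[paste0("carbon_0_30_", short[e])] <-
      sum(cc$carbon[cc$section_top_cm < 30])
    val[paste0("total_se_", short[e])] <- propagate_total_se(cc$se)
    val[paste0("total_carbon_", short[e])] <- sum(cc$carbon)
  }
  # depth-weighted 0-75 cm means
  for (e in ECOSYSTEMS) {
    m <- ref[ref$ecosystem == e, ]
    val[paste0("depth_weighted_mean_", short[e])] <-
      depth_weighted_mean(depth_means_profile(
        mean = m$mean, se = m$se, midpoint_cm = m$midpoint_cm),
        max_depth_cm = 75)$mean
  }
  val <- val[!is.na(val)]
  printed <- reference_printed_values()
  out <- data.frame(check = printed$check,
                    computed = as.numeric(val[printed$check]),
                    printed = printed$printed,
                    tolerance = printed$tolerance)
  out$pass <- abs(out$computed - out$printed) <= out$tolerance + 1e-9
  structure(out, class = c("frp_repro_report", "data.frame"))
}

#' @export
print.frp_repro_report <- function(x, ...) {
  cat("Reproduction of published arithmetic from packaged tables\n")
  y <- x
  y$computed <- sprintf("%.4f", y$computed)
  print.data.frame(y, row.names = FALSE)
  cat(sprintf("%d of %d checks pass\n", sum(x$pass), nrow(x)))
  invisible(x)
}
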