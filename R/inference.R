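# Wald inference on the fitted Tweedie regression: Type-III tests,
# estimated marginal means and Tukey pairwise comparisons.

#' Type-III Wald chi-square tests
#'
#' Tests, for each model term, that its coefficients are jointly zero in
#' the presence of every other term. With the sum-to-zero contrasts the
#' fit uses throughout, these are the conventional Type-III tests; the
#' statistic for term T is `b_T' V_TT^{-1} b_T` with `V` the coefficient
#' covariance, referred to a chi-square distribution on the term's
#' degrees of freedom.
#'
#' @param fit an `frp_fit`.
#' @param include_intercept logical; prepend the intercept row (the test
#'   that the grand log mean is zero), as conventional in Type-III
#'   ANOVA tables.
#' @return data.frame of class `frp_anova` with columns `term`,
#'   `chi_square`, `df`, `p_value`.
#' @export
type3_anova <- function(fit, include_intercept = TRUE) {
  stopifnot(inherits(fit, "frp_fit"))
  labels <- c(if (include_intercept) "(Intercept)", fit$term_labels)
  ids <- c(if (include_intercept) 0L, seq_along(fit$term_labels))
  rows <- lapply(seq_along(ids), function(j) {
    idx <- which(fit$assign == ids[j])
    b <- fit$beta_hat[idx]
    V <- fit$cov_beta[idx, idx, drop = FALSE]
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12)
      stop("singular coefficient covariance for term '", labels[j], "'",
           call. = FALSE)
    chi <- drop(crossprod(b, solve(V, b)))
    data.frame(term = labels[j], chi_square = chi, df = length(idx),
               p_value = stats::pchisq(chi, length(idx),
                                       lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frp_anova", "data.frame")
  out
}

#' @export
print.frp_anova <- function(x, ...) {
  cat("Type-III Wald chi-square tests\n")
  y <- x
  y$chi_square <- sprintf("%.3f", y$chi_square)
  y$p_value <- format.pval(x$p_value, digits = 3, eps = 1e-3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Estimated marginal means
#'
#' Averages the linear predictor with equal weight over the levels of
#' every factor not named in `by`, then back-transforms through the log
#' link. Standard errors are delta-method: on the response scale
#' `SE = exp(lp) * SE(lp)` with `SE(lp)` from the coefficient
#' covariance.
#'
#' @param fit an `frp_fit`.
#' @param by character vector of factor names (`"ecosystem"`,
#'   `"season"`, `"depth"`) to retain; `NULL` gives the single grand
#'   mean.
#' @return data.frame of class `frp_emm` with the `by` columns plus
#'   `mean` (response scale, m m^-2 mo^-1), `se`, `link_est`,
#'   `link_se`. The link-scale covariance, residual df and level count
#'   are attached as attributes for [pairwise_tukey()].
#' @export
marginal_means <- function(fit, by = NULL) {
  stopifnot(inherits(fit, "frp_fit"))
  facs <- c("ecosystem", "season", "depth")
  used <- facs[facs %in% all.vars(fit$formula)]
  if (length(bad <- setdiff(by, used)))
    stop("unknown factor(s) in 'by': ", paste(bad, collapse = ", "),
         call. = FALSE)
  md <- fit$data
  md$depth <- factor(md$depth_top_cm)
  lv <- lapply(md[used], function(f) levels(droplevels(as.factor(f))))
  ref <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!nrow(ref)) ref <- data.frame(row.names = 1)
  # keep declared level order (numeric for depth, canonical otherwise)
  for (v in names(lv)) ref[[v]] <- factor(ref[[v]], levels = lv[[v]])
  # rebuild the depth_top_cm column the model-matrix helper expects
  ref$depth_top_cm <- if ("depth" %in% used)
    as.numeric(as.character(ref$depth)) else md$depth_top_cm[1]
  if (!"ecosystem" %in% used) ref$ecosystem <- md$ecosystem[1]
  if (!"season" %in% used) ref$season <- md$season[1]
  Xg <- frp_model_matrix(fit$formula, ref)
  group <- if (length(by)) interaction(ref[by], drop = FALSE, sep = " / ")
  else factor(rep("(all)", nrow(ref)))
  L <- t(vapply(levels(group), function(g) colMeans(
    Xg[group == g, , drop = FALSE]), numeric(ncol(Xg))))
  est <- drop(L %*% fit$beta_hat)
  V <- L %*% fit$cov_beta %*% t(L)
  se_link <- sqrt(pmax(diag(V), 0))
  out <- if (length(by)) {
    keys <- do.call(rbind, strsplit(levels(group), " / ", fixed = TRUE))
    stats::setNames(as.data.frame(keys, stringsAsFactors = FALSE), by)
  } else data.frame(level = "(all)")
  out$mean <- exp(est)
  out$se <- exp(est) * se_link
  out$link_est <- est
  out$link_se <- se_link
  structure(out, link_vcov = V, df = fit$df_residual, by = by,
            class = c("frp_emm", "data.frame"))
}

#' @export
print.frp_emm <- function(x, ...) {
  cat("Estimated marginal means (response scale, m m^-2 mo^-1)\n")
  print.data.frame(cbind(x[, setdiff(names(x), c("link_est", "link_se")),
                           drop = FALSE]),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey pairwise comparisons of marginal means
#'
#' All pairwise contrasts between the rows of a marginal-mean table,
#' tested on the link (log) scale with studentised-range (Tukey)
#' adjusted p-values. The back-transformed contrast is reported as a
#' response-scale ratio.
#'
#' @param mm an `frp_emm` table.
#' @return data.frame with columns `contrast`, `difference` (log
#'   scale), `ratio`, `se`, `df`, `t_ratio`, `p_adj`. Zero rows when the
#'   table has a single level.
#' @export
pairwise_tukey <- function(mm) {
  stopifnot(inherits(mm, "frp_emm"))
  k <- nrow(mm)
  lab <- if (length(attr(mm, "by")))
    do.call(paste, c(mm[attr(mm, "by")], sep = " "))
  else mm$level
  if (k < 2) {
    out <- data.frame(contrast = character(), difference = numeric(),
                      ratio = numeric(), se = numeric(), df = numeric(),
                      t_ratio = numeric(), p_adj = numeric())
    return(out)
  }
  V <- attr(mm, "link_vcov")
  df <- attr(mm, "df")
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- mm$link_est[i] - mm$link_est[j]
    se <- sqrt(max(V[i, i] + V[j, j] - 2 * V[i, j], 0))
    t <- if (se > 0) d / se else 0
    p <- if (se > 0)
      stats::ptukey(sqrt(2) * abs(t), nmeans = k, df = df,
                    lower.tail = FALSE)
    else 1
    data.frame(contrast = paste(lab[i], "-", lab[j]), difference = d,
               ratio = exp(d), se = se, df = df, t_ratio = t, p_adj = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank fits by small-sample-corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)` with `k` the number
#' of estimated parameters (coefficients plus dispersion and power, plus
#' the random-intercept SD when present). Fits must be on the same
#' data; when `n - k - 1 <= 0` the correction diverges and the fit is
#' flagged.
#'
#' @param fits list of `frp_fit` objects (optionally named).
#' @return data.frame sorted by AICc with columns `model`, `k`,
#'   `loglik`, `aicc`, `delta_aicc`, `diverged`.
#' @export
aicc_compare <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "frp_fit")))
  n <- vapply(fits, function(f) f$n, 0)
  if (length(unique(n)) != 1)
    stop("fits were made on different numbers of observations",
         call. = FALSE)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model_", seq_along(fits))
  k <- vapply(fits, function(f)
    f$rank + 2 + if (!is.null(f$random)) 1 else 0, 0)
  out <- data.frame(model = nm, k = k,
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    aicc = vapply(fits, function(f) f$aicc, 0),
                    diverged = n[1] - k - 1 <= 0)
  out <- out[order(out$aicc), ]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  out
}
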