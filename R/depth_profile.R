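# Extrapolation of the five measured depth means over a 1-m soil
# profile: LOESS through the per-depth means, prediction every 2.5 cm,
# aggregation to 10-cm sections, and depth-weighted profile averages.

#' Build a five-point depth-means profile
#'
#' @param mean per-depth FRP means (m m^-2 mo^-1), ordered by depth.
#' @param se matching standard errors.
#' @param midpoint_cm window midpoints; defaults to the measured windows
#'   1.25, 7.25, 17.25, 37.25, 72.25 cm.
#' @return data.frame of class `frp_depth_means`.
#' @export
depth_means_profile <- function(mean, se = rep(0, length(mean)),
                                midpoint_cm = MEASURED_DEPTHS +
                                  WINDOW_SPAN_CM / 2) {
  if (length(mean) != length(midpoint_cm) || length(se) != length(mean))
    stop("mean, se and midpoint_cm must have equal length", call. = FALSE)
  if (any(mean < 0) || any(se < 0))
    stop("means and SEs must be >= 0", call. = FALSE)
  structure(data.frame(midpoint_cm = midpoint_cm, mean = mean, se = se),
            class = c("frp_depth_means", "data.frame"))
}

#' Fit the LOESS depth smoother
#'
#' Locally weighted linear regression (tricube weights) of the per-depth
#' means on window midpoint, fitted by exact computation
#' (`stats::loess` with a direct surface) so that predictions can be
#' extended below the deepest measured window. The standard errors are
#' passed through an identical smoother, so the uncertainty profile is
#' extrapolated the same way as the means.
#'
#' @param profile an `frp_depth_means` (or data.frame with columns
#'   `midpoint_cm`, `mean` and optionally `se`).
#' @param span smoothing span as a fraction of points entering each
#'   local fit; the default 1 uses all points, tricube-downweighted.
#' @param degree local polynomial degree (0, 1 or 2); default 1.
#' @return object of class `frp_depth_smoother`.
#' @export
fit_depth_loess <- function(profile, span = 1, degree = 1) {
  if (!all(c("midpoint_cm", "mean") %in% names(profile)))
    stop("'profile' needs columns midpoint_cm and mean", call. = FALSE)
  n <- nrow(profile)
  if (!degree %in% 0:2) stop("'degree' must be 0, 1 or 2", call. = FALSE)
  min_span <- (degree + 1) / n
  if (floor(span * n) < degree + 1)
    stop(sprintf(
      "span %.3g too small for %d points at degree %d; minimum feasible span is %.3g",
      span, n, degree, min_span), call. = FALSE)
  if (is.null(profile$se)) profile$se <- 0
  ctrl <- stats::loess.control(surface = "direct")
  sm_mean <- stats::loess(mean ~ midpoint_cm, data = profile, span = span,
                          degree = degree, control = ctrl)
  sm_se <- stats::loess(se ~ midpoint_cm, data = profile, span = span,
                        degree = degree, control = ctrl)
  structure(list(mean = sm_mean, se = sm_se, span = span, degree = degree,
                 profile = profile),
            class = "frp_depth_smoother")
}

#' Predict the 2.5-cm depth grid
#'
#' Evaluates the smoother at the midpoints of the 40 contiguous 2.5-cm
#' windows covering 0-100 cm. Below the deepest measured window the
#' boundary local fit is extended; negative predictions (for means and
#' SEs) are clamped to zero, matching the convention that extrapolated
#' production cannot be negative.
#'
#' @param smoother an `frp_depth_smoother`.
#' @return data.frame of class `frp_depth_grid` with 40 rows and
#'   columns `top_cm`, `midpoint_cm`, `frp_mean`, `frp_se`.
#' @export
predict_depth_grid <- function(smoother) {
  stopifnot(inherits(smoother, "frp_depth_smoother"))
  g <- depth_grid()
  nd <- data.frame(midpoint_cm = g$midpoint_cm)
  out <- data.frame(
    top_cm = g$top_cm,
    midpoint_cm = g$midpoint_cm,
    frp_mean = pmax(stats::predict(smoother$mean, nd), 0),
    frp_se = pmax(stats::predict(smoother$se, nd), 0))
  structure(out, class = c("frp_depth_grid", "data.frame"))
}

#' Aggregate the prediction grid to 10-cm sections
#'
#' Each 10-cm section holds the mean of its four 2.5-cm window
#' predictions (so a section total is the section mean times the
#' section depth, applied downstream in the carbon conversion); the
#' section SE is likewise the mean of the four window SEs, which treats
#' windows within a section as fully dependent smoother evaluations.
#'
#' @param grid an `frp_depth_grid` of 40 windows.
#' @return data.frame of class `frp_binned` with 10 rows and columns
#'   `section_top_cm`, `frp_mean`, `frp_se`.
#' @export
bin_depth_profile <- function(grid) {
  stopifnot(inherits(grid, "frp_depth_grid"), nrow(grid) == 40)
  sec <- (seq_len(40) - 1) %/% 4
  out <- data.frame(
    section_top_cm = seq(0, 90, by = 10),
    frp_mean = as.numeric(tapply(grid$frp_mean, sec, mean)),
    frp_se = as.numeric(tapply(grid$frp_se, sec, mean)))
  structure(out, class = c("frp_binned", "data.frame"))
}

#' Depth-weighted profile mean
#'
#' Weighted mean of the five measured per-depth values over a 0 to
#' `max_depth_cm` profile, each window weighted by the span of the
#' midpoint partition it represents: interval boundaries lie at the
#' surface, halfway between adjacent window midpoints, and at
#' `max_depth_cm`. For the measured windows and a 75-cm profile the
#' widths are 4.25, 8, 15, 27.5 and 20.25 cm.
#'
#' @param profile an `frp_depth_means` (or data.frame with
#'   `midpoint_cm`, `mean` and optionally `se`).
#' @param max_depth_cm profile depth; must be at least the deepest
#'   midpoint.
#' @return list with `mean`, `se` (the same weighting applied to the
#'   SEs) and the `weights` used (summing to 1).
#' @export
depth_weighted_mean <- function(profile, max_depth_cm = 75) {
  if (!all(c("midpoint_cm", "mean") %in% names(profile)))
    stop("'profile' needs columns midpoint_cm and mean", call. = FALSE)
  mid <- profile$midpoint_cm
  if (is.unsorted(mid, strictly = TRUE))
    stop("midpoints must be strictly increasing", call. = FALSE)
  if (max_depth_cm < max(mid))
    stop("'max_depth_cm' must reach the deepest midpoint", call. = FALSE)
  bounds <- c(0, (utils::head(mid, -1) + utils::tail(mid, -1)) / 2,
              max_depth_cm)
  w <- diff(bounds) / max_depth_cm
  list(mean = sum(w * profile$mean),
       se = if (!is.null(profile$se)) sum(w * profile$se) else NA_real_,
       weights = w)
}
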