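#' @importFrom stats setNames
NULL

# canonical factor levels for the study design
ECOSYSTEMS <- c("terra_firme", "hardwood_peat", "palm_peat")
SEASONS <- c("short_wet", "long_wet", "long_dry")
MEASURED_DEPTHS <- c(0, 6, 16, 36, 71)
WINDOW_SPAN_CM <- 2.5

#' Measured minirhizotron depth windows
#'
#' The five photographed windows of the study design. Each window spans
#' 2.5 cm of tube depth; windows are addressed by their top depth and the
#' midpoint is derived, never stored.
#'
#' @return data.frame with columns `top_cm`, `span_cm`, `midpoint_cm`
#'   for the windows topped at 0, 6, 16, 36 and 71 cm.
#' @seealso [depth_grid()] for the 2.5-cm prediction grid to 1 m.
#' @export
depth_windows <- function() {
  data.frame(top_cm = MEASURED_DEPTHS,
             span_cm = WINDOW_SPAN_CM,
             midpoint_cm = MEASURED_DEPTHS + WINDOW_SPAN_CM / 2)
}

#' Prediction grid of 2.5-cm windows over a 1-m profile
#'
#' @return data.frame of 40 contiguous windows with tops 0, 2.5, ...,
#'   97.5 cm and their midpoints.
#' @export
depth_grid <- function() {
  tops <- seq(0, 97.5, by = 2.5)
  data.frame(top_cm = tops,
             span_cm = WINDOW_SPAN_CM,
             midpoint_cm = tops + WINDOW_SPAN_CM / 2)
}

#' Build a validated observation set
#'
#' An observation set is one row per (ecosystem, tube, season, depth
#' window) with the measured new-root length per window area
#' (m m^-2 mo^-1). The full study design holds 3 ecosystems x 16 tubes x
#' 3 seasons x 5 depths = 720 rows.
#'
#' @param data data.frame with columns `ecosystem`, `tube_id`, `season`,
#'   `depth_top_cm`, `frp_length`.
#' @param provenance character tag, one of `"measured"`, `"synthetic"`,
#'   `"fixture"`.
#' @return an object of class `frp_observations` (a data.frame with the
#'   factor columns coerced to the canonical level sets).
#' @export
observation_set <- function(data, provenance = "measured") {
  req <- c("ecosystem", "tube_id", "season", "depth_top_cm", "frp_length")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  provenance <- match.arg(provenance, c("measured", "synthetic", "fixture"))
  obs <- data.frame(
    ecosystem = as.character(data$ecosystem),
    tube_id = as.integer(data$tube_id),
    season = as.character(data$season),
    depth_top_cm = as.numeric(data$depth_top_cm),
    frp_length = as.numeric(data$frp_length)
  )
  bad_eco <- !obs$ecosystem %in% ECOSYSTEMS
  if (any(bad_eco))
    stop("unknown ecosystem level(s) in row(s) ",
         paste(utils::head(which(bad_eco), 5), collapse = ", "),
         ": ", paste(unique(obs$ecosystem[bad_eco]), collapse = ", "),
         call. = FALSE)
  bad_season <- !obs$season %in% SEASONS
  if (any(bad_season))
    stop("unknown season level(s) in row(s) ",
         paste(utils::head(which(bad_season), 5), collapse = ", "),
         call. = FALSE)
  bad_depth <- !obs$depth_top_cm %in% MEASURED_DEPTHS
  if (any(bad_depth))
    stop("depth_top_cm must be one of ",
         paste(MEASURED_DEPTHS, collapse = ", "),
         " (offending row(s) ",
         paste(utils::head(which(bad_depth), 5), collapse = ", "), ")",
         call. = FALSE)
  neg <- !is.finite(obs$frp_length) | obs$frp_length < 0
  if (any(neg))
    stop("frp_length must be finite and >= 0; offending row(s): ",
         paste(utils::head(which(neg), 5), collapse = ", "), call. = FALSE)
  key <- with(obs, paste(ecosystem, tube_id, season, depth_top_cm))
  if (anyDuplicated(key))
    stop("duplicate (ecosystem, tube_id, season, depth) key(s), e.g. ",
         key[duplicated(key)][1], call. = FALSE)
  obs$ecosystem <- factor(obs$ecosystem, levels = ECOSYSTEMS)
  obs$season <- factor(obs$season, levels = SEASONS)
  structure(obs, provenance = provenance,
            class = c("frp_observations", "data.frame"))
}

#' @export
print.frp_observations <- function(x, ...) {
  cat(sprintf("FRP observation set: %d rows (%s)\n", nrow(x),
              attr(x, "provenance")))
  cat(sprintf("  ecosystems: %s\n",
              paste(levels(droplevels(x$ecosystem)), collapse = ", ")))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$frp_length == 0)))
  invisible(x)
}

#' Read an observation CSV
#'
#' Expects a comma-separated UTF-8 file with a header row defining the
#' columns `ecosystem`, `tube_id`, `season`, `depth_top_cm`,
#' `frp_length`.
#'
#' @param path file path.
#' @param provenance provenance tag recorded on the returned set.
#' @return an `frp_observations` object.
#' @export
read_observations <- function(path, provenance = "measured") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_set(df, provenance = provenance)
}

#' Write an observation CSV
#'
#' Inverse of [read_observations()]; the round trip reproduces every
#' field exactly (values are written with full precision).
#'
#' @param obs an `frp_observations` object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "frp_observations"))
  df <- as.data.frame(obs)
  df$ecosystem <- as.character(df$ecosystem)
  df$season <- as.character(df$season)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Report on design completeness of an observation set
#'
#' Checks the observed rows against the full cross of the observed
#' factor levels and tube identifiers, counts observations per
#' (ecosystem, season, depth) cell, and reports the overall fraction of
#' exact zeros. In the field campaign being emulated roughly
#' three-quarters of individual window measurements recorded no new
#' roots.
#'
#' @param obs an `frp_observations` object.
#' @return an object of class `frp_design_report`: a list with elements
#'   `n`, `n_tubes`, `cell_counts` (rows per ecosystem x season x depth),
#'   `missing_keys` (data.frame of absent design keys),
#'   `zero_fraction`, and `full_design` (TRUE when all 3 ecosystems,
#'   3 seasons, 5 depths and 16 tubes are present with no missing keys).
#' @export
validate_design <- function(obs) {
  stopifnot(inherits(obs, "frp_observations"))
  tubes <- sort(unique(obs$tube_id))
  ecos <- levels(droplevels(obs$ecosystem))
  seas <- levels(droplevels(obs$season))
  deps <- sort(unique(obs$depth_top_cm))
  expected <- expand.grid(ecosystem = ecos, tube_id = tubes,
                          season = seas, depth_top_cm = deps,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_obs <- with(obs, paste(ecosystem, tube_id, season, depth_top_cm))
  key_exp <- with(expected, paste(ecosystem, tube_id, season, depth_top_cm))
  missing_keys <- expected[!key_exp %in% key_obs, , drop = FALSE]
  rownames(missing_keys) <- NULL
  cell_counts <- as.data.frame(table(
    ecosystem = obs$ecosystem, season = obs$season,
    depth_top_cm = obs$depth_top_cm), stringsAsFactors = FALSE)
  names(cell_counts)[4] <- "n"
  full <- length(ecos) == 3 && length(seas) == 3 && length(deps) == 5 &&
    length(tubes) == 16 && nrow(missing_keys) == 0
  structure(list(n = nrow(obs), n_tubes = length(tubes),
                 cell_counts = cell_counts, missing_keys = missing_keys,
                 zero_fraction = mean(obs$frp_length == 0),
                 full_design = full),
            class = "frp_design_report")
}

#' @export
print.frp_design_report <- function(x, ...) {
  cat(sprintf("FRP design report: %d observations, %d tubes per ecosystem\n",
              x$n, x$n_tubes))
  cat(sprintf("  missing keys: %d\n", nrow(x$missing_keys)))
  cat(sprintf("  zero fraction: %.3f\n", x$zero_fraction))
  cat(sprintf("  full 3 x 16 x 3 x 5 design: %s\n", x$full_design))
  invisible(x)
}

#' Constants for the root-length to carbon-flux conversion
#'
#' The conversion chain assumes a camera depth of field of 2 mm (the
#' soil depth behind the tube wall within which roots are visible),
#' specific root length (SRL) of 37.1, 45.1 and 51.6 m per g dry mass
#' for the 0-10, 10-20 and 20-100 cm depth bands, a root carbon content
#' of 47.4%, 10-cm profile sections, and annualisation of monthly rates
#' by a factor of twelve.
#'
#' @param depth_of_field_m depth of field in metres.
#' @param srl_by_band named numeric vector of SRL values (m g^-1); names
#'   are the band tops `"0"`, `"10"`, `"20"` covering 0-10, 10-20 and
#'   20-100 cm.
#' @param carbon_fraction carbon mass fraction of root dry mass.
#' @param months_per_year annualisation factor.
#' @param section_depth_m thickness of one profile section in metres.
#' @return an object of class `frp_constants`.
#' @export
conversion_constants <- function(depth_of_field_m = 0.002,
                                 srl_by_band = c("0" = 37.1, "10" = 45.1,
                                                 "20" = 51.6),
                                 carbon_fraction = 0.474,
                                 months_per_year = 12,
                                 section_depth_m = 0.1) {
  vals <- c(depth_of_field_m, srl_by_band, carbon_fraction,
            months_per_year, section_depth_m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all conversion constants must be strictly positive",
         call. = FALSE)
  if (!identical(sort(as.numeric(names(srl_by_band))), c(0, 10, 20)))
    stop("srl_by_band must be named by the band tops 0, 10, 20",
         call. = FALSE)
  structure(list(depth_of_field_m = depth_of_field_m,
                 srl_by_band = srl_by_band,
                 carbon_fraction = carbon_fraction,
                 months_per_year = months_per_year,
                 section_depth_m = section_depth_m),
            class = "frp_constants")
}
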