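# Conversion of depth-binned root-length production to annual carbon
# flux per ground area. The chain: window length rate (m m^-2 mo^-1)
# -> length density in the observed soil slab (divide by the camera
# depth of field) -> biomass density via specific root length -> areal
# biomass over a 10-cm section -> annualised, rescaled to Mg per
# hectare and multiplied by the root carbon fraction.

#' Root length rate to length density
#'
#' FRP is measured as new-root length per window area; dividing by the
#' camera depth of field converts it to length per observed soil
#' volume (the window area cancels).
#'
#' @param frp_length length rate, m m^-2 mo^-1, >= 0.
#' @param constants an `frp_constants` object.
#' @return length density, m m^-3 mo^-1.
#' @export
length_to_density <- function(frp_length, constants = conversion_constants()) {
  stopifnot(inherits(constants, "frp_constants"))
  if (any(frp_length < 0)) stop("frp_length must be >= 0", call. = FALSE)
  frp_length / constants$depth_of_field_m
}

#' Length density to biomass density
#'
#' @param density length density, m m^-3 mo^-1.
#' @param srl specific root length, m g^-1, > 0.
#' @return biomass density, g m^-3 mo^-1.
#' @export
density_to_biomass <- function(density, srl) {
  if (any(srl <= 0)) stop("'srl' must be > 0", call. = FALSE)
  density / srl
}

# SRL for a section by its top depth: 0-10 / 10-20 / 20-100 cm bands
srl_for_section <- function(section_top_cm, constants) {
  if (any(section_top_cm < 0) || any(section_top_cm >= 100))
    stop("section top must lie in [0, 100) cm", call. = FALSE)
  band <- ifelse(section_top_cm < 10, "0",
                 ifelse(section_top_cm < 20, "10", "20"))
  unname(constants$srl_by_band[band])
}

#' Carbon flux of one 10-cm section
#'
#' Applies the full conversion chain to a section-mean FRP rate:
#' `carbon = frp / depth_of_field / SRL * section_depth *
#' months_per_year * 0.01 * carbon_fraction`, where 0.01 converts
#' g m^-2 to Mg ha^-1. With the default constants this collapses to
#' `frp * 2.844 / SRL`.
#'
#' @param section_mean_frp section-mean FRP, m m^-2 mo^-1.
#' @param section_top_cm top of the 10-cm section (0, 10, ..., 90); used
#'   to resolve the SRL band.
#' @param constants an `frp_constants` object.
#' @return carbon flux, Mg C ha^-1 yr^-1.
#' @export
section_carbon <- function(section_mean_frp, section_top_cm,
                           constants = conversion_constants()) {
  stopifnot(inherits(constants, "frp_constants"))
  srl <- srl_for_section(section_top_cm, constants)
  density <- length_to_density(section_mean_frp, constants)
  biomass <- density_to_biomass(density, srl)        # g m^-3 mo^-1
  areal <- biomass * constants$section_depth_m       # g m^-2 mo^-1
  annual <- areal * constants$months_per_year        # g m^-2 yr^-1
  annual * 0.01 * constants$carbon_fraction          # Mg C ha^-1 yr^-1
}

#' Propagate section SEs to a profile total
#'
#' Total SE as the square root of the sum of squared per-section SEs
#' (sections treated as independent).
#'
#' @param section_ses numeric vector of section SEs, all >= 0.
#' @return total SE.
#' @export
propagate_total_se <- function(section_ses) {
  if (any(section_ses < 0)) stop("SEs must be >= 0", call. = FALSE)
  sqrt(sum(section_ses^2))
}

#' Assemble the per-ecosystem carbon table
#'
#' Converts one binned FRP profile per ecosystem to carbon flux per
#' 10-cm section, with the band-correct SRL per section, a total as the
#' sum of sections and a total SE as the root-sum-of-squares of the
#' section SEs. Inputs are monthly section-mean rates already averaged
#' across seasons; the annualisation (x12) happens inside the
#' conversion.
#'
#' @param binned named list of `frp_binned` profiles (one per
#'   ecosystem), or a single `frp_binned`.
#' @param constants an `frp_constants` object.
#' @return data.frame of class `frp_carbon_table` with columns
#'   `ecosystem`, `section_top_cm`, `carbon`, `se`; per-ecosystem totals
#'   are attached as attribute `totals` (data.frame `ecosystem`,
#'   `total`, `total_se`).
#' @export
assemble_carbon_table <- function(binned,
                                  constants = conversion_constants()) {
  if (inherits(binned, "frp_binned")) binned <- list(profile = binned)
  stopifnot(length(binned) >= 1,
            all(vapply(binned, inherits, TRUE, "frp_binned")))
  nm <- names(binned)
  if (is.null(nm)) nm <- paste0("profile_", seq_along(binned))
  rows <- lapply(seq_along(binned), function(i) {
    b <- binned[[i]]
    data.frame(ecosystem = nm[i], section_top_cm = b$section_top_cm,
               carbon = section_carbon(b$frp_mean, b$section_top_cm,
                                       constants),
               se = section_carbon(b$frp_se, b$section_top_cm, constants))
  })
  out <- do.call(rbind, rows)
  totals <- do.call(rbind, lapply(split(out, out$ecosystem)[unique(out$ecosystem)],
    function(d) data.frame(ecosystem = d$ecosystem[1],
                           total = sum(d$carbon),
                           total_se = propagate_total_se(d$se))))
  rownames(out) <- rownames(totals) <- NULL
  structure(out, totals = totals,
            class = c("frp_carbon_table", "data.frame"))
}

#' @export
print.frp_carbon_table <- function(x, ...) {
  cat("Fine root production, Mg C ha^-1 yr^-1 (10-cm sections)\n")
  wide <- stats::reshape(
    as.data.frame(x)[, c("ecosystem", "section_top_cm", "carbon", "se")],
    direction = "wide", idvar = "section_top_cm", timevar = "ecosystem")
  print.data.frame(wide, row.names = FALSE, digits = 3)
  cat("Totals:\n")
  print.data.frame(attr(x, "totals"), row.names = FALSE, digits = 3)
  invisible(x)
}
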