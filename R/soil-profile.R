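#' Soil profile parameters for depth-dependent peat properties
#'
#' Bundles the constants of the depth laws used throughout the model: a
#' power law for bulk density, porosity as the complement of bulk density
#' relative to the specific gravity of peat, Archie's law for tortuosity,
#' a logarithmic soil temperature profile, a Q10 temperature factor, and
#' an exponentially declining microbial-biomass factor. Defaults are the
#' Mer Bleue bog parameterisation.
#'
#' @param a_rho Bulk-density power-law coefficient (g cm^-3); bulk density
#'   at 1 cm depth.
#' @param b_rho Bulk-density power-law exponent (unitless).
#' @param gs Baseline specific gravity of peat (g cm^-3).
#' @param m Archie tortuosity exponent (unitless).
#' @param i_mb,j_mb Microbial-biomass modifier coefficients: the modifier
#'   is `exp(i_mb + j_mb * depth)` with depth in cm.
#' @param x_T Surface (1 cm) growing-season soil temperature (degrees C).
#' @param y_T Temperature log-slope (degrees C per ln cm).
#' @param q10 Q10 temperature sensitivity of mineralization (unitless).
#'
#' @return An object of class `soil_profile_params` (a named list).
#' @export
#' @examples
#' soil <- soil_profile_params()
#' bulk_density(60, soil)
soil_profile_params <- function(a_rho = 0.0107, b_rho = 0.567, gs = 1.5,
                                m = 2.3, i_mb = 0.0287, j_mb = -0.024,
                                x_T = 17.8, y_T = 2.12, q10 = 2.3) {
  stopifnot(a_rho > 0, gs > 0, q10 > 1, y_T >= 0)
  p <- list(a_rho = a_rho, b_rho = b_rho, gs = gs, m = m,
            i_mb = i_mb, j_mb = j_mb, x_T = x_T, y_T = y_T, q10 = q10)
  # every modelled depth (<= 100 cm) must retain positive porosity
  if (a_rho * clamp_depth(100)^b_rho >= gs) {
    rlang::abort("bulk density reaches the specific gravity `gs` within the modelled 1-100 cm range; porosity would be <= 0")
  }
  structure(p, class = "soil_profile_params")
}

#' @export
print.soil_profile_params <- function(x, ...) {
  cat("<soil_profile_params>\n")
  cat(sprintf("  bulk density: %.4g * d^%.3g (g cm^-3), gs = %.3g\n",
              x$a_rho, x$b_rho, x$gs))
  cat(sprintf("  tortuosity: porosity^-%.3g\n", x$m))
  cat(sprintf("  temperature: %.3g - %.3g ln(d) C, Q10 = %.3g\n",
              x$x_T, x$y_T, x$q10))
  cat(sprintf("  microbial biomass: exp(%.4g %+.4g d)\n", x$i_mb, x$j_mb))
  invisible(x)
}

# Depth laws are anchored at 1 cm: the power law gives rho(0) = 0 but the
# observed surface value equals the 1 cm value, so "surface" means 1 cm.
clamp_depth <- function(d) {
  if (any(d < 0)) rlang::abort("depth must be >= 0 cm")
  pmax(d, 1)
}

#' Depth-dependent peat properties
#'
#' Individual property laws and a bundling helper. All laws are pure
#' functions of depth at a fixed point in the growing season; the radial
#' simulation runs at a single depth, so no vertical coupling exists.
#' Depths below 1 cm are clamped to 1 cm (the "surface").
#'
#' @param d Depth below the peat surface (cm), vectorised.
#' @param p A [soil_profile_params()] object.
#' @return `bulk_density()`: g cm^-3; `soil_temperature()`: degrees C;
#'   `microbial_biomass_factor()`: unitless.
#' @export
bulk_density <- function(d, p = soil_profile_params()) {
  p$a_rho * clamp_depth(d)^p$b_rho
}

#' @rdname bulk_density
#' @param rho Bulk density (g cm^-3); must be below `p$gs`.
#' @return `porosity()`: volumetric pore fraction in (0, 1].
#' @export
porosity <- function(rho, p = soil_profile_params()) {
  if (any(rho < 0) || any(rho >= p$gs)) {
    rlang::abort("bulk density must lie in [0, gs) for a physical porosity")
  }
  (p$gs - rho) / p$gs
}

#' @rdname bulk_density
#' @param eps Porosity in (0, 1].
#' @return `tortuosity()`: unitless Archie tortuosity `eps^-m`, >= 1.
#' @export
tortuosity <- function(eps, p = soil_profile_params()) {
  if (any(eps <= 0) || any(eps > 1)) {
    rlang::abort("porosity must lie in (0, 1]")
  }
  eps^(-p$m)
}

#' @rdname bulk_density
#' @export
soil_temperature <- function(d, p = soil_profile_params()) {
  p$x_T - p$y_T * log(clamp_depth(d))
}

#' @rdname bulk_density
#' @param T_C Soil temperature (degrees C).
#' @return `temperature_factor()`: Q10 mineralization multiplier,
#'   `q10^(T/10)` for T > 0 and 0 at or below freezing.
#' @export
temperature_factor <- function(T_C, p = soil_profile_params()) {
  ifelse(T_C > 0, p$q10^(T_C / 10), 0)
}

#' @rdname bulk_density
#' @export
microbial_biomass_factor <- function(d, p = soil_profile_params()) {
  if (any(d < 0)) rlang::abort("depth must be >= 0 cm")
  exp(p$i_mb + p$j_mb * d)
}

#' @rdname bulk_density
#' @return `depth_properties()`: a tibble with one row per depth and
#'   columns `depth`, `rho`, `eps`, `tau`, `T_C`, `f_T`, `f_mb`.
#' @export
#' @examples
#' depth_properties(c(10, 40, 80))
depth_properties <- function(d, p = soil_profile_params()) {
  rho <- bulk_density(d, p)
  eps <- porosity(rho, p)
  T_C <- soil_temperature(d, p)
  tibble::tibble(
    depth = d,
    rho = rho,
    eps = eps,
    tau = tortuosity(eps, p),
    T_C = T_C,
    f_T = temperature_factor(T_C, p),
    f_mb = microbial_biomass_factor(d, p)
  )
}

#' Tabulate the soil profile over a depth grid
#'
#' Convenience wrapper reproducing the depth-profile panels (bulk density,
#' porosity, tortuosity, temperature and its Q10 factor, microbial
#' biomass) as a tidy table.
#'
#' @param depths Numeric vector of depths (cm).
#' @param p A [soil_profile_params()] object.
#' @return A tibble, see [depth_properties()].
#' @export
soil_profile_table <- function(depths = 1:100, p = soil_profile_params()) {
  depth_properties(depths, p)
}
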