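#' Root segment parameters
#'
#' Geometry and electrophysiology of the simulated root segment. All
#' boundary fluxes are expressed per cm of root length, so the relevant
#' geometric quantity is the surface area per unit length `A = 2 pi r0`.
#'
#' @param r0 Root radius (cm).
#' @param Em Membrane potential (V); negative (default -120 mV).
#' @param v0 Volume of water entering the root (cm^3 s^-1 per cm root
#'   length). Carried for the sensitivity design; it only affects the
#'   simulation when the optional advection term is enabled.
#' @return An object of class `root_params`.
#' @export
#' @examples
#' root_params(r0 = 0.064)
root_params <- function(r0 = 0.0641885, Em = -0.120, v0 = 0) {
  stopifnot(r0 > 0, Em < 0, v0 >= 0)
  structure(
    list(r0 = r0, A = 2 * pi * r0, Em = Em, v0 = v0,
         F = 9.649e4,     # Faraday constant, J mol^-1 V^-1
         Rgas = 8.3143),  # gas constant, J mol^-1 K^-1
    class = "root_params"
  )
}

#' @export
print.root_params <- function(x, ...) {
  cat(sprintf("<root_params> r0 = %.5g cm (A = %.5g cm^2/cm), Em = %g mV, v0 = %g cm^3/s\n",
              x$r0, x$A, x$Em * 1000, x$v0))
  invisible(x)
}

#' Rhizoplane fluxes: passive efflux, uptake, and charged-solute efflux
#'
#' Fluxes across the root surface per cm root length, in umol cm^-1
#' hr^-1. Passive efflux of uncharged compounds is permeation down the
#' cytoplasm-to-soil gradient, `A P (Ccyto - Csoil)`. Influx is
#' Michaelis-Menten uptake `Imax Csoil / (KI + Csoil)`. For charged
#' solutes (Z < 0) the efflux follows a Goldman-type net flux density
#' with the membrane potential biasing anions out of the root; influx is
#' blocked by the charge.
#'
#' @param s A single solute row ([solute()] or one row of a solute
#'   table).
#' @param root A [root_params()] object.
#' @param Csoil Soil solution concentration at the rhizoplane
#'   (umol cm^-3).
#' @return Flux in umol per cm root per hr (positive = out of the root
#'   for the efflux functions).
#' @export
passive_efflux <- function(s, root, Csoil) {
  s <- as_solute_row(s)
  if (s$Z != 0) {
    rlang::abort("passive_efflux() applies to uncharged solutes; use ghk_flux() for Z < 0")
  }
  if (any(Csoil < 0)) rlang::abort("Csoil must be >= 0")
  root$A * s$P * (s$Ccyto - Csoil)
}

#' @rdname passive_efflux
#' @export
mm_influx <- function(s, Csoil) {
  s <- as_solute_row(s)
  if (any(Csoil < 0)) rlang::abort("Csoil must be >= 0")
  ifelse(s$KI + Csoil == 0, 0, s$Imax * Csoil / (s$KI + Csoil))
}

#' @rdname passive_efflux
#' @param T_K Membrane temperature (K); the soil temperature at the
#'   root's depth.
#' @details `ghk_flux()` evaluates
#'   `A P u (Ccyto e^u - Csoil) / (e^u - 1)` with
#'   `u = Z Em F / (Rgas T)`; for Z < 0 and Em < 0, u > 0 and the efflux
#'   exceeds the passive uncharged rate. As u -> 0 the expression reduces
#'   to the passive law (the limit is evaluated explicitly for
#'   |u| < 1e-12). The flux vanishes at the reversal condition
#'   `Csoil = Ccyto e^u`.
#' @export
ghk_flux <- function(s, root, Csoil, T_K) {
  s <- as_solute_row(s)
  if (s$Z >= 0) {
    rlang::abort("ghk_flux() applies to charged solutes (Z < 0); use passive_efflux() for Z = 0")
  }
  if (any(T_K <= 0)) rlang::abort("temperature must be positive Kelvin")
  if (any(Csoil < 0)) rlang::abort("Csoil must be >= 0")
  u <- s$Z * root$Em * root$F / (root$Rgas * T_K)
  ifelse(abs(u) < 1e-12,
         root$A * s$P * (s$Ccyto - Csoil),
         root$A * s$P * u * (s$Ccyto * exp(u) - Csoil) / (exp(u) - 1))
}

#' @rdname passive_efflux
#' @details `boundary_flux()` dispatches on the solute charge: uncharged
#'   solutes get (passive efflux, Michaelis-Menten influx); charged
#'   solutes get (Goldman-type efflux, zero influx). The returned `net`
#'   is exactly `efflux - influx`.
#' @return `boundary_flux()`: a tibble with columns `efflux`, `influx`,
#'   `net` (umol cm^-1 hr^-1).
#' @export
#' @examples
#' gl <- builtin_solutes()[1, ]
#' boundary_flux(gl, root_params(), Csoil = 0, T_K = 286)
boundary_flux <- function(s, root, Csoil, T_K = 286.15) {
  s1 <- as_solute_row(s)
  if (s1$Z == 0) {
    efflux <- passive_efflux(s, root, Csoil)
    influx <- mm_influx(s, Csoil)
  } else {
    efflux <- ghk_flux(s, root, Csoil, T_K)
    influx <- rep(0, length(Csoil))
  }
  tibble::tibble(efflux = efflux, influx = influx, net = efflux - influx)
}
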