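#' Concentric annular grid around the root
#'
#' The rhizosphere is discretised into `n` concentric annuli of equal
#' width `dr` starting at the root surface `r0`. Volumes and interface
#' areas are per cm of root length, so shell i holds mass `C[i] * V[i]`
#' (umol per cm root) at solution concentration `C[i]` (umol cm^-3).
#'
#' @param r0 Root radius (cm).
#' @param n Number of annuli (default 500).
#' @param dr Annulus width (cm; default 0.02, i.e. 0.2 mm), giving a
#'   potential rhizosphere radius of `n * dr` = 10 cm at the defaults.
#' @return An object of class `annular_grid`: a list with `r0`, `n`,
#'   `dr`, shell radii `r_inner`, `r_outer`, centre radii `r_mid`, shell
#'   volumes `V` (cm^3 per cm root), and interface areas `A_int` at each
#'   `r_outer` (cm^2 per cm root).
#' @export
#' @examples
#' g <- build_grid(0.05, n = 500, dr = 0.02)
#' max(g$r_outer)  # 10.05 cm
build_grid <- function(r0, n = 500, dr = 0.02) {
  if (r0 <= 0 || dr <= 0 || n < 2 || n != round(n)) {
    rlang::abort("build_grid() needs r0 > 0, dr > 0 and integer n >= 2")
  }
  r_inner <- r0 + (seq_len(n) - 1) * dr
  r_outer <- r_inner + dr
  structure(
    list(r0 = r0, n = as.integer(n), dr = dr,
         r_inner = r_inner, r_outer = r_outer,
         r_mid = (r_inner + r_outer) / 2,
         V = pi * (r_outer^2 - r_inner^2),
         A_int = 2 * pi * r_outer),
    class = "annular_grid"
  )
}

#' @export
print.annular_grid <- function(x, ...) {
  cat(sprintf("<annular_grid> %d annuli of %.3g cm from r0 = %.4g cm (outer radius %.4g cm)\n",
              x$n, x$dr, x$r0, max(x$r_outer)))
  invisible(x)
}

#' Sorption retardation of diffusion
#'
#' Reversible partitioning onto the solid phase slows apparent diffusion
#' by the retardation factor `R = 1 + (rho/eps) * dS/dC`, with the local
#' Langmuir isotherm slope `dS/dC = Smax Ks / (1 + Ks C)^2`. R is >= 1,
#' largest in the dilute limit, and relaxes towards 1 as sorption sites
#' saturate. A `"secant"` variant uses the chord slope `S(C)/C` instead
#' of the tangent.
#'
#' @param s A single solute row.
#' @param dp One-row depth properties ([depth_properties()]).
#' @param C Solution concentration (umol cm^-3), vectorised.
#' @param slope `"tangent"` (default) or `"secant"`.
#' @return Unitless retardation factor, >= 1.
#' @export
retardation_factor <- function(s, dp, C, slope = c("tangent", "secant")) {
  s <- as_solute_row(s)
  slope <- match.arg(slope)
  if (any(C < 0)) rlang::abort("C must be >= 0")
  dSdC <- if (slope == "tangent") {
    s$Smax * s$Ks / (1 + s$Ks * C)^2
  } else {
    ifelse(C > 0, s$Smax * s$Ks / (1 + s$Ks * C), s$Smax * s$Ks)
  }
  1 + dp$rho * dSdC / dp$eps
}

#' Effective diffusion coefficient in saturated peat
#'
#' The aqueous diffusivity is reduced by the pore fraction available to
#' flow, the squared tortuosity of the diffusion path, and the sorption
#' retardation factor: `De = D_inf * eps / (tau^2 * R)`.
#'
#' @inheritParams retardation_factor
#' @param retardation Apply the sorption retardation factor (default
#'   TRUE; FALSE isolates the porosity/tortuosity effect).
#' @return Effective diffusivity (cm^2 s^-1), always <= `D_inf`.
#' @export
#' @examples
#' gl <- builtin_solutes()[1, ]
#' effective_diffusion(gl, depth_properties(10), C = 0)
effective_diffusion <- function(s, dp, C, slope = "tangent",
                                retardation = TRUE) {
  s1 <- as_solute_row(s)
  R <- if (retardation) retardation_factor(s, dp, C, slope) else 1
  s1$D_inf * dp$eps / (dp$tau^2 * R)
}

#' One explicit Fickian exchange step between annuli
#'
#' Conservative finite-volume update: the mass crossing interface i is
#' `-De_i * (C[i+1] - C[i]) / dr * A_int[i] * dt`, with `De_i` supplied
#' per interface (arithmetic mean of the adjacent shells' effective
#' diffusivities in the full engine). The outer boundary is closed, so
#' internal exchange conserves total solution mass exactly. This R
#' implementation is the reference for the compiled engine and for
#' small-scale oracles; `run_to_equilibrium()` uses the compiled core.
#'
#' @param C Solution concentrations per annulus (umol cm^-3).
#' @param grid An [build_grid()] grid.
#' @param De Effective diffusivity per internal interface (length
#'   `n - 1`, cm^2 s^-1), or a scalar.
#' @param dt Time step (s); must satisfy the explicit stability bound
#'   `max(De) * dt / dr^2 <= 0.5`.
#' @return A list with updated `C` and `flux` (umol per cm root moved
#'   outward across each internal interface during the step).
#' @export
diffusion_step <- function(C, grid, De, dt) {
  n <- grid$n
  if (length(C) != n) rlang::abort("length(C) must equal grid$n")
  De <- rep_len(De, n - 1)
  courant <- max(De) * dt / grid$dr^2
  if (courant > 0.5) {
    rlang::abort(sprintf(
      "explicit stability bound violated: max(De)*dt/dr^2 = %.3g > 0.5; reduce dt below %.3g s",
      courant, 0.5 * grid$dr^2 / max(De)))
  }
  i <- seq_len(n - 1)
  flux <- -De * (C[i + 1] - C[i]) / grid$dr * grid$A_int[i] * dt
  dC <- numeric(n)
  dC[i] <- dC[i] - flux / grid$V[i]
  dC[i + 1] <- dC[i + 1] + flux / grid$V[i + 1]
  list(C = C + dC, flux = flux)
}

#' One upwind advection step (optional water-uptake term)
#'
#' Transpiration draws soil water radially inward towards the root at
#' velocity `v(r) = v0 / (2 pi r)` per cm root length, carrying solute
#' with it (first-order upwind differencing). The solute volume flux
#' across every interface is therefore `v0 * C_upwind`; mass crossing the
#' rhizoplane is delivered to the root and reported so it can be added to
#' the influx ledger. Disabled by default in the simulator.
#'
#' @inheritParams diffusion_step
#' @param v0 Water uptake volume (cm^3 s^-1 per cm root length).
#' @return A list with updated `C` and `root_mass` (umol per cm root
#'   advected into the root during the step).
#' @export
advective_step <- function(C, grid, v0, dt) {
  n <- grid$n
  if (length(C) != n) rlang::abort("length(C) must equal grid$n")
  if (v0 < 0) rlang::abort("v0 must be >= 0")
  if (v0 == 0) return(list(C = C, root_mass = 0))
  # inward flow: upwind donor is the outer shell at each interface
  moved <- v0 * C * dt            # out of each shell towards the root
  dC <- -moved / grid$V
  inner <- seq_len(n - 1)
  dC[inner] <- dC[inner] + moved[inner + 1] / grid$V[inner]
  list(C = C + dC, root_mass = moved[1])
}
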