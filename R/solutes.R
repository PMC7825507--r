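#' Define a single exudate solute
#'
#' A solute record carries the physics (aqueous diffusivity, charge),
#' chemistry (Langmuir sorption), and biology (mineralization rate,
#' cytoplasm concentration, membrane permeability, Michaelis-Menten
#' uptake) of one low-molecular-weight carbon compound.
#'
#' Class rules enforced at construction:
#' * `Z` must be 0 (sugars, amino acids: treated as uncharged) or a
#'   negative integer (organic acids).
#' * Charged solutes cannot have active influx (`Imax` must be 0): the
#'   negatively charged root interior prevents anion recapture.
#' * If `P` is missing it defaults by class: 1.15e-4 cm hr^-1 for sugars
#'   and amino acids, 4.32e-4 cm hr^-1 for organic acids.
#'
#' @param name Solute name.
#' @param solute_class One of `"sugar"`, `"amino_acid"`, `"organic_acid"`.
#' @param Z Charge in solution (0 or negative integer).
#' @param D_inf Diffusion coefficient in pure water (cm^2 s^-1).
#' @param Smax Maximum Langmuir sorption (umol g^-1).
#' @param Ks Langmuir affinity coefficient (unitless).
#' @param kd Base mineralization rate (hr^-1).
#' @param Ccyto Root-cell cytoplasm concentration (umol cm^-3).
#' @param P Membrane permeability (cm hr^-1); `NA` for the class default.
#' @param Imax Maximum uptake rate (umol per cm root per hr).
#' @param KI Michaelis-Menten coefficient of uptake (umol cm^-3).
#' @return A one-row tibble of class `rhizo_solute`.
#' @export
#' @examples
#' solute("glucose", "sugar", Z = 0, D_inf = 6.7e-6, Smax = 2.39,
#'        Ks = 0.5, kd = 0.45, Ccyto = 44.7, Imax = 0.0297, KI = 0.109)
solute <- function(name, solute_class, Z = 0, D_inf, Smax = 0, Ks = 0,
                   kd = 0, Ccyto, P = NA_real_, Imax = 0, KI = 0) {
  solute_class <- match.arg(solute_class,
                            c("sugar", "amino_acid", "organic_acid"))
  if (is.na(P)) P <- class_permeability(solute_class)
  s <- tibble::tibble(
    name = as.character(name), solute_class = solute_class,
    Z = Z, D_inf = D_inf, Smax = Smax, Ks = Ks, kd = kd,
    Ccyto = Ccyto, P = P, Imax = Imax, KI = KI
  )
  validate_solutes(s)
  class(s) <- c("rhizo_solute", class(s))
  s
}

class_permeability <- function(solute_class) {
  ifelse(solute_class == "organic_acid", 4.32e-4, 1.15e-4)
}

#' Validate a table of solute parameters
#'
#' Checks the hard physical invariants of a solute table. Violations
#' raise an error naming the offending row and field.
#'
#' @param solutes A data frame with the columns of [solute()].
#' @return The validated table, invisibly.
#' @export
validate_solutes <- function(solutes) {
  required <- c("name", "solute_class", "Z", "D_inf", "Smax", "Ks", "kd",
                "Ccyto", "P", "Imax", "KI")
  missing_cols <- setdiff(required, names(solutes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("solute table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(solutes))) {
    row <- solutes[i, ]
    fail <- function(field, msg) {
      rlang::abort(sprintf("solute '%s' (row %d), field %s: %s",
                           row$name, i, field, msg))
    }
    if (!row$solute_class %in% c("sugar", "amino_acid", "organic_acid")) {
      fail("solute_class", sprintf("unknown class '%s'", row$solute_class))
    }
    if (row$Z > 0 || row$Z != round(row$Z)) {
      fail("Z", "charge must be 0 or a negative integer")
    }
    if (row$Z < -3) fail("Z", "charge below -3 is outside the supported range")
    for (f in c("D_inf", "Smax", "Ks", "kd", "Ccyto", "P", "Imax", "KI")) {
      if (is.na(row[[f]]) || row[[f]] < 0) {
        fail(f, "must be a nonnegative number")
      }
    }
    if (row$D_inf <= 0) fail("D_inf", "must be positive")
    if (row$Z < 0 && row$Imax > 0) {
      fail("Imax", "charged solutes cannot have active influx (Imax must be 0)")
    }
  }
  invisible(solutes)
}

#' Literature ranges of the model parameters
#'
#' The sampling box used for validation warnings and for the global
#' sensitivity design: solute and root parameters span the range of
#' values reported in the literature for sugars and amino acids, depth
#' spans the working 10-100 cm profile, and Q10 spans the labile-carbon
#' range 2.0-2.7.
#'
#' @return A tibble with columns `parameter`, `lo`, `hi`.
#' @export
param_ranges <- function() {
  tibble::tribble(
    ~parameter, ~lo,     ~hi,
    "D_inf",    0.52e-5, 1.28e-5,
    "Smax",     0.12,    19.98,
    "Ks",       0.145,   4.3,
    "kd",       0.15,    2.35,
    "Ccyto",    0.5,     40,
    "P",        1.15e-4, 4.32e-4,
    "Imax",     0.006,   0.07,
    "KI",       0.002,   5.9,
    "v0",       5.0e-10, 5.0e-6,
    "Q10",      2.0,     2.7,
    "depth",    10,      100
  )
}

#' Map a unit-hypercube point to a solute parameter set
#'
#' Each coordinate of `u` is mapped affinely onto the corresponding
#' parameter range, so the map is deterministic and monotone per
#' coordinate (a bijection from the hypercube onto the parameter box).
#'
#' @param u Named numeric vector with values in \[0, 1\]; names must be a
#'   subset of `param_ranges()$parameter`.
#' @param ranges Range table as from [param_ranges()].
#' @return Named numeric vector of parameter values.
#' @export
#' @examples
#' sample_params(c(kd = 0.5, Imax = 0))
sample_params <- function(u, ranges = param_ranges()) {
  if (is.null(names(u)) || !all(names(u) %in% ranges$parameter)) {
    rlang::abort("`u` must be named with parameters listed in `ranges`")
  }
  if (any(u < 0 | u > 1)) rlang::abort("`u` components must lie in [0, 1]")
  idx <- match(names(u), ranges$parameter)
  ranges$lo[idx] + u * (ranges$hi[idx] - ranges$lo[idx])
}

#' @rdname sample_params
#' @param name Name for the sampled solute.
#' @details `sample_solute()` builds a full uncharged solute record from a
#'   hypercube point covering the solute fields (`D_inf`, `Smax`, `Ks`,
#'   `kd`, `Ccyto`, `P`, `Imax`, `KI`).
#' @export
sample_solute <- function(u, ranges = param_ranges(), name = "sampled") {
  fields <- c("D_inf", "Smax", "Ks", "kd", "Ccyto", "P", "Imax", "KI")
  if (is.null(names(u))) names(u) <- fields[seq_along(u)]
  vals <- sample_params(u[fields], ranges)
  solute(name, "sugar", Z = 0, D_inf = vals[["D_inf"]],
         Smax = vals[["Smax"]], Ks = vals[["Ks"]], kd = vals[["kd"]],
         Ccyto = vals[["Ccyto"]], P = vals[["P"]],
         Imax = vals[["Imax"]], KI = vals[["KI"]])
}

#' Built-in example solutes
#'
#' Four named fixtures spanning the three compound classes. Cytoplasm
#' concentrations for glucose, malate, and tartarate are the published
#' sedge root values; the remaining per-solute constants (sorption,
#' mineralization, uptake kinetics) are synthetic stand-ins chosen inside
#' the literature ranges of [param_ranges()], since compound-specific
#' literature values are not bundled with the package. The glucose
#' mineralization rate and uptake maximum are the values recovered by
#' [calibrate_glucose()] under the default soil profile.
#'
#' @return A tibble of solute records, one row per solute.
#' @export
#' @examples
#' builtin_solutes()
builtin_solutes <- function() {
  s <- dplyr::bind_rows(
    solute("glucose", "sugar", Z = 0, D_inf = 6.7e-6,
           Smax = 2.39, Ks = 0.5, kd = 0.45, Ccyto = 44.7,
           Imax = 0.0297, KI = 0.1086278),
    solute("glycine", "amino_acid", Z = 0, D_inf = 1.06e-5,
           Smax = 1.0, Ks = 0.3, kd = 2.0, Ccyto = 5.0,
           Imax = 0.02, KI = 0.05),
    solute("tartarate", "organic_acid", Z = -2, D_inf = 0.52e-5,
           Smax = 8.0, Ks = 1.5, kd = 0.8, Ccyto = 59.5,
           Imax = 0, KI = 0),
    solute("malate", "organic_acid", Z = -2, D_inf = 0.758e-5,
           Smax = 6.0, Ks = 1.0, kd = 0.9, Ccyto = 27.4,
           Imax = 0, KI = 0)
  )
  class(s) <- c("rhizo_solute", class(s))
  s
}

#' Read and write solute parameter tables
#'
#' The on-disk format is a plain CSV with columns `name, class, Z,
#' D_inf_cm2_s, Smax_umol_g, Ks, kd_per_hr, Ccyto_umol_cm3, P_cm_hr,
#' Imax_umol_cm_hr, KI_umol_cm3`. Diffusivities are stored directly in
#' cm^2 s^-1 (e.g. `6.7e-6`). An empty permeability cell is filled with
#' the class default. Write-then-read round-trips are identity on all
#' fields.
#'
#' @param path CSV file path.
#' @return `read_solute_table()`: a validated solute tibble (zero rows,
#'   with a warning, for an empty file).
#' @export
read_solute_table <- function(path) {
  cols <- c(name = "c", class = "c", Z = "d", D_inf_cm2_s = "d",
            Smax_umol_g = "d", Ks = "d", kd_per_hr = "d",
            Ccyto_umol_cm3 = "d", P_cm_hr = "d", Imax_umol_cm_hr = "d",
            KI_umol_cm3 = "d")
  raw <- readr::read_csv(path, col_types = paste(cols, collapse = ""))
  missing_cols <- setdiff(names(cols), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("solute CSV is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    rlang::warn(sprintf("solute table '%s' is empty", path))
  }
  s <- tibble::tibble(
    name = raw$name, solute_class = raw$class, Z = raw$Z,
    D_inf = raw$D_inf_cm2_s, Smax = raw$Smax_umol_g, Ks = raw$Ks,
    kd = raw$kd_per_hr, Ccyto = raw$Ccyto_umol_cm3,
    P = ifelse(is.na(raw$P_cm_hr), class_permeability(raw$class),
               raw$P_cm_hr),
    Imax = raw$Imax_umol_cm_hr, KI = raw$KI_umol_cm3
  )
  if (nrow(s) > 0) validate_solutes(s)
  class(s) <- c("rhizo_solute", class(s))
  s
}

#' @rdname read_solute_table
#' @param solutes A solute tibble as from [builtin_solutes()].
#' @export
write_solute_table <- function(solutes, path) {
  out <- tibble::tibble(
    name = solutes$name, class = solutes$solute_class, Z = solutes$Z,
    D_inf_cm2_s = solutes$D_inf, Smax_umol_g = solutes$Smax,
    Ks = solutes$Ks, kd_per_hr = solutes$kd,
    Ccyto_umol_cm3 = solutes$Ccyto, P_cm_hr = solutes$P,
    Imax_umol_cm_hr = solutes$Imax, KI_umol_cm3 = solutes$KI
  )
  readr::write_csv(out, path)
  invisible(path)
}

# Internal: fetch one solute row as a plain named list.
as_solute_row <- function(s, name = NULL) {
  if (!is.data.frame(s) && is.list(s)) return(s) # already a row list
  if (!is.null(name)) {
    s <- s[s$name == name, ]
    if (nrow(s) == 0) rlang::abort(sprintf("no solute named '%s'", name))
  }
  if (nrow(s) != 1) {
    rlang::abort("expected exactly one solute row; use `name =` to select")
  }
  as.list(s)
}
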