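# Sobol low-discrepancy sequence (Gray-code construction, direction
# numbers from the Joe-Kuo table, dimensions 1-16). Implemented here
# because no installed package provides the generator; cross-checked in
# the tests against the canonical base-sequence values.
sobol_dirs <- function() {
  list(
    # s = polynomial degree, a = coefficient bits, m = initial values
    list(s = 1, a = 0,  m = c(1)),
    list(s = 2, a = 1,  m = c(1, 3)),
    list(s = 3, a = 1,  m = c(1, 3, 1)),
    list(s = 3, a = 2,  m = c(1, 1, 1)),
    list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
    list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
    list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
    list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
    list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
    list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
    list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
    list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
    list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
    list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
    list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49))
  )
}

#' Sobol low-discrepancy sequence
#'
#' Quasi-random points covering the unit hypercube far more evenly than
#' pseudo-random sampling; used to spread the sensitivity ensemble over
#' the multivariate parameter space. Deterministic: the same `n`, `dim`
#' and `skip` always return the same matrix. The first point of the base
#' sequence is the all-zeros corner, so `skip = 1` (the default) drops
#' it to avoid a degenerate all-lower-bound parameter set.
#'
#' @param n Number of points.
#' @param dim Dimension (1-16).
#' @param skip Number of initial base-sequence points to drop.
#' @return An `n x dim` matrix with entries in \[0, 1).
#' @export
#' @examples
#' sobol_sequence(5, 2)
sobol_sequence <- function(n, dim, skip = 1) {
  if (dim < 1 || dim > 16) rlang::abort("sobol_sequence supports 1-16 dimensions")
  if (n < 1) rlang::abort("n must be >= 1")
  total <- n + skip
  L <- max(1, ceiling(log2(total)))
  if (L > 30) rlang::abort("sequence too long (needs 2^30+ points)")
  dirs <- sobol_dirs()
  out <- matrix(0, nrow = total - 1, ncol = dim) # point 0 is all zeros
  for (j in seq_len(dim)) {
    if (j == 1) {
      V <- bitwShiftL(1L, 30L - seq_len(L)) # van der Corput in base 2
    } else {
      dd <- dirs[[j - 1]]
      s <- dd$s
      m <- as.integer(dd$m)
      a_bits <- as.integer(bitwAnd(bitwShiftR(dd$a, (s - 2):0), 1L))
      if (L > s) {
        m <- c(m, integer(L - s))
        for (k in (s + 1):L) {
          val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
          if (s >= 2) {
            for (q in 1:(s - 1)) {
              if (a_bits[q] == 1L) {
                val <- bitwXor(val, bitwShiftL(m[k - q], q))
              }
            }
          }
          m[k] <- val
        }
      }
      V <- bitwShiftL(m[seq_len(L)], 30L - seq_len(L))
    }
    x <- 0L
    for (i in seq_len(total - 1)) {
      # Gray-code: flip the direction of the lowest zero bit of i-1
      c_idx <- 1L
      val <- i - 1L
      while (bitwAnd(val, 1L) == 1L) {
        val <- bitwShiftR(val, 1L)
        c_idx <- c_idx + 1L
      }
      x <- bitwXor(x, V[c_idx])
      out[i, j] <- x / 2^30
    }
  }
  rows <- seq.int(skip, total - 1)
  rows <- rows[rows >= 1]
  res <- out[rows, , drop = FALSE]
  if (skip == 0) res <- rbind(matrix(0, 1, dim), res)[seq_len(n), , drop = FALSE]
  res[seq_len(n), , drop = FALSE]
}

#' Sobol design over the model parameter space
#'
#' Maps a Sobol sequence onto the literature parameter box (see
#' [param_ranges()]): every column's marginal is uniform on its bounds
#' and the joint coverage is low-discrepancy. Depth is sampled jointly
#' with the solute parameters.
#'
#' @param n Number of parameter sets.
#' @param parameters Parameters to vary (default: all of
#'   [param_ranges()]).
#' @param ranges Bounds table.
#' @param skip Base-sequence offset (see [sobol_sequence()]).
#' @return A tibble with `n` rows, one column per parameter.
#' @export
#' @examples
#' sobol_design(8, parameters = c("kd", "Imax", "depth"))
sobol_design <- function(n, parameters = param_ranges()$parameter,
                         ranges = param_ranges(), skip = 1) {
  idx <- match(parameters, ranges$parameter)
  if (anyNA(idx)) {
    rlang::abort(paste0("unknown parameter(s): ",
                        paste(parameters[is.na(idx)], collapse = ", ")))
  }
  if (n < 10 * length(parameters)) {
    rlang::warn("fewer than 10 samples per parameter; sensitivity estimates will be unstable")
  }
  u <- sobol_sequence(n, length(parameters), skip = skip)
  out <- purrr::map2(seq_along(parameters), idx, function(k, i) {
    ranges$lo[i] + u[, k] * (ranges$hi[i] - ranges$lo[i])
  })
  names(out) <- parameters
  tibble::as_tibble(out)
}

#' Simulate a sensitivity ensemble
#'
#' Runs the model once per design row for an uncharged solute (the
#' sensitivity analysis covers sugars and amino acids; charged solutes
#' have no influx pathway to perturb), each at its sampled depth, with
#' sampled Q10 and water-uptake v0, and records the equilibrium outputs.
#' Ensemble runs use a coarser grid than single-solute experiments
#' (see `settings` default); the grid-coarsening bias on the rhizoplane
#' concentration is validated in the tests at under 2%.
#'
#' @param design A [sobol_design()] tibble (must include `depth`; solute
#'   columns default to the built-in glucose values when absent).
#' @param root,soil,settings Base configuration; sampled columns
#'   override the corresponding entries row by row.
#' @param quiet Suppress the non-convergence count message.
#' @return A tibble of class `rhizo_ensemble`: the design columns plus
#'   `rhizoplane_C` (nmol cm^-3), `extent_mm`, `net_exudation`,
#'   `influx` (nmol cm^-1 hr^-1) and `converged`.
#' @export
run_ensemble <- function(design, root = root_params(),
                         soil = soil_profile_params(),
                         settings = sim_settings(n = 375, dr = 0.02,
                                                 dt = 4, max_sim_time = 2e6),
                         quiet = FALSE) {
  if (!"depth" %in% names(design)) {
    rlang::abort("the design must sample `depth`")
  }
  base <- as_solute_row(builtin_solutes(), "glucose")
  get <- function(row, field, default) {
    if (field %in% names(row)) row[[field]] else default
  }
  res <- purrr::map(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    trial <- solute("ensemble", "sugar", Z = 0,
                    D_inf = get(row, "D_inf", base$D_inf),
                    Smax = get(row, "Smax", base$Smax),
                    Ks = get(row, "Ks", base$Ks),
                    kd = get(row, "kd", base$kd),
                    Ccyto = get(row, "Ccyto", base$Ccyto),
                    P = get(row, "P", base$P),
                    Imax = get(row, "Imax", base$Imax),
                    KI = get(row, "KI", base$KI))
    soil_i <- soil
    if ("Q10" %in% names(row)) soil_i$q10 <- row$Q10
    root_i <- root
    if ("v0" %in% names(row)) {
      root_i <- root_params(r0 = root$r0, Em = root$Em, v0 = row$v0)
    }
    # extreme corners legitimately push the gradient to the domain edge;
    # the per-run domain warnings would swamp a 1000-run ensemble
    sm <- suppressWarnings(
      run_to_equilibrium(trial, depth = row$depth, root = root_i,
                         soil = soil_i, settings = settings)$summary)
    sm[, c("rhizoplane_C", "extent_mm", "net_exudation", "influx",
           "converged")]
  })
  out <- dplyr::bind_cols(design, dplyr::bind_rows(res))
  n_bad <- sum(!out$converged)
  if (n_bad > 0 && !quiet) {
    rlang::inform(sprintf(
      "%d of %d ensemble runs hit the simulated-time cap and are flagged converged = FALSE",
      n_bad, nrow(out)))
  }
  class(out) <- c("rhizo_ensemble", class(out))
  out
}

#' Linear depth regression over an ensemble
#'
#' Ordinary least squares of an equilibrium response on soil depth over
#' the converged ensemble members.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param response Response column (default `rhizoplane_C`).
#' @return A one-row tibble: `slope`, `r.squared`, `p.value`, `n`.
#' @export
depth_regression <- function(ensemble, response = "rhizoplane_C") {
  keep <- ensemble$converged
  d <- ensemble[keep, ]
  fit <- stats::lm(d[[response]] ~ d$depth)
  sm <- summary(fit)
  tibble::tibble(slope = stats::coef(fit)[[2]],
                 r.squared = sm$r.squared,
                 p.value = sm$coefficients[2, 4],
                 n = nrow(d))
}

rank_matrix <- function(data, cols) {
  m <- vapply(cols, function(cl) rank(data[[cl]], ties.method = "average"),
              numeric(nrow(data)))
  colnames(m) <- cols
  m
}

#' Partial rank correlation coefficients
#'
#' For each parameter, the correlation between the parameter and the
#' response after (a) rank-transforming every column and (b) removing
#' the rank-linear influence of all other parameters from both. Computed
#' from the precision matrix of the rank-correlation matrix; an
#' equivalent explicit construction (correlating residuals of rank
#' regressions) is used as the independent oracle in the tests.
#'
#' @param data A data frame (e.g. a [run_ensemble()] result; only
#'   converged rows are used when a `converged` column is present).
#' @param response Response column name.
#' @param parameters Parameter columns (default: every numeric column
#'   except the response and bookkeeping columns).
#' @return A tibble of class `rhizo_prcc` with columns `parameter`,
#'   `prcc`, ordered by `abs(prcc)` descending.
#' @export
#' @examples
#' d <- tibble::tibble(a = runif(50), b = runif(50))
#' d$y <- d$a^3
#' prcc(d, "y")
prcc <- function(data, response, parameters = NULL) {
  if ("converged" %in% names(data)) data <- data[data$converged, ]
  if (is.null(parameters)) {
    drop <- c(response, "converged", "rhizoplane_C", "extent_mm",
              "net_exudation", "influx")
    parameters <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          drop)
  }
  p <- length(parameters)
  if (nrow(data) < p + 3) {
    rlang::abort("need at least length(parameters) + 3 complete records")
  }
  rk <- rank_matrix(data, c(parameters, response))
  M <- stats::cor(rk)
  off <- abs(M[parameters, parameters, drop = FALSE])
  diag(off) <- 0
  if (any(off > 1 - 1e-10)) {
    pair <- which(off == max(off), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("parameter columns '%s' and '%s' are collinear on ranks",
                         parameters[pair[1]], parameters[pair[2]]))
  }
  # residual construction: regress each column's ranks on the other
  # parameters' ranks and correlate what is left over
  ry_all <- rk[, p + 1]
  coefs <- vapply(seq_len(p), function(k) {
    X <- cbind(1, rk[, setdiff(seq_len(p), k), drop = FALSE])
    rp <- stats::lm.fit(X, rk[, k])$residuals
    ry <- stats::lm.fit(X, ry_all)$residuals
    if (stats::sd(rp) == 0 || stats::sd(ry) == 0) return(0)
    stats::cor(rp, ry)
  }, numeric(1))
  out <- tibble::tibble(parameter = parameters, prcc = coefs)
  out <- out[order(-abs(out$prcc)), ]
  class(out) <- c("rhizo_prcc", class(out))
  out
}

#' @rdname prcc
#' @param bin_width Depth bin width (cm); simulations are grouped into
#'   `[10, 20), [20, 30), ...` style intervals and the PRCC is computed
#'   per bin with depth excluded from the parameter list.
#' @param depth_col Name of the depth column.
#' @return `binned_prcc()`: a `rhizo_prcc` tibble with an extra `bin`
#'   column; bins with too few records are skipped with a warning.
#' @export
binned_prcc <- function(data, response, parameters = NULL,
                        bin_width = 10, depth_col = "depth") {
  if (!depth_col %in% names(data)) {
    rlang::abort(sprintf("no '%s' column to bin on", depth_col))
  }
  if ("converged" %in% names(data)) data <- data[data$converged, ]
  lo <- floor(min(data[[depth_col]]) / bin_width) * bin_width
  hi <- ceiling(max(data[[depth_col]]) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bins <- cut(data[[depth_col]], breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  if (is.null(parameters)) {
    drop <- c(response, depth_col, "converged", "rhizoplane_C",
              "extent_mm", "net_exudation", "influx")
    parameters <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          drop)
  }
  parameters <- setdiff(parameters, depth_col)
  out <- purrr::map(levels(bins), function(b) {
    sub <- data[!is.na(bins) & bins == b, ]
    if (nrow(sub) < length(parameters) + 3) {
      rlang::warn(sprintf("depth bin %s has too few records (%d); skipped",
                          b, nrow(sub)))
      return(NULL)
    }
    res <- prcc(sub, response, parameters)
    res$bin <- b
    res
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("rhizo_prcc", class(res))
  res
}
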