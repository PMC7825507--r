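test_that("Sobol base sequence reproduces the canonical 2-D values", {
  # first points of the unscrambled base sequence after the zero point
  pts <- sobol_sequence(7, 2, skip = 1)
  expect_equal(pts[, 1], c(0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(pts[, 2], c(0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  # deterministic given the offset
  expect_identical(sobol_sequence(7, 2, skip = 1),
                   sobol_sequence(7, 2, skip = 1))
  # skip = 0 starts at the origin corner
  expect_equal(sobol_sequence(2, 3, skip = 0)[1, ], c(0, 0, 0))
})

test_that("Sobol design covers the parameter box uniformly", {
  des <- sobol_design(1024)
  rg <- param_ranges()
  for (p in names(des)) {
    r <- rg[rg$parameter == p, ]
    expect_gte(min(des[[p]]), r$lo)
    expect_lte(max(des[[p]]), r$hi)
    # column means within 2% of the midpoint (relative to the width)
    expect_lt(abs(mean(des[[p]]) - (r$lo + r$hi) / 2) / (r$hi - r$lo),
              0.02)
  }
  expect_warning(sobol_design(8), "10 samples")
  expect_error(sobol_design(64, parameters = "bogus"), "unknown parameter")
})

test_that("PRCC equals the brute-force partial rank correlation oracle", {
  # explicit construction: rank everything, regress out the other
  # parameters from both sides, correlate the residuals
  prcc_oracle <- function(data, response, parameters) {
    rk <- as.data.frame(lapply(data[c(parameters, response)], rank))
    vapply(parameters, function(p) {
      others <- setdiff(parameters, p)
      fmla <- function(lhs) stats::as.formula(
        paste(lhs, "~", paste(c("1", others), collapse = "+")))
      rp <- stats::residuals(stats::lm(fmla(p), data = rk))
      ry <- stats::residuals(stats::lm(fmla(response), data = rk))
      stats::cor(rp, ry)
    }, numeric(1))
  }
  set.seed(42)
  d <- tibble::tibble(a = runif(20), b = runif(20), c = runif(20))
  d$y <- 2 * d$a - d$b + 0.3 * rnorm(20)
  got <- prcc(d, "y", c("a", "b", "c"))
  want <- prcc_oracle(d, "y", c("a", "b", "c"))
  expect_equal(got$prcc[match(c("a", "b", "c"), got$parameter)],
               unname(want), tolerance = 1e-10)
  expect_true(all(abs(got$prcc) <= 1))
})

test_that("PRCC identifies monotone drivers and ignores pure noise", {
  set.seed(7)
  n <- 500
  d <- tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  # noise-free monotone (and non-linear) dependence on x1 only
  d$y <- exp(3 * d$x1)
  res <- prcc(d, "y", c("x1", "x2", "x3"))
  expect_equal(res$prcc[res$parameter == "x1"], 1, tolerance = 1e-6)
  expect_lt(max(abs(res$prcc[res$parameter != "x1"])), 0.1)
  # pure-noise response: all coefficients near zero
  d$z <- rnorm(n)
  res0 <- prcc(d, "z", c("x1", "x2", "x3"))
  expect_lt(max(abs(res0$prcc)), 0.1)
})

test_that("PRCC is invariant to monotone transforms of any column", {
  set.seed(11)
  d <- tibble::tibble(a = runif(60), b = runif(60))
  d$y <- d$a - 2 * d$b + 0.2 * rnorm(60)
  base <- prcc(d, "y", c("a", "b"))
  warped <- d
  warped$a <- exp(5 * warped$a)      # monotone transform of a parameter
  warped$y <- warped$y^3             # monotone transform of the response
  got <- prcc(warped, "y", c("a", "b"))
  expect_equal(got$prcc, base$prcc, tolerance = 1e-12)
})

test_that("PRCC rejects collinear parameters and tiny tables", {
  d <- tibble::tibble(a = 1:20, b = (1:20) * 2, y = rnorm(20))
  expect_error(prcc(d, "y", c("a", "b")), "collinear")
  expect_error(prcc(d[1:4, ], "y", c("a", "b")), "records")
})

test_that("small ensembles run, regress positively on depth, and bin correctly", {
  des <- suppressWarnings(
    sobol_design(60, parameters = c("depth", "kd", "Imax", "KI")))
  ens <- run_ensemble(des)
  expect_s3_class(ens, "rhizo_ensemble")
  expect_true(all(is.finite(ens$rhizoplane_C[ens$converged])))
  expect_true(all(c("rhizoplane_C", "extent_mm", "net_exudation")
                  %in% names(ens)))
  # deeper soil accumulates more at the rhizoplane
  reg <- depth_regression(ens)
  expect_gt(reg$slope, 0)
  expect_lt(reg$p.value, 0.01)
  # binned PRCC: bins partition the depth range; single-bin input
  # reduces to the plain PRCC
  pr <- prcc(ens, "rhizoplane_C", c("depth", "kd", "Imax", "KI"))
  expect_true(all(abs(pr$prcc) <= 1))
  one_bin <- ens
  one_bin$depth <- 10 + (seq_len(nrow(ens)) %% 10) / 2
  pb <- binned_prcc(one_bin, "rhizoplane_C",
                    parameters = c("kd", "Imax", "KI"), bin_width = 10)
  expect_equal(length(unique(as.character(pb$bin))), 1L)
  direct <- prcc(one_bin, "rhizoplane_C", c("kd", "Imax", "KI"))
  expect_equal(pb$prcc[match(direct$parameter, pb$parameter)],
               direct$prcc)
})

test_that("sparse depth bins are skipped with a warning", {
  set.seed(3)
  d <- tibble::tibble(depth = c(runif(30, 10, 20), 25, 27),
                      kd = runif(32), Imax = runif(32))
  d$rhizoplane_C <- d$kd + rnorm(32, sd = 0.1)
  expect_warning(res <- binned_prcc(d, "rhizoplane_C",
                                    parameters = c("kd", "Imax")),
                 "too few")
  expect_true(all(abs(res$prcc) <= 1))
})

test_that("sobol design + ensemble + prcc is reproducible end to end", {
  des <- suppressWarnings(sobol_design(20, parameters = c("depth", "kd")))
  e1 <- run_ensemble(des, quiet = TRUE,
                     settings = sim_settings(n = 60, dr = 0.05,
                                             max_sim_time = 1e6))
  e2 <- run_ensemble(des, quiet = TRUE,
                     settings = sim_settings(n = 60, dr = 0.05,
                                             max_sim_time = 1e6))
  expect_identical(e1$rhizoplane_C, e2$rhizoplane_C)
  expect_identical(prcc(e1, "rhizoplane_C", c("depth", "kd")),
                   prcc(e2, "rhizoplane_C", c("depth", "kd")))
})

test_that("ensemble grid coarsening shifts the rhizoplane concentration by under 2%", {
  # the ensemble scale-down (7.5 cm domain, 4 s steps, same 0.2 mm
  # cells) against the reference grid (10 cm domain, 1 s steps) on a
  # spread of sampled points
  des <- suppressWarnings(
    sobol_design(5, parameters = c("depth", "kd", "Imax", "KI", "Smax")))
  ens_settings <- sim_settings(n = 375, dr = 0.02, dt = 4,
                               max_sim_time = 2e6)
  for (i in seq_len(nrow(des))) {
    gl <- glucose_fixture()
    gl$kd <- des$kd[i]; gl$Imax <- des$Imax[i]
    gl$KI <- des$KI[i]; gl$Smax <- des$Smax[i]
    fine <- suppressWarnings(run_to_equilibrium(gl, depth = des$depth[i]))
    coarse <- suppressWarnings(
      run_to_equilibrium(gl, depth = des$depth[i], settings = ens_settings))
    expect_lt(abs(coarse$summary$rhizoplane_C - fine$summary$rhizoplane_C) /
                fine$summary$rhizoplane_C, 0.02)
  }
})
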