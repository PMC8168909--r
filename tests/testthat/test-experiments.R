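test_that("concentration sweeps record every grid point with full columns", {
  sw <- tr_fit("sweep")
  expect_s3_class(sw, "alloc_sweep")
  expect_equal(nrow(sw), 2 * 5)
  expect_true(all(sw$ok))
  need <- c("S_ext", "transport", "mu", "r", "f_p", "sa_to_vol", "phi_BP",
            "K_eff", "bp_per_transporter", "capacity_ratio",
            "transport_proteome", "dens_peri_active")
  expect_true(all(need %in% names(sw)))
  # growth is nondecreasing with nutrient availability up to ~1 mM (1%
  # solver slack); at tens of mM periplasmic substrate mass competes in
  # the crowding budget, so the top of the curve may flatten or dip a
  # little, and is only required to stay near the 1 mM level
  for (ty in c("pts", "abc")) {
    mu <- sw$mu[sw$transport == ty & sw$S_ext <= 1]
    expect_true(all(diff(mu) > -0.01 * mu[-1]), info = ty)
    mu_top <- sw$mu[sw$transport == ty & sw$S_ext == 1e2]
    expect_gt(mu_top, 0.9 * max(mu))
  }
  # PTS half-saturation is pinned at K_T across the whole grid
  kpts <- sw$K_eff[sw$transport == "pts"]
  expect_equal(kpts, rep(0.01, length(kpts)), tolerance = 1e-3)
  # ABC effective half-saturation decreases as nutrients get scarcer
  kabc <- sw$K_eff[sw$transport == "abc"]
  expect_lt(kabc[1], tail(kabc, 1))
})

test_that("sweep rows agree with standalone solves (warm starts no artifact)", {
  sw <- tr_fit("sweep")
  row <- sw[sw$transport == "pts" & sw$S_ext == 1e-2, ]
  f <- tr_fit("pts_mid")     # independent solve at the same concentration
  expect_lt(abs(row$mu - f$mu) / f$mu, 0.005)
})

test_that("capacity ratio profile flags unbounded ratios and matches columns", {
  sw <- capacity_ratio_profile(tr_fit("sweep"))
  expect_true(all(is.finite(sw$capacity_ratio[sw$ok])))
  expect_true(!any(sw$capacity_unbounded[sw$ok]))
  man <- sw$V_max_cyto / sw$metabolic_capacity
  expect_equal(sw$capacity_ratio, man)
})

test_that("crossover interpolation finds the sign change of the mu ratio", {
  # log(mu_abc/mu_pts) = (+1, -1) across two decades: the curves cross at
  # the geometric midpoint
  synth <- data.frame(
    S_ext = rep(c(1e-4, 1e-2), 2),
    transport = rep(c("abc", "pts"), each = 2),
    mu = c(exp(1) * 1e-4, exp(-1) * 1e-3, 1e-4, 1e-3),
    ok = TRUE)
  expect_equal(crossover_concentration(synth), 1e-3, tolerance = 1e-12)
  # no crossing, no crossover
  synth$mu[1:2] <- synth$mu[3:4] / 2
  expect_true(is.na(crossover_concentration(synth)))
})

test_that("matched-fit comparison computes the headline ratios", {
  cmp <- compare_summary(tr_fit("pts_sat"), tr_fit("abc_sat"))
  expect_s3_class(cmp, "transport_comparison")
  expect_true(all(vapply(cmp[c("transport_proteome_ratio", "V_max_ratio",
                               "K_ratio", "sa_to_vol_ratio")],
                         is.finite, logical(1))))
  expect_error(compare_summary(tr_fit("pts_mid"), tr_fit("abc_sat")),
               "different external concentrations")
  expect_error(compare_summary(tr_fit("abc_sat"), tr_fit("abc_sat")),
               "PTS fit and an ABC fit")
})

test_that("export writes provenance-stamped CSVs and a JSON sidecar", {
  dir <- tempfile("export")
  sw <- tr_fit("sweep")
  paths <- export_results(list(sweep = as.data.frame(sw)), dir,
                          cell_params(), solver_config(n_starts = 8, seed = 5))
  expect_true(all(file.exists(paths)))
  csv <- readLines(file.path(dir, "sweep.csv"), n = 3)
  expect_match(csv[2], "config_md5")
  side <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_equal(side$solver$seed, 5)
  expect_match(csv[2], side$config_md5)
  # the hash tracks the configuration
  p2 <- export_results(list(sweep = as.data.frame(sw)), tempfile("e2"),
                       cell_params(kE = 3), solver_config(n_starts = 8, seed = 5))
  side2 <- jsonlite::fromJSON(grep("config.json", p2, value = TRUE))
  expect_false(identical(side$config_md5, side2$config_md5))
})

test_that("sensitivity at factor one reproduces the baseline sweep exactly", {
  cp <- cell_params()
  grid <- c(1e-4, 1e-2)
  cfg <- solver_config(n_starts = 4, seed = 13)
  direct <- concentration_sweep(cp, "pts", grid, cfg, passes = 1)
  sens <- sensitivity_sweep(cp, "D", factors = 1, grid = grid, config = cfg,
                            transports = "pts", passes = 1)
  expect_identical(sens$sweeps[["1"]]$mu, direct$mu)
  expect_equal(sens$summary$factor, 1)
})

test_that("K_eff profiling can fold in the diffusive supply step", {
  fit <- tr_fit("abc_oligo")
  base <- keff_profile(fit)
  expect_equal(base$K_M, fit$observables$K_eff, tolerance = 1e-8)
  withd <- keff_profile(fit, include_diffusion = TRUE)
  # an extra transport resistance in series can only raise the apparent
  # half-saturation, and leaves the saturating rate unchanged
  expect_gte(withd$K_M, base$K_M)
  expect_equal(withd$V_max, base$V_max, tolerance = 1e-6)
})
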