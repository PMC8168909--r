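tp <- transport_params()

test_that("PTS uptake has Michaelis-Menten form with K_M = K_T", {
  T_tot <- 1
  expect_equal(pts_uptake(K_T(tp), T_tot, tp), 0.5 * tp$k2 * T_tot)
  expect_equal(pts_uptake(0, T_tot, tp), 0)
  expect_equal(pts_uptake(100 * K_T(tp), T_tot, tp),
               (100 / 101) * tp$k2 * T_tot)
  s <- 10^seq(-5, 2, by = 0.5)
  v <- pts_uptake(s, T_tot, tp)
  expect_true(all(diff(v) > 0))              # monotone increasing
  expect_true(all(v < tp$k2 * T_tot))        # bounded by k2 T_total
  expect_error(pts_uptake(-1, T_tot, tp), "nonnegative")
  expect_error(pts_uptake(1, -1, tp), "nonnegative")
})

test_that("ABC steady state vanishes without carriers and conserves pools", {
  st0 <- abc_steady_state(1e-3, BP_total = 0, T_total = 0.01, tp)
  expect_equal(st0$v_c, 0)
  expect_equal(st0$S_BP, 0)
  expect_equal(st0$T_S_BP, 0)

  cc <- 1 + tp$k2p / tp$k3p
  set.seed(42)
  for (i in 1:25) {
    S_p <- runif_log(1, 1e-4, 3)
    BP <- runif_log(1, 0.5, 2)
    Tt <- runif_log(1, 0.01, 2)
    st <- abc_steady_state(S_p, BP, Tt, tp)
    bp_cons <- st$BP_free + st$S_BP + cc * st$T_S_BP
    t_cons <- st$T_free + cc * st$T_S_BP
    expect_lt(abs(bp_cons - BP) / BP, 1e-8)
    expect_lt(abs(t_cons - Tt) / Tt, 1e-8)
    expect_true(all(unlist(st[c("S_BP", "BP_free", "T_free", "T_S_BP")]) >= 0))
    # translocation flux definition
    expect_equal(st$v_c, tp$k2p * st$T_S_BP)
  }
})

test_that("ABC flux is monotone in substrate and saturates below the cap", {
  v <- abc_uptake(10^seq(-6, 2, by = 1), BP_total = 1, T_total = 0.01, tp)
  expect_true(all(diff(v) >= 0))
  cap <- tp$k2p * tp$k3p / (tp$k2p + tp$k3p) * 0.01
  expect_true(all(v <= cap))
})

test_that("the MM approximation reproduces its algebraic limits", {
  Tt <- 0.01
  # no binding protein: half-saturation reverts to K_D
  expect_equal(abc_mm_approx(1, 0, Tt, tp)$fit$K_M, K_D(tp))
  # BP saturation of V'_max
  vmax_inf <- tp$k2p * tp$k3p / (tp$k2p + tp$k3p) * Tt
  expect_equal(abc_mm_approx(1, 1e9, Tt, tp)$fit$V_max, vmax_inf,
               tolerance = 1e-8)
  # printed formulas
  BP <- 0.7
  f <- abc_mm_approx(1, BP, Tt, tp)$fit
  expect_equal(f$V_max, vmax_inf * BP / (K_Tp(tp) + BP))
  expect_equal(f$K_M, K_Tp(tp) * K_D(tp) / (K_Tp(tp) + BP))
})

test_that("exact ABC rate approaches the MM approximation in its regime", {
  # binding proteins far above transport units and K_Tp, substrate far
  # below the half-saturation
  Tt <- 1e-4
  BP <- 100 * 0.01   # 100x T_total and ~1000x K_Tp... use 1 mM
  BP <- 1
  mm <- abc_mm_approx(1e-7, BP, Tt, tp)
  ex <- abc_steady_state(1e-7, BP, Tt, tp)$v_c
  expect_lt(abs(ex - mm$rate) / ex, 0.05)
})

test_that("specific affinity is V_max/K_M and scales linearly with BP when rare", {
  expect_equal(specific_affinity(mm_fit(1, 1)), 1)
  # PTS affinity independent of substrate: a = k2 T / K_T
  Tt <- 0.3
  a_pts <- specific_affinity(mm_fit(tp$k2 * Tt, K_T(tp)))
  expect_equal(a_pts, tp$k1 * Tt)
  # in the BP << K_Tp regime doubling BP doubles the ABC affinity
  a1 <- specific_affinity(abc_mm_approx(1, 1e-4, 0.01, tp)$fit)
  a2 <- specific_affinity(abc_mm_approx(1, 2e-4, 0.01, tp)$fit)
  expect_equal(a2 / a1, 2, tolerance = 1e-4)
  expect_error(mm_fit(1, 0), "positive")
})

test_that("effective half-saturation recovers an exact MM curve", {
  # with a truly saturating top concentration, (V, K) = (2, 5) come back
  f <- effective_half_saturation(function(s) 2 * s / (5 + s),
                                 grid = 10^seq(-2, 10, length.out = 60))
  expect_equal(f$V_max, 2, tolerance = 1e-9)
  expect_equal(f$K_M, 5, tolerance = 1e-8)
  # at a finite top, K_M is exactly where the rate crosses V_max/2
  g <- effective_half_saturation(function(s) 2 * s / (5 + s),
                                 grid = 10^seq(-3, 4, length.out = 50))
  expect_equal(2 * g$K_M / (5 + g$K_M), g$V_max / 2, tolerance = 1e-9)
  expect_gt(g$gof, 0.999999)
})

test_that("effective half-saturation rejects bad inputs", {
  expect_error(effective_half_saturation(function(s) -s), "monotone")
  expect_error(
    effective_half_saturation(function(s) 1 + 0.001 * s / (1 + s),
                              grid = 10^seq(-3, 2, length.out = 20)),
    "bracket")
})

test_that("effective K_M of the full ABC model decreases with BP abundance", {
  Tt <- 0.01
  grid <- 10^seq(-8, 1, length.out = 50)
  kms <- vapply(c(0.05, 0.2, 1, 5), function(BP) {
    effective_half_saturation(function(s) abc_uptake(s, BP, Tt, tp),
                              grid = grid)$K_M
  }, numeric(1))
  expect_true(all(diff(kms) < 0))
})

test_that("the relaxation oracle settles to the algebraic steady state", {
  st0 <- abc_relaxation_oracle(0, 1, 0.01, tp)
  expect_equal(st0$v_c, 0)
  st <- abc_relaxation_oracle(1e-4, 0.8, 0.02, tp)
  expect_true(attr(st, "converged"))
  expect_equal(st$v_c, tp$k2p * st$T_S_BP)
  ex <- abc_steady_state(1e-4, 0.8, 0.02, tp)
  expect_lt(abs(st$v_c - ex$v_c) / ex$v_c, 1e-6)
  expect_lt(abs(st$S_BP - ex$S_BP) / ex$S_BP, 1e-6)
})
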