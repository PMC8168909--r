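cp <- cell_params(S_ext = 1e-3)

mk_dv <- function(...) {
  args <- list(S_p = 1e-4, S_c = 0.5, A = 0.5, W = 30, P = 1500,
               phi = c(BP = 0.1, T = 0.1, E = 0.2, M = 0.05, R = 0.15),
               r = 0.5, f_p = 0.3, mu = 2e-4)
  args[names(list(...))] <- list(...)
  do.call(decision_vars, args)
}

test_that("diffusive supply follows the printed geometry", {
  expect_equal(diffusive_uptake(1, 1, 0.2, 0.1, 100), 0)       # no gradient
  # direct evaluation: 3*100*1e-6/(0.2*0.01) mM/s
  expect_equal(diffusive_uptake(1e-6, 0, 0.2, 0.1, 100), 0.15)
  # halving the radius quadruples the rate
  v1 <- diffusive_uptake(1e-3, 0, 0.2, 0.2, 100)
  v2 <- diffusive_uptake(1e-3, 0, 0.2, 0.1, 100)
  expect_equal(v2 / v1, 4)
  expect_error(diffusive_uptake(1, 0, 1.2, 0.1, 100), "f_p")
})

test_that("periplasm-to-cytoplasm conversion is f_p/(1 - f_p)", {
  expect_equal(periplasm_to_cytoplasm(1, 0.5), 1)
  expect_equal(periplasm_to_cytoplasm(1, 0.2), 0.25)
  expect_equal(periplasm_to_cytoplasm(1, 1e-6), 1e-6, tolerance = 1e-5)
  expect_error(periplasm_to_cytoplasm(1, 0), "f_p")
  expect_error(periplasm_to_cytoplasm(1, 1), "f_p")
})

test_that("reaction rates saturate and vanish as their pools do", {
  x <- mk_dv()
  v <- reaction_rates(x, cp, "pts")
  pools <- protein_pools(x, cp)
  # half-saturation of protein synthesis at A = K_MR
  xh <- mk_dv(A = cp$K_MR)
  vh <- reaction_rates(xh, cp, "pts")
  expect_equal(vh$v_R, 0.5 * cp$kR * protein_pools(xh, cp)$R)
  # no metabolic enzyme, no metabolic flux
  x0 <- mk_dv(phi = c(BP = 0.1, T = 0.1, E = 0, M = 0.05, R = 0.15))
  expect_equal(reaction_rates(x0, cp, "pts")$v_E, 0)
  # saturation of metabolism in substrate
  xs <- mk_dv(S_c = 1e6)
  expect_equal(reaction_rates(xs, cp, "pts")$v_E, cp$kE * pools$E,
               tolerance = 1e-5)
})

test_that("growth balances are homogeneous and vanish for an empty cell", {
  x <- mk_dv()
  res <- growth_balance_residuals(x, cp, "pts")
  expect_length(res, 5)
  expect_named(res, c("S_p", "S_c", "A", "W", "P"))
  # N v_r and mu x_m are both degree-1 in (pools, mu): doubling the
  # enzyme pools (via P) and mu at fixed metabolite concentrations
  # doubles each flux term individually
  v1 <- reaction_rates(x, cp, "pts")
  x2 <- mk_dv(P = 2 * x$P, mu = 2 * x$mu)
  v2 <- reaction_rates(x2, cp, "pts")
  for (nm in c("v_c", "v_E", "v_W", "v_R"))
    expect_equal(v2[[nm]], 2 * v1[[nm]], info = nm)
})

test_that("stoichiometry encodes 5 substrate to 6 precursors and uptake bases", {
  N <- stoichiometry(0.2)
  expect_equal(dim(N), c(5, 5))
  expect_equal(N["S_c", "v_E"], -5)
  expect_equal(N["A", "v_E"], 6)
  expect_equal(N["S_c", "v_c"], 0.25)      # periplasmic-to-cytoplasmic
  expect_equal(N["S_p", "v_c"], -1)
  expect_equal(N["A", "v_W"], -1)
  expect_equal(N["A", "v_R"], -1)
})

test_that("membrane coverage residual matches the printed spheres", {
  x <- mk_dv()
  # W solving the printed equation zeroes the residual
  W_star <- 3 * (1 + (1 - x$f_p)^(2 / 3)) /
    (x$r * cp$a_w * trophos:::.MOLEC_PER_UM3_PER_MM)
  x0 <- mk_dv(W = W_star)
  expect_equal(membrane_coverage_residual(x0, cp), 0, tolerance = 1e-10)
  # inner-sphere factor (1 - f_p)^(2/3) at f_p = 0.488
  x1 <- mk_dv(f_p = 0.488)
  need <- 4 * pi * (1 + (1 - 0.488)^(2 / 3)) * x1$r^2
  expect_equal((1 - 0.488)^(2 / 3), 0.64, tolerance = 0.04)
  expect_equal(membrane_coverage_residual(mk_dv(f_p = 0.488, W = 0), cp), need)
})

test_that("density margins are the caps for an empty cell and are linear", {
  empty <- mk_dv(S_p = 0, S_c = 0, A = 0, W = 0, P = 0,
                 phi = c(BP = 0.1, T = 0.1, E = 0.2, M = 0.05, R = 0.15))
  m0 <- density_margins(empty, cp)
  expect_equal(unname(m0), c(cp$rho_cyto, cp$rho_peri))
  x <- mk_dv()
  m1 <- density_margins(x, cp)
  x2 <- mk_dv(S_p = 2 * x$S_p, S_c = 2 * x$S_c, A = 2 * x$A, W = 2 * x$W,
              P = 2 * x$P)
  m2 <- density_margins(x2, cp)
  # mass load doubles, so the distance to the cap shrinks linearly
  expect_equal(unname(cp$rho_cyto - m2["cyto"]),
               unname(2 * (cp$rho_cyto - m1["cyto"])))
  expect_equal(unname(cp$rho_peri - m2["peri"]),
               unname(2 * (cp$rho_peri - m1["peri"])))
})

test_that("membrane units enter the cytoplasmic density sum only on request", {
  x <- mk_dv()
  cpw <- cell_params(S_ext = 1e-3, density_includes_membrane = TRUE)
  d0 <- density_margins(x, cp)["cyto"]
  d1 <- density_margins(x, cpw)["cyto"]
  expect_equal(unname(d0 - d1), cp$m_W * x$W)
})

test_that("real-estate margin is the available area without transporters", {
  x0 <- mk_dv(phi = c(BP = 0.1, T = 0, E = 0.2, M = 0.05, R = 0.25))
  expect_equal(real_estate_margin(x0, cp),
               cp$f_SA * 4 * pi * (1 - x0$f_p)^(2 / 3) * x0$r^2)
  # linear in f_SA at fixed geometry
  x <- mk_dv()
  cp2 <- cell_params(S_ext = 1e-3, f_SA = 0.6)
  m1 <- real_estate_margin(x, cp)
  m2 <- real_estate_margin(x, cp2)
  used <- cp$f_SA * 4 * pi * (1 - x$f_p)^(2 / 3) * x$r^2 - m1
  expect_equal(m2, 2 * cp$f_SA * 4 * pi * (1 - x$f_p)^(2 / 3) * x$r^2 - used)
})

test_that("PTS cells have structurally zero binding-protein terms", {
  x <- mk_dv(phi = c(BP = 0, T = 0.2, E = 0.2, M = 0.05, R = 0.15))
  pools <- protein_pools(x, cp)
  expect_equal(pools$BP_total, 0)
  # periplasmic density carries only the substrate term
  expect_equal(unname(density_margins(x, cp)["peri"]),
               cp$rho_peri - cp$m_S * x$S_p)
})
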