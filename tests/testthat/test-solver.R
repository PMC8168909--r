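test_that("variable scaling round-trips exactly", {
  cfg <- solver_config()
  set.seed(3)
  for (i in 1:10) {
    x <- decision_vars(S_p = runif_log(1, 1e-4, 3), S_c = runif_log(1, 1, 2),
                       A = runif_log(1, 1, 2), W = runif_log(1, 30, 1),
                       P = runif_log(1, 1000, 0.5),
                       phi = c(BP = 0.1, T = 0.1, E = 0.2, M = 0.05, R = 0.1),
                       r = runif(1, 0.06, 5), f_p = runif(1, 0.05, 0.95),
                       mu = runif_log(1, 1e-4, 1))
    v <- scale_variables(x, cfg)
    x2 <- unscale_variables(v, cfg)
    expect_equal(unclass(x2), unclass(x), tolerance = 1e-14)
  }
  # a typical optimum scales to order one
  dv <- tr_fit("pts_mid")$decision
  sc <- scale_variables(dv, cfg)
  expect_true(all(abs(sc[c("S_c", "A", "P", "r", "f_p", "mu")]) > 0.01))
  expect_true(all(abs(sc) < 1e3))
})

test_that("random starts are deterministic and respect bounds", {
  cp <- cell_params()
  cfg <- solver_config(seed = 9)
  a <- random_start(9, 4, cfg, cp, "abc")
  b <- random_start(9, 4, cfg, cp, "abc")
  expect_identical(a, b)
  d <- random_start(9, 5, cfg, cp, "abc")
  expect_false(identical(a, d))
  for (i in 1:20) {
    s <- random_start(1, i, cfg, cp, "abc")
    expect_gte(s$r, cp$r_min)
    expect_lte(s$r, cp$r_max)
    expect_gt(s$f_p, 0); expect_lt(s$f_p, 1)
    expect_true(all(s$phi >= 0))
  }
  expect_equal(random_start(1, 3, cfg, cp, "pts")$phi[["BP"]], 0)
})

test_that("the solver returns a feasible optimum with tiny residuals", {
  fit <- tr_fit("pts_mid")
  expect_s3_class(fit, "alloc_fit")
  expect_gt(fit$mu, 0)
  val <- validate_solution(fit)
  expect_true(val$ok)
  expect_lt(max(abs(val$balance_residuals)), 1e-8)
  expect_lt(abs(val$closure_residual), 1e-12)
  expect_true(all(val$margins_scaled > -1e-7))
  # the convergence log is a complete per-start record
  expect_true(all(c("start", "converged", "mu") %in% names(fit$starts)))
  expect_gte(nrow(fit$starts), fit$config$n_starts)
})

test_that("solves are deterministic given (params, seed, config)", {
  cfg <- solver_config(n_starts = 4, seed = 7)
  cp <- cell_params(S_ext = 1e-3)
  f1 <- allocate_proteome(cp, "pts", cfg)
  f2 <- allocate_proteome(cp, "pts", cfg)
  expect_identical(f1$mu, f2$mu)
  expect_identical(unclass(f1$decision), unclass(f2$decision))
  expect_identical(f1$starts, f2$starts)
})

test_that("doubling the number of starts moves the optimum by under 1%", {
  cp <- cell_params(S_ext = 1e-3)
  f1 <- allocate_proteome(cp, "pts", solver_config(n_starts = 6, seed = 2))
  f2 <- allocate_proteome(cp, "pts", solver_config(n_starts = 12, seed = 2))
  expect_lt(abs(f2$mu - f1$mu) / f2$mu, 0.01)
})

test_that("fitted ABC allocations agree with the kinetics module", {
  fit <- tr_fit("abc_oligo")
  dv <- fit$decision
  pools <- protein_pools(dv, fit$params)
  st <- abc_steady_state(dv$S_p, pools$BP_total, pools$T_total,
                         fit$params$transport)
  v <- reaction_rates(dv, fit$params, "abc")
  expect_equal(v$v_c, st$v_c, tolerance = 1e-10)
  # the uptake the solver balanced equals the independent kinetics solve
  expect_equal(periplasm_to_cytoplasm(st$v_c, dv$f_p),
               5 * v$v_E + dv$mu * dv$S_c, tolerance = 1e-6)
})

test_that("solver refuses impossible environments", {
  expect_error(allocate_proteome(cell_params(S_ext = 0), "pts"), "S_ext")
})

test_that("mu is reported consistently across the fit object", {
  fit <- tr_fit("pts_mid")
  expect_identical(fit$mu, fit$decision$mu)
  expect_equal(unname(coef(fit)["mu"]), fit$mu)
  rr <- residuals(fit)
  expect_lt(abs(rr[["closure"]]), 1e-12)
})
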