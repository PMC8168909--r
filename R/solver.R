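## Multi-start constrained maximisation of the steady-state growth rate.
##
## Architecture: the five growth balances are eliminated analytically -
## given proteome fractions, radius and periplasmic fraction, the
## metabolite pools follow in closed form from mu, and mu itself is the
## root of the periplasmic supply balance ("nested" evaluation; residuals
## at the root are ~1e-13). Fast local refinement runs an augmented
## Lagrangian in smooth log/logit coordinates in which the metabolite
## pools are free variables and the substrate:binding-protein complex
## parameterises the ABC transport branch, so every constraint is closed
## form. Multi-start: a large pool of nested-feasible candidates is
## ranked by penalised growth rate; the best are refined; the winner is
## re-polished in the nested parameterisation so the returned optimum
## satisfies the equality constraints to near machine precision.

#' Solver configuration
#'
#' @param n_starts number of local refinements per solve (default 50).
#' @param seed integer seed; every random draw in a solve derives from it.
#' @param constraint_tol feasibility tolerance on scaled constraint
#'   residuals.
#' @param optimality_tol relative tolerance used when comparing candidate
#'   optima (ties broken by smaller residual norm, then lower start index).
#' @param candidate_factor candidate pool size as a multiple of
#'   `n_starts`.
#' @param al_iterations maximal outer augmented-Lagrangian iterations.
#' @param inner_iter iteration cap of each inner quasi-Newton solve.
#' @param scaling named vector of variable scaling targets (the typical
#'   magnitude of each decision variable; scaled variables are
#'   approximately 1 at the optimum).
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(n_starts = 50, seed = 1,
                          constraint_tol = 1e-8, optimality_tol = 1e-9,
                          candidate_factor = 20,
                          al_iterations = 12, inner_iter = 200,
                          scaling = c(S_p = 1e-3, S_c = 1, A = 1, W = 100,
                                      P = 1000,
                                      phi_BP = 0.1, phi_T = 0.1, phi_E = 0.1,
                                      phi_M = 0.1, phi_R = 0.1,
                                      r = 0.5, f_p = 0.5, mu = 1e-4)) {
  stopifnot(n_starts >= 1, constraint_tol > 0, optimality_tol > 0,
            all(scaling > 0))
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 constraint_tol = constraint_tol,
                 optimality_tol = optimality_tol,
                 candidate_factor = candidate_factor,
                 al_iterations = al_iterations, inner_iter = inner_iter,
                 scaling = scaling),
            class = "solver_config")
}

.dv_order <- c("S_p", "S_c", "A", "W", "P",
               "phi_BP", "phi_T", "phi_E", "phi_M", "phi_R",
               "r", "f_p", "mu")

#' Scale decision variables to unit magnitude (and back)
#'
#' Divides each decision variable by its scaling target so that all
#' entries are of order one near the optimum; `unscale_variables()` is
#' the exact inverse, so the round trip is the identity to machine
#' precision.
#'
#' @param x a [decision_vars()] object.
#' @param config a [solver_config()] (supplies the scaling targets).
#' @return `scale_variables()`: a named numeric vector of length 13;
#'   `unscale_variables()`: a [decision_vars()] object.
#' @export
scale_variables <- function(x, config = solver_config()) {
  v <- c(x$S_p, x$S_c, x$A, x$W, x$P, unname(x$phi), x$r, x$f_p, x$mu)
  names(v) <- .dv_order
  v / config$scaling[.dv_order]
}

#' @rdname scale_variables
#' @param v a named scaled vector as produced by `scale_variables()`.
#' @export
unscale_variables <- function(v, config = solver_config()) {
  u <- v * config$scaling[.dv_order]
  decision_vars(S_p = u[["S_p"]], S_c = u[["S_c"]], A = u[["A"]],
                W = u[["W"]], P = u[["P"]],
                phi = c(BP = u[["phi_BP"]], T = u[["phi_T"]], E = u[["phi_E"]],
                        M = u[["phi_M"]], R = u[["phi_R"]]),
                r = u[["r"]], f_p = u[["f_p"]], mu = u[["mu"]])
}

#' Deterministic random start
#'
#' Log-uniform draw of proteome fractions, radius, periplasmic fraction
#' and metabolite pools within the solver bounds, reproducible from
#' `(seed, start_index)` alone and independent of the caller's RNG state.
#'
#' @param seed integer seed.
#' @param start_index index of the start (1-based).
#' @param config a [solver_config()].
#' @param cp a [cell_params()] object (supplies `r_min`, `r_max`).
#' @param transport `"pts"` or `"abc"` (PTS draws have `phi_BP = 0`).
#' @return A [decision_vars()] object (with `mu` set to a nominal value;
#'   the solver re-derives consistent pools before use).
#' @export
random_start <- function(seed, start_index, config = solver_config(),
                         cp = cell_params(), transport = c("pts", "abc")) {
  transport <- match.arg(transport)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(((seed %% 20011L) * 100003L + start_index) %% .Machine$integer.max)
  phis <- exp(runif(4, log(1e-4), log(0.5)))
  if (transport == "pts") phis[1] <- 0
  phi_E <- max(phi_available(cp) - sum(phis), 1e-6)
  r <- exp(runif(1, log(cp$r_min), log(cp$r_max)))
  f_p <- plogis(runif(1, -6, 6))
  decision_vars(S_p = exp(runif(1, log(1e-9), log(10))),
                S_c = exp(runif(1, log(1e-3), log(10))),
                A = exp(runif(1, log(1e-3), log(10))),
                W = 1, P = 1000,
                phi = c(BP = phis[1], T = phis[2], E = phi_E,
                        M = phis[3], R = phis[4]),
                r = r, f_p = f_p, mu = 1e-4)
}

## ---- internal state evaluation ------------------------------------------

## Closed-form state given all internal coordinates. Returns scaled
## equality residuals e (3) and inequality margins h (5), plus the state.
## Coordinates u:
##   abc: log(phi_BP, phi_T, phi_M, phi_R), log r, logit f_p,
##        log A, log S_c, log S_BP
##   pts: log(phi_T, phi_M, phi_R), log r, logit f_p, log A, log S_c, log S_p
.state_core <- function(phi_BP, phi_T, phi_M, phi_R, r, f_p, A, S_c, S_x,
                        transport, cp) {
  tp <- cp$transport
  Phi <- phi_available(cp)
  phi_E <- Phi - phi_BP - phi_T - phi_M - phi_R
  mu <- cp$kR * phi_R / cp$n_R * A / (cp$K_MR + A)
  vol_fac <- if (cp$strict_volume_basis) 1 - f_p else 1
  W <- 3 * (1 + (1 - f_p)^(2 / 3)) / (r * cp$a_w * .MOLEC_PER_UM3_PER_MM * vol_fac)
  v_W <- mu * W
  P <- v_W / (cp$kW * phi_M / cp$n_M * (A / (cp$K_MW + A)))
  v_R <- mu * P
  v_E <- cp$kE * max(phi_E, 1e-12) / cp$n_E * P * S_c / (cp$K_ME + S_c)
  conv <- f_p / (1 - f_p)
  T_tot <- phi_T / cp$n_T * P / conv
  if (transport == "abc") {
    BP_tot <- phi_BP / cp$n_BP * P / conv
    S_BP <- S_x
    Vx <- tp$k2p * tp$k3p / (tp$k2p + tp$k3p) * T_tot
    v_c <- Vx * S_BP / (K_Tp(tp) + S_BP)
    tsb <- v_c / tp$k2p
    ccf <- 1 + tp$k2p / tp$k3p
    BP_free <- BP_tot - S_BP - ccf * tsb
    T_free <- T_tot - ccf * tsb
    S_p <- S_BP * (K_D(tp) + tp$k1p * T_free / tp$k0f) / max(BP_free, 1e-300)
  } else {
    BP_tot <- 0; S_BP <- 0; BP_free <- 0; T_free <- T_tot
    S_p <- S_x
    v_c <- tp$k2 * T_tot * S_p / (K_T(tp) + S_p)
  }
  v_c_cyto <- v_c * conv
  v_diff <- 3 * cp$D * (cp$S_ext - S_p) / (f_p * r^2)
  e <- c((6 * v_E - v_W - v_R - mu * A) / (v_W + v_R + mu * A),
         (v_c_cyto - 5 * v_E - mu * S_c) / (5 * v_E + mu * S_c + 1e-300),
         (v_diff - v_c - mu * S_p) / (v_c + mu * S_p + 1e-300))
  cyto_mass <- cp$m_S * S_c + cp$m_A * A + cp$m_aa * P
  if (cp$density_includes_membrane) cyto_mass <- cyto_mass + cp$m_W * W
  dens_c <- (cp$rho_cyto - cyto_mass) / cp$rho_cyto
  dens_p <- (cp$rho_peri - (cp$m_S * S_p + cp$m_aa * phi_BP * P / conv)) /
    cp$rho_peri
  re <- ((1 - f_p)^(2 / 3) * cp$f_SA -
           phi_T / cp$n_T * P * .MOLEC_PER_UM3_PER_MM * (r / 3) *
           cp$a_T * vol_fac) / cp$f_SA
  h <- c(phi_E = phi_E / Phi, dens_cyto = dens_c, dens_peri = dens_p,
         real_estate = re,
         bp_pool = if (transport == "abc") BP_free / max(BP_tot, 1e-300) else 1)
  list(mu = mu, e = e, h = h,
       phi_BP = phi_BP, phi_T = phi_T, phi_E = phi_E, phi_M = phi_M,
       phi_R = phi_R, r = r, f_p = f_p,
       A = A, S_c = S_c, S_p = S_p, S_BP = S_BP, W = W, P = P,
       T_tot = T_tot, BP_tot = BP_tot,
       v_E = v_E, v_R = v_R, v_W = v_W, v_c = v_c, v_diff = v_diff)
}

.state_from_u <- function(u, transport, cp) {
  if (transport == "abc")
    .state_core(exp(u[1]), exp(u[2]), exp(u[3]), exp(u[4]),
                exp(u[5]), plogis(u[6]), exp(u[7]), exp(u[8]), exp(u[9]),
                transport, cp)
  else
    .state_core(0, exp(u[1]), exp(u[2]), exp(u[3]),
                exp(u[4]), plogis(u[5]), exp(u[6]), exp(u[7]), exp(u[8]),
                transport, cp)
}

.u_from_state <- function(st, transport) {
  if (transport == "abc")
    c(log(st$phi_BP), log(st$phi_T), log(st$phi_M), log(st$phi_R),
      log(st$r), qlogis(st$f_p), log(st$A), log(st$S_c), log(st$S_BP))
  else
    c(log(st$phi_T), log(st$phi_M), log(st$phi_R),
      log(st$r), qlogis(st$f_p), log(st$A), log(st$S_c), log(st$S_p))
}

## Exact steady state for given (phi, r, f_p): mu is the root of the
## periplasmic supply balance; all pools follow in closed form.
.nested_state <- function(phi_BP, phi_T, phi_M, phi_R, r, f_p, transport, cp) {
  tp <- cp$transport
  Phi <- phi_available(cp)
  phi_E <- Phi - phi_BP - phi_T - phi_M - phi_R
  if (phi_E <= 0 || f_p <= 0 || f_p >= 1 || r <= 0) return(NULL)
  muR <- cp$kR * phi_R / cp$n_R
  vol_fac <- if (cp$strict_volume_basis) 1 - f_p else 1
  W <- 3 * (1 + (1 - f_p)^(2 / 3)) / (r * cp$a_w * .MOLEC_PER_UM3_PER_MM * vol_fac)
  conv <- f_p / (1 - f_p)
  at_mu <- function(mu) {
    A <- cp$K_MR * mu / (muR - mu)
    v_W <- mu * W
    P <- v_W / (cp$kW * phi_M / cp$n_M * (A / (cp$K_MW + A)))
    v_R <- mu * P
    v_E <- (v_W + v_R + mu * A) / 6
    vEmax <- cp$kE * phi_E / cp$n_E * P
    if (v_E >= vEmax) return(NULL)
    S_c <- cp$K_ME * v_E / (vEmax - v_E)
    v_c_cyto <- 5 * v_E + mu * S_c
    v_c <- v_c_cyto / conv
    T_tot <- phi_T / cp$n_T * P / conv
    if (transport == "pts") {
      Vm <- tp$k2 * T_tot
      if (v_c >= Vm) return(NULL)
      S_x <- K_T(tp) * v_c / (Vm - v_c)
      S_p <- S_x
    } else {
      BP_tot <- phi_BP / cp$n_BP * P / conv
      Vx <- tp$k2p * tp$k3p / (tp$k2p + tp$k3p) * T_tot
      if (v_c >= Vx) return(NULL)
      S_BP <- K_Tp(tp) * v_c / (Vx - v_c)
      tsb <- v_c / tp$k2p
      ccf <- 1 + tp$k2p / tp$k3p
      BP_free <- BP_tot - S_BP - ccf * tsb
      T_free <- T_tot - ccf * tsb
      if (BP_free <= 0 || T_free <= 0) return(NULL)
      S_p <- S_BP * (K_D(tp) + tp$k1p * T_free / tp$k0f) / BP_free
      S_x <- S_BP
    }
    v_diff <- 3 * cp$D * (cp$S_ext - S_p) / (f_p * r^2)
    list(g = v_diff - v_c - mu * S_p, A = A, S_c = S_c, S_x = S_x)
  }
  gf <- function(mu) {
    s <- at_mu(mu)
    if (is.null(s) || !is.finite(s$g)) -1 - mu else s$g
  }
  lo <- muR * 1e-12
  if (gf(lo) <= 0) return(NULL)
  hi <- muR * (1 - 1e-10)
  k <- 0
  while (gf(hi) > 0 && k < 60) {  # push the bracket toward the domain edge
    hi <- muR - (muR - hi) / 3
    k <- k + 1
  }
  if (gf(hi) > 0) return(NULL)
  root <- uniroot(gf, c(lo, hi), tol = muR * 1e-14)$root
  s <- at_mu(root)
  if (is.null(s)) return(NULL)
  .state_core(phi_BP, phi_T, phi_M, phi_R, r, f_p, s$A, s$S_c, s$S_x,
              transport, cp)
}

## One augmented-Lagrangian run from u0; returns best feasible state seen.
.al_run <- function(u0, transport, cp, musc, config, lo, hi, best0 = NULL) {
  obj <- function(u, lam, nu, rho) {
    s <- .state_from_u(u, transport, cp)
    if (any(!is.finite(c(s$mu, s$e, s$h)))) return(1e6)
    pen_e <- sum(lam * s$e + 0.5 * rho * s$e^2)
    pen_h <- sum(ifelse(s$h < nu / rho, 0.5 * rho * (nu / rho - s$h)^2, 0))
    -s$mu / musc + pen_e + pen_h
  }
  tol <- config$constraint_tol
  best <- best0
  lam <- rep(0, 3); nu <- rep(1, 5); rho <- 100
  u <- u0
  for (it in seq_len(config$al_iterations)) {
    fit <- try(nlminb(u, obj, lam = lam, nu = nu, rho = rho,
                      lower = lo, upper = hi,
                      control = list(iter.max = config$inner_iter,
                                     eval.max = 2.5 * config$inner_iter)),
               silent = TRUE)
    if (inherits(fit, "try-error")) break
    u <- fit$par
    s <- .state_from_u(u, transport, cp)
    if (any(!is.finite(c(s$mu, s$e, s$h)))) break
    lam <- lam + rho * s$e
    nu <- pmax(0, nu - rho * s$h)
    feas <- max(abs(s$e)) < tol && min(s$h) > -tol
    loose <- max(abs(s$e)) < 1e-6 && min(s$h) > -1e-6
    if (loose && (is.null(best) || s$mu > best$s$mu)) best <- list(s = s, u = u)
    if (feas && it >= 3) break
    rho <- min(rho * 5, 1e10)
  }
  best
}

## Nested-parameterisation polish: inequalities via augmented Lagrangian,
## equalities exact by construction.
.nested_polish <- function(st, transport, cp, musc, config, lbr, ubr) {
  nphi <- if (transport == "abc") 4L else 3L
  th0 <- c(if (transport == "abc") log(st$phi_BP),
           log(st$phi_T), log(st$phi_M), log(st$phi_R),
           log(st$r), qlogis(st$f_p))
  nes <- function(th) {
    i <- if (transport == "abc") 1L else 0L
    phi_BP <- if (transport == "abc") exp(th[1]) else 0
    .nested_state(phi_BP, exp(th[i + 1]), exp(th[i + 2]), exp(th[i + 3]),
                  exp(th[i + 4]), plogis(th[i + 5]), transport, cp)
  }
  nu <- rep(1, 5); rho <- 1e4
  objn <- function(th, nu, rho) {
    s <- nes(th)
    if (is.null(s) || any(!is.finite(c(s$mu, s$h)))) return(1e6)
    -s$mu / musc + sum(ifelse(s$h < nu / rho, 0.5 * rho * (nu / rho - s$h)^2, 0))
  }
  th <- th0
  for (it in 1:6) {
    fit <- try(nlminb(th, objn, nu = nu, rho = rho,
                      lower = c(rep(log(1e-10), nphi), lbr, -6),
                      upper = c(rep(log(0.6), nphi), ubr, 6),
                      control = list(iter.max = 120, eval.max = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) break
    th <- fit$par
    s <- nes(th)
    if (is.null(s)) break
    nu <- pmax(0, nu - rho * s$h)
    if (min(s$h) > -config$constraint_tol && it >= 2) break
    rho <- min(rho * 10, 1e10)
  }
  nes(th)
}

#' Maximise the steady-state growth rate over the proteome allocation
#'
#' Solves the constrained allocation problem for one transport type at
#' one external nutrient concentration: maximise the growth rate `mu`
#' over the metabolite pools, proteome fractions, cell radius and
#' periplasmic volume fraction, subject to the five growth balances,
#' proteome closure, membrane coverage, the two density caps and the
#' inner-membrane real-estate limit. Multi-start local optimisation with
#' deterministic seeding; the returned optimum is the best feasible
#' converged point, re-polished so equality residuals are at
#' round-off level, and is refused if no feasible start converged.
#'
#' @param cp a [cell_params()] object (its `S_ext` is the environment).
#' @param transport `"pts"` or `"abc"`.
#' @param config a [solver_config()].
#' @param S_ext optional override of `cp$S_ext` (mM).
#' @param extra_starts optional list of warm-start coordinate vectors (as
#'   stored in `fit$warm`), tried in addition to the random starts.
#' @return An object of class `"alloc_fit"`; see [summary.alloc_fit()].
#'   Components include `mu`, `decision` (a [decision_vars()]),
#'   `observables` (V_max, K_eff, specific affinity, BP:T ratio, SA:V,
#'   capacity ratio, transport proteome fraction), `residuals`,
#'   `margins`, `active`, and a per-start convergence log `starts`.
#' @seealso [validate_solution()], [concentration_sweep()]
#' @export
#' @examples
#' \donttest{
#' cp <- cell_params(S_ext = 1e-2)
#' fit <- allocate_proteome(cp, "pts", solver_config(n_starts = 8, seed = 1))
#' summary(fit)
#' }
allocate_proteome <- function(cp, transport = c("pts", "abc"),
                              config = solver_config(), S_ext = NULL,
                              extra_starts = NULL) {
  stopifnot(inherits(cp, "cell_params"))
  transport <- match.arg(transport)
  if (!is.null(S_ext)) cp$S_ext <- S_ext
  if (cp$S_ext <= 0)
    stop("S_ext must be positive: a cell cannot grow on zero substrate")
  nphi <- if (transport == "abc") 4L else 3L
  nv <- nphi + 5L
  lbr <- log(cp$r_min); ubr <- log(cp$r_max)
  lo <- c(rep(log(1e-10), nphi), lbr, -6, rep(log(1e-14), 2), log(1e-18))
  hi <- c(rep(log(0.6), nphi), ubr, 6, rep(log(1e4), 2), log(1e4))

  ## ---- candidate pool ----------------------------------------------------
  n_cand <- config$candidate_factor * config$n_starts
  cand <- vector("list", n_cand); score <- rep(-Inf, n_cand)
  best_cand <- NULL
  n_found <- 0L; i <- 0L
  max_tries <- 15L * n_cand
  while (n_found < n_cand && i < max_tries) {
    i <- i + 1L
    rs <- random_start(config$seed, i, config, cp, transport)
    phis <- rs$phi
    if (sum(phis[c("BP", "T", "M", "R")]) >= phi_available(cp) * 0.98) next
    f_p <- rs$f_p
    if (transport == "abc" && i %% 2L == 0L) {
      ## seed half the ABC candidates at the periplasmic density cap
      conv <- max(1e-3, phis[["BP"]] * 0.8 * cp$rho_cyto / (0.9 * cp$rho_peri))
      f_p <- min(max(conv / (1 + conv), 0.0025), 0.9975)
    }
    st <- .nested_state(phis[["BP"]], phis[["T"]], phis[["M"]], phis[["R"]],
                        rs$r, f_p, transport, cp)
    if (is.null(st)) next
    u <- .u_from_state(st, transport)
    if (!all(is.finite(u))) next
    n_found <- n_found + 1L
    cand[[n_found]] <- u
    score[n_found] <- st$mu * exp(3 * min(0, min(st$h)))
    if (min(st$h) > -config$constraint_tol &&
        (is.null(best_cand) || st$mu > best_cand$s$mu))
      best_cand <- list(s = st, u = u)
  }
  if (n_found == 0L)
    stop("no feasible starting point found; the parameter set may admit no ",
         "growing steady state at S_ext = ", cp$S_ext, " mM")
  cand <- cand[seq_len(n_found)]
  score <- score[seq_len(n_found)]
  starts <- cand[order(-score)][seq_len(min(config$n_starts, n_found))]
  if (!is.null(extra_starts)) {
    ## re-derive each warm start's allocation as an exact steady state at
    ## this environment; a feasible one is an incumbent, not just a start
    warm_u <- list()
    for (u0 in extra_starts) {
      u0 <- as.numeric(u0)
      if (length(u0) != nv || !all(is.finite(u0))) next
      s0 <- .state_from_u(u0, transport, cp)
      ns <- .nested_state(s0$phi_BP, s0$phi_T, s0$phi_M, s0$phi_R,
                          s0$r, s0$f_p, transport, cp)
      if (is.null(ns)) next
      un <- .u_from_state(ns, transport)
      if (!all(is.finite(un))) next
      warm_u <- c(warm_u, list(un))
      if (min(ns$h) < -config$constraint_tol) {
        ## mildly infeasible at this environment: repair in place with the
        ## nested inequality polish before considering it an incumbent
        ns <- .nested_polish(ns, transport, cp, max(ns$mu, 1e-12), config,
                             log(cp$r_min), log(cp$r_max))
        if (is.null(ns)) next
        un <- .u_from_state(ns, transport)
        if (!all(is.finite(un))) next
        warm_u <- c(warm_u, list(un))
      }
      if (min(ns$h) > -config$constraint_tol &&
          (is.null(best_cand) || ns$mu > best_cand$s$mu))
        best_cand <- list(s = ns, u = un)
    }
    starts <- c(warm_u, starts)
  }
  musc <- max(vapply(starts, function(u) .state_from_u(u, transport, cp)$mu,
                     numeric(1)))

  ## ---- local refinement --------------------------------------------------
  best <- best_cand
  log_rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    res <- .al_run(starts[[k]], transport, cp, musc, config, lo, hi)
    accepted <- !is.null(res)
    if (accepted) {
      better <- is.null(best) ||
        res$s$mu > best$s$mu * (1 + config$optimality_tol) ||
        (abs(res$s$mu - best$s$mu) <= config$optimality_tol * best$s$mu &&
           max(abs(res$s$e)) < max(abs(best$s$e)))
      if (better) best <- res
    }
    sk <- if (accepted) res$s else .state_from_u(starts[[k]], transport, cp)
    log_rows[[k]] <- data.frame(start = k, converged = accepted,
                                mu = if (accepted) res$s$mu else NA_real_,
                                max_resid = max(abs(sk$e)),
                                min_margin = min(sk$h))
  }
  if (is.null(best))
    stop("no feasible converged start out of ", length(starts),
         "; see the start log for residuals")

  ## ---- exact polish ------------------------------------------------------
  pol <- .nested_polish(best$s, transport, cp, musc, config, lbr, ubr)
  ok_pol <- !is.null(pol) && min(pol$h) > -config$constraint_tol * 10 &&
    max(abs(pol$e)) < config$constraint_tol
  if (ok_pol && pol$mu >= best$s$mu * (1 - 1e-6)) {
    best <- list(s = pol, u = .u_from_state(pol, transport))
  } else {
    ## at minimum re-solve the balances exactly at the incumbent allocation
    s0 <- best$s
    ex <- .nested_state(s0$phi_BP, s0$phi_T, s0$phi_M, s0$phi_R,
                        s0$r, s0$f_p, transport, cp)
    if (!is.null(ex) && min(ex$h) > -config$constraint_tol * 10)
      best <- list(s = ex, u = .u_from_state(ex, transport))
    else if (ok_pol)
      best <- list(s = pol, u = .u_from_state(pol, transport))
  }
  st <- best$s

  dv <- decision_vars(S_p = st$S_p, S_c = st$S_c, A = st$A, W = st$W, P = st$P,
                      phi = c(BP = st$phi_BP, T = st$phi_T, E = st$phi_E,
                              M = st$phi_M, R = st$phi_R),
                      r = st$r, f_p = st$f_p, mu = st$mu)
  fit <- structure(
    list(mu = st$mu, decision = dv, transport = transport, params = cp,
         config = config,
         observables = .derive_observables(dv, cp, transport),
         residuals = growth_balance_residuals(dv, cp, transport),
         margins = c(density_margins(dv, cp),
                     real_estate = real_estate_margin(dv, cp)),
         scaled_state = list(e = st$e, h = st$h),
         active = st$h < 1e-5,
         starts = do.call(rbind, log_rows),
         warm = list(best$u)),
    class = "alloc_fit")
  fit
}

## derived observables at a solved allocation
.derive_observables <- function(dv, cp, transport) {
  tp <- cp$transport
  pools <- protein_pools(dv, cp)
  conv <- dv$f_p / (1 - dv$f_p)
  grid <- 10^seq(-7, 2, length.out = 60)
  if (transport == "pts") {
    up <- function(s) pts_uptake(s, pools$T_total, tp)
    keff_fit <- effective_half_saturation(up, grid)
    mm <- mm_fit(tp$k2 * pools$T_total, K_T(tp))
  } else {
    up <- function(s) abc_steady_state(s, pools$BP_total, pools$T_total, tp)$v_c
    keff_fit <- effective_half_saturation(up, grid)
    mm <- abc_mm_approx(1, pools$BP_total, pools$T_total, tp)$fit
  }
  V_max_cyto <- periplasm_to_cytoplasm(keff_fit$V_max, dv$f_p)
  met_capacity <- 5 * cp$kE * pools$E
  list(V_max = keff_fit$V_max,
       V_max_cyto = V_max_cyto,
       K_eff = keff_fit$K_M,
       K_eff_gof = keff_fit$gof,
       K_M_approx = mm$K_M,
       V_max_approx = mm$V_max,
       specific_affinity = specific_affinity(keff_fit),
       bp_per_transporter = if (pools$T_total > 0)
         pools$BP_total / pools$T_total else NA_real_,
       sa_to_vol = 3 / dv$r,
       metabolic_capacity = met_capacity,
       capacity_ratio = if (met_capacity > 0) V_max_cyto / met_capacity else Inf,
       transport_proteome = dv$phi[["BP"]] + dv$phi[["T"]])
}

#' Re-verify a solved allocation from scratch
#'
#' Recomputes every constraint at the fitted decision variables in
#' unscaled units using the cell-model functions (independently of the
#' solver's internal bookkeeping): the five growth balances, proteome
#' closure, membrane coverage, both density margins and the real-estate
#' margin; flags active inequality constraints; and cross-checks the
#' solver's uptake rate against the kinetics module.
#'
#' @param fit an `"alloc_fit"` from [allocate_proteome()].
#' @param tol feasibility tolerance on scaled residuals.
#' @return An object of class `"alloc_validation"`: list with `ok`,
#'   scaled residuals, margins, and active-constraint flags.
#' @export
validate_solution <- function(fit, tol = fit$config$constraint_tol) {
  stopifnot(inherits(fit, "alloc_fit"))
  dv <- fit$decision; cp <- fit$params
  v <- reaction_rates(dv, cp, fit$transport)
  res <- growth_balance_residuals(dv, cp, fit$transport)
  scale_bal <- c(abs(v$v_diff) + v$v_c + dv$mu * dv$S_p,
                 periplasm_to_cytoplasm(v$v_c, dv$f_p) + 5 * v$v_E + dv$mu * dv$S_c,
                 6 * v$v_E + v$v_W + v$v_R + dv$mu * dv$A,
                 v$v_W + dv$mu * dv$W,
                 v$v_R + dv$mu * dv$P)
  res_scaled <- res / pmax(scale_bal, 1e-300)
  closure <- proteome_closure_residual(dv, cp)
  memb <- membrane_coverage_residual(dv, cp)
  memb_scaled <- memb / (4 * pi * (1 + (1 - dv$f_p)^(2 / 3)) * dv$r^2)
  margins <- c(density_margins(dv, cp), real_estate = real_estate_margin(dv, cp))
  margins_scaled <- margins / c(cp$rho_cyto, cp$rho_peri,
                                cp$f_SA * 4 * pi * (1 - dv$f_p)^(2 / 3) * dv$r^2)
  ok <- max(abs(res_scaled)) < tol && abs(closure) < 1e-12 &&
    abs(memb_scaled) < tol && min(margins_scaled) > -10 * tol
  structure(list(ok = ok,
                 balance_residuals = res_scaled,
                 closure_residual = closure,
                 membrane_residual = memb_scaled,
                 margins = margins,
                 margins_scaled = margins_scaled,
                 active = abs(margins_scaled) < 1e-5,
                 mu = dv$mu, tol = tol),
            class = "alloc_validation")
}

#' @export
print.alloc_validation <- function(x, ...) {
  cat(if (x$ok) "Solution validated" else "VALIDATION FAILURE",
      sprintf("(tolerance %.1e)\n", x$tol))
  cat(sprintf("  max |growth balance| (scaled): %.3e\n",
              max(abs(x$balance_residuals))))
  cat(sprintf("  proteome closure: %.3e; membrane coverage: %.3e\n",
              x$closure_residual, x$membrane_residual))
  cat("  inequality margins (scaled):",
      paste(sprintf("%s = %.3e%s", names(x$margins_scaled), x$margins_scaled,
                    ifelse(x$active, "*", "")), collapse = ", "), "\n")
  if (any(x$active)) cat("  (* = active)\n")
  invisible(x)
}
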