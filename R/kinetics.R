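## Uptake kinetics: PTS, exact ABC steady state, Michaelis-Menten
## approximation, effective half-saturation extraction and the
## independent ODE relaxation oracle.
##
## All rates are expressed as change in periplasmic concentration per
## time (mM/s); convert with periplasm_to_cytoplasm() where a cytoplasmic
## basis is needed.

#' PTS uptake rate
#'
#' Cytoplasmic uptake rate of the two-step phosphotransferase scheme at
#' steady state, `v = k2 [T]_total S_p / (K_T + S_p)` - Michaelis-Menten
#' in form, with half-saturation equal to the transport-unit dissociation
#' constant `K_T = k2/k1`.
#'
#' @param S_p periplasmic free-substrate concentration (mM); may be a
#'   vector.
#' @param T_total transport-unit abundance divided by periplasmic volume
#'   (mM).
#' @param tp a [transport_params()] object.
#' @return Uptake rate (mM/s, periplasmic basis), same length as `S_p`.
#' @export
#' @examples
#' tp <- transport_params()
#' pts_uptake(K_T(tp), 1, tp)  # half of k2 * T_total
pts_uptake <- function(S_p, T_total, tp) {
  stopifnot(inherits(tp, "transport_params"))
  if (any(S_p < 0)) stop("S_p must be nonnegative")
  if (T_total < 0) stop("T_total must be nonnegative")
  tp$k2 * T_total * S_p / (K_T(tp) + S_p)
}

#' Exact steady state of the four-step ABC transport scheme
#'
#' Solves the coupled steady-state system of the ABC scheme - substrate
#' binding to the periplasmic binding protein (BP), docking of the loaded
#' BP on the transport unit, irreversible translocation, and BP release -
#' for the species concentrations and the cytoplasmic uptake rate at a
#' fixed periplasmic free-substrate concentration.
#'
#' The coupled system reduces to a single scalar equation in the
#' substrate:binding-protein complex `[S:BP]`: with the translocation
#' complex `[T:S:BP]` and free pools expressed through `[S:BP]` via the
#' flux relation and the two conservation laws, the binding equilibrium
#' `[S:BP] (K_D + k1p [T]/k0f) = S_p [BP]` is monotone in `[S:BP]` and is
#' bracketed on `[0, x_max)` where `x_max` exhausts the free BP pool; the
#' root is refined to near machine precision.
#'
#' Both conservation identities
#' `BP_free + S_BP + (1 + k2p/k3p) T_S_BP = BP_total` and
#' `T_free + (1 + k2p/k3p) T_S_BP = T_total`
#' hold at the returned state to better than 1e-8 relative.
#'
#' @param S_p periplasmic free-substrate concentration (mM), scalar.
#' @param BP_total total binding-protein concentration, periplasmic basis
#'   (mM).
#' @param T_total total transport-unit concentration, periplasmic basis
#'   (mM).
#' @param tp a [transport_params()] object.
#' @return An object of class `"abc_state"`: list with `S_BP`, `BP_free`,
#'   `T_free`, `T_S_BP` (translocation-complex concentration), `T_BP`
#'   (post-translocation complex), `v_c` (uptake rate, mM/s periplasmic
#'   basis), and the inputs.
#' @seealso [abc_relaxation_oracle()] for the independent ODE check,
#'   [abc_mm_approx()] for the closed-form approximation.
#' @export
#' @examples
#' tp <- transport_params()
#' st <- abc_steady_state(1e-3, BP_total = 1, T_total = 0.01, tp)
#' st$v_c
abc_steady_state <- function(S_p, BP_total, T_total, tp) {
  stopifnot(inherits(tp, "transport_params"))
  if (length(S_p) != 1L || S_p < 0) stop("S_p must be a nonnegative scalar")
  if (BP_total < 0 || T_total < 0) stop("pools must be nonnegative")
  kTp <- K_Tp(tp); kD <- K_D(tp)
  cc <- 1 + tp$k2p / tp$k3p
  fx <- tp$k3p / (tp$k2p + tp$k3p)           # T_S_BP fraction of Eq-2 flux
  tsb_of <- function(x) fx * T_total * x / (kTp + x)
  bp_free <- function(x) BP_total - x - cc * tsb_of(x)
  if (S_p == 0 || BP_total == 0 || T_total == 0) {
    ## either no substrate, no carrier or no transporter: no complexes
    x <- 0
    if (T_total == 0 && BP_total > 0 && S_p > 0) {
      ## pure binding equilibrium
      x <- S_p * BP_total / (kD + S_p)
    }
    st <- list(S_BP = x, BP_free = BP_total - x, T_free = T_total,
               T_S_BP = 0, T_BP = 0, v_c = 0,
               S_p = S_p, BP_total = BP_total, T_total = T_total)
    return(structure(st, class = "abc_state"))
  }
  ## bracket: largest admissible S_BP exhausts the BP pool
  if (bp_free(BP_total) >= 0) {
    x_max <- BP_total
  } else {
    x_max <- uniroot(bp_free, c(0, BP_total), tol = BP_total * 1e-15)$root
  }
  eqn <- function(x) {
    tf <- T_total - cc * tsb_of(x)
    x * (kD + tp$k1p * tf / tp$k0f) - S_p * bp_free(x)
  }
  up <- x_max * (1 - 1e-13)
  if (eqn(up) < 0) {
    ## numerically saturated: essentially the whole pool is loaded
    x <- up
  } else {
    x <- uniroot(eqn, c(0, up), tol = x_max * 1e-15)$root
  }
  tsb <- tsb_of(x)
  st <- list(S_BP = x,
             BP_free = BP_total - x - cc * tsb,
             T_free = T_total - cc * tsb,
             T_S_BP = tsb,
             T_BP = (tp$k2p / tp$k3p) * tsb,
             v_c = tp$k2p * tsb,
             S_p = S_p, BP_total = BP_total, T_total = T_total)
  structure(st, class = "abc_state")
}

#' @export
print.abc_state <- function(x, ...) {
  cat("ABC transport steady state (mM, periplasmic basis)\n")
  cat(sprintf("  S_p = %.4g, BP_total = %.4g, T_total = %.4g\n",
              x$S_p, x$BP_total, x$T_total))
  cat(sprintf("  S:BP = %.4g, BP_free = %.4g, T_free = %.4g, T:S:BP = %.4g\n",
              x$S_BP, x$BP_free, x$T_free, x$T_S_BP))
  cat(sprintf("  uptake v_c = %.4g mM/s\n", x$v_c))
  invisible(x)
}

#' ABC uptake rate (exact)
#'
#' Convenience wrapper around [abc_steady_state()] returning only the
#' uptake rate; vectorised over `S_p`.
#'
#' @inheritParams abc_steady_state
#' @return Uptake rate(s) (mM/s, periplasmic basis).
#' @export
abc_uptake <- function(S_p, BP_total, T_total, tp) {
  vapply(S_p, function(s) abc_steady_state(s, BP_total, T_total, tp)$v_c,
         numeric(1))
}

#' Michaelis-Menten fit object
#'
#' A maximal uptake rate and half-saturation concentration pair, the
#' canonical summary of an uptake curve.
#'
#' @param V_max maximal uptake rate (mM/s).
#' @param K_M half-saturation concentration (mM).
#' @param gof optional goodness-of-fit of the MM form over the sampled
#'   curve (coefficient of determination).
#' @return An object of class `"mm_fit"`.
#' @export
mm_fit <- function(V_max, K_M, gof = NA_real_) {
  if (V_max <= 0 || K_M <= 0) stop("V_max and K_M must be positive")
  structure(list(V_max = V_max, K_M = K_M, gof = gof), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: V_max = %.4g mM/s, K_M = %.4g mM",
              x$V_max, x$K_M))
  if (is.finite(x$gof)) cat(sprintf(" (R^2 of MM form: %.6f)", x$gof))
  cat("\n")
  invisible(x)
}

#' Michaelis-Menten approximation of ABC transport
#'
#' Closed-form approximation of the ABC uptake rate, valid when binding
#' proteins greatly outnumber occupied transport units and free transport
#' units are scarce (`[T] << k0r/k1p`):
#' \deqn{V'_{max} = \frac{k'_2 k'_3}{k'_2+k'_3}\,[T]_{tot}
#'       \frac{[BP]_{tot}}{K'_T+[BP]_{tot}},\qquad
#'       K'_M = \frac{K'_T K_D}{K'_T+[BP]_{tot}}.}
#' The half-saturation concentration is an emergent, decreasing function
#' of binding-protein abundance: at `BP_total = 0` it equals `K_D` and it
#' falls as `1/BP_total` once `BP_total >> K_Tp`.
#'
#' @inheritParams abc_steady_state
#' @param S_p periplasmic free-substrate concentration(s) (mM).
#' @return A list with `rate` (the approximate uptake, same length as
#'   `S_p`) and `fit` (an [mm_fit()] holding `V_max` and `K_M`).
#' @export
#' @examples
#' tp <- transport_params()
#' abc_mm_approx(1e-5, BP_total = 1, T_total = 0.01, tp)$fit
abc_mm_approx <- function(S_p, BP_total, T_total, tp) {
  stopifnot(inherits(tp, "transport_params"))
  if (any(S_p < 0) || BP_total < 0 || T_total < 0)
    stop("concentrations must be nonnegative")
  kTp <- K_Tp(tp)
  Vmax <- (tp$k2p * tp$k3p / (tp$k2p + tp$k3p)) * T_total *
    BP_total / (kTp + BP_total)
  Km <- kTp * K_D(tp) / (kTp + BP_total)
  list(rate = Vmax * S_p / (Km + S_p),
       fit = structure(list(V_max = Vmax, K_M = Km, gof = NA_real_),
                       class = "mm_fit"))
}

#' Specific affinity of an uptake system
#'
#' `a = V_max / K_M`, the initial slope of the uptake curve (per second);
#' the key fitness metric at sub-saturating nutrient concentrations.
#'
#' @param fit an [mm_fit()] object.
#' @return The specific affinity (/s).
#' @export
specific_affinity <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  if (fit$K_M == 0) stop("K_M must be positive")
  fit$V_max / fit$K_M
}

#' Effective half-saturation concentration of an uptake curve
#'
#' Profiles an arbitrary uptake function over a concentration grid,
#' takes `V_max` as the rate at the saturating (top) concentration and
#' locates `K_M` as the concentration where the rate crosses `V_max/2`,
#' by monotone bracketing on the grid followed by bisection of the
#' continuous curve to 1e-10 relative precision. A least-squares-free
#' diagnostic of how well the curve follows the Michaelis-Menten form is
#' reported as the coefficient of determination between the sampled
#' curve and `V_max S/(K_M + S)`.
#'
#' @param uptake_fn function mapping concentration (mM) to uptake rate
#'   (mM/s); must be monotone nondecreasing over the grid.
#' @param grid concentration grid (mM), strictly increasing; default 60
#'   log-spaced points from 1e-7 to 1e2 mM.
#' @param saturating_conc concentration treated as saturating; default the
#'   top of the grid.
#' @return An [mm_fit()] with the extracted `V_max`, `K_M` and the
#'   MM-form goodness of fit.
#' @export
#' @examples
#' f <- effective_half_saturation(function(s) 2 * s / (5 + s))
#' c(f$V_max, f$K_M)  # recovers (2, 5)
effective_half_saturation <- function(uptake_fn,
                                      grid = 10^seq(-7, 2, length.out = 60),
                                      saturating_conc = max(grid)) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  v <- vapply(grid, uptake_fn, numeric(1))
  if (any(diff(v) < -1e-9 * max(abs(v))))
    stop("uptake samples are not monotone nondecreasing on the grid")
  V_max <- uptake_fn(saturating_conc)
  if (V_max <= 0) stop("uptake at the saturating concentration is not positive")
  half <- V_max / 2
  idx <- which(v[-1] >= half & v[-length(v)] < half)
  if (length(idx) == 0) {
    if (v[1] >= half)
      stop("half-rate not bracketed: rate already above V_max/2 at the grid bottom")
    stop("half-rate not bracketed on the grid")
  }
  lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
  g <- function(s) uptake_fn(s) - half
  K_M <- uniroot(g, c(lo, hi), tol = lo * 1e-10)$root
  pred <- V_max * grid / (K_M + grid)
  gof <- 1 - sum((v - pred)^2) / sum((v - mean(v))^2)
  structure(list(V_max = V_max, K_M = K_M, gof = gof), class = "mm_fit")
}

#' ODE relaxation oracle for the ABC steady state
#'
#' Independent verification of [abc_steady_state()]: integrates the
#' mass-action ODEs of the four-step scheme (substrate binding, docking,
#' translocation, release) with the periplasmic free substrate clamped at
#' `S_p`, until every species derivative falls below 1e-10 of the species
#' scale, and returns the terminal state. The post-translocation
#' transport-unit:binding-protein complex `T:BP` is resolved as its own
#' species here, whereas the algebraic solution lumps it into the
#' `(1 + k2p/k3p)` conservation factor; at steady state the two agree.
#'
#' @inheritParams abc_steady_state
#' @param horizon maximal integration time (s); a warning reporting the
#'   final derivative norms is thrown if the system has not settled.
#' @return An `"abc_state"` (as [abc_steady_state()]), with attribute
#'   `"converged"`.
#' @export
abc_relaxation_oracle <- function(S_p, BP_total, T_total, tp, horizon = 1e6) {
  stopifnot(inherits(tp, "transport_params"))
  if (S_p < 0 || BP_total < 0 || T_total < 0)
    stop("concentrations must be nonnegative")
  deriv <- function(t, y, parms) {
    sbp <- y[1]; tsb <- y[2]; tbp <- y[3]
    bp <- BP_total - sbp - tsb - tbp
    tf <- T_total - tsb - tbp
    list(c(tp$k0f * S_p * bp - tp$k0r * sbp - tp$k1p * sbp * tf,
           tp$k1p * sbp * tf - tp$k2p * tsb,
           tp$k2p * tsb - tp$k3p * tbp))
  }
  y <- c(0, 0, 0)
  scale <- max(BP_total, T_total, 1e-12)
  k_slow <- min(tp$k0r, tp$k2p, tp$k3p)
  t_end <- 10 / k_slow                        # slowest first-order scale
  converged <- FALSE
  elapsed <- 0
  while (elapsed < horizon) {
    t_end <- min(t_end, horizon - elapsed)
    sol <- suppressWarnings(
      deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                     rtol = 1e-12, atol = 1e-18 * scale, maxsteps = 5e5))
    t_reached <- sol[nrow(sol), 1]
    y <- unname(sol[nrow(sol), -1])
    elapsed <- elapsed + t_reached
    dy <- deriv(0, y, NULL)[[1]]
    ## settled when each species changes by < 1e-10 of itself per
    ## slowest-rate time unit, or when the residual drift could not move
    ## any pool perceptibly over the whole horizon
    if (all(abs(dy) < 1e-10 * k_slow * pmax(abs(y), 1e-12 * scale) |
              abs(dy) * horizon < 1e-6 * scale)) {
      converged <- TRUE
      break
    }
    if (t_reached >= t_end) t_end <- t_end * 10
  }
  if (!converged) {
    dy <- deriv(0, y, NULL)[[1]]
    warning(sprintf(
      "relaxation not settled within horizon; final |dy| = %.3g, %.3g, %.3g",
      dy[1], dy[2], dy[3]))
  }
  st <- list(S_BP = y[1],
             BP_free = BP_total - y[1] - y[2] - y[3],
             T_free = T_total - y[2] - y[3],
             T_S_BP = y[2],
             T_BP = y[3],
             v_c = tp$k2p * y[2],
             S_p = S_p, BP_total = BP_total, T_total = T_total)
  structure(st, class = "abc_state", converged = converged)
}
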