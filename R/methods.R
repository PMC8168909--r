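## S3 methods for fitted allocations.

#' @export
print.alloc_fit <- function(x, ...) {
  cat(sprintf("Optimal %s-cell proteome allocation at S_ext = %g mM\n",
              toupper(x$transport), x$params$S_ext))
  cat(sprintf("  growth rate mu = %.4g /s (doubling time %.3g h)\n",
              x$mu, log(2) / x$mu / 3600))
  phi <- x$decision$phi
  cat("  phi:", paste(sprintf("%s = %.4g", names(phi), phi), collapse = ", "), "\n")
  cat(sprintf("  r = %.4g um (SA:V = %.3g /um), f_p = %.4g\n",
              x$decision$r, x$observables$sa_to_vol, x$decision$f_p))
  cat(sprintf("  K_eff = %.4g mM, V_max = %.4g mM/s (periplasmic basis)\n",
              x$observables$K_eff, x$observables$V_max))
  invisible(x)
}

#' Summary of a fitted allocation
#'
#' @param object an `"alloc_fit"`.
#' @param ... unused.
#' @return An object of class `"summary.alloc_fit"` collecting the
#'   optimum, derived observables, constraint activity and the
#'   multi-start convergence record.
#' @export
summary.alloc_fit <- function(object, ...) {
  conv <- object$starts[object$starts$converged, , drop = FALSE]
  distinct <- if (nrow(conv) > 0)
    length(unique(round(log(conv$mu), 3))) else 0L
  structure(list(fit = object,
                 n_starts = nrow(object$starts),
                 n_converged = nrow(conv),
                 n_distinct_optima = distinct,
                 validation = validate_solution(object)),
            class = "summary.alloc_fit")
}

#' @export
print.summary.alloc_fit <- function(x, ...) {
  print(x$fit)
  ob <- x$fit$observables
  cat(sprintf("  specific affinity a = V_max/K_eff = %.4g /s\n",
              ob$specific_affinity))
  cat(sprintf("  BP per transport unit = %.4g; transport proteome share = %.4g\n",
              ob$bp_per_transporter, ob$transport_proteome))
  cat(sprintf("  transport/metabolic capacity ratio = %.4g\n",
              ob$capacity_ratio))
  cat(sprintf("  starts: %d run, %d converged, ~%d distinct local optima\n",
              x$n_starts, x$n_converged, x$n_distinct_optima))
  act <- names(x$validation$active)[x$validation$active]
  cat("  active inequality constraints:",
      if (length(act)) paste(act, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
coef.alloc_fit <- function(object, ...) {
  scale_variables(object$decision, object$config) *
    object$config$scaling[.dv_order]
}

#' Constraint residuals of a fitted allocation
#'
#' @param object an `"alloc_fit"`.
#' @param ... unused.
#' @return The five growth-balance residuals (mM/s) plus the proteome
#'   closure and membrane-coverage residuals.
#' @export
residuals.alloc_fit <- function(object, ...) {
  c(object$residuals,
    closure = proteome_closure_residual(object$decision, object$params),
    membrane = membrane_coverage_residual(object$decision, object$params))
}

#' Uptake curve of a fitted allocation
#'
#' Evaluates the fitted cell's uptake rate (exact transport model with
#' the optimised protein abundances held fixed) at new periplasmic
#' substrate concentrations.
#'
#' @param object an `"alloc_fit"`.
#' @param newdata numeric vector of substrate concentrations (mM);
#'   default a log grid around the fitted `K_eff`.
#' @param basis `"periplasmic"` (native) or `"cytoplasmic"`.
#' @param ... unused.
#' @return Data frame with columns `S_p` and `rate`.
#' @export
predict.alloc_fit <- function(object,
                              newdata = NULL,
                              basis = c("periplasmic", "cytoplasmic"), ...) {
  basis <- match.arg(basis)
  if (is.null(newdata))
    newdata <- object$observables$K_eff * 10^seq(-2, 4, length.out = 40)
  pools <- protein_pools(object$decision, object$params)
  tp <- object$params$transport
  rate <- if (object$transport == "pts") {
    pts_uptake(newdata, pools$T_total, tp)
  } else {
    abc_uptake(newdata, pools$BP_total, pools$T_total, tp)
  }
  if (basis == "cytoplasmic")
    rate <- periplasm_to_cytoplasm(rate, object$decision$f_p)
  data.frame(S_p = newdata, rate = rate)
}

#' Plot the uptake curve of a fitted allocation
#'
#' Log-log uptake curve with the effective half-saturation concentration
#' and maximal rate marked.
#'
#' @param x an `"alloc_fit"`.
#' @param ... passed to `plot.default`.
#' @export
plot.alloc_fit <- function(x, ...) {
  pr <- predict(x)
  plot(pr$S_p, pr$rate, type = "l", log = "xy",
       xlab = "periplasmic substrate (mM)",
       ylab = "uptake rate (mM/s)",
       main = sprintf("%s cell optimised at S_ext = %g mM",
                      toupper(x$transport), x$params$S_ext), ...)
  abline(v = x$observables$K_eff, lty = 2)
  abline(h = x$observables$V_max / 2, lty = 3)
  mtext(sprintf("K_eff = %.3g mM", x$observables$K_eff), side = 3, line = 0,
        adj = 0, cex = 0.8)
  invisible(x)
}

#' Effective half-saturation profile of a fitted allocation
#'
#' Re-extracts `(V_max, K_M)` from the fitted cell's uptake curve with
#' the optimised protein abundances held fixed. By default the curve is
#' the transport system alone as a function of the periplasmic free
#' substrate; with `include_diffusion = TRUE` the curve is uptake as a
#' function of the *external* concentration, with the periplasmic level
#' solved self-consistently from the diffusive boundary-layer supply
#' (no growth dilution), so the extracted half-saturation also reflects
#' the cell's diffusive envelope.
#'
#' @param fit an `"alloc_fit"`.
#' @param include_diffusion couple the diffusive supply step into the
#'   profiled curve.
#' @param grid concentration grid handed to
#'   [effective_half_saturation()].
#' @return An [mm_fit()].
#' @export
keff_profile <- function(fit, include_diffusion = FALSE,
                         grid = 10^seq(-7, 2, length.out = 60)) {
  stopifnot(inherits(fit, "alloc_fit"))
  cp <- fit$params; dv <- fit$decision
  pools <- protein_pools(dv, cp)
  transport_rate <- if (fit$transport == "pts") {
    function(s) pts_uptake(s, pools$T_total, cp$transport)
  } else {
    function(s) abc_steady_state(s, pools$BP_total, pools$T_total,
                                 cp$transport)$v_c
  }
  fn <- if (!include_diffusion) transport_rate else function(s_ext) {
    if (s_ext == 0) return(0)
    bal <- function(s_p) diffusive_uptake(s_ext, s_p, dv$f_p, dv$r, cp$D) -
      transport_rate(s_p)
    s_p <- uniroot(bal, c(0, s_ext), tol = s_ext * 1e-12)$root
    transport_rate(s_p)
  }
  effective_half_saturation(fn, grid)
}
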