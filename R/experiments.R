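## Reproduction drivers: concentration sweeps, PTS-vs-ABC comparison,
## sensitivity analyses and tabular export.

#' Sweep the allocation problem over external nutrient concentrations
#'
#' Solves the growth-maximisation problem for each transport type at
#' every concentration of a log-spaced grid. Each grid point is
#' warm-started from its neighbour's optimum in addition to the random
#' multi-starts, in a forward and a backward pass; the better of the two
#' passes is kept, which guards against basin-hopping artifacts along
#' the grid. Failed grid points are recorded (`ok = FALSE`), never
#' silently dropped.
#'
#' @param cp a [cell_params()] object.
#' @param transports character vector, subset of `c("pts", "abc")`.
#' @param grid strictly increasing positive concentration grid (mM);
#'   default 40 log-spaced points spanning 1 nM to 100 mM.
#' @param config a [solver_config()]; the sweep default uses 12 starts
#'   per point (plus warm starts).
#' @param passes 1 (forward only) or 2 (forward + backward).
#' @param keep_fits keep the full `"alloc_fit"` objects as an attribute.
#' @return A data frame of class `"alloc_sweep"`, one row per
#'   (concentration, transport): growth rate, geometry, proteome
#'   fractions, V_max, K_eff, BP:T ratio, capacity ratio and
#'   active-constraint flags.
#' @export
concentration_sweep <- function(cp,
                                transports = c("pts", "abc"),
                                grid = 10^seq(-6, 2, length.out = 40),
                                config = solver_config(n_starts = 12),
                                passes = 2,
                                keep_fits = FALSE) {
  stopifnot(all(transports %in% c("pts", "abc")), all(diff(grid) > 0),
            all(grid > 0))
  fits <- list()
  for (ty in transports) {
    warm <- NULL
    for (ii in seq_along(grid)) {
      key <- paste(ty, ii)
      f <- try(allocate_proteome(cp, ty, config, S_ext = grid[ii],
                                 extra_starts = warm), silent = TRUE)
      if (inherits(f, "try-error")) {
        fits[[key]] <- attr(f, "condition")$message
        warm <- NULL
      } else {
        fits[[key]] <- f
        warm <- f$warm
      }
    }
    if (passes >= 2) {
      warm <- NULL
      for (ii in rev(seq_along(grid))) {
        key <- paste(ty, ii)
        prevf <- fits[[key]]
        f <- try(allocate_proteome(cp, ty, config, S_ext = grid[ii],
                                   extra_starts = warm), silent = TRUE)
        if (!inherits(f, "try-error")) {
          if (!inherits(prevf, "alloc_fit") || f$mu > prevf$mu) fits[[key]] <- f
          warm <- fits[[key]]$warm
        }
      }
    }
    ## repair: growth cannot fall as nutrients rise; a dip marks a local
    ## optimum, so re-solve dips warm-started from the better neighbour
    for (rep_round in 1:3) {
      dips <- 0L
      for (ii in seq_along(grid)[-1]) {
        f_lo <- fits[[paste(ty, ii - 1L)]]
        f_hi <- fits[[paste(ty, ii)]]
        if (!inherits(f_lo, "alloc_fit")) next
        if (inherits(f_hi, "alloc_fit") && f_hi$mu >= f_lo$mu * (1 - 0.005)) next
        dips <- dips + 1L
        ws <- c(f_lo$warm, if (inherits(f_hi, "alloc_fit")) f_hi$warm)
        f <- try(allocate_proteome(cp, ty, config, S_ext = grid[ii],
                                   extra_starts = ws), silent = TRUE)
        if (!inherits(f, "try-error") &&
            (!inherits(f_hi, "alloc_fit") || f$mu > f_hi$mu))
          fits[[paste(ty, ii)]] <- f
      }
      if (dips == 0L) break
    }
  }
  rows <- list()
  for (ty in transports) for (ii in seq_along(grid)) {
    f <- fits[[paste(ty, ii)]]
    if (inherits(f, "alloc_fit")) {
      ob <- f$observables; dv <- f$decision
      rows[[paste(ty, ii)]] <- data.frame(
        S_ext = grid[ii], transport = ty, ok = TRUE, mu = f$mu,
        r = dv$r, f_p = dv$f_p, sa_to_vol = ob$sa_to_vol,
        phi_BP = dv$phi[["BP"]], phi_T = dv$phi[["T"]], phi_E = dv$phi[["E"]],
        phi_M = dv$phi[["M"]], phi_R = dv$phi[["R"]],
        V_max = ob$V_max, V_max_cyto = ob$V_max_cyto,
        K_eff = ob$K_eff, K_M_approx = ob$K_M_approx,
        specific_affinity = ob$specific_affinity,
        bp_per_transporter = ob$bp_per_transporter,
        metabolic_capacity = ob$metabolic_capacity,
        capacity_ratio = ob$capacity_ratio,
        transport_proteome = ob$transport_proteome,
        dens_cyto_active = unname(f$active["dens_cyto"]),
        dens_peri_active = unname(f$active["dens_peri"]),
        real_estate_active = unname(f$active["real_estate"]),
        note = "")
    } else {
      rows[[paste(ty, ii)]] <- data.frame(
        S_ext = grid[ii], transport = ty, ok = FALSE, mu = NA_real_,
        r = NA_real_, f_p = NA_real_, sa_to_vol = NA_real_,
        phi_BP = NA_real_, phi_T = NA_real_, phi_E = NA_real_,
        phi_M = NA_real_, phi_R = NA_real_,
        V_max = NA_real_, V_max_cyto = NA_real_,
        K_eff = NA_real_, K_M_approx = NA_real_,
        specific_affinity = NA_real_, bp_per_transporter = NA_real_,
        metabolic_capacity = NA_real_, capacity_ratio = NA_real_,
        transport_proteome = NA_real_,
        dens_cyto_active = NA, dens_peri_active = NA,
        real_estate_active = NA,
        note = as.character(f))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- cp
  attr(out, "config") <- config
  if (keep_fits) attr(out, "fits") <- fits
  class(out) <- c("alloc_sweep", "data.frame")
  out
}

#' Transport-to-metabolic capacity ratio profile
#'
#' Appends (or recomputes) the ratio of the maximal uptake rate to the
#' maximal metabolic processing rate, both on the cytoplasmic basis with
#' the 5:1 substrate stoichiometry folded in, so a perfectly matched cell
#' has ratio 1. A zero metabolic pool is reported as an infinite ratio
#' with a flag.
#'
#' @param sweep an `"alloc_sweep"` data frame.
#' @return The sweep with columns `capacity_ratio` and
#'   `capacity_unbounded` (logical).
#' @export
capacity_ratio_profile <- function(sweep) {
  stopifnot(is.data.frame(sweep),
            all(c("V_max_cyto", "metabolic_capacity") %in% names(sweep)))
  ratio <- ifelse(sweep$metabolic_capacity > 0,
                  sweep$V_max_cyto / sweep$metabolic_capacity, Inf)
  sweep$capacity_ratio <- ratio
  sweep$capacity_unbounded <- !is.finite(ratio)
  sweep
}

#' Concentration at which the growth-rate curves cross
#'
#' Locates the external concentration where the ABC and PTS optimal
#' growth rates are equal, by log-linear interpolation of
#' `log(mu_ABC / mu_PTS)` between the bracketing grid points.
#'
#' @param sweep an `"alloc_sweep"` containing both transport types.
#' @return The crossover concentration (mM), or `NA` if the curves do
#'   not cross inside the grid.
#' @export
crossover_concentration <- function(sweep) {
  ab <- sweep[sweep$transport == "abc" & sweep$ok, c("S_ext", "mu")]
  pt <- sweep[sweep$transport == "pts" & sweep$ok, c("S_ext", "mu")]
  m <- merge(ab, pt, by = "S_ext", suffixes = c("_abc", "_pts"))
  m <- m[order(m$S_ext), ]
  if (nrow(m) < 2) return(NA_real_)
  d <- log(m$mu_abc / m$mu_pts)
  ix <- which(d[-nrow(m)] > 0 & d[-1] <= 0)
  if (length(ix) == 0) return(NA_real_)
  i <- ix[1]
  w <- d[i] / (d[i] - d[i + 1])
  exp((1 - w) * log(m$S_ext[i]) + w * log(m$S_ext[i + 1]))
}

#' @export
plot.alloc_sweep <- function(x, what = c("mu", "sa_to_vol", "K_eff"), ...) {
  what <- match.arg(what)
  ok <- x[x$ok, ]
  cols <- c(pts = "firebrick", abc = "royalblue")
  plot(NA, xlim = range(ok$S_ext), ylim = range(ok[[what]], na.rm = TRUE),
       log = "xy", xlab = "external substrate (mM)", ylab = what, ...)
  for (ty in unique(ok$transport)) {
    d <- ok[ok$transport == ty, ]
    lines(d$S_ext, d[[what]], col = cols[[ty]], lwd = 2)
    points(d$S_ext, d[[what]], col = cols[[ty]], pch = 16, cex = 0.6)
  }
  legend("topleft", legend = toupper(unique(ok$transport)),
         col = cols[unique(ok$transport)], lwd = 2, bty = "n")
  invisible(x)
}

#' Parameter sensitivity sweeps
#'
#' Re-runs a concentration sweep with one parameter multiplied by each of
#' a set of factors, and summarises whether the growth-rate crossover
#' between the ABC and PTS cells persists. The special name `"k3p"`
#' covers the dissociation-rate sensitivity case (e.g. raising
#' `k3p` to `k2p` by factor 100).
#'
#' @param cp baseline [cell_params()].
#' @param param name of a parameter of [cell_params()] or
#'   [transport_params()].
#' @param factors positive multiplicative factors (factor 1 reproduces
#'   the baseline).
#' @param grid,config,transports,passes as in [concentration_sweep()].
#' @return A list with `sweeps` (one `"alloc_sweep"` per factor) and
#'   `summary` (data frame: factor, crossover presence, crossover
#'   concentration).
#' @export
sensitivity_sweep <- function(cp, param, factors = c(0.01, 0.1, 1, 10, 100),
                              grid = 10^seq(-6, 2, length.out = 9),
                              config = solver_config(n_starts = 12),
                              transports = c("pts", "abc"),
                              passes = 2) {
  stopifnot(all(factors > 0))
  tkeys <- names(unclass(cp$transport))
  sweeps <- list()
  summ <- list()
  for (fc in factors) {
    cpi <- cp
    if (param %in% tkeys) {
      targs <- as.list(unclass(cp$transport))
      targs[[param]] <- targs[[param]] * fc
      cpi$transport <- do.call(transport_params, targs)
    } else if (param %in% names(cp) && is.numeric(cp[[param]])) {
      cpi[[param]] <- cp[[param]] * fc
    } else stop("unknown parameter: ", param)
    sw <- concentration_sweep(cpi, transports, grid, config, passes)
    xc <- crossover_concentration(sw)
    sweeps[[as.character(fc)]] <- sw
    summ[[as.character(fc)]] <- data.frame(param = param, factor = fc,
                                           crossover = is.finite(xc),
                                           crossover_conc = xc)
  }
  list(sweeps = sweeps, summary = do.call(rbind, summ))
}

#' Compare matched PTS and ABC optima
#'
#' Head-to-head ratios of two fitted allocations at the same external
#' concentration: transport proteome share, maximal uptake rate,
#' half-saturation and surface-area-to-volume ratio.
#'
#' @param pts_fit,abc_fit `"alloc_fit"` objects solved at the same
#'   `S_ext` for PTS and ABC transport respectively.
#' @return An object of class `"transport_comparison"`.
#' @export
compare_summary <- function(pts_fit, abc_fit) {
  stopifnot(inherits(pts_fit, "alloc_fit"), inherits(abc_fit, "alloc_fit"))
  if (pts_fit$transport != "pts" || abc_fit$transport != "abc")
    stop("arguments must be a PTS fit and an ABC fit, in that order")
  if (abs(log(pts_fit$params$S_ext / abc_fit$params$S_ext)) > 1e-9)
    stop("the two fits were solved at different external concentrations")
  op <- pts_fit$observables; oa <- abc_fit$observables
  structure(list(
    S_ext = pts_fit$params$S_ext,
    mu_pts = pts_fit$mu, mu_abc = abc_fit$mu,
    transport_proteome_ratio = oa$transport_proteome / op$transport_proteome,
    V_max_ratio = op$V_max_cyto / oa$V_max_cyto,
    K_ratio = op$K_eff / oa$K_eff,
    sa_to_vol_ratio = op$sa_to_vol / oa$sa_to_vol),
    class = "transport_comparison")
}

#' @export
print.transport_comparison <- function(x, ...) {
  cat(sprintf("PTS vs ABC at S_ext = %g mM\n", x$S_ext))
  cat(sprintf("  mu: PTS %.4g /s, ABC %.4g /s (PTS:ABC = %.3g)\n",
              x$mu_pts, x$mu_abc, x$mu_pts / x$mu_abc))
  cat(sprintf("  transport proteome ABC:PTS = %.3g\n",
              x$transport_proteome_ratio))
  cat(sprintf("  V_max PTS:ABC = %.3g (cytoplasmic basis)\n", x$V_max_ratio))
  cat(sprintf("  K_M(PTS) / K_eff(ABC) = %.4g\n", x$K_ratio))
  cat(sprintf("  SA:V PTS:ABC = %.3g\n", x$sa_to_vol_ratio))
  invisible(x)
}

#' Export result tables with provenance
#'
#' Writes each table as CSV preceded by comment lines documenting units
#' and a hash of the full configuration, plus a JSON sidecar carrying the
#' parameter set, solver configuration and seed, sufficient to reproduce
#' the tables bitwise.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param cp the [cell_params()] used.
#' @param config the [solver_config()] used.
#' @return Invisibly, the written file paths.
#' @export
export_results <- function(tables, dir, cp, config = solver_config()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- list(params = .flatten_params(cp),
              solver = unclass(config))
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(c("# trophos result table; units: mM, s, um, Da",
                 paste0("# config_md5: ", hash)), con)
    write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  sidecar <- file.path(dir, "config.json")
  writeLines(jsonlite::toJSON(c(cfg, list(config_md5 = hash)),
                              digits = NA, auto_unbox = TRUE, pretty = TRUE),
             sidecar)
  invisible(c(paths, sidecar))
}

.flatten_params <- function(cp) {
  out <- unclass(cp)
  out$transport <- unclass(out$transport)
  out
}
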