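#' Kinetic parameters of the PTS and ABC transport systems
#'
#' Rate constants of the two-step PTS scheme and the four-step ABC scheme.
#' The derived dissociation constants are never stored: [K_T()], [K_D()]
#' and [K_Tp()] recompute them from the rates on every call, so the rates
#' are the single source of truth.
#'
#' Defaults are the glucose-PTS / maltose-ABC reference set: translocation
#' rates `k2 = k2p = 200` /s and transport-unit dissociation constants
#' `K_T ~ K_Tp ~ 10` uM for both systems, binding-protein kinetics
#' `k0f = 1e5` /mM/s and `k0r = 100` /s (so `K_D = 1` uM), a
#' transport-unit association rate 100-fold lower for ABC than for PTS
#' (`k1p = 0.01 k1`, slow diffusion of the bulky binding protein), and a
#' BP/transport-unit dissociation rate 100-fold below translocation
#' (`k3p = 0.01 k2p`, same diffusive bottleneck). Note `k3p = 0.01 k2p`
#' makes `K_Tp = 9.901` uM, i.e. the two dissociation constants match to
#' 1%, not exactly.
#'
#' @param k1 PTS substrate/transport-unit association rate (/mM/s).
#' @param k2 PTS translocation rate (/s).
#' @param k0f substrate/binding-protein association rate (/mM/s).
#' @param k0r substrate/binding-protein dissociation rate (/s).
#' @param k1p bound-complex/transport-unit association rate (/mM/s).
#' @param k2p ABC translocation rate (/s).
#' @param k3p transport-unit/binding-protein dissociation rate (/s).
#'
#' @return An object of class `"transport_params"`: a named list of the
#'   seven rates.
#' @seealso [K_T()], [K_D()], [K_Tp()], [pts_uptake()], [abc_steady_state()]
#' @export
#' @examples
#' tp <- transport_params()
#' K_T(tp) * 1e3   # uM
#' K_Tp(tp) * 1e3  # uM, approximately equal by construction
transport_params <- function(k1 = 2e4, k2 = 200,
                             k0f = 1e5, k0r = 100,
                             k1p = 0.01 * k1, k2p = k2, k3p = 0.01 * k2p) {
  tp <- list(k1 = k1, k2 = k2, k0f = k0f, k0r = k0r,
             k1p = k1p, k2p = k2p, k3p = k3p)
  for (nm in names(tp)) {
    v <- tp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("transport rate '", nm, "' must be a single positive number")
  }
  structure(tp, class = "transport_params")
}

#' Derived dissociation constants of the transport schemes
#'
#' `K_T = k2/k1` is the PTS transport-unit dissociation constant,
#' `K_D = k0r/k0f` the substrate/binding-protein dissociation constant and
#' `K_Tp = k2p*k3p/(k1p*(k2p + k3p))` the ABC transport-unit dissociation
#' constant. All in mM; always recomputed from the rates.
#'
#' @param tp a [transport_params()] object.
#' @return A single concentration (mM).
#' @export
K_T <- function(tp) tp$k2 / tp$k1

#' @rdname K_T
#' @export
K_D <- function(tp) tp$k0r / tp$k0f

#' @rdname K_T
#' @export
K_Tp <- function(tp) tp$k2p * tp$k3p / (tp$k1p * (tp$k2p + tp$k3p))

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport kinetics (mM, s)\n")
  cat(sprintf("  PTS: k1 = %g /mM/s, k2 = %g /s  (K_T = %.4g uM)\n",
              x$k1, x$k2, 1e3 * K_T(x)))
  cat(sprintf("  ABC: k0f = %g /mM/s, k0r = %g /s (K_D = %.4g uM)\n",
              x$k0f, x$k0r, 1e3 * K_D(x)))
  cat(sprintf("       k1p = %g /mM/s, k2p = %g /s, k3p = %g /s (K_Tp = %.4g uM)\n",
              x$k1p, x$k2p, x$k3p, 1e3 * K_Tp(x)))
  invisible(x)
}

#' Whole-cell model parameters
#'
#' All parameters of the coarse-grained self-replicator cell: transport
#' kinetics, metabolic/membrane/ribosomal turnover numbers, proteomic
#' costs (amino acids per enzyme copy), geometry, diffusivity, density
#' caps and fixed "other"-proteome fractions. Units: mM, s, um, Da.
#'
#' The proteomic cost vector encodes that an ABC binding protein costs
#' four-fold fewer amino acids than a transport unit
#' (`n_BP = n_T / 4` by default).
#'
#' Metabolic stoichiometry: the catabolic reaction converts 5 substrate
#' molecules into 6 amino-acid precursors per reaction event
#' (coefficients -5/+6 applied to the reaction rate `v_E`).
#'
#' The default values are the package baseline, chosen from
#' *E. coli*-scale physiology (see the methods vignette for the
#' justification of each value); the transport kinetics defaults are the
#' measured glucose-PTS/maltose reference set.
#'
#' @param transport a [transport_params()] object.
#' @param D substrate diffusivity in the outer boundary layer/periplasm
#'   (um^2/s).
#' @param kE,K_ME metabolic turnover (/s per enzyme) and half-saturation
#'   (mM) of the catabolic reaction (5 S_c -> 6 A).
#' @param kW,K_MW membrane-synthesis turnover and half-saturation (A -> W).
#' @param kR,K_MR protein-synthesis (ribosome) turnover (amino acids
#'   polymerised /s per ribosome) and half-saturation (A -> P).
#' @param n_BP,n_T,n_E,n_M,n_R amino acids per copy of binding protein,
#'   transport unit, metabolic enzyme, membrane-synthesis enzyme and
#'   ribosome. Enzyme copy concentration is `[X] = phi_X * P / n_X`
#'   (i.e. `alpha_X = 1/n_X`).
#' @param a_w membrane area per membrane unit (um^2).
#' @param a_T inner-membrane area per transport unit (um^2).
#' @param f_SA fraction of the inner membrane available to transport units.
#' @param rho_cyto,rho_peri maximal cytoplasmic and periplasmic mass
#'   densities (mM x Da; 1e5 mM x Da = 100 g/L).
#' @param m_S,m_A,m_aa,m_W molecular masses (Da) of substrate, free amino
#'   acid, protein-incorporated amino acid, membrane unit.
#' @param phi_O_cyto,phi_O_peri fixed "other"-protein proteome fractions.
#' @param r_min,r_max radius bounds of the model domain (um). `r_min`
#'   0.06 um corresponds to a maximal surface-area-to-volume ratio of
#'   50 /um.
#' @param S_ext external substrate concentration (mM), the environmental
#'   control variable.
#' @param density_includes_membrane logical; count membrane units in the
#'   cytoplasmic density sum (default `FALSE`: membrane units sit in the
#'   bilayer, not the cytoplasm).
#' @param strict_volume_basis logical; if `TRUE`, the membrane-coverage
#'   and real-estate constraints multiply concentrations by the
#'   cytoplasmic volume rather than the total cell volume. The default
#'   `FALSE` follows the model equations as printed.
#'
#' @return An object of class `"cell_params"`.
#' @seealso [allocate_proteome()], [read_params()], [write_params()]
#' @export
#' @examples
#' cp <- cell_params(S_ext = 1e-6)  # 1 nM environment
#' cp$transport
cell_params <- function(transport = transport_params(),
                        D = 100,
                        kE = 2, K_ME = 0.1,
                        kW = 0.5, K_MW = 0.1,
                        kR = 20, K_MR = 0.1,
                        n_T = 1500, n_BP = n_T / 4,
                        n_E = 2500, n_M = 500, n_R = 7459,
                        a_w = 5e-7, a_T = 2.5e-5, f_SA = 0.3,
                        rho_cyto = 3e5, rho_peri = 5e4,
                        m_S = 180, m_A = 110, m_aa = 110, m_W = 700,
                        phi_O_cyto = 0.35, phi_O_peri = 0.05,
                        r_min = 0.06, r_max = 10,
                        S_ext = 1e-3,
                        density_includes_membrane = FALSE,
                        strict_volume_basis = FALSE) {
  if (!inherits(transport, "transport_params"))
    stop("'transport' must be a transport_params object")
  num <- list(D = D, kE = kE, K_ME = K_ME, kW = kW, K_MW = K_MW,
              kR = kR, K_MR = K_MR,
              n_BP = n_BP, n_T = n_T, n_E = n_E, n_M = n_M, n_R = n_R,
              a_w = a_w, a_T = a_T, f_SA = f_SA,
              rho_cyto = rho_cyto, rho_peri = rho_peri,
              m_S = m_S, m_A = m_A, m_aa = m_aa, m_W = m_W,
              phi_O_cyto = phi_O_cyto, phi_O_peri = phi_O_peri,
              r_min = r_min, r_max = r_max, S_ext = S_ext)
  for (nm in setdiff(names(num), "S_ext")) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("cell parameter '", nm, "' must be a single positive number")
  }
  if (S_ext < 0) stop("S_ext must be nonnegative")
  if (phi_O_cyto + phi_O_peri >= 1)
    stop("fixed 'other' proteome fractions must sum to less than 1")
  if (f_SA > 1) stop("f_SA is a fraction and must be <= 1")
  if (r_min >= r_max) stop("r_min must be below r_max")
  cp <- c(list(transport = transport), num,
          list(density_includes_membrane = isTRUE(density_includes_membrane),
               strict_volume_basis = isTRUE(strict_volume_basis)))
  structure(cp, class = "cell_params")
}

#' Proteome fraction available to the optimised protein groups
#'
#' `1 - phi_O_cyto - phi_O_peri`: the share of the proteome left to the
#' five optimised groups after the fixed "other" fractions.
#'
#' @param cp a [cell_params()] object.
#' @return A scalar in (0, 1).
#' @export
phi_available <- function(cp) 1 - cp$phi_O_cyto - cp$phi_O_peri

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell model parameters (mM, s, um, Da)\n")
  print(x$transport)
  cat(sprintf("  diffusivity D = %g um^2/s; S_ext = %g mM\n", x$D, x$S_ext))
  cat(sprintf("  turnover: kE = %g, kW = %g, kR = %g /s; K_M (E,W,R) = %g, %g, %g mM\n",
              x$kE, x$kW, x$kR, x$K_ME, x$K_MW, x$K_MR))
  cat(sprintf("  protein sizes (aa): BP %g, T %g, E %g, M %g, R %g\n",
              x$n_BP, x$n_T, x$n_E, x$n_M, x$n_R))
  cat(sprintf("  geometry: a_w = %g, a_T = %g um^2; f_SA = %g; r in [%g, %g] um\n",
              x$a_w, x$a_T, x$f_SA, x$r_min, x$r_max))
  cat(sprintf("  density caps: cyto %g, peri %g mM*Da; phi_O = %g + %g\n",
              x$rho_cyto, x$rho_peri, x$phi_O_cyto, x$phi_O_peri))
  invisible(x)
}

## keys written to / read from parameter files, in file order
.param_file_keys <- function() {
  c("k1", "k2", "k0f", "k0r", "k1p", "k2p", "k3p",
    "D", "kE", "K_ME", "kW", "K_MW", "kR", "K_MR",
    "n_BP", "n_T", "n_E", "n_M", "n_R",
    "a_w", "a_T", "f_SA", "rho_cyto", "rho_peri",
    "m_S", "m_A", "m_aa", "m_W",
    "phi_O_cyto", "phi_O_peri", "r_min", "r_max", "S_ext")
}

#' Read or write a flat key = value parameter file
#'
#' The file format is plain text, one `key = value` pair per line;
#' `#` starts a comment; keys match the arguments of [transport_params()]
#' and [cell_params()]. Unknown keys are an error, missing keys fall back
#' to the package baseline. The shipped baseline file is at
#' `system.file("extdata", "baseline.params", package = "trophos")`.
#'
#' @param path file path.
#' @param base a [cell_params()] object supplying defaults for keys not
#'   present in the file.
#' @return [read_params()] returns a [cell_params()] object;
#'   [write_params()] returns `path` invisibly.
#' @export
#' @examples
#' f <- system.file("extdata", "baseline.params", package = "trophos")
#' cp <- read_params(f)
read_params <- function(path, base = cell_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line(s): ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  logical_keys <- c("density_includes_membrane", "strict_volume_basis")
  known <- c(.param_file_keys(), logical_keys)
  if (any(!keys %in% known))
    stop("unknown parameter key(s): ", paste(setdiff(keys, known), collapse = ", "))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated key(s): ",
                                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  given <- setNames(as.list(vals), keys)
  tkeys <- c("k1", "k2", "k0f", "k0r", "k1p", "k2p", "k3p")
  targs <- as.list(unclass(base$transport))
  for (k in intersect(keys, tkeys)) targs[[k]] <- given[[k]]
  cargs <- unclass(base)
  cargs$transport <- do.call(transport_params, targs)
  for (k in setdiff(keys, tkeys)) {
    cargs[[k]] <- if (k %in% logical_keys) given[[k]] > 0 else given[[k]]
  }
  do.call(cell_params, cargs)
}

#' @rdname read_params
#' @param cp a [cell_params()] object to serialise.
#' @export
write_params <- function(cp, path) {
  stopifnot(inherits(cp, "cell_params"))
  flat <- c(unclass(cp$transport),
            unclass(cp)[setdiff(.param_file_keys(),
                                c("k1", "k2", "k0f", "k0r", "k1p", "k2p", "k3p"))])
  hdr <- c("# trophos cell-model parameters",
           "# units: concentrations mM, time s, length um, mass Da",
           sprintf("# derived: K_T = %.6g mM, K_D = %.6g mM, K_Tp = %.6g mM",
                   K_T(cp$transport), K_D(cp$transport), K_Tp(cp$transport)))
  body <- sprintf("%s = %.15g", names(flat), unlist(flat))
  body <- c(body,
            sprintf("density_includes_membrane = %d", cp$density_includes_membrane),
            sprintf("strict_volume_basis = %d", cp$strict_volume_basis))
  writeLines(c(hdr, body), path)
  invisible(path)
}
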