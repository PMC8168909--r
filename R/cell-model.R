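## Whole-cell self-replicator model: decision variables, geometry,
## metabolite balances, proteome bookkeeping and constraint
## residuals/margins of the growth-maximisation problem.

#' Decision variables of the allocation problem
#'
#' The optimisation vector: intracellular metabolite pools
#' `x_m = (S_p, S_c, A, W, P)`, the proteome fractions
#' `phi = (phi_BP, phi_T, phi_E, phi_M, phi_R)`, cell radius `r`,
#' periplasmic volume fraction `f_p`, and the steady-state exponential
#' growth rate `mu`. Concentration bases: `S_p` per periplasmic volume;
#' `S_c`, `A`, `W`, `P` per cytoplasmic volume (`P` counts amino acids
#' incorporated into protein).
#'
#' For PTS cells `phi_BP` is structurally zero.
#'
#' @param S_p,S_c,A,W,P metabolite pools (mM).
#' @param phi named numeric vector of proteome fractions, names
#'   `c("BP","T","E","M","R")`, each nonnegative.
#' @param r cell radius (um).
#' @param f_p periplasmic volume fraction, in (0, 1).
#' @param mu growth rate (/s), nonnegative.
#' @return An object of class `"decision_vars"`.
#' @export
decision_vars <- function(S_p, S_c, A, W, P, phi, r, f_p, mu) {
  if (!all(c("BP", "T", "E", "M", "R") %in% names(phi)))
    stop("phi must be named with BP, T, E, M, R")
  phi <- phi[c("BP", "T", "E", "M", "R")]
  if (any(phi < 0)) stop("proteome fractions must be nonnegative")
  if (any(c(S_p, S_c, A, W, P) < 0)) stop("metabolite pools must be nonnegative")
  if (f_p <= 0 || f_p >= 1) stop("f_p must lie strictly inside (0, 1)")
  if (r <= 0) stop("r must be positive")
  if (mu < 0) stop("mu must be nonnegative")
  structure(list(S_p = S_p, S_c = S_c, A = A, W = W, P = P,
                 phi = phi, r = r, f_p = f_p, mu = mu),
            class = "decision_vars")
}

#' @export
print.decision_vars <- function(x, ...) {
  cat("Decision variables\n")
  cat(sprintf("  pools (mM): S_p = %.4g, S_c = %.4g, A = %.4g, W = %.4g, P = %.4g\n",
              x$S_p, x$S_c, x$A, x$W, x$P))
  cat("  phi:", paste(sprintf("%s = %.4g", names(x$phi), x$phi), collapse = ", "), "\n")
  cat(sprintf("  r = %.4g um, f_p = %.4g, mu = %.4g /s\n", x$r, x$f_p, x$mu))
  invisible(x)
}

#' Diffusive supply of substrate to the periplasm
#'
#' Diffusion-limited (not porin-limited) exchange across the outer
#' boundary layer, expressed as change in periplasmic concentration:
#' `v_diff = 3 D (S_ext - S_p) / (f_p r^2)`. The sign follows the
#' concentration difference.
#'
#' @param S_ext,S_p external and periplasmic substrate concentrations (mM).
#' @param f_p periplasmic volume fraction.
#' @param r cell radius (um).
#' @param D diffusivity (um^2/s).
#' @return Supply rate (mM/s, periplasmic basis).
#' @export
#' @examples
#' diffusive_uptake(1e-6, 0, f_p = 0.2, r = 0.1, D = 100)  # 0.15 mM/s
diffusive_uptake <- function(S_ext, S_p, f_p, r, D) {
  if (r <= 0) stop("r must be positive")
  if (f_p <= 0 || f_p >= 1) stop("f_p must lie strictly inside (0, 1)")
  3 * D * (S_ext - S_p) / (f_p * r^2)
}

#' Convert a periplasmic-basis rate to the cytoplasmic basis
#'
#' Multiplies by the volume ratio `f_p / (1 - f_p)`: a change of 1 mM/s
#' in the periplasm corresponds to `f_p/(1-f_p)` mM/s of cytoplasmic
#' concentration change.
#'
#' @param rate_peri rate on the periplasmic-concentration basis (mM/s).
#' @param f_p periplasmic volume fraction in (0, 1).
#' @return Rate on the cytoplasmic-concentration basis (mM/s).
#' @export
periplasm_to_cytoplasm <- function(rate_peri, f_p) {
  if (any(f_p <= 0) || any(f_p >= 1)) stop("f_p must lie strictly inside (0, 1)")
  rate_peri * f_p / (1 - f_p)
}

#' Protein pools implied by an allocation
#'
#' Enzyme copy concentrations `[X] = phi_X P / n_X` on the cytoplasmic
#' basis, plus the transport pools converted to the periplasmic basis
#' (`T_total` and, for ABC cells, `BP_total` are abundances divided by
#' the periplasmic volume, hence the factor `(1 - f_p)/f_p`).
#'
#' @param x a [decision_vars()] object.
#' @param cp a [cell_params()] object.
#' @return Named list: `E`, `M`, `R`, `T_cyto`, `BP_cyto` (mM, cytoplasmic
#'   basis) and `T_total`, `BP_total` (mM, periplasmic basis).
#' @export
protein_pools <- function(x, cp) {
  conv <- x$f_p / (1 - x$f_p)
  list(E = x$phi[["E"]] * x$P / cp$n_E,
       M = x$phi[["M"]] * x$P / cp$n_M,
       R = x$phi[["R"]] * x$P / cp$n_R,
       T_cyto = x$phi[["T"]] * x$P / cp$n_T,
       BP_cyto = x$phi[["BP"]] * x$P / cp$n_BP,
       T_total = x$phi[["T"]] * x$P / cp$n_T / conv,
       BP_total = x$phi[["BP"]] * x$P / cp$n_BP / conv)
}

#' Michaelis-Menten reaction rates of the cell model
#'
#' The five reaction rates: diffusive supply, cytoplasmic uptake (PTS
#' from the two-step scheme or ABC from the exact four-step steady
#' state), catabolism (`v_E = kE [E] S_c/(K_ME + S_c)`), membrane
#' synthesis (`v_W = kW [M] A/(K_MW + A)`) and protein synthesis
#' (`v_R = kR [R] A/(K_MR + A)`). `v_diff` and `v_c` are on the
#' periplasmic basis, the rest on the cytoplasmic basis.
#'
#' @param x a [decision_vars()] object.
#' @param cp a [cell_params()] object.
#' @param transport `"pts"` or `"abc"`.
#' @return Named list of rates `v_diff`, `v_c`, `v_E`, `v_W`, `v_R`
#'   (mM/s).
#' @export
reaction_rates <- function(x, cp, transport = c("pts", "abc")) {
  transport <- match.arg(transport)
  if (any(c(x$S_p, x$S_c, x$A, x$P) < 0)) stop("negative concentrations")
  pools <- protein_pools(x, cp)
  v_c <- if (transport == "pts") {
    pts_uptake(x$S_p, pools$T_total, cp$transport)
  } else {
    abc_steady_state(x$S_p, pools$BP_total, pools$T_total, cp$transport)$v_c
  }
  list(v_diff = diffusive_uptake(cp$S_ext, x$S_p, x$f_p, x$r, cp$D),
       v_c = v_c,
       v_E = cp$kE * pools$E * x$S_c / (cp$K_ME + x$S_c),
       v_W = cp$kW * pools$M * x$A / (cp$K_MW + x$A),
       v_R = cp$kR * pools$R * x$A / (cp$K_MR + x$A))
}

#' Stoichiometry matrix of the cell model
#'
#' Rows are the five metabolite pools `(S_p, S_c, A, W, P)`, columns the
#' reaction rates `(v_diff, v_c, v_E, v_W, v_R)`. Diffusion feeds the
#' periplasmic substrate; uptake drains it (periplasmic basis) and feeds
#' the cytoplasmic substrate (converted by the periplasm-to-cytoplasm
#' volume ratio, which therefore appears in the matrix); catabolism turns
#' 5 substrate into 6 amino-acid precursors per reaction event; membrane
#' and protein synthesis each drain one precursor per unit made.
#'
#' @param f_p periplasmic volume fraction.
#' @return A 5 x 5 matrix.
#' @export
stoichiometry <- function(f_p) {
  conv <- f_p / (1 - f_p)
  N <- rbind(S_p = c(1, -1,    0,  0,  0),
             S_c = c(0, conv, -5,  0,  0),
             A   = c(0,  0,    6, -1, -1),
             W   = c(0,  0,    0,  1,  0),
             P   = c(0,  0,    0,  0,  1))
  colnames(N) <- c("v_diff", "v_c", "v_E", "v_W", "v_R")
  N
}

#' Steady-state growth balance residuals
#'
#' `N v_r - mu x_m` for the five metabolite pools: the equality-constraint
#' surface of balanced exponential growth. All five vanish at a steady
#' state.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector of length 5 (mM/s).
#' @export
growth_balance_residuals <- function(x, cp, transport = c("pts", "abc")) {
  transport <- match.arg(transport)
  v <- reaction_rates(x, cp, transport)
  vr <- c(v$v_diff, v$v_c, v$v_E, v$v_W, v$v_R)
  xm <- c(x$S_p, x$S_c, x$A, x$W, x$P)
  drop(stoichiometry(x$f_p) %*% vr) - x$mu * xm
}

#' Membrane coverage residual
#'
#' Requires the membrane-unit pool to cover both the outer sphere and the
#' inner (cytoplasmic) sphere:
#' `4 pi (1 + (1 - f_p)^(2/3)) r^2 = [W] V a_w`, with `V` the total cell
#' volume `4 pi r^3 / 3` as printed in the model (or the cytoplasmic
#' volume if `strict_volume_basis`). Returns required-minus-provided area
#' (um^2); zero at feasible points.
#'
#' @inheritParams reaction_rates
#' @return Scalar residual (um^2).
#' @export
membrane_coverage_residual <- function(x, cp) {
  vol <- 4 * pi * x$r^3 / 3
  if (cp$strict_volume_basis) vol <- vol * (1 - x$f_p)
  need <- 4 * pi * (1 + (1 - x$f_p)^(2 / 3)) * x$r^2
  have <- x$W * .MOLEC_PER_UM3_PER_MM * vol * cp$a_w
  need - have
}

#' Density margins of cytoplasm and periplasm
#'
#' Molecular crowding limits: `rho_cyto - sum(m_j x_j)` over the
#' cytoplasmic pools (substrate, free amino acids, protein; membrane
#' units optionally via `density_includes_membrane`) and
#' `rho_peri - (m_S S_p + binding-protein mass)` over the periplasmic
#' pools, with the binding-protein species mass taken from the proteome
#' allocation converted to the periplasmic basis. Positive margins are
#' feasible; a zero margin means the constraint is active.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector `c(cyto, peri)` (mM x Da).
#' @export
density_margins <- function(x, cp) {
  cyto_mass <- cp$m_S * x$S_c + cp$m_A * x$A + cp$m_aa * x$P
  if (cp$density_includes_membrane) cyto_mass <- cyto_mass + cp$m_W * x$W
  conv <- x$f_p / (1 - x$f_p)
  bp_mass_peri <- cp$m_aa * x$phi[["BP"]] * x$P / conv
  c(cyto = cp$rho_cyto - cyto_mass,
    peri = cp$rho_peri - (cp$m_S * x$S_p + bp_mass_peri))
}

#' Inner-membrane real-estate margin
#'
#' Membrane-bound transport units must fit in the fraction `f_SA` of the
#' inner-membrane surface:
#' `f_SA 4 pi (1 - f_p)^(2/3) r^2 - [T] V a_T`, with `V` the total cell
#' volume as printed (or cytoplasmic volume under
#' `strict_volume_basis`). Positive margin feasible, zero active.
#'
#' @inheritParams reaction_rates
#' @return Scalar margin (um^2).
#' @export
real_estate_margin <- function(x, cp) {
  vol <- 4 * pi * x$r^3 / 3
  if (cp$strict_volume_basis) vol <- vol * (1 - x$f_p)
  T_cyto <- x$phi[["T"]] * x$P / cp$n_T
  cp$f_SA * 4 * pi * (1 - x$f_p)^(2 / 3) * x$r^2 -
    T_cyto * .MOLEC_PER_UM3_PER_MM * vol * cp$a_T
}

#' Proteome closure residual
#'
#' `phi_BP + phi_T + phi_E + phi_M + phi_R + phi_O_cyto + phi_O_peri - 1`;
#' zero when the proteome fractions close.
#'
#' @inheritParams reaction_rates
#' @return Scalar residual.
#' @export
proteome_closure_residual <- function(x, cp) {
  sum(x$phi) + cp$phi_O_cyto + cp$phi_O_peri - 1
}
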