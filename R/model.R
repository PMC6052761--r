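# ---------------------------------------------------------------------------
# The multispecies desmoplastic tumor model: parameters, pointwise algebra,
# boundary conditions, and the Crank-Nicolson right-hand sides.
#
# Volume fractions phi_V (viable tumor), phi_D (dead tumor), phi_E (ECM)
# evolve by Cahn-Hilliard-type advection-diffusion with chemical potentials
# mu_T, mu_E; healthy host cells close the mixture, phi_H = 1 - phi_V -
# phi_D - phi_E.  Nutrients/waste and tumorigenic factors are quasi-steady
# reaction-diffusion species; myofibroblasts (F_E) and vessel densities
# (B_nE, L_nE) are transient, advected by the ECM velocity with
# chemo-/haptotactic fluxes.
# ---------------------------------------------------------------------------

#' Smooth interpolation function Q3
#'
#' `Q3(x) = x^2 (3 - 2x)` on the clamped argument, so `Q3(0) = 0`,
#' `Q3(1) = 1` with vanishing slope at both ends.  Used to blend
#' phase-specific coefficients.
#'
#' @param x numeric (array ok).
#' @return numeric of the same shape.
#' @export
q3_smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Model parameters with documented defaults
#'
#' Constants printed in the model description (mitosis/necrosis/lysis rates,
#' viability thresholds, far-field vessel densities, ECM secretion and
#' degradation rates) carry their published values.  Constants that live
#' only in the (unavailable) supplementary tables -- bulk-energy constants,
#' interface coefficients, diffusivity/uptake triples, vessel kinetics,
#' Lame/eigenstrain values -- are order-one placeholder defaults chosen so
#' the uniform host tissue (phi_E = 0.35, no tumor) is a bulk equilibrium
#' and the healthy domain stays normoxic while a growing tumor develops
#' hypoxia; every placeholder is tagged in the shipped reference
#' configuration.
#'
#' @param ... replace any default by name.
#' @return a `tmg_model_params` list.
#' @export
model_params <- function(...) {
  p <- list(
    # bulk free energy (ternary well); A3 = A5 = preferred ECM fraction
    A1 = 1, A2 = 0.5, A3 = 0.35, A4 = 0.5, A5 = 0.35,
    # interface coefficients: the diffuse interface spans a few length
    # units so it stays resolved on every grid of the shipped convergence
    # protocol; cross-adhesion at half the self-adhesion strength
    eps_T = 2, eps_E = 2, eps_TE = 0.5, eps_e = 0,
    # mobilities and Darcy coefficients
    Mbar = 1, k_alpha = 1, k_beta = 1, R_alpha_beta = 1,
    gamma_T = 1, gamma_E = 1,
    # Lame constants and (isotropic) eigenstrain magnitudes
    L1E = 2, L2E = 1, L1C = 1, L2C = 0.5, estar_E = 0.05, estar_C = 0,
    # diffusivity triples (psi_E, psi_T, psi_H) for the effective blend;
    # oxygen/glucose penetration depths are a fraction of the seed radius
    # so the tumor center turns hypoxic and necroses
    D_n = c(12, 12, 15), D_g = c(8, 8, 10), D_w = c(30, 35, 40),
    D_l = c(20, 20, 25), D_b = c(20, 20, 25), D_a = c(25, 25, 30),
    D_s = c(20, 20, 25), D_r = c(20, 20, 25),
    D_tgf = c(8, 8, 10), D_taf = c(8, 8, 10), D_m = c(5, 5, 5),
    D_F = 0.5, D_BnE = 0.1, D_LnE = 0.1,
    # vascular transfer / uptake rate triples
    k_n1 = c(1, 1, 1), k_n2 = c(0.5, 5, 0.05),
    k_g1 = c(1, 1, 1), k_g2 = c(0.2, 2, 0.02),
    k_w = c(1, 1, 1), k_l = c(1, 1, 1),
    k_f = 1, k_r = 1, R_g_n = 1,
    # ion charges (lactate, bicarbonate, H+, Na+, Cl-)
    z_l = -1, z_b = -1, z_a = 1, z_s = 1, z_r = -1,
    # tumorigenic factors: production (by phi_V) and decay/uptake rates
    lambda_tgf = 1, lambda_de_tgf = 0.5, lambda_U_tgf = 0.5,
    lambda_taf = 1, lambda_de_taf = 0.5, lambda_U_taf = 0.5,
    # matrix degrading enzymes and myofibroblasts
    lambda_prod_m = 1, lambda_de_m = 1,
    lambda_M_F = 0.5, lambda_A_F = 0.1,
    # vessels: sprouting and pressure-crushing kinetics
    lambda_sp_B = 0.5, lambda_cr_B = 0.25, lambda_sp_L = 0.5,
    lambda_cr_L = 0.25, p_crush = 0.5,
    chi_che_BnE = 0.2, chi_hap_BnE = 0.2, A_che_BnE = 1, A_hap_BnE = 1,
    chi_che_LnE = 0.2, chi_hap_LnE = 0.2, A_che_LnE = 1, A_hap_LnE = 1,
    # printed source-term constants and thresholds
    lambda_M_V = 1, lambda_N_V = 3, lambda_L_D = 1,
    lambda_F_E = 5, lambda_de_E = 5, F_n_EF = 2,
    n_h = 0.3, n_v_V = 0.21, g_v_V = 0.1, n_v_F = 0.21, tgf_F_E = 0.2,
    # far-field vessel densities and supply normalization
    B_inf = 0.2, L_inf = 0.2,
    # initial condition
    phi_V_seed = 0.65, phi_E0 = 0.35, seed_side = 10, F_E0 = 0.1,
    # vessel-supply reference: n_C = B_nE*phi_E / supply_ref so the
    # far-field vasculature delivers unit concentration
    supply_ref = 0.2 * 0.35,
    # regional sprouting fractions by domain octant
    sprout_fractions = seq(0.1, 0.8, by = 0.1),
    Q3 = q3_smoothstep)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown model parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  structure(p, class = "tmg_model_params")
}

#' Bulk free energy derivatives
#'
#' Pointwise derivatives of the ternary bulk free energy with respect to the
#' total tumor fraction and the ECM fraction:
#' \deqn{\partial F_b/\partial\phi_T = 2A_1\phi_T(1-\phi_T-\phi_E)
#'   (1-2\phi_T-\phi_E) + (A_5-A_3)(2\phi_E-A_5-A_3)}
#' \deqn{\partial F_b/\partial\phi_E = 2(\phi_T+A_2)(\phi_E-A_3)
#'   - 2A_1\phi_T^2(1-\phi_T-\phi_E)
#'   + (\phi_E-A_5)[2(1-\phi_T+A_4)-3\phi_E+A_5]}
#'
#' @param phi_T,phi_E numeric arrays.
#' @param params a [model_params()] list.
#' @return list with `dT` and `dE`.
#' @export
bulk_energy_derivatives <- function(phi_T, phi_E, params) {
  u <- 1 - phi_T - phi_E
  v <- 1 - 2 * phi_T - phi_E
  dT <- 2 * params$A1 * phi_T * u * v +
    (params$A5 - params$A3) * (2 * phi_E - params$A5 - params$A3)
  dE <- 2 * (phi_T + params$A2) * (phi_E - params$A3) -
    2 * params$A1 * phi_T^2 * u +
    (phi_E - params$A5) * (2 * (1 - phi_T + params$A4) - 3 * phi_E +
                             params$A5)
  list(dT = dT, dE = dE)
}

#' Effective phase-blended coefficient
#'
#' Blends a diffusivity or mass-transfer coefficient across the ECM, tumor,
#' and healthy-host phases:
#' \deqn{\psi = \psi_E Q_3(\phi_E) + [1-Q_3(\phi_E)]\{\psi_T
#'   Q_3(\phi_T/\phi_C) + \psi_H[1-Q_3(\phi_T/\phi_C)]\}}
#' with total cell fraction \eqn{\phi_C = \phi_T + \phi_H = 1 - \phi_E};
#' where \eqn{\phi_C = 0} the cell blend degenerates to \eqn{\psi_H}.
#'
#' @param phi_T,phi_E numeric arrays.
#' @param psi_E,psi_T,psi_H phase coefficients.
#' @param params a [model_params()] (provides `Q3`).
#' @return numeric array.
#' @export
effective_coefficient <- function(phi_T, phi_E, psi_E, psi_T, psi_H,
                                  params) {
  Q3 <- params$Q3
  phi_C <- 1 - phi_E
  ratio <- ifelse(phi_C > 1e-12, phi_T / phi_C, 0)
  qe <- Q3(phi_E); qt <- Q3(ratio)
  psi_E * qe + (1 - qe) * (psi_T * qt + psi_H * (1 - qt))
}

eff3 <- function(phi_T, phi_E, triple, params) {
  effective_coefficient(phi_T, phi_E, triple[1], triple[2], triple[3],
                        params)
}

#' Heaviside step with H(0) = 1
#' @param x numeric.
#' @return numeric 0/1 of the same shape.
#' @export
heaviside <- function(x) as.numeric(x >= 0)

#' Source terms of the phase fields and tissue species
#'
#' Pointwise evaluation of the viable-tumor, dead-tumor and ECM sources
#' (mitosis gated by hypoxia and upregulated by growth factors, necrosis
#' below the viability limits, lysis, ECM secretion by myofibroblasts with
#' the hypoxia-adjusted factor, ECM degradation by matrix-degrading
#' enzymes), plus the placeholder-parameterized sources of m, F_E and the
#' vessel densities.
#'
#' @param fl named list of numeric arrays: `phi_V`, `phi_D`, `phi_E`, `n`,
#'   `g`, `tgf`, `taf`, `m`, `F_E`, `B_nE`, `L_nE`, `p`, and `sprout`
#'   (regional sprouting fraction).
#' @param params a [model_params()].
#' @return named list of source arrays `S_V`, `S_D`, `S_E`, `S_m`, `S_FE`,
#'   `S_BnE`, `S_LnE`.
#' @export
source_terms <- function(fl, params) {
  P <- params
  H <- heaviside
  phi_T <- fl$phi_V + fl$phi_D
  necro <- 1 - H(fl$n - P$n_v_V) * H(fl$g - P$g_v_V)
  S_V <- (P$lambda_M_V * fl$n * (1 + fl$tgf) * H(fl$n - P$n_h) -
            P$lambda_N_V * necro) * fl$phi_V
  S_D <- P$lambda_N_V * necro * fl$phi_V - P$lambda_L_D * fl$phi_D
  room <- 1 - phi_T - fl$phi_E
  A_FE <- room * (1 + fl$tgf) *
    (1 + P$F_n_EF * (P$n_h - fl$n) / (P$n_h - P$n_v_F) * H(P$n_h - fl$n)) *
    H(fl$n - P$n_v_F) * H(fl$tgf - P$tgf_F_E) * H(room)
  Ftis <- fl$F_E * fl$phi_E
  S_E <- P$lambda_F_E * A_FE * Ftis - P$lambda_de_E * fl$m * fl$phi_E
  S_m <- P$lambda_prod_m * fl$phi_V * (1 + fl$tgf) - P$lambda_de_m * fl$m
  S_FE <- P$lambda_M_F * fl$F_E * (1 + fl$tgf) * H(fl$n - P$n_v_F) *
    (1 - fl$F_E) - P$lambda_A_F * fl$F_E
  crush_B <- P$lambda_cr_B * H(fl$p - P$p_crush) * fl$B_nE
  crush_L <- P$lambda_cr_L * H(fl$p - P$p_crush) * fl$L_nE
  S_BnE <- P$lambda_sp_B * fl$sprout * fl$taf * fl$B_nE *
    pmax(1 - fl$B_nE, 0) - crush_B
  S_LnE <- P$lambda_sp_L * fl$sprout * fl$taf * fl$L_nE *
    pmax(1 - fl$L_nE, 0) - crush_L
  list(S_V = S_V, S_D = S_D, S_E = S_E, S_m = S_m, S_FE = S_FE,
       S_BnE = S_BnE, S_LnE = S_LnE)
}

#' Default boundary conditions of the tumor model
#'
#' Zero-Neumann for the phase fields and myofibroblasts; homogeneous
#' Dirichlet for the pressures, chemical potentials, waste products, ions,
#' growth/angiogenic factors and enzymes; Dirichlet 1 for oxygen and
#' glucose; Dirichlet at the far-field densities for the vessels.
#'
#' @param params a [model_params()].
#' @return named list of [bc()] descriptors (covers previous-time copies
#'   and auxiliary fields as well).
#' @export
default_bcs <- function(params) {
  bcs <- list(
    phi_V = bc("neumann"), phi_D = bc("neumann"), phi_E = bc("neumann"),
    F_E = bc("neumann"),
    p = bc("dirichlet", 0), q = bc("dirichlet", 0),
    mu_T = bc("dirichlet", 0), mu_E = bc("dirichlet", 0),
    n = bc("dirichlet", 1), g = bc("dirichlet", 1),
    w = bc("dirichlet", 0), l = bc("dirichlet", 0), b = bc("dirichlet", 0),
    a = bc("dirichlet", 0), s = bc("dirichlet", 0), r = bc("dirichlet", 0),
    tgf = bc("dirichlet", 0), taf = bc("dirichlet", 0),
    m = bc("dirichlet", 0),
    B_nE = bc("dirichlet", params$B_inf),
    L_nE = bc("dirichlet", params$L_inf))
  for (f in c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E"))
    bcs[[paste0(f, "_prev")]] <- bcs[[f]]
  bcs
}

# Neumann bc for any field not covered explicitly (coefficients, RHS, ...)
bcs_with_default <- function(bcs, fields) {
  for (f in fields) if (is.null(bcs[[f]])) bcs[[f]] <- bc("neumann")
  bcs
}

# ---------------------------------------------------------------------------
# Finite-difference helpers on ghost-padded arrays.
# ---------------------------------------------------------------------------

# 7-point Laplacian; returns a padded array with valid interior
lap3 <- function(a, eta) {
  d <- dim(a)
  i <- 2:(d[1] - 1L); j <- 2:(d[2] - 1L); k <- 2:(d[3] - 1L)
  out <- array(0, d)
  out[i, j, k] <-
    (a[i + 1L, j, k] + a[i - 1L, j, k] + a[i, j + 1L, k] +
       a[i, j - 1L, k] + a[i, j, k + 1L] + a[i, j, k - 1L] -
       6 * a[i, j, k]) / eta^2
  out
}

# face-centered difference along axis ax: (a[i+1] - a[i]) / eta over all
# faces of the interior (dims n+1 along ax, n on the others)
face_grad <- function(a, eta, ax) {
  d <- dim(a)
  idx <- list(2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L))
  lo <- idx; lo[[ax]] <- 1:(d[ax] - 1L)
  hi <- idx; hi[[ax]] <- 2:d[ax]
  (a[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] -
     a[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]) / eta
}

# face-centered average along axis ax (same shape as face_grad)
face_avg <- function(a, ax) {
  d <- dim(a)
  idx <- list(2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L))
  lo <- idx; lo[[ax]] <- 1:(d[ax] - 1L)
  hi <- idx; hi[[ax]] <- 2:d[ax]
  0.5 * (a[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] +
           a[lo[[1]], lo[[2]], lo[[3]], drop = FALSE])
}

# divergence of face fluxes (fx: (n+1, n, n) etc.); interior-sized result
div_face <- function(fx, fy, fz, eta) {
  dx <- dim(fx)
  nx <- dx[1] - 1L; ny <- dx[2]; nz <- dx[3]
  (fx[2:(nx + 1L), , , drop = FALSE] - fx[1:nx, , , drop = FALSE] +
     fy[, 2:(ny + 1L), , drop = FALSE] - fy[, 1:ny, , drop = FALSE] +
     fz[, , 2:(nz + 1L), drop = FALSE] - fz[, , 1:nz, drop = FALSE]) / eta
}

# first-order upwind face value of a cell quantity given face velocities
upwind_face <- function(a, u_face, ax) {
  d <- dim(a)
  idx <- list(2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L))
  lo <- idx; lo[[ax]] <- 1:(d[ax] - 1L)
  hi <- idx; hi[[ax]] <- 2:d[ax]
  al <- a[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
  ah <- a[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
  ifelse(u_face >= 0, al, ah)
}

# upwind divergence of (a * u) from face velocities; interior-sized result
upwind_div <- function(a, ux, uy, uz, eta) {
  div_face(ux * upwind_face(a, ux, 1L),
           uy * upwind_face(a, uy, 2L),
           uz * upwind_face(a, uz, 3L), eta)
}

# ---------------------------------------------------------------------------
# Chemical potentials and Crank-Nicolson right-hand sides.
# ---------------------------------------------------------------------------

#' Evaluate the chemical potentials from the phase fields
#'
#' `mu_T = dFb/dphi_T - eps_T^2 lap(phi_T) - eps_TE^2 lap(phi_E)` and
#' `mu_E = dFb/dphi_E + dW/dphi_E - eps_E^2 lap(phi_E) - eps_TE^2
#' lap(phi_T)` with 7-point Laplacians, written into the `mu_T`/`mu_E`
#' fields of every block of the level.  Used for consistent initialization;
#' within a time step the potentials are unknowns of the implicit system.
#'
#' @param h hierarchy with valid `phi_*` ghosts on the level.
#' @param kappa level index.
#' @param params a [model_params()].
#' @return the updated hierarchy.
#' @export
chemical_potentials <- function(h, kappa, params) {
  lv <- get_level(h, kappa)
  for (ib in seq_along(lv$blocks)) {
    b <- lv$blocks[[ib]]
    phi_T <- b$data$phi_V + b$data$phi_D
    phi_E <- b$data$phi_E
    fb <- bulk_energy_derivatives(phi_T, phi_E, params)
    lT <- lap3(phi_T, lv$eta); lE <- lap3(phi_E, lv$eta)
    dW <- elastic_dW_block(b, params, lv$eta)
    lv$blocks[[ib]]$data$mu_T <-
      fb$dT - params$eps_T^2 * lT - params$eps_TE^2 * lE
    lv$blocks[[ib]]$data$mu_E <-
      fb$dE + dW - params$eps_E^2 * lE - params$eps_TE^2 * lT
  }
  set_level(h, kappa, lv)
}

#' Build the Crank-Nicolson system for the phase fields
#'
#' Sets the base right-hand sides of the coupled implicit block from the
#' previous-time fields stored in `*_prev`: for each phase,
#' `R = phi_prev + theta * (1/2 div(M grad mu)_prev - div(phi u_alpha)_prev
#' + S_prev)`, and for the potential equations the explicitly treated
#' surface-adhesion cross terms `R = -eps_TE^2 lap(phi_prev)` (plus the
#' explicit elastic derivative for `mu_E`).  The advective terms use
#' first-order upwinding on the stored face velocities; treating the cross
#' terms and advection at the old time level makes the overall scheme
#' first-order accurate in time.
#'
#' @param h hierarchy with `*_prev` fields, face velocities (`u_alpha_*`)
#'   and source fields (`S_V`, `S_D`, `S_E`) present on every level.
#' @param params a [model_params()].
#' @param theta time step.
#' @return list with the updated hierarchy (`h`, RHS fields `R0_*`/`R_*`
#'   set) and the `tmg_system` (`sys`).
#' @export
crank_nicolson_system <- function(h, params, theta) {
  sys <- ch_system(params, theta)
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    h <- build_ch_rhs_level(h, kappa, params, theta)
  }
  list(h = h, sys = sys)
}

# assemble the CH right-hand sides on one level (from *_prev data)
build_ch_rhs_level <- function(h, kappa, params, theta) {
  lv <- get_level(h, kappa)
  eta <- lv$eta
  for (ib in seq_along(lv$blocks)) {
    b <- lv$blocks[[ib]]
    pV <- b$data$phi_V_prev; pD <- b$data$phi_D_prev
    pE <- b$data$phi_E_prev
    mT <- b$data$mu_T_prev; mE <- b$data$mu_E_prev
    d <- dim(pV)
    ux <- b$face_data$u_alpha_x; uy <- b$face_data$u_alpha_y
    uz <- b$face_data$u_alpha_z
    if (is.null(ux)) {
      ux <- array(0, c(d[1] - 1L, d[2] - 2L, d[3] - 2L))
      uy <- array(0, c(d[1] - 2L, d[2] - 1L, d[3] - 2L))
      uz <- array(0, c(d[1] - 2L, d[2] - 2L, d[3] - 1L))
    }
    mob <- function(phi) params$Mbar * pmax(phi, 0)
    fick <- function(phi, mu) {
      div_face(face_avg(mob(phi), 1L) * face_grad(mu, eta, 1L),
               face_avg(mob(phi), 2L) * face_grad(mu, eta, 2L),
               face_avg(mob(phi), 3L) * face_grad(mu, eta, 3L), eta)
    }
    zero <- array(0, d)
    Svi <- if (!is.null(b$data$S_V)) interior(b$data$S_V) else 0
    Sdi <- if (!is.null(b$data$S_D)) interior(b$data$S_D) else 0
    Sei <- if (!is.null(b$data$S_E)) interior(b$data$S_E) else 0
    R1 <- zero
    interior(R1) <- interior(pV) +
      theta * (0.5 * fick(pV, mT) - upwind_div(pV, ux, uy, uz, eta) + Svi)
    R2 <- zero
    interior(R2) <- interior(pD) +
      theta * (0.5 * fick(pD, mT) - upwind_div(pD, ux, uy, uz, eta) + Sdi)
    R3 <- zero
    interior(R3) <- interior(pE) +
      theta * (0.5 * fick(pE, mE) - upwind_div(pE, ux, uy, uz, eta) + Sei)
    R4 <- -params$eps_TE^2 * lap3(pE, eta)
    dW <- elastic_dW_block(b, params, eta, prev = TRUE)
    R5 <- -params$eps_TE^2 * lap3(pV + pD, eta) + dW
    for (u in c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E")) {
      arr <- switch(u, phi_V = R1, phi_D = R2, phi_E = R3, mu_T = R4,
                    mu_E = R5)
      lv$blocks[[ib]]$data[[paste0("R0_", u)]] <- arr
      lv$blocks[[ib]]$data[[paste0("R_", u)]] <- arr
    }
  }
  set_level(h, kappa, lv)
}
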