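# ---------------------------------------------------------------------------
# Quasi-steady species, pressures/velocities, and transient tissue species.
#
# All of these reuse the multigrid machinery through scalar Helmholtz
# systems  a(x)*c - div(D(x) grad c) = f;  nonlinearity (ion drift, the
# bicarbonate buffer reaction) is handled by lagged Picard iteration.
# ---------------------------------------------------------------------------

# species solved per profile
profile_species <- function(profile) {
  if (profile == "lite") c("n", "g", "tgf", "taf")
  else c("n", "g", "tgf", "taf", "w", "l", "b", "a", "s")
}

profile_fields <- function(profile) {
  base <- c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E",
            "phi_V_prev", "phi_D_prev", "phi_E_prev", "mu_T_prev",
            "mu_E_prev",
            "p", "n", "g", "tgf", "taf", "m", "F_E", "B_nE", "L_nE")
  if (profile == "full")
    base <- c(base, "q", "w", "l", "b", "a", "s", "r", "u_1", "u_2", "u_3")
  base
}

# ---------------------------------------------------------------------------
# Coefficient fields (computed pointwise from phi, so ghost values come for
# free from the phi ghosts).
# ---------------------------------------------------------------------------

# effective diffusivities, reaction coefficients and supply RHS per block;
# uses the current phi fields (prev = FALSE) or the *_prev copies
update_species_coefficients <- function(h, params, profile, prev = FALSE) {
  sfx <- if (prev) "_prev" else ""
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    for (ib in seq_along(lv$blocks)) {
      b <- lv$blocks[[ib]]
      pT <- b$data[[paste0("phi_V", sfx)]] + b$data[[paste0("phi_D", sfx)]]
      pE <- b$data[[paste0("phi_E", sfx)]]
      supply <- b$data$B_nE * pE / params$supply_ref
      dat <- list(
        D_n_eff = eff3(pT, pE, params$D_n, params),
        D_g_eff = eff3(pT, pE, params$D_g, params),
        D_tgf_eff = eff3(pT, pE, params$D_tgf, params),
        D_taf_eff = eff3(pT, pE, params$D_taf, params),
        D_m_eff = eff3(pT, pE, params$D_m, params),
        a_n = eff3(pT, pE, params$k_n1, params) +
          eff3(pT, pE, params$k_n2, params),
        a_g = eff3(pT, pE, params$k_g1, params) +
          eff3(pT, pE, params$k_g2, params),
        a_tgf = array(params$lambda_tgf + params$lambda_de_tgf +
                        params$lambda_U_tgf, dim(pT)),
        a_taf = array(params$lambda_taf + params$lambda_de_taf +
                        params$lambda_U_taf, dim(pT)),
        R0_n = eff3(pT, pE, params$k_n1, params) * supply,
        R0_g = eff3(pT, pE, params$k_g1, params) * supply,
        R0_tgf = params$lambda_tgf * b$data[[paste0("phi_V", sfx)]],
        R0_taf = params$lambda_taf * b$data[[paste0("phi_V", sfx)]],
        K_alpha = array(params$k_alpha, dim(pT)),
        K_one = array(1, dim(pT)),
        A_zero = array(0, dim(pT)))
      if (profile == "full") {
        dat$D_w_eff <- eff3(pT, pE, params$D_w, params)
        dat$D_l_eff <- eff3(pT, pE, params$D_l, params)
        dat$D_b_eff <- eff3(pT, pE, params$D_b, params)
        dat$D_a_eff <- eff3(pT, pE, params$D_a, params)
        dat$D_s_eff <- eff3(pT, pE, params$D_s, params)
        dat$D_r_eff <- eff3(pT, pE, params$D_r, params)
        dat$a_w <- params$k_f + eff3(pT, pE, params$k_w, params)
        dat$a_l <- eff3(pT, pE, params$k_l, params)
        dat$a_b <- array(0, dim(pT))
        dat$a_a <- array(0, dim(pT))
        dat$a_s <- array(0, dim(pT))
        dat$k_n2_eff <- eff3(pT, pE, params$k_n2, params)
        dat$k_g2_eff <- eff3(pT, pE, params$k_g2, params)
      }
      if (is.null(b$data$sprout)) {
        geo <- cell_geometry(lv, b, h$domain)
        ctr <- (h$domain$L + h$domain$R) / 2
        octv <- params$sprout_fractions
        xo <- as.numeric(geo$centers[[1]] > ctr[1])
        yo <- as.numeric(geo$centers[[2]] > ctr[2])
        zo <- as.numeric(geo$centers[[3]] > ctr[3])
        oct <- outer(outer(xo, 2 * yo, "+"), 4 * zo, "+") + 1
        dat$sprout <- array(octv[oct], dim(pT))
      }
      for (nm in names(dat)) lv$blocks[[ib]]$data[[nm]] <- dat[[nm]]
    }
    h <- set_level(h, kappa, lv)
  }
  h
}

# evaluate and store the model source terms on every block
update_sources <- function(h, params, prev = FALSE) {
  sfx <- if (prev) "_prev" else ""
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    for (ib in seq_along(lv$blocks)) {
      b <- lv$blocks[[ib]]
      fl <- list(phi_V = b$data[[paste0("phi_V", sfx)]],
                 phi_D = b$data[[paste0("phi_D", sfx)]],
                 phi_E = b$data[[paste0("phi_E", sfx)]],
                 n = b$data$n, g = b$data$g, tgf = b$data$tgf,
                 taf = b$data$taf, m = b$data$m, F_E = b$data$F_E,
                 B_nE = b$data$B_nE, L_nE = b$data$L_nE, p = b$data$p,
                 sprout = b$data$sprout)
      S <- source_terms(fl, params)
      for (nm in names(S)) lv$blocks[[ib]]$data[[nm]] <- S[[nm]]
      lv$blocks[[ib]]$data$S_tot <- S$S_V + S$S_D + S$S_E
    }
    h <- set_level(h, kappa, lv)
  }
  h
}

# ---------------------------------------------------------------------------
# Quasi-steady solves.
# ---------------------------------------------------------------------------

#' Solve the quasi-steady species system
#'
#' Solves the linear reaction-diffusion equations for oxygen, glucose and
#' the tumorigenic factors (and, in the full profile, CO2 and the charged
#' species with their shared electro-diffusive drift, by lagged Picard
#' iteration) to quasi-steady state on the whole hierarchy, using the
#' multigrid machinery.  The chloride concentration closes algebraically
#' from electroneutrality.
#'
#' @param h hierarchy with current coefficient fields (see the simulation
#'   driver).
#' @param params a [model_params()].
#' @param cfg a [solver_config()].
#' @param bcs boundary conditions.
#' @param profile `"lite"` or `"full"`.
#' @param picard_iter Picard rounds for the coupled ion system.
#' @return the updated hierarchy.
#' @export
quasi_steady_species_system <- function(h, params, cfg, bcs,
                                        profile = "lite",
                                        picard_iter = 3L) {
  for (X in c("n", "g", "tgf", "taf")) {
    sys <- scalar_system(X, bcs[[X]], paste0("a_", X), paste0("D_", X, "_eff"))
    h <- fmg_solve(h, sys, cfg)$h
  }
  if (profile == "full") {
    for (it in seq_len(picard_iter)) {
      # CO2: production from oxygen consumption + buffer reaction (lagged)
      h <- map_blocks(h, function(b, lv) {
        b$data$R0_w <- b$data$k_n2_eff * b$data$n +
          params$k_r * b$data$b * b$data$a
        b
      })
      sys <- scalar_system("w", bcs$w, "a_w", "D_w_eff")
      h <- fmg_solve(h, sys, cfg)$h
      h <- ion_drift_rhs(h, params)
      for (X in c("l", "b", "a", "s")) {
        sys <- scalar_system(X, bcs[[X]], paste0("a_", X),
                             paste0("D_", X, "_eff"))
        h <- fmg_solve(h, sys, cfg)$h
      }
      # electroneutrality closure
      h <- map_blocks(h, function(b, lv) {
        b$data$r <- -(params$z_l * b$data$l + params$z_b * b$data$b +
                        params$z_a * b$data$a + params$z_s * b$data$s) /
          params$z_r
        b
      })
    }
  }
  h
}

# apply a function block-wise over the whole hierarchy
map_blocks <- function(h, f) {
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    for (ib in seq_along(lv$blocks))
      lv$blocks[[ib]] <- f(lv$blocks[[ib]], lv)
    h <- set_level(h, kappa, lv)
  }
  h
}

# RHS of the charged species: production terms plus (lagged, explicit)
# electro-diffusive drift divergence.  The shared drift field is
#   Evec = (sum_i z_i D_i grad c_i) / (sum_i z_i^2 D_i c_i)
# with an epsilon floor on the denominator.
ion_drift_rhs <- function(h, params) {
  P <- params
  map_blocks(h, function(b, lv) {
    eta <- lv$eta
    sp <- list(l = P$z_l, b = P$z_b, a = P$z_a, s = P$z_s, r = P$z_r)
    den_c <- 0
    for (X in names(sp))
      den_c <- den_c + sp[[X]]^2 * b$data[[paste0("D_", X, "_eff")]] *
        b$data[[X]]
    drift_div <- function(X) {
      DX <- b$data[[paste0("D_", X, "_eff")]]
      fl <- list()
      for (ax in 1:3) {
        num <- 0
        for (Y in names(sp))
          num <- num + sp[[Y]] *
            face_avg(b$data[[paste0("D_", Y, "_eff")]], ax) *
            face_grad(b$data[[Y]], eta, ax)
        den <- pmax(face_avg(den_c, ax), 1e-12)
        fl[[ax]] <- face_avg(DX, ax) * sp[[X]] * face_avg(b$data[[X]], ax) *
          num / den
      }
      div_face(fl[[1]], fl[[2]], fl[[3]], eta)
    }
    zero <- array(0, dim(b$data$n))
    src <- list(
      l = 2 * P$R_g_n * b$data$k_g2_eff * b$data$g -
        (1 / 3) * b$data$k_n2_eff * b$data$n,
      b = P$k_f * b$data$w - P$k_r * b$data$b * b$data$a,
      a = 2 * P$R_g_n * b$data$k_g2_eff * b$data$g -
        (1 / 3) * b$data$k_n2_eff * b$data$n +
        P$k_f * b$data$w - P$k_r * b$data$b * b$data$a,
      s = zero)
    # the k_r b a sink is lagged into the RHS; linear decay a_X handles the
    # k_l type losses (a_l set in the coefficients; others zero)
    for (X in c("l", "b", "a", "s")) {
      R <- zero
      interior(R) <- interior(src[[X]]) - drift_div(X)
      b$data[[paste0("R0_", X)]] <- R
    }
    b
  })
}

# ---------------------------------------------------------------------------
# Pressures and face velocities.
# ---------------------------------------------------------------------------

# Darcy forcing at faces: G = gamma_T eps_T mu_T grad(phi_T) +
# gamma_E eps_E mu_E grad(phi_E), per axis
darcy_forcing_faces <- function(b, params, eta, sfx = "") {
  pT <- b$data[[paste0("phi_V", sfx)]] + b$data[[paste0("phi_D", sfx)]]
  pE <- b$data[[paste0("phi_E", sfx)]]
  mT <- b$data[[paste0("mu_T", sfx)]]
  mE <- b$data[[paste0("mu_E", sfx)]]
  lapply(1:3, function(ax) {
    params$gamma_T * params$eps_T * face_avg(mT, ax) *
      face_grad(pT, eta, ax) +
      params$gamma_E * params$eps_E * face_avg(mE, ax) *
      face_grad(pE, eta, ax)
  })
}

#' Solve the cell-ECM and interstitial pressures and the face velocities
#'
#' The solid-phase pressure solves
#' `div(k_alpha (grad p - G)) = -(S_V + S_D + S_E)` with `G` the
#' thermodynamic Darcy forcing, Dirichlet `p = 0`; the interstitial
#' pressure solves `lap q = (R_ab / k_beta) S_tot` (full profile).  Face
#' velocities follow: `u_alpha = -k_alpha (grad p - G)`,
#' `u_beta = -k_beta grad q`, and the ECM velocity
#' `u_E = u_alpha - Mbar phi_E grad mu_E`.
#'
#' @inheritParams quasi_steady_species_system
#' @param sfx `""` to use current phase fields, `"_prev"` for the stored
#'   previous-time copies (used when rebuilding a regridded level).
#' @return the updated hierarchy (velocities in each block's `face_data`).
#' @export
pressure_velocity_solve <- function(h, params, cfg, bcs, profile = "lite",
                                    sfx = "") {
  # RHS for p
  h <- map_blocks(h, function(b, lv) {
    G <- darcy_forcing_faces(b, params, lv$eta, sfx)
    R <- array(0, dim(b$data$p))
    interior(R) <- interior(b$data$S_tot) -
      div_face(params$k_alpha * G[[1]], params$k_alpha * G[[2]],
               params$k_alpha * G[[3]], lv$eta)
    b$data$R0_p <- R
    b
  })
  sys <- scalar_system("p", bcs$p, "A_zero", "K_alpha")
  h <- fmg_solve(h, sys, cfg)$h
  if (profile == "full") {
    h <- map_blocks(h, function(b, lv) {
      R <- array(0, dim(b$data$p))
      interior(R) <- -(params$R_alpha_beta / params$k_beta) *
        interior(b$data$S_tot)
      b$data$R0_q <- R
      b
    })
    sys <- scalar_system("q", bcs$q, "A_zero", "K_one")
    h <- fmg_solve(h, sys, cfg)$h
  }
  # face velocities
  for (kappa in h$kappa_min:h$kappa_max) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    h <- fill_ghosts(h, kappa, c("p", if (profile == "full") "q"), bcs)
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      b <- lv$blocks[[ib]]
      G <- darcy_forcing_faces(b, params, lv$eta, sfx)
      pE <- b$data[[paste0("phi_E", sfx)]]
      mE <- b$data[[paste0("mu_E", sfx)]]
      axn <- c("x", "y", "z")
      for (ax in 1:3) {
        ua <- -params$k_alpha * (face_grad(b$data$p, lv$eta, ax) - G[[ax]])
        b$face_data[[paste0("u_alpha_", axn[ax])]] <- ua
        b$face_data[[paste0("u_E_", axn[ax])]] <- ua -
          params$Mbar * pmax(face_avg(pE, ax), 0) *
          face_grad(mE, lv$eta, ax)
        if (profile == "full")
          b$face_data[[paste0("u_beta_", axn[ax])]] <-
            -params$k_beta * face_grad(b$data$q, lv$eta, ax)
      }
      lv$blocks[[ib]] <- b
    }
    h <- set_level(h, kappa, lv)
  }
  h
}

# ---------------------------------------------------------------------------
# Transient tissue species (m, F_E, B_nE, L_nE).
# ---------------------------------------------------------------------------

#' Advance the transient tissue species one time step
#'
#' Matrix-degrading enzymes diffuse with a source (Crank-Nicolson);
#' myofibroblasts are advected by the ECM velocity with an explicit
#' counter-gradient growth-factor flux; the vessel densities combine
#' implicit (CN) diffusion with explicit upwinded advection and
#' chemo-/haptotactic fluxes.  Sources are evaluated at the current state.
#'
#' @inheritParams quasi_steady_species_system
#' @param theta time step.
#' @return the updated hierarchy.
#' @export
transient_species_step <- function(h, params, cfg, bcs, theta,
                                   profile = "lite") {
  P <- params
  axn <- c("x", "y", "z")
  # --- matrix-degrading enzymes: CN diffusion + source ------------------
  h <- map_blocks(h, function(b, lv) {
    eta <- lv$eta
    Dm <- b$data$D_m_eff
    diff_old <- div_face(face_avg(Dm, 1L) * face_grad(b$data$m, eta, 1L),
                         face_avg(Dm, 2L) * face_grad(b$data$m, eta, 2L),
                         face_avg(Dm, 3L) * face_grad(b$data$m, eta, 3L),
                         eta)
    R <- array(0, dim(b$data$m))
    interior(R) <- (2 / theta) * interior(b$data$m) + diff_old +
      2 * interior(b$data$S_m)
    b$data$R0_m <- R
    b$data$a_m <- array(2 / theta, dim(b$data$m))
    b
  })
  h <- fmg_solve(h, scalar_system("m", bcs$m, "a_m", "D_m_eff"), cfg)$h
  # --- myofibroblasts: fully explicit (no self-diffusion) ---------------
  h <- map_blocks(h, function(b, lv) {
    eta <- lv$eta
    ux <- b$face_data$u_E_x; uy <- b$face_data$u_E_y
    uz <- b$face_data$u_E_z
    FE <- b$data$F_E
    adv <- upwind_div(FE, ux, uy, uz, eta)
    ctx <- div_face(
      P$D_F * face_avg(FE, 1L) * face_grad(b$data$tgf, eta, 1L),
      P$D_F * face_avg(FE, 2L) * face_grad(b$data$tgf, eta, 2L),
      P$D_F * face_avg(FE, 3L) * face_grad(b$data$tgf, eta, 3L), eta)
    new <- FE
    interior(new) <- interior(FE) +
      theta * (-adv - ctx + interior(b$data$S_FE))
    b$data$F_E <- new
    b
  })
  h <- fill_all_levels(h, "F_E", bcs)
  # --- vessel densities: CN diffusion + explicit advection/taxis --------
  for (V in c("B_nE", "L_nE")) {
    DV <- if (V == "B_nE") P$D_BnE else P$D_LnE
    chc <- if (V == "B_nE") P$chi_che_BnE * P$A_che_BnE else
      P$chi_che_LnE * P$A_che_LnE
    chh <- if (V == "B_nE") P$chi_hap_BnE * P$A_hap_BnE else
      P$chi_hap_LnE * P$A_hap_LnE
    SV <- if (V == "B_nE") "S_BnE" else "S_LnE"
    h <- map_blocks(h, function(b, lv) {
      eta <- lv$eta
      ux <- b$face_data$u_E_x; uy <- b$face_data$u_E_y
      uz <- b$face_data$u_E_z
      B <- b$data[[V]]
      diff_old <- div_face(DV * face_grad(B, eta, 1L),
                           DV * face_grad(B, eta, 2L),
                           DV * face_grad(B, eta, 3L), eta)
      adv <- upwind_div(B, ux, uy, uz, eta)
      taxis <- div_face(
        face_avg(B, 1L) * (chc * face_grad(b$data$taf, eta, 1L) +
                             chh * face_grad(b$data$phi_E, eta, 1L)),
        face_avg(B, 2L) * (chc * face_grad(b$data$taf, eta, 2L) +
                             chh * face_grad(b$data$phi_E, eta, 2L)),
        face_avg(B, 3L) * (chc * face_grad(b$data$taf, eta, 3L) +
                             chh * face_grad(b$data$phi_E, eta, 3L)), eta)
      R <- array(0, dim(B))
      interior(R) <- (2 / theta) * interior(B) + diff_old +
        2 * (-adv - taxis + interior(b$data[[SV]]))
      b$data[[paste0("R0_", V)]] <- R
      b$data[[paste0("a_", V)]] <- array(2 / theta, dim(B))
      b$data[[paste0("D_", V, "_const")]] <- array(DV, dim(B))
      b
    })
    h <- fmg_solve(h, scalar_system(V, bcs[[V]], paste0("a_", V),
                                    paste0("D_", V, "_const")), cfg)$h
  }
  h
}

# fill ghosts of one field on every non-empty level, coarse to fine
fill_all_levels <- function(h, fields, bcs) {
  for (kappa in h$kappa_min:h$kappa_max) {
    if (length(get_level(h, kappa)$blocks) == 0L) next
    h <- fill_ghosts(h, kappa, fields, bcs)
  }
  h
}

# restrict fields from fine levels onto the coarse data beneath them
sync_down <- function(h, fields, bcs) {
  if (h$kappa_max <= h$kappa_min) return(h)
  for (kappa in h$kappa_max:(h$kappa_min + 1L)) {
    lv <- get_level(h, kappa)
    if (length(lv$blocks) == 0L) next
    for (b in lv$blocks) {
      clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
      for (f in fields)
        h <- deposit_box(h, kappa - 1L, clo, chi, f,
                         restrict_avg(interior(b$data[[f]])))
    }
    h <- fill_ghosts(h, kappa - 1L, fields, bcs)
  }
  h
}
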