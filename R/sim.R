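# ---------------------------------------------------------------------------
# End-to-end simulation driver: initial conditions, the operator-split time
# step, the run loop, the convergence study, and manufactured fixtures.
#
# One time step:
#   1. quasi-steady species solves (effective coefficients from phi),
#   2. source terms and the Darcy pressure/velocity solve,
#   3. the implicit Crank-Nicolson Cahn-Hilliard step for the phase fields,
#      solved by the adaptive FAS-FMG pass, which may flag/cluster/regrid
#      the refinement levels while ascending,
#   4. transient tissue species (enzymes, myofibroblasts, vessels).
# Species, sources and velocities enter the phase-field step at the old
# time level (operator splitting), consistent with the first-order overall
# accuracy of the scheme.
# ---------------------------------------------------------------------------

ch_fields <- c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E")
ch_prev_fields <- paste0(ch_fields, "_prev")

#' Construct the initial tumor state
#'
#' Builds the global levels, seeds a sharp-interfaced cube of viable tumor
#' cells (`phi_V = 0.65` by default, side 10 of a (0,40)^3 domain) at the
#' domain center, distributes the ECM evenly (`phi_E = 0.35`), sets all
#' diffusible concentrations to their boundary values and the vessels to
#' their far-field densities, and initializes the chemical potentials
#' consistently from the phase fields.
#'
#' @param params a [model_params()].
#' @param cfg a [solver_config()].
#' @param domain list with `L`, `R` bounds (default (0,40)^3).
#' @param root_cells root-level cells per axis (default 32).
#' @param n_global number of global levels (default 3).
#' @param kappa_max finest refinement level allowed (default 2).
#' @param profile `"lite"` (ions and elasticity off) or `"full"`.
#' @param seed_side side length of the seeded cube (0 for no tumor).
#' @return a `tmg_state` list: hierarchy `h`, `params`, `cfg`, `bcs`,
#'   `profile`, `time`, `step`, and a `log` data frame.
#' @export
initial_condition <- function(params = model_params(),
                              cfg = solver_config(),
                              domain = list(L = c(0, 0, 0),
                                            R = c(40, 40, 40)),
                              root_cells = 32L, n_global = 3L,
                              kappa_max = 2L, profile = c("lite", "full"),
                              seed_side = params$seed_side) {
  profile <- match.arg(profile)
  if (seed_side > min(domain$R - domain$L))
    stop("seed exceeds the domain")
  h <- build_hierarchy(domain, rep(root_cells, 3L), n_global, kappa_max)
  flds <- profile_fields(profile)
  bcs <- bcs_with_default(default_bcs(params), flds)
  ctr <- (domain$L + domain$R) / 2
  for (kappa in h$kappa_min:0L) {
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      b <- block_add_fields(lv$blocks[[ib]], flds)
      geo <- cell_geometry(lv, b, h$domain)
      inx <- abs(geo$centers[[1]] - ctr[1]) <= seed_side / 2
      iny <- abs(geo$centers[[2]] - ctr[2]) <= seed_side / 2
      inz <- abs(geo$centers[[3]] - ctr[3]) <= seed_side / 2
      seed <- outer(outer(inx, iny, "&"), inz, "&")
      b$data$phi_V <- array(params$phi_V_seed * seed, dim(b$data$phi_V))
      b$data$phi_E <- array(params$phi_E0, dim(b$data$phi_E))
      b$data$n <- array(1, dim(b$data$n))
      b$data$g <- array(1, dim(b$data$g))
      b$data$F_E <- array(params$F_E0, dim(b$data$F_E))
      b$data$B_nE <- array(params$B_inf, dim(b$data$B_nE))
      b$data$L_nE <- array(params$L_inf, dim(b$data$L_nE))
      lv$blocks[[ib]] <- b
    }
    h <- set_level(h, kappa, lv)
    h <- fill_ghosts(h, kappa, flds, bcs)
    h <- chemical_potentials(h, kappa, params)
    h <- fill_ghosts(h, kappa, c("mu_T", "mu_E"), bcs)
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks))
      for (f in ch_fields)
        lv$blocks[[ib]]$data[[paste0(f, "_prev")]] <-
          lv$blocks[[ib]]$data[[f]]
    h <- set_level(h, kappa, lv)
  }
  structure(list(h = h, params = params, cfg = cfg, bcs = bcs,
                 profile = profile, time = 0, step = 0L,
                 log = data.frame()),
            class = "tmg_state")
}

# regrid hook used inside the FMG pass: flag the total tumor fraction on
# the just-converged level, buffer, cluster, rebuild level kappa+1, and set
# up everything the new level needs for the remaining implicit solve
make_regrid_hook <- function(params, cfg, bcs, profile, theta) {
  force(params); force(cfg); force(bcs); force(profile); force(theta)
  function(h, kappa) {
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks))
      lv$blocks[[ib]]$data$phi_T <-
        lv$blocks[[ib]]$data$phi_V + lv$blocks[[ib]]$data$phi_D
    h <- set_level(h, kappa, lv)
    flags <- flag_undivided_gradient(h, kappa, "phi_T", cfg$C_kappa)
    flags <- buffer_flags(flags, h, cfg$buffer_radius)
    bl <- generate_blocks(flags, h, cfg$threshold_eff, cfg$threshold_size,
                          cfg$min_eff)
    fields_now <- setdiff(profile_fields(profile), ch_prev_fields)
    h <- regrid_transfer(h, kappa + 1L, bl, fields_now, ch_prev_fields,
                         bcs)
    if (length(bl$boxes) > 0L) {
      h <- update_species_coefficients(h, params, profile, prev = TRUE)
      h <- update_sources(h, params, prev = TRUE)
      h <- update_velocities_level(h, kappa + 1L, params, bcs, profile,
                                   sfx = "_prev")
      h <- build_ch_rhs_level(h, kappa + 1L, params, theta)
    }
    h
  }
}

# recompute face velocities on one level from the (p, phi, mu) fields
update_velocities_level <- function(h, kappa, params, bcs, profile, sfx = "") {
  lv <- get_level(h, kappa)
  if (length(lv$blocks) == 0L) return(h)
  need <- c("p", paste0(c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E"), sfx))
  h <- fill_ghosts(h, kappa, need, bcs)
  lv <- get_level(h, kappa)
  axn <- c("x", "y", "z")
  for (ib in seq_along(lv$blocks)) {
    b <- lv$blocks[[ib]]
    G <- darcy_forcing_faces(b, params, lv$eta, sfx)
    pE <- b$data[[paste0("phi_E", sfx)]]
    mE <- b$data[[paste0("mu_E", sfx)]]
    for (ax in 1:3) {
      ua <- -params$k_alpha * (face_grad(b$data$p, lv$eta, ax) - G[[ax]])
      b$face_data[[paste0("u_alpha_", axn[ax])]] <- ua
      b$face_data[[paste0("u_E_", axn[ax])]] <- ua -
        params$Mbar * pmax(face_avg(pE, ax), 0) * face_grad(mE, lv$eta, ax)
    }
    lv$blocks[[ib]] <- b
  }
  set_level(h, kappa, lv)
}

#' Advance the simulation by one time step
#'
#' @param state a `tmg_state`.
#' @param adapt flag/cluster/regrid the refinement levels during the FMG
#'   pass (default: yes if the hierarchy allows refinement levels).
#' @param verbose print solver progress.
#' @return the updated state.
#' @export
tumor_step <- function(state, adapt = state$h$kappa_max >= 1L,
                       verbose = FALSE) {
  h <- state$h; params <- state$params; cfg <- state$cfg
  bcs <- state$bcs; profile <- state$profile
  theta <- cfg$theta
  flds <- setdiff(profile_fields(profile), ch_prev_fields)
  h <- fill_all_levels(h, flds, bcs)
  h <- update_species_coefficients(h, params, profile)
  h <- quasi_steady_species_system(h, params, cfg, bcs, profile)
  h <- fill_all_levels(h, c("n", "g", "tgf", "taf"), bcs)
  h <- update_sources(h, params)
  h <- pressure_velocity_solve(h, params, cfg, bcs, profile)
  if (profile == "full" && params$eps_e > 0)
    h <- solve_displacement(h, params)$h
  # previous-time copies for the implicit phase-field step
  h <- map_blocks(h, function(b, lv) {
    for (f in ch_fields) b$data[[paste0(f, "_prev")]] <- b$data[[f]]
    b
  })
  cn <- crank_nicolson_system(h, params, theta)
  hook <- if (adapt) make_regrid_hook(params, cfg, bcs, profile, theta)
  out <- fmg_solve(cn$h, cn$sys, cfg, regrid = hook, verbose = verbose)
  h <- out$h
  h <- sync_down(h, ch_fields, bcs)
  # transient species with the new phase fields
  h <- update_species_coefficients(h, params, profile)
  h <- update_sources(h, params)
  h <- transient_species_step(h, params, cfg, bcs, theta, profile)
  h <- sync_down(h, c("m", "F_E", "B_nE", "L_nE"), bcs)
  state$h <- h
  state$time <- state$time + theta
  state$step <- state$step + 1L
  state$log <- rbind(state$log, data.frame(
    step = state$step, time = state$time, dof = count_dof(h),
    cycles_finest = unname(out$cycles[length(out$cycles)]),
    residual_finest = unname(out$residuals[length(out$residuals)])))
  state
}

#' Run a simulation
#'
#' Advances the state until `end_time`, optionally writing field snapshots
#' and the residual/DOF log on a cadence.
#'
#' @param state a `tmg_state` from [initial_condition()] (or a fixture).
#' @param end_time end time (a positive multiple of the time step).
#' @param out_dir optional output directory for snapshots and logs.
#' @param cadence write outputs every `cadence` steps (0 = only at the end).
#' @param verbose print progress.
#' @return the final state.
#' @export
run_simulation <- function(state, end_time, out_dir = NULL, cadence = 0L,
                           verbose = FALSE) {
  theta <- state$cfg$theta
  nsteps <- round(end_time / theta)
  if (abs(nsteps * theta - end_time) > 1e-9 * max(1, end_time))
    stop("end_time must be a positive multiple of the time step")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (s in seq_len(nsteps)) {
    state <- tryCatch(tumor_step(state, verbose = verbose),
                      error = function(e) {
                        if (!is.null(out_dir))
                          write_checkpoint(state,
                                           file.path(out_dir,
                                                     "abort_state.rds"))
                        stop(e)
                      })
    if (verbose)
      message(sprintf("step %d t=%.4f dof=%d", state$step, state$time,
                      count_dof(state$h)))
    if (!is.null(out_dir) && cadence > 0L && state$step %% cadence == 0L)
      write_output(state, out_dir)
  }
  if (!is.null(out_dir)) write_output(state, out_dir)
  state
}

#' Sample the composite solution onto the uniform grid of a level
#'
#' Builds the full-domain uniform array of a field at the spacing of level
#' `kappa_max` by cubic interpolation of the coarser composite, overwritten
#' with actual fine-block data wherever refined blocks exist.
#'
#' @param state a `tmg_state` (or list with `h`, `bcs`).
#' @param field field name.
#' @param kappa target level (default the finest).
#' @param interp `"linear"` (trilinear, monotone -- the default, matching
#'   the order of the scheme's prolongation) or `"cubic"` for regions not
#'   covered by refined blocks.
#' @return 3D array of `root_cells * 2^kappa` values per axis.
#' @export
sample_uniform <- function(state, field, kappa = state$h$kappa_max,
                           interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  h <- state$h
  u <- NULL
  for (k in h$kappa_min:kappa) {
    ndom <- level_ncells_domain(h, k)
    if (is.null(u)) {
      u <- extract_box(h, k, c(1L, 1L, 1L), ndom, field)
    } else {
      up <- array(NA_real_, ndom %/% 2L + 2L)
      up[2:(ndom[1] %/% 2L + 1L), 2:(ndom[2] %/% 2L + 1L),
         2:(ndom[3] %/% 2L + 1L)] <- u
      up <- fill_na_margin(up)   # mirror extrapolation at the boundary
      u <- if (interp == "linear") prolong_linear(up) else
        fmg_interp_cubic(up, margin = 1L)
      if (length(get_level(h, k)$blocks) > 0L) {
        lvdat <- extract_box(h, k, c(1L, 1L, 1L), ndom, field)
        use <- !is.na(lvdat)
        u[use] <- lvdat[use]
      }
    }
  }
  u
}

#' Grid convergence study of the coupled model
#'
#' Runs the simulation at successively doubled root resolutions with the
#' time step following the linear refinement path `theta = 0.032 * eta`
#' (eta the finest-level spacing; the step is rounded so `end_time` is hit
#' exactly), samples the total tumor fraction onto each run's uniform grid
#' at the finest spacing, and measures the l2 norms of successive
#' differences after averaging the finer run down to the coarser grid.  The
#' convergence rate is `log2(e_coarse / e_fine)`.
#'
#' @param root_sizes increasing root-level sizes in ratio 2 (>= 3 of them
#'   for a rate).
#' @param kappa_max refinement levels per run.
#' @param end_time common end time.
#' @param params,cfg model and solver settings (the time step in `cfg` is
#'   overridden per run).
#' @param profile model profile.
#' @param n_global global levels per run; `NULL` (default) picks enough
#'   levels that the coarsest global grid is 8^3.
#' @param verbose print per-run progress.
#' @return list with `errors`, `rates`, and the per-run `thetas`.
#' @export
convergence_study <- function(root_sizes = c(8L, 16L, 32L), kappa_max = 1L,
                              end_time = 1.0, params = model_params(),
                              cfg = solver_config(), profile = "lite",
                              n_global = NULL, verbose = FALSE) {
  root_sizes <- as.integer(root_sizes)
  if (length(root_sizes) < 2L || any(diff(root_sizes) != root_sizes[-length(root_sizes)]))
    stop("root sizes must double")
  fields <- list(); thetas <- numeric(0)
  for (root in root_sizes) {
    eta_fin <- 40 / (root * 2^kappa_max)
    theta0 <- 0.032 * eta_fin
    # step count whose uniform step lies closest to the refinement path
    cand <- unique(pmax(1L, c(floor(end_time / theta0),
                              ceiling(end_time / theta0))))
    nst <- cand[which.min(abs(end_time / cand - theta0))]
    theta <- end_time / nst
    cfg_r <- cfg; cfg_r$theta <- theta
    ng <- if (is.null(n_global)) max(1L, as.integer(log2(root / 8)) + 1L)
      else n_global
    st <- initial_condition(params, cfg_r, root_cells = root,
                            n_global = ng, kappa_max = kappa_max,
                            profile = profile)
    st <- run_simulation(st, end_time, verbose = verbose)
    pt <- sample_uniform(st, "phi_V") + sample_uniform(st, "phi_D")
    fields[[length(fields) + 1L]] <- pt
    thetas <- c(thetas, theta)
    if (verbose) message(sprintf("root %d done (theta=%.4g)", root, theta))
  }
  errors <- numeric(0)
  for (i in seq_len(length(fields) - 1L)) {
    coarse <- fields[[i]]
    fine <- restrict_avg(fields[[i + 1L]])
    errors <- c(errors, sqrt(mean((coarse - fine)^2)))
  }
  rates <- if (length(errors) >= 2L) log2(errors[-length(errors)] /
                                            errors[-1]) else numeric(0)
  list(errors = errors, rates = rates, thetas = thetas)
}

#' Manufactured-solution and validation fixtures
#'
#' Returns self-contained validation problems:
#' \describe{
#'   \item{`poisson_mms`}{3D Poisson `-lap u = f` on (0,1)^3 with analytic
#'     solution `sin(pi x) sin(pi y) sin(pi z)`, homogeneous Dirichlet.}
#'   \item{`heat_mms`}{scalar heat equation with the same initial mode,
#'     analytic decay `exp(-3 pi^2 t)`, Crank-Nicolson stepping.}
#'   \item{`cahn_hilliard_scalar`}{single-species Cahn-Hilliard (double
#'     well, smooth spherical initial data, no-flux boundaries) for
#'     conservation checks, expressed through the coupled system with the
#'     ECM and dead phases inert.}
#'   \item{`tumor`}{the standard seeded tumor state.}
#' }
#'
#' @param name fixture name.
#' @param root_cells root cells per axis.
#' @param n_global global levels.
#' @param kappa_max finest refinement level.
#' @param theta time step (where relevant).
#' @return a list describing the fixture (see details of each element).
#' @export
fixture_generators <- function(name = c("poisson_mms", "heat_mms",
                                        "cahn_hilliard_scalar", "tumor"),
                               root_cells = 16L, n_global = 1L,
                               kappa_max = 0L, theta = 1e-3) {
  name <- match.arg(name)
  dom1 <- list(L = c(0, 0, 0), R = c(1, 1, 1))
  if (name == "poisson_mms") {
    h <- build_hierarchy(dom1, rep(root_cells, 3L), n_global, kappa_max)
    exact <- function(x, y, z) {
      outer(outer(sin(pi * x), sin(pi * y)), sin(pi * z))
    }
    h <- map_blocks(h, function(b, lv) {
      b <- block_add_fields(b, c("u", "R0_u", "R_u", "a0", "k1"))
      geo <- cell_geometry(lv, b, dom1)
      b$data$k1 <- array(1, dim(b$data$u))
      f <- 3 * pi^2 * exact(geo$centers[[1]], geo$centers[[2]],
                            geo$centers[[3]])
      b$data$R0_u <- f; b$data$R_u <- f
      b
    })
    sys <- scalar_system("u", bc("dirichlet", 0), "a0", "k1")
    list(name = name, h = h, sys = sys, exact = exact,
         bcs = sys_bcs(sys))
  } else if (name == "heat_mms") {
    h <- build_hierarchy(dom1, rep(root_cells, 3L), n_global, kappa_max)
    exact <- function(x, y, z, t) {
      exp(-3 * pi^2 * t) * outer(outer(sin(pi * x), sin(pi * y)),
                                 sin(pi * z))
    }
    h <- map_blocks(h, function(b, lv) {
      b <- block_add_fields(b, c("u", "R0_u", "R_u", "a_cn", "k1"))
      geo <- cell_geometry(lv, b, dom1)
      b$data$k1 <- array(1, dim(b$data$u))
      b$data$a_cn <- array(2 / theta, dim(b$data$u))
      u0 <- array(0, dim(b$data$u))
      u0[] <- exact(geo$centers[[1]], geo$centers[[2]], geo$centers[[3]],
                    0)
      b$data$u <- u0
      b
    })
    sys <- scalar_system("u", bc("dirichlet", 0), "a_cn", "k1")
    list(name = name, h = h, sys = sys, exact = exact, theta = theta,
         bcs = sys_bcs(sys),
         # build the CN right-hand side from the current u
         advance_rhs = function(h) {
           map_blocks(h, function(b, lv) {
             lap_old <- lap3(b$data$u, lv$eta)
             R <- (2 / theta) * b$data$u + lap_old
             R[is.na(R)] <- 0
             b$data$R0_u <- R; b$data$R_u <- R
             b
           })
         })
  } else if (name == "cahn_hilliard_scalar") {
    params <- model_params(A1 = 1, A2 = 0, A3 = 0, A4 = 0, A5 = 0,
                           eps_T = 0.1, eps_E = 0.1, eps_TE = 0,
                           Mbar = 1)
    h <- build_hierarchy(dom1, rep(root_cells, 3L), n_global, kappa_max)
    bcs <- list(phi_V = bc("neumann"), phi_D = bc("neumann"),
                phi_E = bc("neumann"), mu_T = bc("neumann"),
                mu_E = bc("neumann"))
    for (f in ch_prev_fields) bcs[[f]] <- bcs[[sub("_prev$", "", f)]]
    h <- map_blocks(h, function(b, lv) {
      b <- block_add_fields(b, c(ch_fields, ch_prev_fields))
      geo <- cell_geometry(lv, b, dom1)
      r2 <- outer(outer((geo$centers[[1]] - 0.5)^2,
                        (geo$centers[[2]] - 0.5)^2, "+"),
                  (geo$centers[[3]] - 0.5)^2, "+")
      b$data$phi_V <- array(0.5 * (1 + tanh((0.25 - sqrt(r2)) /
                                              (sqrt(2) * 0.1))),
                            dim(b$data$phi_V))
      b
    })
    for (k in h$kappa_min:h$kappa_max) {
      if (length(get_level(h, k)$blocks) == 0L) next
      h <- fill_ghosts(h, k, ch_fields, bcs)
      h <- chemical_potentials(h, k, params)
      h <- fill_ghosts(h, k, c("mu_T", "mu_E"), bcs)
    }
    list(name = name, h = h, params = params, theta = theta, bcs = bcs)
  } else {
    list(name = name,
         state = initial_condition(root_cells = root_cells,
                                   n_global = n_global,
                                   kappa_max = kappa_max))
  }
}
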