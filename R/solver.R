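# ---------------------------------------------------------------------------
# Nonlinear adaptive FAS multigrid machinery.
#
# A "system" bundles, for one implicit solve, the unknown field names, their
# boundary conditions, and how to relax / apply the level operator on one
# block.  Two kinds exist: a scalar variable-coefficient Helmholtz system
#   a(x) psi - div(k(x) grad psi) = f
# (pressure, quasi-steady species, Crank-Nicolson heat steps) and the
# coupled Cahn-Hilliard block for (phi_V, phi_D, phi_E, mu_T, mu_E).
#
# RHS storage: the base right-hand side of each unknown u lives in field
# "R0_<u>"; the working RHS "R_<u>" is what the kernels see.  On the finest
# level they coincide; on coarser levels the FAS cycle overwrites the
# working RHS with the tau-corrected value on the fine-overlap region each
# cycle and resets it from the base elsewhere.
# ---------------------------------------------------------------------------

#' Multigrid solver configuration
#'
#' @param gamma cycle index: 1 for V-cycles, 2 for W-cycles.
#' @param nu0 smoothing steps on the coarsest level (defaults to nu1 + nu2).
#' @param nu1,nu2 pre-/post-correction smoothing steps per cycle.
#' @param nu_b extra smoothing steps applied to cells within `d_kappa` of a
#'   block boundary after each smoothing phase.
#' @param r_kappa number of cycles performed on global levels below the
#'   root during the FMG pass.
#' @param sigma factor by which the residual tolerance is reduced per finer
#'   level; the finest level gets `tol_min`.
#' @param tol_min residual tolerance on the finest level.
#' @param theta time step size.
#' @param C_kappa critical value of the undivided gradient test.
#' @param threshold_eff,threshold_size,min_eff clustering controls (see
#'   [generate_blocks()]).
#' @param buffer_radius flag buffering radius in cells.
#' @param max_outer cap on cycles per level per solve.
#' @param coarse_solver `"tol"` (default): the coarsest level is relaxed in
#'   batches of `nu0` sweeps until its residual meets the coarsest-level
#'   tolerance, an effectively exact iterative coarse solve; `"nu0"`:
#'   exactly `nu0` sweeps per visit.
#' @return a `tmg_solver_config` list.
#' @export
solver_config <- function(gamma = 1L, nu0 = NULL, nu1 = 2L, nu2 = 2L,
                          nu_b = 2L, r_kappa = 1L, sigma = 4,
                          tol_min = 5e-4, theta = 1e-2, C_kappa = 0.05,
                          threshold_eff = 0.9, threshold_size = 1000,
                          min_eff = 0.5, buffer_radius = 4L,
                          max_outer = 50L,
                          coarse_solver = c("tol", "nu0")) {
  if (is.null(nu0)) nu0 <- nu1 + nu2
  coarse_solver <- match.arg(coarse_solver)
  stopifnot(gamma >= 1L, nu0 >= 0L, nu1 >= 0L, nu2 >= 0L, sigma > 1,
            theta > 0)
  structure(list(gamma = as.integer(gamma), nu0 = as.integer(nu0),
                 nu1 = as.integer(nu1), nu2 = as.integer(nu2),
                 nu_b = as.integer(nu_b), r_kappa = as.integer(r_kappa),
                 sigma = sigma, tol_min = tol_min, theta = theta,
                 C_kappa = C_kappa, threshold_eff = threshold_eff,
                 threshold_size = threshold_size, min_eff = min_eff,
                 buffer_radius = as.integer(buffer_radius),
                 max_outer = as.integer(max_outer),
                 coarse_solver = coarse_solver),
            class = "tmg_solver_config")
}

# coarsest-level solve: nu0 sweeps, or sweep batches to the coarsest-level
# tolerance (the printed algorithm allows a direct solve here)
solve_coarsest <- function(h, sys, cfg) {
  if (identical(cfg$coarse_solver, "nu0"))
    return(smooth(h, h$kappa_min, sys, cfg$nu0, cfg))
  tol_c <- cfg$tol_min * cfg$sigma^(h$kappa_max - h$kappa_min)
  for (it in seq_len(100L)) {
    h <- smooth(h, h$kappa_min, sys, cfg$nu0, cfg)
    if (residual_norm(h, h$kappa_min, sys) <= tol_c) break
  }
  h
}

# near-boundary extra-smoothing depth
d_kappa_depth <- function(h, kappa, block) {
  if (kappa <= 0L) as.integer(2^(kappa - h$kappa_min))
  else max(1L, min(block_dims(block)) %/% 8L)
}

#' Scalar Helmholtz system
#'
#' Describes the implicit problem `a(x)*psi - div(k(x) grad psi) = f` on the
#' hierarchy.  The coefficient fields must exist (with valid ghosts) on every
#' block; the base RHS lives in `R0_<unknown>`.
#'
#' @param unknown unknown field name.
#' @param bc a [bc()] descriptor for the unknown.
#' @param acoef,kcoef field names of the cell-centered coefficients.
#' @return a `tmg_system` of kind `"scalar"`.
#' @export
scalar_system <- function(unknown, bc, acoef, kcoef) {
  structure(list(kind = "scalar", unknowns = unknown,
                 bcs = setNames(list(bc), unknown),
                 acoef = acoef, kcoef = kcoef),
            class = "tmg_system")
}

#' Coupled Cahn-Hilliard system for the tumor phase fields
#'
#' The implicit Crank-Nicolson block for (phi_V, phi_D, phi_E, mu_T, mu_E);
#' see [crank_nicolson_system()] for the right-hand sides.
#'
#' @param params a [model_params()] list (bulk-energy constants, interface
#'   coefficients, mobility scale).
#' @param theta time step.
#' @param bcs boundary conditions for the five unknowns; defaults to the
#'   model's (zero-Neumann phases, zero-Dirichlet potentials).
#' @return a `tmg_system` of kind `"ch"`.
#' @export
ch_system <- function(params, theta, bcs = NULL) {
  un <- c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E")
  if (is.null(bcs))
    bcs <- list(phi_V = bc("neumann"), phi_D = bc("neumann"),
                phi_E = bc("neumann"), mu_T = bc("dirichlet", 0),
                mu_E = bc("dirichlet", 0))
  structure(list(kind = "ch", unknowns = un, bcs = bcs,
                 params = params, theta = theta),
            class = "tmg_system")
}

sys_unknowns <- function(sys) sys$unknowns
sys_bcs <- function(sys) sys$bcs
rhs_work <- function(sys) paste0("R_", sys$unknowns)
rhs_base <- function(sys) paste0("R0_", sys$unknowns)

ch_par_vec <- function(sys, eta) {
  p <- sys$params
  c(theta = sys$theta, Mbar = p$Mbar, epsT2 = p$eps_T^2, epsE2 = p$eps_E^2,
    A1 = p$A1, A2 = p$A2, A3 = p$A3, A4 = p$A4, A5 = p$A5, eta = eta)
}

# one relaxation pass over a block (returns updated unknown arrays)
sys_sweep_block <- function(sys, block, eta, color = 2L, depth = 0L) {
  losum <- sum(block$lo)
  if (sys$kind == "scalar") {
    u <- sys$unknowns
    out <- scalar_sweep_cpp(block$data[[u]], block$data[[paste0("R_", u)]],
                            block$data[[sys$acoef]],
                            block$data[[sys$kcoef]],
                            eta, losum, color, depth)
    setNames(list(out), u)
  } else {
    fl <- block$data[sys$unknowns]
    rh <- setNames(block$data[rhs_work(sys)], sys$unknowns)
    ch_sweep_cpp(fl, rh, ch_par_vec(sys, eta), losum, color, depth)
  }
}

# level operator L applied to the current iterate of a block
sys_apply_block <- function(sys, block, eta) {
  if (sys$kind == "scalar") {
    u <- sys$unknowns
    out <- scalar_apply_cpp(block$data[[u]], block$data[[sys$acoef]],
                            block$data[[sys$kcoef]], eta)
    setNames(list(out), u)
  } else {
    ch_apply_cpp(block$data[sys$unknowns], ch_par_vec(sys, eta))
  }
}

# residual arrays (working RHS minus operator), padded with zeros in ghosts
sys_residual_block <- function(sys, block, eta) {
  ap <- sys_apply_block(sys, block, eta)
  out <- list()
  for (u in sys$unknowns)
    out[[u]] <- block$data[[paste0("R_", u)]] - ap[[u]]
  out
}

#' Smoothing: Red-Black Gauss-Seidel relaxation on one level
#'
#' Performs `nu` full sweeps (red cells -- even global index-sum parity --
#' then black, ghosts refilled between sweeps), followed by `nu_b` extra
#' sweeps restricted to cells within the near-boundary depth `d_kappa` of a
#' block boundary.  Scalar systems use pointwise linear updates; the coupled
#' Cahn-Hilliard system solves each cell's nonlinear diagonal block by a
#' small Newton iteration (Picard fallback on failure).
#'
#' @param h hierarchy.
#' @param kappa level.
#' @param sys a `tmg_system`.
#' @param nu number of sweeps.
#' @param cfg a [solver_config()].
#' @return the updated hierarchy.
#' @export
smooth <- function(h, kappa, sys, nu, cfg) {
  un <- sys_unknowns(sys)
  bcs <- sys_bcs(sys)
  sweep_once <- function(h, depth_by_block) {
    h <- fill_ghosts(h, kappa, un, bcs)
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      upd <- sys_sweep_block(sys, lv$blocks[[ib]], lv$eta,
                             color = 2L, depth = depth_by_block[ib])
      for (u in un) lv$blocks[[ib]]$data[[u]] <- upd[[u]]
    }
    set_level(h, kappa, lv)
  }
  lv <- get_level(h, kappa)
  nb <- length(lv$blocks)
  if (nb == 0L) return(h)
  if (nu > 0L)
    for (s in seq_len(nu)) h <- sweep_once(h, rep(0L, nb))
  if (cfg$nu_b > 0L && nu > 0L) {
    depths <- vapply(lv$blocks, function(b) d_kappa_depth(h, kappa, b),
                     integer(1))
    for (s in seq_len(cfg$nu_b)) h <- sweep_once(h, depths)
  }
  h
}

#' Scaled discrete l2 residual norm on a level
#'
#' `sqrt(sum(residual^2) / n)` over the interior cells of all blocks of the
#' level (summed over all unknowns of the system).  With
#' `exclude_finer = TRUE`, cells covered by level `kappa + 1` blocks are
#' excluded (finest data wins on overlaps).
#'
#' @inheritParams smooth
#' @param exclude_finer drop cells under the next finer level.
#' @return the residual norm (0 for an empty level).
#' @export
residual_norm <- function(h, kappa, sys, exclude_finer = FALSE) {
  lv <- get_level(h, kappa)
  if (length(lv$blocks) == 0L) return(0)
  fine_boxes <- NULL
  if (exclude_finer && kappa < h$kappa_max) {
    fine_boxes <- lapply(get_level(h, kappa + 1L)$blocks, function(b)
      list(lo = (b$lo + 1L) %/% 2L, hi = b$hi %/% 2L))
  }
  ss <- 0; n <- 0
  for (b in lv$blocks) {
    res <- sys_residual_block(sys, b, lv$eta)
    mask <- array(TRUE, block_dims(b))
    if (!is.null(fine_boxes)) {
      for (fb in fine_boxes) {
        il <- pmax(fb$lo, b$lo); ih <- pmin(fb$hi, b$hi)
        if (any(il > ih)) next
        mask[(il[1] - b$lo[1] + 1L):(ih[1] - b$lo[1] + 1L),
             (il[2] - b$lo[2] + 1L):(ih[2] - b$lo[2] + 1L),
             (il[3] - b$lo[3] + 1L):(ih[3] - b$lo[3] + 1L)] <- FALSE
      }
    }
    for (u in sys_unknowns(sys)) {
      r <- interior(res[[u]])
      ss <- ss + sum(r[mask]^2)
      n <- n + sum(mask)
    }
  }
  if (n == 0L) return(0)
  sqrt(ss / n)
}

# reset working RHS from base on a level
reset_rhs <- function(h, kappa, sys) {
  lv <- get_level(h, kappa)
  for (ib in seq_along(lv$blocks))
    for (u in sys_unknowns(sys))
      lv$blocks[[ib]]$data[[paste0("R_", u)]] <-
        lv$blocks[[ib]]$data[[paste0("R0_", u)]]
  set_level(h, kappa, lv)
}

#' Recursive adaptive FAS cycle
#'
#' One multigrid cycle at level `kappa`: pre-smoothing, restriction of the
#' iterate to the overlap of the level below, construction of the coarse
#' right-hand side with the tau (relative truncation) correction on the
#' overlap (the coarse level's own RHS is kept elsewhere), recursive coarse
#' solve (or `nu0` smoothing at the coarsest level), coarse-grid correction
#' prolonged trilinearly and added on the overlap, and post-smoothing, with
#' ghost updates between stages.  On a single-level hierarchy the cycle
#' reduces to `nu1 + nu2` smoothing sweeps.
#'
#' @inheritParams smooth
#' @return the updated hierarchy.
#' @export
adapfas_cycle <- function(h, kappa, sys, cfg) {
  if (kappa < h$kappa_min) stop("recursion below the coarsest level")
  un <- sys_unknowns(sys)
  bcs <- sys_bcs(sys)
  h <- smooth(h, kappa, sys, cfg$nu1, cfg)
  has_coarse <- kappa > h$kappa_min &&
    length(get_level(h, kappa - 1L)$blocks) > 0L
  if (has_coarse) {
    h <- fill_ghosts(h, kappa, un, bcs)
    lv <- get_level(h, kappa)
    eta_f <- lv$eta
    # residual on the fine level, restricted per block
    stash <- list()
    for (ib in seq_along(lv$blocks)) {
      b <- lv$blocks[[ib]]
      res <- sys_residual_block(sys, b, eta_f)
      clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
      rr <- lapply(res, function(a) restrict_avg(interior(a)))
      stash[[ib]] <- list(clo = clo, chi = chi, res = rr)
      # restrict the iterate onto the coarse overlap
      for (u in un)
        h <- deposit_box(h, kappa - 1L, clo, chi, u,
                         restrict_avg(interior(b$data[[u]])))
    }
    h <- fill_ghosts(h, kappa - 1L, un, bcs)
    clv <- get_level(h, kappa - 1L)
    # snapshot of the initialized coarse iterate (for the correction)
    psi0 <- lapply(clv$blocks, function(cb) cb$data[un])
    # working RHS: base everywhere, tau-corrected on the overlap
    h <- reset_rhs(h, kappa - 1L, sys)
    clv <- get_level(h, kappa - 1L)
    for (icb in seq_along(clv$blocks)) {
      cb <- clv$blocks[[icb]]
      Lc <- sys_apply_block(sys, cb, clv$eta)
      for (ent in stash) {
        il <- pmax(ent$clo, cb$lo); ih <- pmin(ent$chi, cb$hi)
        if (any(il > ih)) next
        si <- (il[1] - ent$clo[1] + 1L):(ih[1] - ent$clo[1] + 1L)
        sj <- (il[2] - ent$clo[2] + 1L):(ih[2] - ent$clo[2] + 1L)
        sk <- (il[3] - ent$clo[3] + 1L):(ih[3] - ent$clo[3] + 1L)
        ci <- (il[1] - cb$lo[1] + 2L):(ih[1] - cb$lo[1] + 2L)
        cj <- (il[2] - cb$lo[2] + 2L):(ih[2] - cb$lo[2] + 2L)
        ck <- (il[3] - cb$lo[3] + 2L):(ih[3] - cb$lo[3] + 2L)
        for (u in un) {
          w <- cb$data[[paste0("R_", u)]]
          w[ci, cj, ck] <- ent$res[[u]][si, sj, sk, drop = FALSE] +
            Lc[[u]][ci, cj, ck]
          cb$data[[paste0("R_", u)]] <- w
        }
      }
      clv$blocks[[icb]] <- cb
    }
    h <- set_level(h, kappa - 1L, clv)
    # coarse solve
    if (kappa - 1L == h$kappa_min) {
      h <- solve_coarsest(h, sys, cfg)
    } else {
      for (g in seq_len(cfg$gamma))
        h <- adapfas_cycle(h, kappa - 1L, sys, cfg)
    }
    h <- fill_ghosts(h, kappa - 1L, un, bcs)
    clv <- get_level(h, kappa - 1L)
    # coarse-grid correction: e = psi_bar - psi0 on the overlap, prolonged
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      b <- lv$blocks[[ib]]
      clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
      for (u in un) {
        ebar <- extract_box(h, kappa - 1L, clo - 1L, chi + 1L, u)
        e0 <- extract_box_snapshot(clv$blocks, psi0, u, clo - 1L, chi + 1L)
        e <- ebar - e0
        corr <- prolong_linear(e)
        a <- b$data[[u]]
        interior(a) <- interior(a) + corr
        b$data[[u]] <- a
      }
      lv$blocks[[ib]] <- b
    }
    h <- set_level(h, kappa, lv)
  }
  h <- smooth(h, kappa, sys, cfg$nu2, cfg)
  fill_ghosts(h, kappa, un, bcs)
}

# extract_box over a saved snapshot of block data (same block geometry)
extract_box_snapshot <- function(blocks, snap, field, lo, hi) {
  out <- array(NA_real_, hi - lo + 1L)
  for (pass in 1:2) {
    for (jb in seq_along(blocks)) {
      b <- blocks[[jb]]
      ext <- if (pass == 1L) 0L else 1L
      il <- pmax(lo, b$lo - ext); ih <- pmin(hi, b$hi + ext)
      if (any(il > ih)) next
      src <- snap[[jb]][[field]]
      tgt <- out[(il[1] - lo[1] + 1L):(ih[1] - lo[1] + 1L),
                 (il[2] - lo[2] + 1L):(ih[2] - lo[2] + 1L),
                 (il[3] - lo[3] + 1L):(ih[3] - lo[3] + 1L), drop = FALSE]
      na <- is.na(tgt)
      if (!any(na)) next
      rep_ <- src[(il[1] - b$lo[1] + 2L):(ih[1] - b$lo[1] + 2L),
                  (il[2] - b$lo[2] + 2L):(ih[2] - b$lo[2] + 2L),
                  (il[3] - b$lo[3] + 2L):(ih[3] - b$lo[3] + 2L), drop = FALSE]
      tgt[na] <- rep_[na]
      out[(il[1] - lo[1] + 1L):(ih[1] - lo[1] + 1L),
          (il[2] - lo[2] + 1L):(ih[2] - lo[2] + 1L),
          (il[3] - lo[3] + 1L):(ih[3] - lo[3] + 1L)] <- tgt
    }
  }
  out
}

# cubic FMG interpolation of the solution from level kappa to the blocks of
# level kappa+1 (initial-guess transfer, the Pi operator)
pi_interp_level <- function(h, kappa, fields, bcs) {
  lv1 <- get_level(h, kappa + 1L)
  if (length(lv1$blocks) == 0L) return(h)
  h <- fill_ghosts(h, kappa, fields, bcs)
  for (ib in seq_along(lv1$blocks)) {
    b <- lv1$blocks[[ib]]
    clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
    for (f in fields) {
      cp <- extract_box(h, kappa, clo - 2L, chi + 2L, f)
      a <- b$data[[f]]
      interior(a) <- fmg_interp_cubic(cp, margin = 2L)
      lv1$blocks[[ib]]$data[[f]] <- a
    }
  }
  h <- set_level(h, kappa + 1L, lv1)
  fill_ghosts(h, kappa + 1L, fields, bcs)
}

#' Adaptive full-multigrid solve
#'
#' Runs the FMG pass over the hierarchy: `nu0` smoothing at the coarsest
#' level; `r_kappa` cycles per global level below the root; on levels
#' `kappa >= 0`, cycles until the level residual norm drops below
#' `tol_kappa = tol_min * sigma^(kappa_max - kappa)`; after a level
#' converges, the solution is interpolated cubically upward as the finer
#' level's initial guess.  An optional `regrid` hook is called after each
#' level `0 <= kappa < kappa_max` converges and may rebuild level
#' `kappa + 1` (flag + cluster + migrate); without it, existing finer blocks
#' just receive the interpolated initial guess.
#'
#' @inheritParams smooth
#' @param cfg a [solver_config()].
#' @param regrid optional `function(h, kappa)` returning the hierarchy with
#'   level `kappa + 1` rebuilt.
#' @param verbose print per-level cycle counts and residuals.
#' @return list with the hierarchy (`h`), per-level cycle counts
#'   (`cycles`), and final residual norms (`residuals`).
#' @export
fmg_solve <- function(h, sys, cfg, regrid = NULL, verbose = FALSE) {
  un <- sys_unknowns(sys)
  bcs <- sys_bcs(sys)
  kmax <- h$kappa_max
  cycles <- setNames(integer(kmax - h$kappa_min + 1L),
                     as.character(h$kappa_min:kmax))
  resid <- setNames(rep(NA_real_, length(cycles)), names(cycles))
  for (kappa in h$kappa_min:kmax) {
    if (length(get_level(h, kappa)$blocks) == 0L) break
    h <- reset_rhs(h, kappa, sys)
    if (kappa == h$kappa_min && kappa < kmax) {
      h <- solve_coarsest(h, sys, cfg)
    } else if (kappa < 0L) {
      for (r in seq_len(cfg$r_kappa)) {
        h <- adapfas_cycle(h, kappa, sys, cfg)
        cycles[as.character(kappa)] <- cycles[as.character(kappa)] + 1L
      }
    } else {
      tol_k <- cfg$tol_min * cfg$sigma^(kmax - kappa)
      r <- 0L
      repeat {
        r <- r + 1L
        h <- adapfas_cycle(h, kappa, sys, cfg)
        rn <- residual_norm(h, kappa, sys)
        if (verbose)
          message(sprintf("  level %+d cycle %d residual %.3e (tol %.3e)",
                          kappa, r, rn, tol_k))
        if (rn <= tol_k) break
        if (r >= cfg$max_outer)
          stop(sprintf(
            "fmg_solve[%s]: level %d did not reach tol %.3e in %d cycles (residual %.3e)",
            paste(un, collapse = ","), kappa, tol_k, cfg$max_outer, rn))
      }
      cycles[as.character(kappa)] <- r
      resid[as.character(kappa)] <- rn
    }
    if (kappa < kmax) {
      if (kappa >= 0L && !is.null(regrid)) h <- regrid(h, kappa)
      h <- pi_interp_level(h, kappa, un, bcs)
    }
  }
  list(h = h, cycles = cycles, residuals = resid)
}

# relative truncation error tau = L_{k-1}(R psi) - R(L_k psi) on the coarse
# cells under level kappa; returns a list of per-coarse-overlap entries
tau_coarse <- function(h, kappa, sys) {
  un <- sys_unknowns(sys)
  bcs <- sys_bcs(sys)
  h <- fill_ghosts(h, kappa, un, bcs)
  lv <- get_level(h, kappa)
  out <- list()
  for (b in lv$blocks) {
    clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
    for (u in un)
      h <- deposit_box(h, kappa - 1L, clo, chi, u,
                       restrict_avg(interior(b$data[[u]])))
  }
  h <- fill_ghosts(h, kappa - 1L, un, bcs)
  clv <- get_level(h, kappa - 1L)
  for (b in lv$blocks) {
    clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
    Lf <- sys_apply_block(sys, b, lv$eta)
    tau_tot <- array(0, chi - clo + 1L)
    for (icb in seq_along(clv$blocks)) {
      cb <- clv$blocks[[icb]]
      Lc <- sys_apply_block(sys, cb, clv$eta)
      il <- pmax(clo, cb$lo); ih <- pmin(chi, cb$hi)
      if (any(il > ih)) next
      for (u in un) {
        RLf <- restrict_avg(interior(Lf[[u]]))
        tau_tot[(il[1] - clo[1] + 1L):(ih[1] - clo[1] + 1L),
                (il[2] - clo[2] + 1L):(ih[2] - clo[2] + 1L),
                (il[3] - clo[3] + 1L):(ih[3] - clo[3] + 1L)] <-
          tau_tot[(il[1] - clo[1] + 1L):(ih[1] - clo[1] + 1L),
                  (il[2] - clo[2] + 1L):(ih[2] - clo[2] + 1L),
                  (il[3] - clo[3] + 1L):(ih[3] - clo[3] + 1L)] +
          (Lc[[u]][(il[1] - cb$lo[1] + 2L):(ih[1] - cb$lo[1] + 2L),
                   (il[2] - cb$lo[2] + 2L):(ih[2] - cb$lo[2] + 2L),
                   (il[3] - cb$lo[3] + 2L):(ih[3] - cb$lo[3] + 2L)] -
             RLf[(il[1] - clo[1] + 1L):(ih[1] - clo[1] + 1L),
                 (il[2] - clo[2] + 1L):(ih[2] - clo[2] + 1L),
                 (il[3] - clo[3] + 1L):(ih[3] - clo[3] + 1L)])
      }
    }
    out[[length(out) + 1L]] <- list(clo = clo, chi = chi, tau = tau_tot)
  }
  out
}
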