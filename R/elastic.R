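# ---------------------------------------------------------------------------
# ECM elastic energy: strain/stress assembly, the chemical-potential
# contribution dW/dphi_E, and the displacement solve div(T) = 0.
#
# The eigenstrains of ECM and cells are taken isotropic (scalar magnitude
# times the identity); the Lame coefficients interpolate between the cell
# and ECM phases through Q3(phi_E).  Elasticity is disabled by default
# (eps_e = 0) since its constants are placeholder values.
# ---------------------------------------------------------------------------

# centered cell derivative along axis ax; interior-sized result
grad_centered <- function(a, eta, ax) {
  d <- dim(a)
  idx <- list(2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L))
  lo <- idx; lo[[ax]] <- idx[[ax]] - 1L
  hi <- idx; hi[[ax]] <- idx[[ax]] + 1L
  (a[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] -
     a[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]) / (2 * eta)
}

# strain, total strain (minus eigenstrain), stress and stress-jump tensors
# on the interior of one block; components named 11,22,33,12,13,23
elastic_state_block <- function(b, params, eta, prev = FALSE) {
  P <- params
  sfx <- if (prev) "_prev" else ""
  pE <- interior(b$data[[paste0("phi_E", sfx)]])
  q <- P$Q3(pE)
  d <- dim(b$data[[paste0("phi_E", sfx)]])
  u <- lapply(1:3, function(i) {
    f <- paste0("u_", i)
    if (!is.null(b$data[[f]])) b$data[[f]] else array(0, d)
  })
  E <- list()
  for (m in 1:3) for (n in m:3) {
    E[[paste0(m, n)]] <- 0.5 * (grad_centered(u[[m]], eta, n) +
                                  grad_centered(u[[n]], eta, m))
  }
  estar_T <- P$estar_E - P$estar_C          # eigenstrain jump (isotropic)
  ET <- E
  for (m in 1:3) {
    mm <- paste0(m, m)
    ET[[mm]] <- E[[mm]] - (q * estar_T + P$estar_C)
  }
  L1 <- q * (P$L1E - P$L1C) + P$L1C
  L2 <- q * (P$L2E - P$L2C) + P$L2C
  trET <- ET[["11"]] + ET[["22"]] + ET[["33"]]
  TT <- Tst <- list()
  for (m in 1:3) for (n in m:3) {
    mn <- paste0(m, n)
    dl <- as.numeric(m == n)
    TT[[mn]] <- 2 * L2 * ET[[mn]] + dl * L1 * trET
    Tst[[mn]] <- 2 * (1 - P$L2C) * ET[[mn]] + dl * (P$L1E - P$L1C) * trET
  }
  list(E = E, ET = ET, TT = TT, Tst = Tst, trET = trET, q = q, pE = pE,
       estar_T = estar_T)
}

#' Elastic contribution to the ECM chemical potential
#'
#' `dW/dphi_E = eps_e [6 phi_E (1 - phi_E)] *
#'   sum_ij [ (1/2) (E_T)_ij T*_ij - (E*_T)_ij T_ij ]`
#' evaluated pointwise on one block (zero array when `eps_e = 0`).
#'
#' @param b a `tmg_block` carrying `phi_E` (and `u_1..u_3` if a
#'   displacement has been solved).
#' @param params a [model_params()].
#' @param eta mesh spacing.
#' @param prev use the `_prev` phase fields.
#' @return ghost-padded array (interior valid, ghosts zero).
#' @export
elastic_dW_block <- function(b, params, eta, prev = FALSE) {
  sfx <- if (prev) "_prev" else ""
  d <- dim(b$data[[paste0("phi_E", sfx)]])
  out <- array(0, d)
  if (params$eps_e == 0) return(out)
  st <- elastic_state_block(b, params, eta, prev)
  contr <- 0
  for (m in 1:3) for (n in m:3) {
    mn <- paste0(m, n)
    w <- if (m == n) 1 else 2          # off-diagonal pairs count twice
    contr <- contr + w * 0.5 * st$ET[[mn]] * st$Tst[[mn]]
  }
  # (E*_T)_ij T_ij with isotropic eigenstrain jump: estar_T * tr(T)
  trT <- st$TT[["11"]] + st$TT[["22"]] + st$TT[["33"]]
  contr <- contr - st$estar_T * trT
  interior(out) <- params$eps_e * 6 * st$pE * (1 - st$pE) * contr
  out
}

#' Solve the mechanical equilibrium for the displacement field
#'
#' Finds `u_d` with `div(T) = 0` and zero boundary displacement by damped
#' pseudo-time relaxation on the root level's uniform grid; the stress is
#' reassembled from the current displacement every iteration.  With zero
#' eigenstrains the solution is `u = 0` and the iteration exits
#' immediately.
#'
#' @param h hierarchy (fields `u_1..u_3` are created on the root if absent).
#' @param params a [model_params()]; Lame constants must be positive.
#' @param tol residual tolerance (scaled l2 of `div T`).
#' @param max_iter iteration cap.
#' @return list with the updated hierarchy and the final residual.
#' @export
solve_displacement <- function(h, params, tol = 1e-6, max_iter = 2000L) {
  P <- params
  if (min(P$L1E, P$L2E, P$L1C, P$L2C) <= 0)
    stop("Lame constants must be positive")
  lv <- get_level(h, 0L)
  b <- lv$blocks[[1]]
  eta <- lv$eta
  d <- dim(b$data$phi_E)
  for (i in 1:3)
    if (is.null(b$data[[paste0("u_", i)]]))
      b$data[[paste0("u_", i)]] <- array(0, d)
  ubc <- bc("dirichlet", 0)
  tau <- eta^2 / (8 * (2 * max(P$L2E, P$L2C) + max(P$L1E, P$L1C)))
  res <- Inf
  for (it in seq_len(max_iter)) {
    for (i in 1:3)
      b$data[[paste0("u_", i)]] <-
        apply_bc_array(b$data[[paste0("u_", i)]], ubc, b$lo, b$hi,
                       level_ncells_domain(h, 0L))
    st <- elastic_state_block(b, P, eta)
    # pad stress components to take centered derivatives (zero-extended)
    Tpad <- lapply(st$TT, function(a) {
      out <- array(0, d); interior(out) <- a; out
    })
    comp <- function(m, n) Tpad[[paste0(min(m, n), max(m, n))]]
    rs <- 0
    for (i in 1:3) {
      div_i <- grad_centered(comp(i, 1), eta, 1L) +
        grad_centered(comp(i, 2), eta, 2L) +
        grad_centered(comp(i, 3), eta, 3L)
      rs <- rs + sum(div_i^2)
      ui <- b$data[[paste0("u_", i)]]
      interior(ui) <- interior(ui) + tau * div_i
      b$data[[paste0("u_", i)]] <- ui
    }
    res <- sqrt(rs / (3 * prod(d - 2L)))
    if (res <= tol) break
  }
  lv$blocks[[1]] <- b
  h <- set_level(h, 0L, lv)
  list(h = h, residual = res)
}
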