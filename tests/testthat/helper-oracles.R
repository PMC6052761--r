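# Independent reference implementations used as oracles: plain dense arrays
# and scalar loops, no use of the package's block/transfer machinery.

# pad an interior array with Dirichlet-0 ghosts (2*v - interior convention)
pad_dirichlet0 <- function(u) {
  d <- dim(u)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- u
  p[1, , ] <- -p[2, , ]; p[d[1] + 2L, , ] <- -p[d[1] + 1L, , ]
  p[, 1, ] <- -p[, 2, ]; p[, d[2] + 2L, ] <- -p[, d[2] + 1L, ]
  p[, , 1] <- -p[, , 2]; p[, , d[3] + 2L] <- -p[, , d[3] + 1L]
  p
}

# dense 7-point operator a*u - lap(u) with Dirichlet-0 boundary
dense_helmholtz_apply <- function(u, acoef, eta) {
  p <- pad_dirichlet0(u)
  d <- dim(u)
  i <- 2:(d[1] + 1L); j <- 2:(d[2] + 1L); k <- 2:(d[3] + 1L)
  lap <- (p[i + 1L, j, k] + p[i - 1L, j, k] + p[i, j + 1L, k] +
            p[i, j - 1L, k] + p[i, j, k + 1L] + p[i, j, k - 1L] -
            6 * p[i, j, k]) / eta^2
  acoef * u - lap
}

# one scalar-loop Red-Black Gauss-Seidel sweep (red = even 1-based index
# sum, then black); ghosts frozen during the sweep, Dirichlet 0
dense_rbgs_sweep <- function(u, f, acoef, eta) {
  d <- dim(u)
  p <- pad_dirichlet0(u)
  for (color in 0:1) {
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      if ((i + j + k) %% 2L != color) next
      nsum <- (p[i, j + 1L, k + 1L] + p[i + 2L, j + 1L, k + 1L] +
                 p[i + 1L, j, k + 1L] + p[i + 1L, j + 2L, k + 1L] +
                 p[i + 1L, j + 1L, k] + p[i + 1L, j + 1L, k + 2L]) / eta^2
      p[i + 1L, j + 1L, k + 1L] <-
        (f[i, j, k] + nsum) / (acoef + 6 / eta^2)
    }
  }
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# dense classical two-grid FAS cycle for -lap(u) = f (Dirichlet 0):
# nu1 pre-smoothing RB-GS sweeps on the fine grid, coarse initialization by
# 8-child averaging, coarse RHS = restrict(residual) + Lc(R u), nu0 coarse
# RB-GS sweeps, trilinear prolongation of the correction (Dirichlet-0
# ghosts), nu2 post-smoothing.
dense_twogrid_fas <- function(u, f, eta, nu1 = 2L, nu2 = 2L, nu0 = 4L) {
  for (s in seq_len(nu1)) u <- dense_rbgs_sweep(u, f, 0, eta)
  # residual and restriction
  r <- f - dense_helmholtz_apply(u, 0, eta)
  rst <- function(a) {
    d <- dim(a)
    i1 <- seq.int(1L, d[1], 2L); j1 <- seq.int(1L, d[2], 2L)
    k1 <- seq.int(1L, d[3], 2L)
    (a[i1, j1, k1] + a[i1 + 1L, j1, k1] + a[i1, j1 + 1L, k1] +
       a[i1 + 1L, j1 + 1L, k1] + a[i1, j1, k1 + 1L] +
       a[i1 + 1L, j1, k1 + 1L] + a[i1, j1 + 1L, k1 + 1L] +
       a[i1 + 1L, j1 + 1L, k1 + 1L]) / 8
  }
  uc0 <- rst(u)
  etac <- 2 * eta
  fc <- rst(r) + dense_helmholtz_apply(uc0, 0, etac)
  uc <- uc0
  for (s in seq_len(nu0)) uc <- dense_rbgs_sweep(uc, fc, 0, etac)
  e <- uc - uc0
  # trilinear prolongation with Dirichlet-0 ghosts on the correction
  ep <- pad_dirichlet0(e)
  dc <- dim(e)
  ef <- array(0, 2L * dc)
  ic <- 2:(dc[1] + 1L); jc <- 2:(dc[2] + 1L); kc <- 2:(dc[3] + 1L)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    sx <- 2L * ox - 1L; sy <- 2L * oy - 1L; sz <- 2L * oz - 1L
    val <- (27 * ep[ic, jc, kc] +
              9 * (ep[ic + sx, jc, kc] + ep[ic, jc + sy, kc] +
                     ep[ic, jc, kc + sz]) +
              3 * (ep[ic + sx, jc + sy, kc] + ep[ic + sx, jc, kc + sz] +
                     ep[ic, jc + sy, kc + sz]) +
              ep[ic + sx, jc + sy, kc + sz]) / 64
    ef[seq.int(1L + ox, 2L * dc[1], 2L), seq.int(1L + oy, 2L * dc[2], 2L),
       seq.int(1L + oz, 2L * dc[3], 2L)] <- val
  }
  u <- u + ef
  for (s in seq_len(nu2)) u <- dense_rbgs_sweep(u, f, 0, eta)
  u
}

# sample a function of (x, y, z) on the padded cell centers of a block
sample_on_block <- function(h, kappa, block, fn) {
  lv <- get_level(h, kappa)
  geo <- cell_geometry(lv, block, h$domain)
  out <- array(0, tumormg:::block_dims(block) + 2L)
  for (i in seq_along(geo$centers[[1]]))
    for (j in seq_along(geo$centers[[2]]))
      for (k in seq_along(geo$centers[[3]]))
        out[i, j, k] <- fn(geo$centers[[1]][i], geo$centers[[2]][j],
                           geo$centers[[3]][k])
  out
}

# build a single-level (or global-only) hierarchy carrying one scalar field
# system u with given rhs field and coefficients
make_scalar_hierarchy <- function(root, n_global, kappa_max = 0L,
                                  domain = list(L = c(0, 0, 0),
                                                R = c(1, 1, 1))) {
  h <- build_hierarchy(domain, rep(root, 3L), n_global, kappa_max)
  tumormg:::map_blocks(h, function(b, lv) {
    tumormg:::block_add_fields(b, c("u", "R0_u", "R_u", "a0", "k1"))
  }) -> h
  tumormg:::map_blocks(h, function(b, lv) {
    b$data$k1 <- array(1, dim(b$data$u))
    b
  })
}

# interior view shortcuts
intr <- function(a) tumormg:::interior(a)
interior <- function(a) tumormg:::interior(a)
`interior<-` <- function(arr, value) {
  d <- dim(arr)
  arr[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] <- value
  arr
}

# mini driver: one Crank-Nicolson Cahn-Hilliard step on a fixture hierarchy
ch_fixture_step <- function(h, params, theta, bcs, cfg) {
  h <- tumormg:::map_blocks(h, function(b, lv) {
    for (f in c("phi_V", "phi_D", "phi_E", "mu_T", "mu_E"))
      b$data[[paste0(f, "_prev")]] <- b$data[[f]]
    b
  })
  for (k in h$kappa_min:h$kappa_max) {
    if (length(tumormg:::get_level(h, k)$blocks) == 0L) next
    h <- tumormg:::build_ch_rhs_level(h, k, params, theta)
  }
  sys <- ch_system(params, theta, bcs = bcs)
  fmg_solve(h, sys, cfg)$h
}
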