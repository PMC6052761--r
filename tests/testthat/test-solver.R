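test_that("Red-Black relaxation matches a scalar-loop reference sweep
          exactly and is the identity at a fixed point", {
  set.seed(5)
  n <- 6L
  h <- make_scalar_hierarchy(n, 1L)
  eta <- get_level(h, 0)$eta
  u0 <- array(rnorm(n^3), rep(n, 3))
  f0 <- array(rnorm(n^3), rep(n, 3))
  h <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$u) <- u0
    interior(b$data$R_u) <- f0
    b$data$a0 <- array(1.5, dim(b$data$u))
    b
  })
  sys <- scalar_system("u", bc("dirichlet", 0), "a0", "k1")
  cfg <- solver_config(nu_b = 0L)
  h1 <- smooth(h, 0, sys, 1L, cfg)
  ref <- u0
  # reference sweep with acoef 1.5 (adapting the Poisson oracle update)
  d <- rep(n, 3L)
  p <- pad_dirichlet0(ref)
  for (color in 0:1) for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    if ((i + j + k) %% 2L != color) next
    nsum <- (p[i, j + 1, k + 1] + p[i + 2, j + 1, k + 1] +
               p[i + 1, j, k + 1] + p[i + 1, j + 2, k + 1] +
               p[i + 1, j + 1, k] + p[i + 1, j + 1, k + 2]) / eta^2
    p[i + 1, j + 1, k + 1] <- (f0[i, j, k] + nsum) / (1.5 + 6 / eta^2)
  }
  ref <- p[2:(n + 1), 2:(n + 1), 2:(n + 1)]
  got <- intr(get_level(h1, 0)$blocks[[1]]$data$u)
  expect_lt(max(abs(got - ref)), 1e-13)

  # zero sweeps are the identity
  h0 <- smooth(h, 0, sys, 0L, cfg)
  expect_identical(intr(get_level(h0, 0)$blocks[[1]]$data$u), u0)

  # an exact discrete solution is a fixed point of the smoother
  uex <- array(rnorm(n^3), rep(n, 3))
  fex <- dense_helmholtz_apply(uex, 1.5, eta)
  h2 <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$u) <- uex
    interior(b$data$R_u) <- fex
    b
  })
  h2s <- smooth(h2, 0, sys, 3L, cfg)
  expect_lt(max(abs(intr(get_level(h2s, 0)$blocks[[1]]$data$u) - uex)),
            1e-11)
})

test_that("residual norms are scaled l2 over interior cells", {
  set.seed(6)
  n <- 6L
  h <- make_scalar_hierarchy(n, 1L)
  eta <- get_level(h, 0)$eta
  u0 <- array(rnorm(n^3), rep(n, 3))
  f0 <- array(rnorm(n^3), rep(n, 3))
  h <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$u) <- u0
    interior(b$data$R_u) <- f0
    b$data$a0 <- array(2, dim(b$data$u))
    b
  })
  sys <- scalar_system("u", bc("dirichlet", 0), "a0", "k1")
  h <- fill_ghosts(h, 0, "u", list(u = bc("dirichlet", 0)))
  # matches the dense computation
  rd <- f0 - dense_helmholtz_apply(u0, 2, eta)
  expect_equal(residual_norm(h, 0, sys), sqrt(mean(rd^2)))
  # exact solution -> 0; constant residual -> |c|
  hx <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$R_u) <- dense_helmholtz_apply(u0, 2, eta)
    b
  })
  expect_lt(residual_norm(hx, 0, sys), 1e-12)
  hc <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$R_u) <- dense_helmholtz_apply(u0, 2, eta) - 0.7
    b
  })
  expect_equal(residual_norm(hc, 0, sys), 0.7)
})

test_that("a cycle on a single-level hierarchy is nu1+nu2 smoothing", {
  set.seed(7)
  n <- 6L
  h <- make_scalar_hierarchy(n, 1L)
  u0 <- array(rnorm(n^3), rep(n, 3))
  f0 <- array(rnorm(n^3), rep(n, 3))
  h <- tumormg:::map_blocks(h, function(b, lv) {
    interior(b$data$u) <- u0
    interior(b$data$R_u) <- f0
    b$data$a0 <- array(1, dim(b$data$u))
    b
  })
  sys <- scalar_system("u", bc("dirichlet", 0), "a0", "k1")
  cfg <- solver_config(nu1 = 2L, nu2 = 1L, nu_b = 0L)
  h1 <- adapfas_cycle(h, 0, sys, cfg)
  h2 <- smooth(h, 0, sys, 3L, cfg)
  expect_equal(intr(get_level(h1, 0)$blocks[[1]]$data$u),
               intr(get_level(h2, 0)$blocks[[1]]$data$u), tolerance = 1e-14)
})

test_that("the adaptive two-level cycle on an everything-refined mesh
          matches the dense two-grid FAS oracle", {
  set.seed(8)
  nC <- 8L; nF <- 16L
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       rep(nC, 3L), 1L, 1L)
  h <- tumormg:::map_blocks(h, function(b, lv) {
    b <- tumormg:::block_add_fields(b, c("u", "R0_u", "R_u", "a0", "k1"))
    b$data$k1 <- array(1, dim(b$data$u))
    b
  })
  lv1 <- get_level(h, 1)
  b1 <- tumormg:::block_add_fields(
    tumormg:::new_block(c(1L, 1L, 1L), rep(nF, 3L)),
    c("u", "R0_u", "R_u", "a0", "k1"))
  b1$data$k1 <- array(1, dim(b1$data$u))
  u0 <- array(rnorm(nF^3), rep(nF, 3))
  f0 <- array(rnorm(nF^3), rep(nF, 3))
  interior(b1$data$u) <- u0
  interior(b1$data$R_u) <- f0
  interior(b1$data$R0_u) <- f0
  lv1$blocks <- list(b1)
  h <- tumormg:::set_level(h, 1, lv1)
  etaF <- get_level(h, 1)$eta
  cfg <- solver_config(nu1 = 2L, nu2 = 2L, nu0 = 4L, nu_b = 0L,
                       coarse_solver = "nu0")
  h1 <- adapfas_cycle(h, 1, sys <- scalar_system("u", bc("dirichlet", 0),
                                                 "a0", "k1"), cfg)
  got <- intr(get_level(h1, 1)$blocks[[1]]$data$u)
  ref <- dense_twogrid_fas(u0, f0, etaF, nu1 = 2L, nu2 = 2L, nu0 = 4L)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("inserting the exact discrete solution yields zero coarse
          correction", {
  # FAS consistency: with the iterate already exact and smoothing disabled,
  # the cycle leaves it unchanged
  set.seed(9)
  nC <- 4L; nF <- 8L
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       rep(nC, 3L), 1L, 1L)
  h <- tumormg:::map_blocks(h, function(b, lv) {
    b <- tumormg:::block_add_fields(b, c("u", "R0_u", "R_u", "a0", "k1"))
    b$data$k1 <- array(1, dim(b$data$u))
    b
  })
  lv1 <- get_level(h, 1)
  b1 <- tumormg:::block_add_fields(
    tumormg:::new_block(c(1L, 1L, 1L), rep(nF, 3L)),
    c("u", "R0_u", "R_u", "a0", "k1"))
  b1$data$k1 <- array(1, dim(b1$data$u))
  uex <- array(rnorm(nF^3), rep(nF, 3))
  etaF <- 1 / nF
  fex <- dense_helmholtz_apply(uex, 0, etaF)
  interior(b1$data$u) <- uex
  interior(b1$data$R_u) <- fex
  interior(b1$data$R0_u) <- fex
  lv1$blocks <- list(b1)
  h <- tumormg:::set_level(h, 1, lv1)
  cfg <- solver_config(nu1 = 0L, nu2 = 0L, nu0 = 0L, nu_b = 0L,
                       coarse_solver = "nu0")
  h1 <- adapfas_cycle(h, 1, scalar_system("u", bc("dirichlet", 0),
                                          "a0", "k1"), cfg)
  got <- intr(get_level(h1, 1)$blocks[[1]]$data$u)
  expect_lt(max(abs(got - uex)), 1e-12)
})

test_that("one Crank-Nicolson heat step matches a dense linear-algebra
          oracle", {
  n <- 6L; theta <- 1e-3
  fx <- fixture_generators("heat_mms", root_cells = n, theta = theta)
  h <- fx$advance_rhs(fx$h)
  cfg <- solver_config(tol_min = 1e-12, theta = theta)
  out <- fmg_solve(h, fx$sys, cfg)
  got <- intr(get_level(out$h, 0)$blocks[[1]]$data$u)
  # dense CN system: (2/theta) u1 - lap u1 = (2/theta) u0 + lap u0
  eta <- 1 / n
  u0 <- intr(get_level(fx$h, 0)$blocks[[1]]$data$u)
  rhs <- (2 / theta) * u0 - dense_helmholtz_apply(u0, 0, eta)
  N <- n^3
  A <- matrix(0, N, N)
  for (c in seq_len(N)) {
    e <- numeric(N); e[c] <- 1
    A[, c] <- as.vector(dense_helmholtz_apply(array(e, rep(n, 3)),
                                              2 / theta, eta))
  }
  ref <- array(solve(A, as.vector(rhs)), rep(n, 3))
  expect_lt(max(abs(got - ref)), 1e-8)
  # steady input: theta -> equations satisfied by the old solution when
  # the rhs is built from it and the operator is linear
  expect_true(all(is.finite(got)))
})

test_that("FMG reaches discretization accuracy with mesh-independent
          cycle counts on the Poisson fixture", {
  cfg <- solver_config(tol_min = 1e-8)
  errs <- numeric(0); cycles <- integer(0)
  for (root in c(8L, 16L, 32L)) {
    ng <- as.integer(log2(root / 4)) + 1L   # coarsest level 4^3
    fx <- fixture_generators("poisson_mms", root_cells = root,
                             n_global = ng)
    out <- fmg_solve(fx$h, fx$sys, cfg)
    lv <- get_level(out$h, 0)
    b <- lv$blocks[[1]]
    geo <- cell_geometry(lv, b, list(L = c(0, 0, 0), R = c(1, 1, 1)))
    ex <- fx$exact(geo$centers[[1]], geo$centers[[2]], geo$centers[[3]])
    errs <- c(errs, max(abs(intr(b$data$u) - intr(ex))))
    cycles <- c(cycles, out$cycles[["0"]])
  }
  # cycle counts to a fixed tolerance vary by at most 2 across sizes
  expect_lte(max(cycles) - min(cycles), 2L)
  # O(eta^2) error: each halving divides the error by about 4
  expect_gt(errs[1] / errs[2], 2.5)
  expect_gt(errs[2] / errs[3], 2.5)
})
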