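test_that("bulk free energy derivatives reproduce hand-computed values", {
  p0 <- model_params(A1 = 1, A2 = 0, A3 = 0, A4 = 0, A5 = 0)
  # dFb/dphi_T at phi_T = 0.25, phi_E = 0: 2*0.25*0.75*0.5
  expect_equal(bulk_energy_derivatives(0.25, 0, p0)$dT, 0.1875)
  # dFb/dphi_E at phi_T = 0, phi_E = 0.5: 0.5*(2 - 1.5)
  expect_equal(bulk_energy_derivatives(0, 0.5, p0)$dE, 0.25)
  # with A3 = A5 the phi_T derivative vanishes at phi_T = 0
  p1 <- model_params(A3 = 0.4, A5 = 0.4)
  expect_equal(bulk_energy_derivatives(0, 0.7, p1)$dT, 0)
  # vectorized evaluation equals scalar evaluation
  set.seed(1)
  pt <- runif(20); pe <- runif(20)
  v <- bulk_energy_derivatives(pt, pe, p1)
  s <- vapply(1:20, function(i)
    bulk_energy_derivatives(pt[i], pe[i], p1)$dT, numeric(1))
  expect_identical(v$dT, s)
})

test_that("effective coefficients blend the phase endpoints", {
  p <- model_params()
  expect_equal(effective_coefficient(0, 1, 2, 5, 9, p), 2)     # pure ECM
  expect_equal(effective_coefficient(1, 0, 2, 5, 9, p), 5)     # pure tumor
  expect_equal(effective_coefficient(0, 0, 2, 5, 9, p), 9)     # pure host
  # degenerate phi_C -> host-coefficient blend
  expect_equal(effective_coefficient(0, 1 - 1e-15, 2, 5, 9, p), 2)
  # Q3 endpoints and clamping
  expect_equal(q3_smoothstep(c(-0.5, 0, 0.5, 1, 1.5)),
               c(0, 0, 0.5, 1, 1))
})

test_that("source terms reproduce the printed worked values", {
  p <- model_params()
  base <- list(phi_V = 0.5, phi_D = 0, phi_E = 0.35, n = 1, g = 1,
               tgf = 0, taf = 0, m = 0, F_E = 0, B_nE = 0.2, L_nE = 0.2,
               p = 0, sprout = 0.5)
  S <- source_terms(base, p)
  expect_equal(S$S_V, 0.5)   # lambda_M,V * n * (1 + tgf) * phi_V
  # hypoxic below viability: necrosis at rate 3
  hyp <- base; hyp$n <- 0.1
  Sh <- source_terms(hyp, p)
  expect_equal(Sh$S_V, -1.5)
  expect_equal(Sh$S_D, 1.5)  # the same term enters S_D with + sign
  # lysis of dead cells
  ded <- base; ded$phi_D <- 0.2
  expect_equal(source_terms(ded, p)$S_D - S$S_D, -1 * 0.2)
  # growth-factor gate: tgf below the threshold shuts ECM production
  lo <- base; lo$tgf <- 0.1; lo$m <- 0.3; lo$F_E <- 0.5
  expect_equal(source_terms(lo, p)$S_E, -p$lambda_de_E * 0.3 * 0.35)
  # Heaviside convention H(0) = 1: tgf exactly at threshold produces ECM
  at <- base; at$tgf <- p$tgf_F_E; at$F_E <- 0.5; at$phi_V <- 0.3
  expect_gt(source_terms(at, p)$S_E, 0)
  # pointwise algebra: array evaluation equals scalar-loop evaluation
  set.seed(2)
  arr <- lapply(base, function(v) array(runif(8), c(2, 2, 2)))
  Sa <- source_terms(arr, p)
  for (i in 1:8) {
    sc <- source_terms(lapply(arr, function(a) a[[i]]), p)
    for (nm in names(Sa)) expect_equal(Sa[[nm]][[i]], sc[[nm]])
  }
})

test_that("boundary conditions follow the model's table", {
  p <- model_params()
  bcs <- default_bcs(p)
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(4, 4, 4), 1, 0)
  h <- tumormg:::map_blocks(h, function(b, lv) {
    b <- tumormg:::block_add_fields(b, c("phi_V", "n", "B_nE"))
    b$data$phi_V[] <- 0.65; b$data$n[] <- 0.8; b$data$B_nE[] <- 0.3
    b
  })
  h <- apply_bcs(h, 0, c("phi_V", "n", "B_nE"), bcs)
  b <- get_level(h, 0)$blocks[[1]]
  expect_equal(b$data$phi_V[1, 3, 3], 0.65)        # zero-Neumann mirror
  expect_equal(b$data$n[1, 3, 3], 2 * 1 - 0.8)     # Dirichlet 1
  expect_equal(b$data$B_nE[1, 3, 3], 2 * 0.2 - 0.3)  # far-field 0.2
})

test_that("chemical potentials reduce to the bulk derivative on uniform
          fields and their Laplacian term is exact on quadratics", {
  p <- model_params(eps_TE = 0)
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(8, 8, 8), 1, 0)
  h <- tumormg:::map_blocks(h, function(b, lv) {
    b <- tumormg:::block_add_fields(b, c("phi_V", "phi_D", "phi_E",
                                         "mu_T", "mu_E"))
    b$data$phi_V[] <- 0.4; b$data$phi_E[] <- 0.35
    b
  })
  h <- chemical_potentials(h, 0, p)
  b <- get_level(h, 0)$blocks[[1]]
  fb <- bulk_energy_derivatives(0.4, 0.35, p)
  expect_lt(max(abs(intr(b$data$mu_T) - fb$dT)), 1e-12)
  expect_lt(max(abs(intr(b$data$mu_E) - fb$dE)), 1e-12)
  # phi_T sampling a quadratic: Laplacian term equals the analytic value
  h2 <- tumormg:::map_blocks(h, function(b, lv) {
    b$data$phi_V <- sample_on_block(h, 0, b, function(x, y, z)
      0.1 + 0.2 * x^2 + 0.3 * y^2 - 0.1 * z^2)
    b$data$phi_E[] <- 0
    b
  })
  h2 <- chemical_potentials(h2, 0, p)
  b2 <- get_level(h2, 0)$blocks[[1]]
  lap_analytic <- 2 * (0.2 + 0.3 - 0.1)
  fbq <- bulk_energy_derivatives(intr(b2$data$phi_V), 0, p)
  expect_lt(max(abs(intr(b2$data$mu_T) -
                      (fbq$dT - p$eps_T^2 * lap_analytic))), 1e-9)
})

test_that("the mixture closure holds cell-wise after construction and
          stepping", {
  st <- initial_condition(cfg = solver_config(theta = 1e-2),
                          root_cells = 8L, n_global = 1L, kappa_max = 0L)
  for (k in st$h$kappa_min:st$h$kappa_max) {
    for (b in get_level(st$h, k)$blocks) {
      phiH <- 1 - b$data$phi_V - b$data$phi_D - b$data$phi_E
      expect_true(all(phiH > -1e-12))
      expect_lt(max(abs(b$data$phi_V + b$data$phi_D + b$data$phi_E +
                          phiH - 1)), 1e-14)
    }
  }
})

test_that("quasi-steady oxygen returns the exact constant solution when
          uptake vanishes and supply balances", {
  # k_n2 = 0 and n_C = 1 with Dirichlet 1: n = 1 solves the equation
  p <- model_params(k_n2 = c(0, 0, 0),
                    supply_ref = 0.2 * 0.35)   # B_inf*phi_E0 -> n_C = 1
  cfg <- solver_config(tol_min = 1e-10)
  st <- initial_condition(p, cfg, root_cells = 8L, n_global = 1L,
                          kappa_max = 0L, seed_side = 0)
  h <- tumormg:::update_species_coefficients(st$h, p, "lite")
  h <- quasi_steady_species_system(h, p, cfg, st$bcs, "lite")
  b <- get_level(h, 0)$blocks[[1]]
  expect_lt(max(abs(intr(b$data$n) - 1)), 1e-8)
})

test_that("with zero production the charged species vanish and chloride
          closes to zero by electroneutrality", {
  p <- model_params(k_n2 = c(0, 0, 0), k_g2 = c(0, 0, 0), k_f = 0,
                    k_r = 0)
  cfg <- solver_config(tol_min = 1e-8)
  st <- initial_condition(p, cfg, root_cells = 8L, n_global = 1L,
                          kappa_max = 0L, profile = "full", seed_side = 0)
  h <- tumormg:::update_species_coefficients(st$h, p, "full")
  h <- quasi_steady_species_system(h, p, cfg, st$bcs, "full",
                                   picard_iter = 2L)
  b <- get_level(h, 0)$blocks[[1]]
  for (X in c("l", "b", "a", "s", "r"))
    expect_lt(max(abs(intr(b$data[[X]]))), 1e-6)
})
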