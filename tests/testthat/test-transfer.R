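# Polynomial-exactness degrees: restriction and trilinear prolongation are
# exact on linear fields, the two-stage ghost fill on quadratics, the FMG
# interpolation on cubics.

poly_field <- function(dims, coords, fn) {
  out <- array(0, dims)
  for (i in seq_along(coords[[1]]))
    for (j in seq_along(coords[[2]]))
      for (k in seq_along(coords[[3]]))
        out[i, j, k] <- fn(coords[[1]][i], coords[[2]][j], coords[[3]][k])
  out
}

test_that("averaging restriction is exact on linear fields", {
  n <- 8
  xs <- ((1:n) - 0.5) / n
  fine <- poly_field(c(n, n, n), list(xs, xs, xs),
                     function(x, y, z) 1 + 2 * x - 3 * y + 0.5 * z)
  xc <- ((1:(n / 2)) - 0.5) / (n / 2)
  ref <- poly_field(rep(n / 2, 3), list(xc, xc, xc),
                    function(x, y, z) 1 + 2 * x - 3 * y + 0.5 * z)
  expect_lt(max(abs(restrict_avg(fine) - ref)), 1e-12)
  expect_error(restrict_avg(array(0, c(3, 4, 4))), "even")
  # constants are preserved exactly
  expect_equal(restrict_avg(array(4.2, c(4, 4, 4))),
               array(4.2, c(2, 2, 2)))
  # one coarse cell whose children are 1..8 averages to 4.5
  expect_equal(restrict_avg(array(1:8, c(2, 2, 2)))[1, 1, 1], 4.5)
})

test_that("trilinear prolongation uses the {27,9,3,1}/64 weights and is
          exact on linears", {
  nc <- 4
  xs <- ((0:(nc + 1)) - 0.5)            # coarse spacing 1, with ghosts
  coarse <- poly_field(rep(nc + 2, 3), list(xs, xs, xs),
                       function(x, y, z) 0.3 + x + 2 * y + 3 * z)
  fine <- prolong_linear(coarse)
  xf <- ((1:(2 * nc)) - 0.5) / 2
  ref <- poly_field(rep(2 * nc, 3), list(xf, xf, xf),
                    function(x, y, z) 0.3 + x + 2 * y + 3 * z)
  expect_lt(max(abs(fine - ref)), 1e-12)
  # constants reproduce exactly (weights sum to 64/64)
  expect_equal(prolong_linear(array(2.5, c(4, 4, 4))),
               array(2.5, c(4, 4, 4)))
  expect_equal(prolong_linear(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)))
  # weights: a delta at coarse cell (2,2,2) (children are fine cells 3-4)
  # contributes 27/64 to its own children, 9/64 across one axis, 3/64
  # across two, 1/64 across three
  delta <- array(0, c(5, 5, 5)); delta[3, 3, 3] <- 1
  fd <- prolong_linear(delta)
  expect_equal(fd[4, 4, 4], 27 / 64)
  expect_equal(fd[3, 3, 3], 27 / 64)
  expect_equal(fd[5, 4, 4], 9 / 64)
  expect_equal(fd[5, 5, 4], 3 / 64)
  expect_equal(fd[5, 5, 5], 1 / 64)
})

test_that("cubic FMG interpolation uses the {-7,105,35,-5}/128 weights and
          is exact on cubics", {
  nc <- 6; g <- 2
  xs <- (((1 - g):(nc + g)) - 0.5)
  f3 <- function(x, y, z) x^3 - 2 * y^3 + 0.5 * z^3 + x * y - z + 1
  coarse <- poly_field(rep(nc + 2 * g, 3), list(xs, xs, xs), f3)
  fine <- fmg_interp_cubic(coarse, margin = g)
  xf <- ((1:(2 * nc)) - 0.5) / 2
  ref <- poly_field(rep(2 * nc, 3), list(xf, xf, xf), f3)
  expect_lt(max(abs(fine - ref)), 1e-10)
  # constants (weights sum to 128/128) and zeros
  expect_equal(fmg_interp_cubic(array(3.7, rep(10, 3)), margin = 2),
               array(3.7, rep(12, 3)))
  expect_equal(fmg_interp_cubic(array(0, rep(10, 3)), margin = 2),
               array(0, rep(12, 3)))
  # 1D weights via a delta plane constant in y/z (tensor factors are then
  # exact on constants): children of cells j-1..j+2 read off the stencil
  nc2 <- 8
  dl <- array(0, c(nc2 + 4, 5, 5)); dl[6, , ] <- 1     # coarse cell 4
  fd <- fmg_interp_cubic(dl, margin = 2)
  line <- fd[, 2, 2]
  # cell 4's own children carry 105/128 (left) and 105/128's partner 35?
  # weights at the fine positions: left child of j gets 105 when j is the
  # source, 35 when j-1 is, -7 when j+1 is, -5 when j+2 is
  expect_equal(line[7], 105 / 128)   # left child of cell 4
  expect_equal(line[8], 105 / 128)   # right child of cell 4
  expect_equal(line[6], 35 / 128)    # right child of cell 3
  expect_equal(line[9], 35 / 128)    # left child of cell 5
  expect_equal(line[5], -7 / 128)    # left child of cell 3
  expect_equal(line[10], -7 / 128)   # right child of cell 5
  expect_equal(line[4], -5 / 128)    # right child of cell 2
  expect_equal(line[11], -5 / 128)   # left child of cell 6
})

test_that("quadratic ghost filling reproduces quadratics (with cross
          terms) and copies same-level neighbor data", {
  qf <- function(x, y, z)
    1 + 2 * x - y + 0.5 * z + x^2 - 0.3 * y^2 + 0.2 * z^2 +
    0.4 * x * y - 0.1 * y * z + 0.25 * x * z
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(8, 8, 8), 1, 1)
  lv0 <- get_level(h, 0)
  b0 <- tumormg:::block_add_fields(lv0$blocks[[1]], "u")
  b0$data$u <- sample_on_block(h, 0, b0, qf)
  lv0$blocks[[1]] <- b0
  h <- tumormg:::set_level(h, 0, lv0)
  lv1 <- get_level(h, 1)
  b1 <- tumormg:::block_add_fields(tumormg:::new_block(c(5, 5, 5),
                                                       c(12, 12, 12)), "u")
  ref <- sample_on_block(h, 1, b1, qf)
  arr <- ref
  d <- dim(arr)
  ghost <- array(TRUE, d)
  ghost[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  arr[ghost] <- 0
  b1$data$u <- arr
  lv1$blocks <- list(b1)
  h <- tumormg:::set_level(h, 1, lv1)
  bf <- fill_ghost_quadratic(h, 1, 1, "u")
  expect_lt(max(abs(bf$data$u[ghost] - ref[ghost])), 1e-12)

  # a ghost lying inside an abutting same-level block takes that block's
  # interior value verbatim
  b2 <- tumormg:::block_add_fields(tumormg:::new_block(c(13, 5, 5),
                                                       c(14, 12, 12)), "u")
  b2$data$u <- array(77, dim(b2$data$u))
  lv1 <- get_level(h, 1)
  lv1$blocks <- list(bf, b2)
  h <- tumormg:::set_level(h, 1, lv1)
  bf2 <- fill_ghost_quadratic(h, 1, 1, "u")
  expect_equal(unique(as.vector(bf2$data$u[dim(bf2$data$u)[1], 2:9, 2:9])),
               77)
})

test_that("transfer operators are linear maps", {
  set.seed(42)
  d <- c(6, 6, 6)
  f1 <- array(rnorm(prod(d)), d); f2 <- array(rnorm(prod(d)), d)
  a <- 1.7; b <- -0.4
  expect_equal(restrict_avg(a * f1 + b * f2),
               a * restrict_avg(f1) + b * restrict_avg(f2))
  g1 <- array(rnorm(6^3), c(6, 6, 6)); g2 <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(prolong_linear(a * g1 + b * g2),
               a * prolong_linear(g1) + b * prolong_linear(g2))
  c1 <- array(rnorm(10^3), rep(10, 3)); c2 <- array(rnorm(10^3), rep(10, 3))
  expect_equal(fmg_interp_cubic(a * c1 + b * c2, margin = 2),
               a * fmg_interp_cubic(c1, margin = 2) +
                 b * fmg_interp_cubic(c2, margin = 2))
})

test_that("restriction of a prolonged linear field reproduces it", {
  nc <- 4
  xs <- ((0:(nc + 1)) - 0.5)
  coarse <- poly_field(rep(nc + 2, 3), list(xs, xs, xs),
                       function(x, y, z) 2 - x + 0.5 * y + 3 * z)
  back <- restrict_avg(prolong_linear(coarse))
  expect_lt(max(abs(back - coarse[2:(nc + 1), 2:(nc + 1), 2:(nc + 1)])),
            1e-12)
})

test_that("boundary conditions set ghosts by mirror or reflection", {
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(4, 4, 4), 1, 0)
  h <- tumormg:::map_blocks(h, function(b, lv)
    tumormg:::block_add_fields(b, c("fneu", "fdir"), value = 0.8))
  h <- apply_bcs(h, 0, c("fneu", "fdir"),
                 list(fneu = bc("neumann"), fdir = bc("dirichlet", 1)))
  b <- get_level(h, 0)$blocks[[1]]
  expect_equal(b$data$fneu[1, 3, 3], 0.8)          # mirror
  expect_equal(b$data$fdir[1, 3, 3], 2 * 1 - 0.8)  # reflection through bc
})
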