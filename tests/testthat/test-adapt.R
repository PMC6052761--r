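make_flag_hierarchy <- function(root = 16L) {
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       rep(root, 3L), 1L, 1L)
  tumormg:::map_blocks(h, function(b, lv)
    tumormg:::block_add_fields(b, "psi"))
}

set_psi <- function(h, fn) {
  tumormg:::map_blocks(h, function(b, lv) {
    b$data$psi <- sample_on_block(h, lv$kappa, b, fn)
    b
  })
}

test_that("undivided gradient test flags step interfaces, not uniform
          fields", {
  h <- make_flag_hierarchy(16L)
  h <- set_psi(h, function(x, y, z) 0.65)
  fl <- flag_undivided_gradient(h, 0, "psi", C = 0.05)
  expect_equal(nrow(fl$cells), 0L)
  # 1D-like step: psi = 1 for cell index i <= 5, else 0 (eta = 1/16)
  h <- set_psi(h, function(x, y, z) as.numeric(x < 5.5 / 16))
  fl <- flag_undivided_gradient(h, 0, "psi", C = 0.05)
  # undivided centered difference is 1 at i = 5 and 6 only
  expect_setequal(unique(fl$cells[, 1]), c(5L, 6L))
  expect_equal(sort(unique(fl$cells[, 2])), 1:16)
  # comparison is against C as printed (not C^2): squared sum 1 > 0.05
  flb <- flag_undivided_gradient(h, 0, "psi", C = 1.0001)
  expect_equal(nrow(flb$cells), 0L)
})

test_that("flag buffering grows a 9x9x9 cube, clipped at boundaries", {
  h <- make_flag_hierarchy(16L)
  fl <- list(kappa = 0L, ndom = c(16L, 16L, 16L),
             cells = matrix(c(8L, 8L, 8L), 1))
  fb <- buffer_flags(fl, h, radius = 4L)
  expect_equal(nrow(fb$cells), 9L^3)
  fl2 <- list(kappa = 0L, ndom = c(16L, 16L, 16L),
              cells = matrix(c(1L, 1L, 1L), 1))
  fb2 <- buffer_flags(fl2, h, radius = 4L)
  expect_equal(nrow(fb2$cells), 5L^3)
  fl3 <- list(kappa = 0L, ndom = c(16L, 16L, 16L),
              cells = matrix(integer(0), 0, 3))
  expect_equal(nrow(buffer_flags(fl3, h)$cells), 0L)
})

test_that("relative truncation error test is quiet on representable
          solutions and matches a dense computation", {
  # psi linear: both level operators reproduce a*psi - lap(psi) with
  # lap = 0 exactly, and restriction is exact on linears -> tau = 0
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(8, 8, 8), 2L, 0L)
  h <- tumormg:::map_blocks(h, function(b, lv) {
    b <- tumormg:::block_add_fields(b, c("u", "R0_u", "R_u", "a1", "k1"))
    b$data$k1 <- array(1, dim(b$data$u))
    b$data$a1 <- array(1, dim(b$data$u))
    b$data$u <- sample_on_block(h, lv$kappa, b,
                                function(x, y, z) 1 + x - 2 * y + z)
    b
  })
  sys <- scalar_system("u", bc("neumann"), "a1", "k1")
  fl <- flag_truncation_error(h, 0, sys, threshold = 1e-8)
  expect_equal(nrow(fl$cells), 0L)
  # threshold Inf flags nothing on any data
  h2 <- tumormg:::map_blocks(h, function(b, lv) {
    b$data$u <- sample_on_block(h, lv$kappa, b,
                                function(x, y, z) sin(3 * x) * cos(y))
    b
  })
  expect_equal(nrow(flag_truncation_error(h2, 0, sys, Inf)$cells), 0L)
  # smooth field: tau matches the dense two-level computation
  tau <- tumormg:::tau_coarse(h2, 0, sys)[[1]]$tau
  bF <- get_level(h2, 0)$blocks[[1]]
  uf <- intr(bF$data$u)
  # dense oracle with mirror (neumann) ghost padding
  pad_n <- function(u) {
    d <- dim(u); p <- array(0, d + 2L)
    p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- u
    p[1, , ] <- p[2, , ]; p[d[1] + 2, , ] <- p[d[1] + 1, , ]
    p[, 1, ] <- p[, 2, ]; p[, d[2] + 2, ] <- p[, d[2] + 1, ]
    p[, , 1] <- p[, , 2]; p[, , d[3] + 2] <- p[, , d[3] + 1]
    p
  }
  app <- function(u, eta) {
    p <- pad_n(u); d <- dim(u)
    i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
    u - (p[i + 1, j, k] + p[i - 1, j, k] + p[i, j + 1, k] +
           p[i, j - 1, k] + p[i, j, k + 1] + p[i, j, k - 1] -
           6 * p[i, j, k]) / eta^2
  }
  tau_dense <- app(restrict_avg(uf), get_level(h2, -1)$eta) -
    restrict_avg(app(uf, get_level(h2, 0)$eta))
  expect_lt(max(abs(tau - tau_dense)), 1e-10)
})

test_that("clustering accepts a solid box as one block with unit
          efficiency", {
  h <- make_flag_hierarchy(16L)
  cells <- as.matrix(expand.grid(3:14, 3:14, 3:14))
  dimnames(cells) <- NULL
  fl <- list(kappa = 0L, ndom = c(16L, 16L, 16L),
             cells = cells)
  bl <- generate_blocks(fl, h)
  expect_length(bl$boxes, 1L)
  expect_equal(bl$boxes[[1]]$lo, 2L * c(3L, 3L, 3L) - 1L)
  expect_equal(bl$boxes[[1]]$hi, 2L * c(14L, 14L, 14L))
})

test_that("clustering splits two clusters at the empty gap", {
  h <- make_flag_hierarchy(32L)
  c1 <- as.matrix(expand.grid(2:9, 4:12, 4:12))
  c2 <- as.matrix(expand.grid(22:30, 4:12, 4:12))
  cells <- rbind(c1, c2); dimnames(cells) <- NULL
  fl <- list(kappa = 0L, ndom = rep(32L, 3), cells = cells)
  # small threshold_size so the bounding box is not accepted outright
  bl <- generate_blocks(fl, h, threshold_eff = 0.9, threshold_size = 100,
                        min_eff = 0.5)
  expect_length(bl$boxes, 2L)
  los <- t(vapply(bl$boxes, function(b) b$lo, integer(3)))
  his <- t(vapply(bl$boxes, function(b) b$hi, integer(3)))
  ord <- order(los[, 1])
  expect_equal(los[ord[1], ], 2L * c(2L, 4L, 4L) - 1L)
  expect_equal(his[ord[1], ], 2L * c(9L, 12L, 12L))
  expect_equal(los[ord[2], ], 2L * c(22L, 4L, 4L) - 1L)
  expect_equal(his[ord[2], ], 2L * c(30L, 12L, 12L))
})

test_that("clustering covers all flags with disjoint blocks obeying the
          acceptance rules on randomized flag sets", {
  set.seed(7)
  h <- make_flag_hierarchy(32L)
  for (trial in 1:5) {
    nblob <- sample(1:4, 1)
    cells <- NULL
    for (bi in seq_len(nblob)) {
      ctr <- sample(4:28, 3, replace = TRUE)
      rad <- sample(1:4, 3, replace = TRUE)
      g <- expand.grid(max(1, ctr[1] - rad[1]):min(32, ctr[1] + rad[1]),
                       max(1, ctr[2] - rad[2]):min(32, ctr[2] + rad[2]),
                       max(1, ctr[3] - rad[3]):min(32, ctr[3] + rad[3]))
      cells <- rbind(cells, as.matrix(g))
    }
    cells <- unique(cells); dimnames(cells) <- NULL
    fl <- list(kappa = 0L, ndom = rep(32L, 3), cells = cells)
    bl <- generate_blocks(fl, h, threshold_eff = 0.9,
                          threshold_size = 50, min_eff = 0.5)
    # coverage: every flagged cell (doubled) lies in exactly one block
    cnt <- integer(nrow(cells))
    vol_flagged <- 0
    for (bx in bl$boxes) {
      clo <- (bx$lo + 1L) %/% 2L; chi <- bx$hi %/% 2L
      inb <- cells[, 1] >= clo[1] & cells[, 1] <= chi[1] &
        cells[, 2] >= clo[2] & cells[, 2] <= chi[2] &
        cells[, 3] >= clo[3] & cells[, 3] <= chi[3]
      cnt <- cnt + inb
    }
    expect_true(all(cnt >= 1L))
    # disjointness (pairwise in the fine index space)
    if (length(bl$boxes) > 1) {
      for (i in seq_along(bl$boxes)) for (j in seq_along(bl$boxes)) {
        if (i >= j) next
        il <- pmax(bl$boxes[[i]]$lo, bl$boxes[[j]]$lo)
        ih <- pmin(bl$boxes[[i]]$hi, bl$boxes[[j]]$hi)
        expect_true(any(il > ih))
      }
    }
    # acceptance rules in the flag index space
    m <- array(FALSE, rep(32L, 3)); m[cells] <- TRUE
    for (bx in bl$boxes) {
      clo <- (bx$lo + 1L) %/% 2L; chi <- bx$hi %/% 2L
      vol <- prod(chi - clo + 1L)
      nf <- sum(m[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]])
      eff <- nf / vol
      expect_true(eff >= 0.5 || vol <= 2 * 50)
    }
  }
})

test_that("regridding preserves constants, copies previous-time data
          bit-identically, and averages removed blocks down", {
  params <- model_params()
  bcs <- list(u = bc("neumann"), u_prev = bc("neumann"))
  h <- build_hierarchy(list(L = c(0, 0, 0), R = c(1, 1, 1)),
                       c(8, 8, 8), 1L, 1L)
  h <- tumormg:::map_blocks(h, function(b, lv)
    tumormg:::block_add_fields(b, c("u", "u_prev"), value = 0.37))
  # old fine level with an arbitrary (non-constant) previous-time field
  lv1 <- get_level(h, 1)
  ob <- tumormg:::block_add_fields(tumormg:::new_block(c(3, 3, 3),
                                                       c(10, 10, 10)),
                                   c("u", "u_prev"), value = 0.37)
  set.seed(3)
  ob$data$u_prev <- array(runif(prod(dim(ob$data$u_prev))),
                          dim(ob$data$u_prev))
  ob$data$u <- array(runif(prod(dim(ob$data$u))), dim(ob$data$u))
  lv1$blocks <- list(ob)
  h <- tumormg:::set_level(h, 1, lv1)
  old_prev <- ob$data$u_prev

  # new blocks identical to old: previous-time data copied bit-identically
  bl <- list(kappa = 1L, boxes = list(list(lo = c(3L, 3L, 3L),
                                           hi = c(10L, 10L, 10L))))
  h2 <- regrid_transfer(h, 1L, bl, fields_now = "u", fields_prev = "u_prev",
                        bcs = bcs)
  nb <- get_level(h2, 1)$blocks[[1]]
  expect_identical(intr(nb$data$u_prev), intr(old_prev))

  # the old block's current data was averaged down before rebuilding
  bC <- get_level(h2, 0)$blocks[[1]]
  expect_equal(intr(bC$data$u)[2:5, 2:5, 2:5],
               restrict_avg(intr(ob$data$u)))

  # removing the fine level entirely leaves 8-child averages on the coarse
  h3 <- regrid_transfer(h, 1L, list(kappa = 1L, boxes = list()),
                        fields_now = "u", fields_prev = "u_prev",
                        bcs = bcs)
  expect_length(get_level(h3, 1)$blocks, 0L)
  bC3 <- get_level(h3, 0)$blocks[[1]]
  expect_equal(intr(bC3$data$u_prev)[2:5, 2:5, 2:5],
               restrict_avg(intr(old_prev)))

  # a globally constant field stays constant on every level after regrid
  h4 <- tumormg:::map_blocks(h, function(b, lv) {
    b$data$u <- array(0.37, dim(b$data$u))
    b$data$u_prev <- array(0.37, dim(b$data$u))
    b
  })
  h4 <- regrid_transfer(h4, 1L, bl, "u", "u_prev", bcs)
  for (k in h4$kappa_min:1) for (b in get_level(h4, k)$blocks) {
    expect_lt(max(abs(b$data$u - 0.37)), 1e-13)
    expect_lt(max(abs(b$data$u_prev - 0.37)), 1e-13)
  }
})
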