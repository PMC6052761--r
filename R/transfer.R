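# ---------------------------------------------------------------------------
# Inter-grid transfer operators.
#
# Conventions: a coarse cell c covers fine cells 2c-1 and 2c per axis, so a
# fine box lo..hi (lo odd, hi even -- blocks are even-aligned) maps to the
# coarse box (lo+1)/2 .. hi/2.  Fine cell centers sit at +/- eta_c/4 from
# their parent coarse center, which fixes the interpolation weights:
# trilinear prolongation {27,9,3,1}/64, quadratic ghost fill {30,5,-3}/32,
# cubic FMG interpolation {-7,105,35,-5}/128.
# ---------------------------------------------------------------------------

#' Fine-to-coarse restriction by averaging
#'
#' Each coarse cell receives the mean of its eight fine children.
#'
#' @param fine 3D array of fine cell values (interior only, no ghosts);
#'   extents must be even.
#' @return 3D array of coarse cell values with halved extents.
#' @export
restrict_avg <- function(fine) {
  d <- dim(fine)
  if (is.null(d) || length(d) != 3L) stop("fine must be a 3D array")
  if (any(d %% 2L != 0L)) stop("fine extents must be even per axis")
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  k1 <- seq.int(1L, d[3], 2L); k2 <- k1 + 1L
  (fine[i1, j1, k1, drop = FALSE] + fine[i2, j1, k1, drop = FALSE] +
   fine[i1, j2, k1, drop = FALSE] + fine[i2, j2, k1, drop = FALSE] +
   fine[i1, j1, k2, drop = FALSE] + fine[i2, j1, k2, drop = FALSE] +
   fine[i1, j2, k2, drop = FALSE] + fine[i2, j2, k2, drop = FALSE]) / 8
}

# Replace NA entries in the one-cell margin of a padded array by the nearest
# interior value (constant extrapolation); used as a last-resort guard when a
# transfer stencil pokes outside the available coarse data.
fill_na_margin <- function(arr) {
  d <- dim(arr)
  for (ax in 1:3) {
    idx_lo <- slice_index(d, ax, 1L)
    idx_in <- slice_index(d, ax, 2L)
    sl <- arr[idx_lo$i, idx_lo$j, idx_lo$k, drop = FALSE]
    na <- is.na(sl)
    if (any(na)) {
      inn <- arr[idx_in$i, idx_in$j, idx_in$k, drop = FALSE]
      sl[na] <- inn[na]
      arr[idx_lo$i, idx_lo$j, idx_lo$k] <- sl
    }
    idx_hi <- slice_index(d, ax, d[ax])
    idx_in <- slice_index(d, ax, d[ax] - 1L)
    sl <- arr[idx_hi$i, idx_hi$j, idx_hi$k, drop = FALSE]
    na <- is.na(sl)
    if (any(na)) {
      inn <- arr[idx_in$i, idx_in$j, idx_in$k, drop = FALSE]
      sl[na] <- inn[na]
      arr[idx_hi$i, idx_hi$j, idx_hi$k] <- sl
    }
  }
  arr
}

# index helper: full ranges except position `at` along axis `ax`
slice_index <- function(d, ax, at) {
  out <- list(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  out[[ax]] <- at
  out
}

#' Coarse-to-fine trilinear prolongation
#'
#' Each fine child value is the tensor-product linear interpolant at its
#' center: weight 27/64 on the parent coarse cell, 9/64 on the three face
#' neighbors toward the child's octant, 3/64 on the three edge neighbors and
#' 1/64 on the corner neighbor.
#'
#' @param coarse 3D array with a one-cell margin (ghost layer) on every
#'   face; `NA` margin entries are replaced by constant extrapolation.
#' @return fine 3D array of extents `2 * (dim(coarse) - 2)`.
#' @export
prolong_linear <- function(coarse) {
  d <- dim(coarse)
  if (is.null(d) || length(d) != 3L) stop("coarse must be a 3D array")
  if (anyNA(coarse)) coarse <- fill_na_margin(coarse)
  if (anyNA(coarse[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)]))
    stop("missing coarse data under fine target")
  nc <- d - 2L
  fine <- array(0, 2L * nc)
  ic <- 2:(nc[1] + 1L); jc <- 2:(nc[2] + 1L); kc <- 2:(nc[3] + 1L)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    sx <- 2L * ox - 1L; sy <- 2L * oy - 1L; sz <- 2L * oz - 1L
    C0  <- coarse[ic,      jc,      kc,      drop = FALSE]
    Cx  <- coarse[ic + sx, jc,      kc,      drop = FALSE]
    Cy  <- coarse[ic,      jc + sy, kc,      drop = FALSE]
    Cz  <- coarse[ic,      jc,      kc + sz, drop = FALSE]
    Cxy <- coarse[ic + sx, jc + sy, kc,      drop = FALSE]
    Cxz <- coarse[ic + sx, jc,      kc + sz, drop = FALSE]
    Cyz <- coarse[ic,      jc + sy, kc + sz, drop = FALSE]
    Cxyz <- coarse[ic + sx, jc + sy, kc + sz, drop = FALSE]
    val <- (27 * C0 + 9 * (Cx + Cy + Cz) + 3 * (Cxy + Cxz + Cyz) + Cxyz) / 64
    fine[seq.int(1L + ox, 2L * nc[1], 2L),
         seq.int(1L + oy, 2L * nc[2], 2L),
         seq.int(1L + oz, 2L * nc[3], 2L)] <- val
  }
  fine
}

# refine a (n + 2g) x M matrix along rows by cubic Lagrange interpolation,
# falling back to quadratic, then to injection, where stencil rows are
# missing (NA) or outside the matrix.
refine_rows_cubic <- function(A, g) {
  n <- nrow(A) - 2L * g
  if (n < 1L) stop("no interior rows")
  nas <- matrix(NA_real_, 2L, ncol(A))
  Ap <- rbind(nas, A, nas)             # rows shifted by +2
  j <- (g + 3L):(g + n + 2L)           # interior rows in Ap
  rc <- (-7 * Ap[j - 1L, , drop = FALSE] + 105 * Ap[j, , drop = FALSE] +
          35 * Ap[j + 1L, , drop = FALSE] - 5 * Ap[j + 2L, , drop = FALSE]) / 128
  rq <- (-3 * Ap[j - 1L, , drop = FALSE] + 30 * Ap[j, , drop = FALSE] +
           5 * Ap[j + 1L, , drop = FALSE]) / 32
  lc <- (-5 * Ap[j - 2L, , drop = FALSE] + 35 * Ap[j - 1L, , drop = FALSE] +
         105 * Ap[j, , drop = FALSE] - 7 * Ap[j + 1L, , drop = FALSE]) / 128
  lq <- (5 * Ap[j - 1L, , drop = FALSE] + 30 * Ap[j, , drop = FALSE] -
         3 * Ap[j + 1L, , drop = FALSE]) / 32
  cp <- Ap[j, , drop = FALSE]
  bad <- !is.finite(rc); rc[bad] <- rq[bad]
  bad <- !is.finite(rc); rc[bad] <- cp[bad]
  bad <- !is.finite(lc); lc[bad] <- lq[bad]
  bad <- !is.finite(lc); lc[bad] <- cp[bad]
  out <- matrix(0, 2L * n, ncol(A))
  out[seq.int(1L, 2L * n, 2L), ] <- lc
  out[seq.int(2L, 2L * n, 2L), ] <- rc
  out
}

#' Cubic Lagrangian FMG interpolation
#'
#' Coarse-to-fine interpolation used to seed finer levels in the full
#' multigrid pass and to populate newly refined blocks.  One-dimensional
#' weights are (-7, 105, 35, -5)/128 (mirrored for the other child); 3D
#' values are built by tensor-product application axis by axis (x, then y,
#' then z).  Where the 4-point stencil would leave the supplied data, the
#' scheme degrades gracefully to quadratic, then to injection.
#'
#' @param coarse 3D array with a `margin`-cell border of coarse data on
#'   every face (entries may be `NA` where unavailable).
#' @param margin border width (>= 1); with `margin = 2` the full cubic
#'   stencil is available for every fine target.
#' @return fine 3D array of extents `2 * (dim(coarse) - 2*margin)`.
#' @export
fmg_interp_cubic <- function(coarse, margin = 1L) {
  d <- dim(coarse)
  if (is.null(d) || length(d) != 3L) stop("coarse must be a 3D array")
  g <- as.integer(margin)
  stopifnot(g >= 1L, all(d > 2L * g))
  arr <- coarse
  marg <- c(g, g, g)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    m2 <- refine_rows_cubic(m, marg[ax])
    dp2 <- dp; dp2[1] <- nrow(m2)
    ap2 <- array(m2, dp2)
    arr <- aperm(ap2, order(perm))
    marg[ax] <- 0L
  }
  if (anyNA(arr)) stop("insufficient coarse data for FMG interpolation")
  arr
}

# ---------------------------------------------------------------------------
# Box extraction / deposition on a level (assembles data across blocks).
# ---------------------------------------------------------------------------

# Extract field values over index box lo..hi (level index space) from all
# blocks of a level.  Interior data is preferred; ghost data of any block is
# used where no interior covers a cell; remaining cells are NA.
extract_box <- function(h, kappa, lo, hi, field) {
  lv <- get_level(h, kappa)
  out <- array(NA_real_, hi - lo + 1L)
  for (b in lv$blocks) {
    il <- pmax(lo, b$lo); ih <- pmin(hi, b$hi)
    if (any(il > ih)) next
    src <- b$data[[field]]
    out[(il[1] - lo[1] + 1L):(ih[1] - lo[1] + 1L),
        (il[2] - lo[2] + 1L):(ih[2] - lo[2] + 1L),
        (il[3] - lo[3] + 1L):(ih[3] - lo[3] + 1L)] <-
      src[(il[1] - b$lo[1] + 2L):(ih[1] - b$lo[1] + 2L),
          (il[2] - b$lo[2] + 2L):(ih[2] - b$lo[2] + 2L),
          (il[3] - b$lo[3] + 2L):(ih[3] - b$lo[3] + 2L)]
  }
  if (anyNA(out)) {
    for (b in lv$blocks) {
      il <- pmax(lo, b$lo - 1L); ih <- pmin(hi, b$hi + 1L)
      if (any(il > ih)) next
      src <- b$data[[field]]
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

# Write array `arr` (covering index box lo..hi) into the interiors of all
# blocks of level kappa where they overlap the box.  Returns the hierarchy.
deposit_box <- function(h, kappa, lo, hi, field, arr) {
  lv <- get_level(h, kappa)
  for (ib in seq_along(lv$blocks)) {
    b <- lv$blocks[[ib]]
    il <- pmax(lo, b$lo); ih <- pmin(hi, b$hi)
    if (any(il > ih)) next
    dst <- b$data[[field]]
    dst[(il[1] - b$lo[1] + 2L):(ih[1] - b$lo[1] + 2L),
        (il[2] - b$lo[2] + 2L):(ih[2] - b$lo[2] + 2L),
        (il[3] - b$lo[3] + 2L):(ih[3] - b$lo[3] + 2L)] <-
      arr[(il[1] - lo[1] + 1L):(ih[1] - lo[1] + 1L),
          (il[2] - lo[2] + 1L):(ih[2] - lo[2] + 1L),
          (il[3] - lo[3] + 1L):(ih[3] - lo[3] + 1L)]
    lv$blocks[[ib]]$data[[field]] <- dst
  }
  set_level(h, kappa, lv)
}

# ---------------------------------------------------------------------------
# Physical boundary conditions on padded block arrays.
# ---------------------------------------------------------------------------

#' Boundary-condition descriptor
#'
#' @param type `"neumann"` (zero normal derivative; ghost mirrors the
#'   adjacent interior cell) or `"dirichlet"` (ghost = `2*value - interior`,
#'   the second-order cell-centered convention).
#' @param value Dirichlet boundary value (ignored for Neumann).
#' @export
bc <- function(type = c("neumann", "dirichlet"), value = 0) {
  type <- match.arg(type)
  list(type = type, value = value)
}

# Apply a physical BC to the ghost faces of one padded array that lie on the
# domain boundary.  Applied axis by axis so edge/corner ghosts at physical
# boundaries become consistent.
apply_bc_array <- function(arr, bcspec, blo, bhi, ndom) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (blo[ax] == 1L) {
      gi <- slice_index(d, ax, 1L); ii <- slice_index(d, ax, 2L)
      inn <- arr[ii$i, ii$j, ii$k, drop = FALSE]
      arr[gi$i, gi$j, gi$k] <-
        if (bcspec$type == "dirichlet") 2 * bcspec$value - inn else inn
    }
    if (bhi[ax] == ndom[ax]) {
      gi <- slice_index(d, ax, d[ax]); ii <- slice_index(d, ax, d[ax] - 1L)
      inn <- arr[ii$i, ii$j, ii$k, drop = FALSE]
      arr[gi$i, gi$j, gi$k] <-
        if (bcspec$type == "dirichlet") 2 * bcspec$value - inn else inn
    }
  }
  arr
}

#' Apply physical boundary conditions on a level
#'
#' Fills the ghost faces lying on the external domain boundary for the named
#' fields of every block of level `kappa`.
#'
#' @param h a `tmg_hierarchy`.
#' @param kappa level index.
#' @param fields character vector of field names.
#' @param bcs named list mapping field name to a [bc()] descriptor.
#' @return the updated hierarchy.
#' @export
apply_bcs <- function(h, kappa, fields, bcs) {
  lv <- get_level(h, kappa)
  ndom <- level_ncells_domain(h, kappa)
  for (ib in seq_along(lv$blocks)) {
    b <- lv$blocks[[ib]]
    if (all(b$lo > 1L & b$hi < ndom)) next
    for (f in fields) {
      lv$blocks[[ib]]$data[[f]] <-
        apply_bc_array(b$data[[f]], bcs[[f]], b$lo, b$hi, ndom)
    }
  }
  set_level(h, kappa, lv)
}

# ---------------------------------------------------------------------------
# Coarse-fine ghost interpolation (two-stage quadratic) + same-level copy.
# ---------------------------------------------------------------------------

# Tangential quadratic pass: values of a coarse line at fine tangential
# positions.  C is a matrix whose rows span coarse indices ct0..ct0+nrow-1;
# tfine are fine indices.  Returns matrix with one row per fine index.
tang_quad <- function(C, ct0, tfine) {
  ct <- (tfine + 1L) %/% 2L
  dv <- ifelse(tfine %% 2L == 0L, 1L, -1L)   # even fine index: +1/4 child
  r0 <- ct - ct0 + 1L
  (30 * C[r0, , drop = FALSE] + 5 * C[r0 + dv, , drop = FALSE] -
     3 * C[r0 - dv, , drop = FALSE]) / 32
}

# Fill the coarse-fine interpolated ghosts of one refined block: face ghosts
# by the two-stage quadratic (tangential passes per tangential axis, then a
# quadratic normal pass through the intermediate point and two interior fine
# cells), edge and corner ghosts by the diagonal quadratic rule (nearest
# coarse point plus two fine diagonal interior points).
fill_ghost_block_quadratic <- function(h, kappa, block, fields) {
  ndom <- level_ncells_domain(h, kappa)
  dims <- block_dims(block)
  wN <- c(8 / 15, 2 / 3, -1 / 5)  # (intermediate, 1st interior, 2nd interior)
  for (f in fields) {
    arr <- block$data[[f]]
    d <- dim(arr)
    # ---- faces -------------------------------------------------------
    for (ax in 1:3) for (side in c(-1L, 1L)) {
      gn <- if (side < 0L) block$lo[ax] - 1L else block$hi[ax] + 1L
      if (gn < 1L || gn > ndom[ax]) next    # physical boundary face
      cn <- (gn + 1L) %/% 2L
      tax <- setdiff(1:3, ax)
      t1 <- block$lo[tax[1]]:block$hi[tax[1]]
      t2 <- block$lo[tax[2]]:block$hi[tax[2]]
      c1 <- ((t1[1] + 1L) %/% 2L - 1L):((t1[length(t1)] + 1L) %/% 2L + 1L)
      c2 <- ((t2[1] + 1L) %/% 2L - 1L):((t2[length(t2)] + 1L) %/% 2L + 1L)
      lo_c <- hi_c <- integer(3)
      lo_c[ax] <- hi_c[ax] <- cn
      lo_c[tax[1]] <- c1[1]; hi_c[tax[1]] <- c1[length(c1)]
      lo_c[tax[2]] <- c2[1]; hi_c[tax[2]] <- c2[length(c2)]
      cp <- extract_box(h, kappa - 1L, lo_c, hi_c, f)
      # collapse the singleton normal axis; tangential axes stay in
      # increasing order so column-major layout is preserved
      cm <- matrix(as.vector(cp), nrow = length(c1), ncol = length(c2))
      m1 <- tang_quad(cm, c1[1], t1)                   # n1 x nc2
      m2 <- tang_quad(t(m1), c2[1], t2)                # n2 x n1
      interm <- t(m2)                                  # n1 x n2
      # normal pass
      i1 <- if (side < 0L) 2L else d[ax] - 1L          # 1st interior (padded)
      i2 <- if (side < 0L) 3L else d[ax] - 2L
      gpad <- if (side < 0L) 1L else d[ax]
      s1 <- slice_index(d, ax, i1); s2 <- slice_index(d, ax, i2)
      s1[[tax[1]]] <- 2:(d[tax[1]] - 1L); s1[[tax[2]]] <- 2:(d[tax[2]] - 1L)
      s2[[tax[1]]] <- 2:(d[tax[1]] - 1L); s2[[tax[2]]] <- 2:(d[tax[2]] - 1L)
      g <- slice_index(d, ax, gpad)
      g[[tax[1]]] <- 2:(d[tax[1]] - 1L); g[[tax[2]]] <- 2:(d[tax[2]] - 1L)
      in1 <- arr[s1$i, s1$j, s1$k, drop = FALSE]
      in2 <- arr[s2$i, s2$j, s2$k, drop = FALSE]
      val <- wN[1] * interm + wN[2] * drop3(in1, ax) + wN[3] * drop3(in2, ax)
      arr[g$i, g$j, g$k] <- val
    }
    # ---- edges (outside along two axes) ------------------------------
    for (a1 in 1:2) for (a2 in (a1 + 1):3) {
      a3 <- setdiff(1:3, c(a1, a2))
      for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) {
        g1 <- if (s1 < 0L) block$lo[a1] - 1L else block$hi[a1] + 1L
        g2 <- if (s2 < 0L) block$lo[a2] - 1L else block$hi[a2] + 1L
        if (g1 < 1L || g1 > ndom[a1] || g2 < 1L || g2 > ndom[a2]) next
        cn1 <- (g1 + 1L) %/% 2L; cn2 <- (g2 + 1L) %/% 2L
        t3 <- block$lo[a3]:block$hi[a3]
        c3 <- ((t3[1] + 1L) %/% 2L - 1L):((t3[length(t3)] + 1L) %/% 2L + 1L)
        lo_c <- hi_c <- integer(3)
        lo_c[a1] <- hi_c[a1] <- cn1; lo_c[a2] <- hi_c[a2] <- cn2
        lo_c[a3] <- c3[1]; hi_c[a3] <- c3[length(c3)]
        cl <- extract_box(h, kappa - 1L, lo_c, hi_c, f)
        cm <- matrix(as.vector(cl), ncol = 1L)
        ci <- tang_quad(cm, c3[1], t3)[, 1]           # coarse value per t3
        # fine diagonal interior cells (padded indices)
        p1a <- if (s1 < 0L) 2L else d[a1] - 1L
        p1b <- if (s1 < 0L) 3L else d[a1] - 2L
        p2a <- if (s2 < 0L) 2L else d[a2] - 1L
        p2b <- if (s2 < 0L) 3L else d[a2] - 2L
        gp1 <- if (s1 < 0L) 1L else d[a1]
        gp2 <- if (s2 < 0L) 1L else d[a2]
        idx <- function(p1, p2) {
          ii <- slice_index(d, a1, p1)
          ii[[a2]] <- p2
          ii[[a3]] <- 2:(d[a3] - 1L)
          ii
        }
        ia <- idx(p1a, p2a); ib <- idx(p1b, p2b); ig <- idx(gp1, gp2)
        da <- as.vector(arr[ia$i, ia$j, ia$k])
        db <- as.vector(arr[ib$i, ib$j, ib$k])
        arr[ig$i, ig$j, ig$k] <- wN[1] * ci + wN[2] * da + wN[3] * db
      }
    }
    # ---- corners (outside along all three axes) ----------------------
    for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) for (s3 in c(-1L, 1L)) {
      ss <- c(s1, s2, s3)
      gidx <- ifelse(ss < 0L, block$lo - 1L, block$hi + 1L)
      if (any(gidx < 1L | gidx > ndom)) next
      cnn <- (gidx + 1L) %/% 2L
      cv <- extract_box(h, kappa - 1L, cnn, cnn, f)[1, 1, 1]
      pa <- ifelse(ss < 0L, 2L, d - 1L)
      pb <- ifelse(ss < 0L, 3L, d - 2L)
      gp <- ifelse(ss < 0L, 1L, d)
      val <- wN[1] * cv + wN[2] * arr[pa[1], pa[2], pa[3]] +
        wN[3] * arr[pb[1], pb[2], pb[3]]
      arr[gp[1], gp[2], gp[3]] <- val
    }
    block$data[[f]] <- arr
  }
  block
}

drop3 <- function(a, ax) {
  # drop the singleton normal axis of a face slice, keeping tangential order
  tax <- setdiff(1:3, ax)
  m <- aperm(a, c(tax, ax))
  dim(m) <- dim(m)[1:2]
  m
}

# Overwrite ghost cells of `block` that overlap the interior of a same-level
# neighbor by that neighbor's (more accurate) cell-centered data.
exchange_ghosts_block <- function(block, level, self_index, fields) {
  d0 <- block$lo - 1L; d1 <- block$hi + 1L
  for (jb in seq_along(level$blocks)) {
    if (jb == self_index) next
    nb <- level$blocks[[jb]]
    il <- pmax(d0, nb$lo); ih <- pmin(d1, nb$hi)
    if (any(il > ih)) next
    for (f in fields) {
      src <- nb$data[[f]]; dst <- block$data[[f]]
      dst[(il[1] - d0[1] + 1L):(ih[1] - d0[1] + 1L),
          (il[2] - d0[2] + 1L):(ih[2] - d0[2] + 1L),
          (il[3] - d0[3] + 1L):(ih[3] - d0[3] + 1L)] <-
        src[(il[1] - nb$lo[1] + 2L):(ih[1] - nb$lo[1] + 2L),
            (il[2] - nb$lo[2] + 2L):(ih[2] - nb$lo[2] + 2L),
            (il[3] - nb$lo[3] + 2L):(ih[3] - nb$lo[3] + 2L)]
      block$data[[f]] <- dst
    }
  }
  block
}

#' Fill all ghost layers of one level
#'
#' Global levels (`kappa <= 0`) only need physical boundary conditions.
#' Refined levels are filled in three stages: quadratic interpolation from
#' the level below (faces via two tangential passes with weights
#' \{30, 5, -3\}/32 followed by a normal quadratic pass; edges/corners via
#' the diagonal rule), then ghosts overlapping a same-level neighbor's
#' interior are replaced by that data, then physical boundary faces are set
#' from the boundary conditions.
#'
#' @inheritParams apply_bcs
#' @return the updated hierarchy.
#' @export
fill_ghosts <- function(h, kappa, fields, bcs) {
  lv <- get_level(h, kappa)
  if (kappa > h$kappa_min) {
    # make sure the coarse level's physical ghosts are usable
    h <- apply_bcs(h, kappa - 1L, fields, bcs)
  }
  if (kappa >= 1L) {
    lv <- get_level(h, kappa)
    for (ib in seq_along(lv$blocks)) {
      lv$blocks[[ib]] <-
        fill_ghost_block_quadratic(h, kappa, lv$blocks[[ib]], fields)
    }
    for (ib in seq_along(lv$blocks)) {
      lv$blocks[[ib]] <- exchange_ghosts_block(lv$blocks[[ib]], lv, ib, fields)
    }
    h <- set_level(h, kappa, lv)
  }
  apply_bcs(h, kappa, fields, bcs)
}

#' Quadratic coarse-fine ghost interpolation for one block
#'
#' Lower-level entry point of [fill_ghosts()] exposed for testing and reuse:
#' fills the ghost layer of `block` (a refined-level block) from the level
#' below, then overwrites ghosts overlapping same-level neighbors.
#'
#' @param h a `tmg_hierarchy`.
#' @param kappa refined level index (>= 1).
#' @param block_index which block of the level to fill.
#' @param fields field names.
#' @return the filled `tmg_block`.
#' @export
fill_ghost_quadratic <- function(h, kappa, block_index, fields) {
  lv <- get_level(h, kappa)
  b <- fill_ghost_block_quadratic(h, kappa, lv$blocks[[block_index]], fields)
  exchange_ghosts_block(b, lv, block_index, fields)
}
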