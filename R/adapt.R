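# ---------------------------------------------------------------------------
# Refinement machinery: flagging, flag buffering, signature-based clustering
# of flagged cells into rectangular blocks, and data migration onto the new
# grid structure.
# ---------------------------------------------------------------------------

#' Flag cells by the undivided gradient test
#'
#' Flags every interior cell of level `kappa` where the sum of squared
#' undivided centered differences of the indicator field exceeds the
#' critical value:
#' \deqn{(\psi_{i+1,j,k}-\psi_{i-1,j,k})^2 + (\psi_{i,j+1,k}-\psi_{i,j-1,k})^2
#'   + (\psi_{i,j,k+1}-\psi_{i,j,k-1})^2 > C}
#' No division by the mesh spacing is performed, and the squared sum is
#' compared against `C` itself (not `C^2`).
#'
#' @param h a `tmg_hierarchy` with valid ghosts for `field` on `kappa`.
#' @param kappa level to test.
#' @param field indicator field name (typically the total tumor fraction).
#' @param C critical value (default 0.05).
#' @return a flag set: list with `kappa`, `ndom` (domain cells per axis at
#'   this level) and `cells`, an n-by-3 integer matrix of flagged indices in
#'   level index space.
#' @export
flag_undivided_gradient <- function(h, kappa, field, C = 0.05) {
  lv <- get_level(h, kappa)
  ndom <- level_ncells_domain(h, kappa)
  cells <- NULL
  for (b in lv$blocks) {
    a <- b$data[[field]]
    d <- dim(a)
    i <- 2:(d[1] - 1L); j <- 2:(d[2] - 1L); k <- 2:(d[3] - 1L)
    g2 <- (a[i + 1L, j, k, drop = FALSE] - a[i - 1L, j, k, drop = FALSE])^2 +
          (a[i, j + 1L, k, drop = FALSE] - a[i, j - 1L, k, drop = FALSE])^2 +
          (a[i, j, k + 1L, drop = FALSE] - a[i, j, k - 1L, drop = FALSE])^2
    w <- which(g2 > C, arr.ind = TRUE)
    if (nrow(w) > 0L) {
      w <- sweep(w, 2L, b$lo - 1L, "+")
      cells <- rbind(cells, w)
    }
  }
  if (is.null(cells)) cells <- matrix(integer(0), 0L, 3L)
  dimnames(cells) <- NULL
  list(kappa = kappa, ndom = ndom, cells = cells)
}

#' Flag cells by the relative truncation error test
#'
#' Flags level-`kappa` cells where the relative truncation error
#' \eqn{\tau_h^{2h} = L_{\kappa-1}(R\psi) - R\,L_\kappa(\psi)} between the
#' level and the level below exceeds `threshold`.  The comparison is made on
#' the coarse grid and each flagged coarse cell flags its (up to) eight
#' children on level `kappa`.  Provided as an alternative refinement
#' criterion; the undivided gradient test is the default.
#'
#' @param h hierarchy with valid ghosts on `kappa` and `kappa - 1`.
#' @param kappa level to test (`kappa > kappa_min`).
#' @param system a solver system (see [scalar_system()]), whose operator is
#'   applied on both levels.
#' @param threshold flag where `|tau| > threshold`.
#' @return a flag set as in [flag_undivided_gradient()].
#' @export
flag_truncation_error <- function(h, kappa, system, threshold) {
  tau <- tau_coarse(h, kappa, system)   # defined with the solver systems
  cells <- NULL
  for (ent in tau) {
    w <- which(abs(ent$tau) > threshold, arr.ind = TRUE)
    if (nrow(w) > 0L) {
      w <- sweep(w, 2L, ent$clo - 1L, "+")
      # coarse cell c -> fine children 2c-1, 2c per axis
      for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
        wf <- cbind(2L * w[, 1] - 1L + ox, 2L * w[, 2] - 1L + oy,
                    2L * w[, 3] - 1L + oz)
        cells <- rbind(cells, wf)
      }
    }
  }
  if (is.null(cells)) cells <- matrix(integer(0), 0L, 3L)
  ndom <- level_ncells_domain(h, kappa)
  keep <- cells[, 1] >= 1L & cells[, 1] <= ndom[1] &
          cells[, 2] >= 1L & cells[, 2] <= ndom[2] &
          cells[, 3] >= 1L & cells[, 3] <= ndom[3]
  cells <- cells[keep, , drop = FALSE]
  cells <- unique(cells)
  dimnames(cells) <- NULL
  list(kappa = kappa, ndom = ndom, cells = cells)
}

# logical coverage mask of the level's block union
level_mask <- function(h, kappa) {
  ndom <- level_ncells_domain(h, kappa)
  m <- array(FALSE, ndom)
  for (b in get_level(h, kappa)$blocks)
    m[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
  m
}

#' Buffer a flag set
#'
#' Every flagged cell additionally flags the `radius` cells on each side
#' along every axis (a `(2*radius+1)^3` cube, 9x9x9 with the default
#' radius 4), clipped at the external domain boundary and at the boundary of
#' the level's block union so refined blocks stay properly nested.
#'
#' @param flags a flag set.
#' @param h the hierarchy (for the level coverage mask).
#' @param radius buffer radius in cells (default 4).
#' @return the buffered flag set.
#' @export
buffer_flags <- function(flags, h, radius = 4L) {
  if (nrow(flags$cells) == 0L) return(flags)
  ndom <- flags$ndom
  m <- array(FALSE, ndom)
  m[flags$cells] <- TRUE
  for (ax in 1:3) {
    acc <- m
    for (s in seq_len(radius)) {
      n <- ndom[ax]
      idx_to <- slice_index(ndom, ax, 1L:(n - s))
      idx_from <- slice_index(ndom, ax, (1L + s):n)
      acc[idx_to$i, idx_to$j, idx_to$k] <-
        acc[idx_to$i, idx_to$j, idx_to$k] |
        m[idx_from$i, idx_from$j, idx_from$k]
      acc[idx_from$i, idx_from$j, idx_from$k] <-
        acc[idx_from$i, idx_from$j, idx_from$k] |
        m[idx_to$i, idx_to$j, idx_to$k]
    }
    m <- acc
  }
  m <- m & level_mask(h, flags$kappa)
  cells <- which(m, arr.ind = TRUE)
  dimnames(cells) <- NULL
  list(kappa = flags$kappa, ndom = ndom, cells = cells)
}

# signatures: number of flagged cells in each slice along each axis of the
# sub-box blo..bhi of mask m
box_signatures <- function(m, blo, bhi) {
  sub <- m[blo[1]:bhi[1], blo[2]:bhi[2], blo[3]:bhi[3], drop = FALSE]
  list(apply(sub, 1L, sum), apply(sub, 2L, sum), apply(sub, 3L, sum))
}

trim_box <- function(sig, blo, bhi) {
  for (ax in 1:3) {
    s <- sig[[ax]]
    nz <- which(s > 0L)
    if (length(nz) == 0L) return(NULL)
    blo[ax] <- blo[ax] + nz[1] - 1L
    bhi[ax] <- bhi[ax] - (length(s) - nz[length(nz)])
    sig[[ax]] <- s[nz[1]:nz[length(nz)]]
  }
  list(lo = blo, hi = bhi)
}

# most central index from a candidate set (ties toward the lower index)
most_central <- function(cand, center) {
  d <- abs(cand - center)
  cand[order(d, cand)][1]
}

#' Cluster flagged cells into refined blocks
#'
#' Signature-based clustering: starting from the bounding box of all flags,
#' each candidate box is (1) accepted if its efficiency (flagged/total
#' cells) reaches `threshold_eff` or its size is at most `2*threshold_size`
#' cells; otherwise it is split (2) at the most central zero-signature gap
#' (longest axis first), else (3) at the most central sign change of the
#' signature's second difference, else (4) accepted if efficiency is at
#' least `min_eff`, otherwise bisected at the midpoint of its longest axis;
#' (5) empty edge slices of every new box are trimmed.  The result is
#' expressed in the index space of level `kappa + 1` (indices doubled) and
#' clipped to the union of level-`kappa` blocks so the new level nests
#' properly.
#'
#' @param flags a (typically buffered) flag set on level `kappa`.
#' @param h the hierarchy.
#' @param threshold_eff efficiency above which a box is accepted (0.9).
#' @param threshold_size size acceptance bound in cells (10^3).
#' @param min_eff lowest efficiency tolerated before bisection (0.5).
#' @return list with `kappa` (`= flags$kappa + 1`) and `boxes`, a list of
#'   `list(lo, hi)` integer corner pairs on the refined level.
#' @export
generate_blocks <- function(flags, h, threshold_eff = 0.9,
                            threshold_size = 1000, min_eff = 0.5) {
  kfine <- flags$kappa + 1L
  if (nrow(flags$cells) == 0L)
    return(list(kappa = kfine, boxes = list()))
  m <- array(FALSE, flags$ndom)
  m[flags$cells] <- TRUE
  bbox <- list(lo = apply(flags$cells, 2L, min),
               hi = apply(flags$cells, 2L, max))
  work <- list(bbox)
  accepted <- list()
  while (length(work) > 0L) {
    bx <- work[[length(work)]]
    work[[length(work)]] <- NULL
    sig <- box_signatures(m, bx$lo, bx$hi)
    tb <- trim_box(sig, bx$lo, bx$hi)
    if (is.null(tb)) next                      # no flags at all
    blo <- tb$lo; bhi <- tb$hi
    sig <- box_signatures(m, blo, bhi)         # signatures of trimmed box
    len <- bhi - blo + 1L
    vol <- prod(len)
    nfl <- sum(sig[[1]])
    eff <- nfl / vol
    if (eff >= threshold_eff || vol <= 2 * threshold_size) {
      accepted[[length(accepted) + 1L]] <- list(lo = blo, hi = bhi)
      next
    }
    ax_order <- order(-len, 1:3)
    split_at <- NULL
    for (ax in ax_order) {                     # step 2: zero-signature gaps
      gaps <- which(sig[[ax]] == 0L)
      gaps <- gaps[gaps > 1L & gaps < len[ax]]
      if (length(gaps) > 0L) {
        g <- most_central(gaps, (len[ax] + 1) / 2)
        split_at <- list(ax = ax, left_hi = blo[ax] + g - 1L)
        break
      }
    }
    if (is.null(split_at)) {                   # step 3: inflection points
      for (ax in ax_order) {
        s <- sig[[ax]]
        if (len[ax] < 4L) next
        dd <- s[1:(len[ax] - 2L)] - 2 * s[2:(len[ax] - 1L)] +
          s[3:len[ax]]                         # dd[i] at slice i+1
        sc <- which(dd[-length(dd)] * dd[-1] < 0)  # sign change i+1 -> i+2
        if (length(sc) > 0L) {
          g <- most_central(sc + 1L, (len[ax] + 1) / 2)
          split_at <- list(ax = ax, left_hi = blo[ax] + g - 1L)
          break
        }
      }
    }
    if (is.null(split_at)) {                   # step 4
      if (eff >= min_eff) {
        accepted[[length(accepted) + 1L]] <- list(lo = blo, hi = bhi)
        next
      }
      ax <- ax_order[1]
      split_at <- list(ax = ax, left_hi = blo[ax] + len[ax] %/% 2L - 1L)
    }
    ax <- split_at$ax
    l1 <- blo; h1 <- bhi; h1[ax] <- split_at$left_hi
    l2 <- blo; h2 <- bhi; l2[ax] <- split_at$left_hi + 1L
    work[[length(work) + 1L]] <- list(lo = l1, hi = h1)
    work[[length(work) + 1L]] <- list(lo = l2, hi = h2)
  }
  # double to the finer index space and clip to the parent block union
  boxes <- list()
  parents <- get_level(h, flags$kappa)$blocks
  for (bx in accepted) {
    flo <- 2L * bx$lo - 1L; fhi <- 2L * bx$hi
    for (pb in parents) {
      plo <- 2L * pb$lo - 1L; phi <- 2L * pb$hi
      il <- pmax(flo, plo); ih <- pmin(fhi, phi)
      if (all(il <= ih))
        boxes[[length(boxes) + 1L]] <- list(lo = il, hi = ih)
    }
  }
  list(kappa = kfine, boxes = boxes)
}

#' Rebuild a refined level from a new block list and migrate data
#'
#' Current-time data on the new blocks is generated by cubic interpolation
#' from the level below; previous-time data is copied bit-identically from
#' old blocks where new cells overlap them and cubic-interpolated from the
#' coarse level elsewhere.  Before the new level is built, all old fine data
#' is averaged down to the coarse level, so regions no longer covered retain
#' the (restricted) fine information.  Ghosts are filled afterwards.
#'
#' @param h hierarchy.
#' @param kappa refined level being rebuilt (>= 1).
#' @param blocklist result of [generate_blocks()] with `kappa` matching.
#' @param fields_now current-time field names (interpolated from coarse).
#' @param fields_prev previous-time field names (copy where overlapping).
#' @param bcs boundary conditions for ghost filling.
#' @return the updated hierarchy.
#' @export
regrid_transfer <- function(h, kappa, blocklist, fields_now, fields_prev,
                            bcs) {
  stopifnot(blocklist$kappa == kappa, kappa >= 1L)
  allf <- union(fields_now, fields_prev)
  old_blocks <- get_level(h, kappa)$blocks
  # average all old fine data down to the coarse level
  for (b in old_blocks) {
    clo <- (b$lo + 1L) %/% 2L; chi <- b$hi %/% 2L
    for (f in allf)
      h <- deposit_box(h, kappa - 1L, clo, chi, f,
                       restrict_avg(interior(b$data[[f]])))
  }
  h <- fill_ghosts(h, kappa - 1L, allf, bcs)
  # proper nesting check
  pmask <- level_mask(h, kappa - 1L)
  new_blocks <- list()
  for (bx in blocklist$boxes) {
    clo <- (bx$lo + 1L) %/% 2L; chi <- bx$hi %/% 2L
    if (!all(pmask[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]]))
      stop("regrid_transfer: new block not nested in the level below")
    nb <- new_block(bx$lo, bx$hi)
    nb <- block_add_fields(nb, allf)
    for (f in allf) {
      cp <- extract_box(h, kappa - 1L, clo - 2L, chi + 2L, f)
      fine <- fmg_interp_cubic(cp, margin = 2L)
      a <- nb$data[[f]]
      interior(a) <- fine
      nb$data[[f]] <- a
    }
    # previous-time data: copy from overlapping old blocks
    for (f in fields_prev) {
      a <- nb$data[[f]]
      for (ob in old_blocks) {
        il <- pmax(bx$lo, ob$lo); ih <- pmin(bx$hi, ob$hi)
        if (any(il > ih)) next
        a[(il[1] - bx$lo[1] + 2L):(ih[1] - bx$lo[1] + 2L),
          (il[2] - bx$lo[2] + 2L):(ih[2] - bx$lo[2] + 2L),
          (il[3] - bx$lo[3] + 2L):(ih[3] - bx$lo[3] + 2L)] <-
          ob$data[[f]][(il[1] - ob$lo[1] + 2L):(ih[1] - ob$lo[1] + 2L),
                       (il[2] - ob$lo[2] + 2L):(ih[2] - ob$lo[2] + 2L),
                       (il[3] - ob$lo[3] + 2L):(ih[3] - ob$lo[3] + 2L)]
      }
      nb$data[[f]] <- a
    }
    new_blocks[[length(new_blocks) + 1L]] <- nb
  }
  lv <- get_level(h, kappa)
  lv$blocks <- new_blocks
  h <- set_level(h, kappa, lv)
  if (length(new_blocks) > 0L) h <- fill_ghosts(h, kappa, allf, bcs)
  h
}
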