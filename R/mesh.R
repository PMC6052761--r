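#' @useDynLib tumormg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Block-structured cell-centered Cartesian mesh hierarchy.
#
# Grid levels are numbered kappa = kappa_min, ..., 0, ..., kappa_max.  Levels
# kappa <= 0 are "global": a single block covering the whole domain, each
# twice as fine as the one below; kappa = 0 is the root.  Levels kappa >= 1
# consist of rectangular blocks of refined mesh nested in the level below.
# Cell-centered storage with one ghost layer per face: interior cells are
# indexed 1..N per axis, ghosts 0 and N+1, and stored arrays carry the
# padding, so arr[i+1, j+1, k+1] is cell (i, j, k).
# ---------------------------------------------------------------------------

#' Create a mesh block
#'
#' A block is a rectangular box of cells in the index space of one grid
#' level.  `lo` and `hi` are inclusive 1-based interior cell indices.  Field
#' arrays are allocated with one ghost layer on every face.
#'
#' @param lo,hi integer triples, inclusive cell-index corners.
#' @return an object of class `"tmg_block"`.
#' @keywords internal
new_block <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi >= lo))
  structure(list(lo = lo, hi = hi, data = list(), face_data = list()),
            class = "tmg_block")
}

#' @keywords internal
block_dims <- function(block) block$hi - block$lo + 1L

#' @keywords internal
block_ncell <- function(block) prod(block_dims(block))

#' Allocate named cell-centered fields on a block
#'
#' @param block a `tmg_block`.
#' @param names character vector of field names.
#' @param value initial fill value.
#' @return the block with the new arrays (ghost-padded) attached.
#' @keywords internal
block_add_fields <- function(block, names, value = 0) {
  d <- block_dims(block) + 2L
  for (nm in names) block$data[[nm]] <- array(value, dim = d)
  block
}

#' Interior view of a ghost-padded block array
#' @keywords internal
interior <- function(arr) {
  d <- dim(arr)
  arr[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L), drop = FALSE]
}

#' Replace the interior of a ghost-padded array
#' @keywords internal
`interior<-` <- function(arr, value) {
  d <- dim(arr)
  arr[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] <- value
  arr
}

#' Create a grid level
#'
#' @param kappa integer level index.
#' @param eta mesh spacing (uniform and equal on all axes).
#' @param blocks list of `tmg_block`s; pairwise non-overlapping.
#' @keywords internal
new_level <- function(kappa, eta, blocks = list()) {
  structure(list(kappa = as.integer(kappa), eta = eta, blocks = blocks),
            class = "tmg_level")
}

#' Build a multilevel mesh hierarchy
#'
#' Constructs the global levels `kappa_min..0` (one full-domain block each,
#' spacing halving per level so that `eta[kappa+1] = eta[kappa]/2`) and empty
#' refinement levels `1..kappa_max`.
#'
#' @param domain list with numeric triples `L` and `R`, the lower and upper
#'   physical domain bounds per axis.
#' @param root_cells integer triple: cells per axis on the root level
#'   (`kappa = 0`).  Must be divisible by `2^(n_global-1)` so every coarser
#'   global level has a whole number of cells, and the spacing
#'   `(R - L)/root_cells` must be equal on all axes (cubic cells).
#' @param n_global number of global levels (root plus coarser levels);
#'   `kappa_min = -(n_global - 1)`.
#' @param kappa_max finest level index (>= 0); levels `1..kappa_max` start
#'   empty and are populated by the regridder.
#' @return an object of class `"tmg_hierarchy"`.
#' @examples
#' h <- build_hierarchy(list(L = c(0, 0, 0), R = c(40, 40, 40)),
#'                      root_cells = c(32, 32, 32), n_global = 3,
#'                      kappa_max = 2)
#' count_dof(h)  # 8^3 + 16^3 + 32^3 = 37376
#' @export
build_hierarchy <- function(domain, root_cells, n_global, kappa_max = 0L) {
  stopifnot(n_global >= 1L, kappa_max >= 0L)
  root_cells <- as.integer(rep_len(root_cells, 3L))
  L <- as.numeric(domain$L); R <- as.numeric(domain$R)
  stopifnot(length(L) == 3L, length(R) == 3L, all(R > L))
  kappa_min <- -(n_global - 1L)
  div <- 2L^(n_global - 1L)
  if (any(root_cells %% div != 0L))
    stop("root_cells must be divisible by 2^(n_global-1) = ", div)
  eta_axes <- (R - L) / root_cells
  if (diff(range(eta_axes)) > 1e-12 * max(eta_axes))
    stop("anisotropic spacing: (R-L)/root_cells must be equal on all axes")
  eta0 <- eta_axes[1]
  levels <- vector("list", n_global + kappa_max)
  for (kappa in kappa_min:0L) {
    n <- root_cells %/% (2L^(-kappa))
    blk <- new_block(c(1L, 1L, 1L), n)
    levels[[kappa - kappa_min + 1L]] <-
      new_level(kappa, eta0 * 2^(-kappa), list(blk))
  }
  if (kappa_max >= 1L) {
    for (kappa in 1L:kappa_max)
      levels[[kappa - kappa_min + 1L]] <-
        new_level(kappa, eta0 / 2^kappa, list())
  }
  structure(list(kappa_min = kappa_min, kappa_max = as.integer(kappa_max),
                 domain = list(L = L, R = R), root_cells = root_cells,
                 levels = levels),
            class = "tmg_hierarchy")
}

#' Access one level of a hierarchy by its kappa index
#'
#' @param h a `tmg_hierarchy`.
#' @param kappa level index (`kappa_min..kappa_max`).
#' @return the `tmg_level`.
#' @export
get_level <- function(h, kappa) h$levels[[kappa - h$kappa_min + 1L]]

#' @keywords internal
set_level <- function(h, kappa, level) {
  h$levels[[kappa - h$kappa_min + 1L]] <- level
  h
}

#' Cells per axis of the (conceptual) full-domain grid at a level
#' @keywords internal
level_ncells_domain <- function(h, kappa) {
  as.integer(round(h$root_cells * 2^kappa))
}

#' Cell-center and edge coordinates of a block
#'
#' Centers obey `x_i = L + (i - 1/2) * eta` and edges `x_{i+1/2} = L + i*eta`
#' in level index space; ghost centers extend the same formula to `i = lo-1`
#' and `i = hi+1`.
#'
#' @param level a `tmg_level`.
#' @param block a `tmg_block` belonging to `level`.
#' @param domain domain bounds as in [build_hierarchy()].
#' @return list with `centers` and `edges`: each a list of three numeric
#'   vectors (per axis).  `centers[[ax]]` has `n+2` entries (ghosts first and
#'   last); `edges[[ax]]` has `n+1` entries.
#' @export
cell_geometry <- function(level, block, domain) {
  eta <- level$eta
  centers <- edges <- vector("list", 3L)
  for (ax in 1:3) {
    idx <- (block$lo[ax] - 1L):(block$hi[ax] + 1L)
    centers[[ax]] <- domain$L[ax] + (idx - 0.5) * eta
    edges[[ax]] <- domain$L[ax] + ((block$lo[ax] - 1L):block$hi[ax]) * eta
  }
  list(centers = centers, edges = edges)
}

#' Count the degrees of freedom of a hierarchy
#'
#' Sum of interior cell counts over all blocks of all levels.  External
#' boundary and internal (ghost) cells are excluded, and coarse cells that
#' lie underneath refined blocks are counted (every level contributes its
#' full cell count).
#'
#' @param h a `tmg_hierarchy`.
#' @return integer total cell count.
#' @export
count_dof <- function(h) {
  tot <- 0
  for (lv in h$levels) for (b in lv$blocks) tot <- tot + block_ncell(b)
  as.integer(tot)
}

#' Export a mesh summary
#'
#' Per-level spacing, block corner coordinates (physical and index space)
#' and DOF, as a list convertible to JSON.
#'
#' @param h a `tmg_hierarchy`.
#' @param path optional file path; if given, the summary is written as JSON.
#' @return the summary list, invisibly when written to file.
#' @export
mesh_summary <- function(h, path = NULL) {
  out <- list(kappa_min = h$kappa_min, kappa_max = h$kappa_max,
              domain = h$domain, dof = count_dof(h), levels = list())
  for (lv in h$levels) {
    blocks <- lapply(lv$blocks, function(b) {
      list(lo = b$lo, hi = b$hi,
           xlo = h$domain$L + (b$lo - 1L) * lv$eta,
           xhi = h$domain$L + b$hi * lv$eta,
           cells = block_ncell(b))
    })
    out$levels[[length(out$levels) + 1L]] <-
      list(kappa = lv$kappa, eta = lv$eta, n_blocks = length(lv$blocks),
           dof = sum(vapply(lv$blocks, block_ncell, numeric(1))),
           blocks = blocks)
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' @export
print.tmg_hierarchy <- function(x, ...) {
  cat(sprintf("<tmg_hierarchy> levels %d..%d, domain [%g,%g]^3, DOF %d\n",
              x$kappa_min, x$kappa_max, x$domain$L[1], x$domain$R[1],
              count_dof(x)))
  for (lv in x$levels)
    cat(sprintf("  kappa %+d  eta %-8.5g  blocks %d\n", lv$kappa, lv$eta,
                length(lv$blocks)))
  invisible(x)
}
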