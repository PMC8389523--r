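#' Build a rounded aggregate of cells in medium (free boundary conditions)
#'
#' Constructs the standard initial condition for sorting runs: `n_cells`
#' square cells of `sqrt(a0) x sqrt(a0)` sites tiled into a rounded cluster
#' at the lattice center (the `n_cells` whole squares closest to the center,
#' so every cell starts at exactly `a0` sites), surrounded by at least
#' `margin` sites of medium on every side. Exactly
#' `round(ratio_blue * n_cells)` cells are drawn uniformly at random to be
#' blue; the rest are yellow. Square shapes relax within a few MCS and are
#' irrelevant to the long-time kinetics.
#'
#' @param n_cells number of cells (>= 1).
#' @param ratio_blue fraction of blue cells in `[0, 1]` (default 0.5).
#' @param a0 sites per cell; must be a perfect square (default 100).
#' @param margin medium sites on every side; default `5 * sqrt(a0)`.
#' @param seed optional integer seed for the type assignment.
#' @param lattice_size optional `c(rows, cols)`; errors if too small for the
#'   aggregate plus margin.
#' @return a [cpm_state()] with `bc = "free"`.
#' @export
#' @examples
#' s <- build_aggregate(50, ratio_blue = 0.2, seed = 1)
#' table(cell_table(s)$type)  # 10 B, 40 Y
build_aggregate <- function(n_cells, ratio_blue = 0.5, a0 = 100,
                            margin = NULL, seed = NULL, lattice_size = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (ratio_blue < 0 || ratio_blue > 1) stop("ratio_blue must be in [0, 1]")
  side <- sqrt(a0)
  if (side != round(side)) stop("a0 must be a perfect square")
  side <- as.integer(side)
  if (is.null(margin)) margin <- 5L * side
  if (!is.null(seed)) set.seed(seed)

  # candidate square blocks on a grid large enough to cover the disk; pick
  # the n_cells blocks whose centers are closest to the origin (deterministic
  # tie-break by block coordinates)
  half <- ceiling(sqrt(n_cells / pi)) + 2L
  bl <- expand.grid(bi = -half:half, bj = -half:half)
  cx <- (bl$bi + 0.5) * side
  cy <- (bl$bj + 0.5) * side
  ord <- order(cx^2 + cy^2, bl$bi, bl$bj)
  sel <- bl[ord[seq_len(n_cells)], ]

  bi0 <- min(sel$bi); bj0 <- min(sel$bj)
  nbi <- max(sel$bi) - bi0 + 1L; nbj <- max(sel$bj) - bj0 + 1L
  nr <- nbi * side + 2L * margin
  nc <- nbj * side + 2L * margin
  if (!is.null(lattice_size)) {
    if (lattice_size[1] < nr || lattice_size[2] < nc)
      stop(sprintf("lattice too small for disk + margin: need >= %d x %d", nr, nc))
    nr <- as.integer(lattice_size[1]); nc <- as.integer(lattice_size[2])
  }
  grid <- matrix(0L, nr, nc)
  r_off <- margin + as.integer(floor((nr - 2L * margin - nbi * side) / 2))
  c_off <- margin + as.integer(floor((nc - 2L * margin - nbj * side) / 2))
  for (i in seq_len(n_cells)) {
    r0 <- r_off + (sel$bi[i] - bi0) * side
    c0 <- c_off + (sel$bj[i] - bj0) * side
    grid[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side)] <- i
  }
  cpm_state(grid, types = assign_types(n_cells, ratio_blue), bc = "free")
}

# exact-count random type assignment: blue count is round(ratio * n), not
# binomially sampled, so the mixture ratio is a controlled variable
assign_types <- function(n_cells, ratio_blue) {
  n_blue <- round(ratio_blue * n_cells)
  types <- rep(2L, n_cells)
  if (n_blue > 0) types[sample.int(n_cells, n_blue)] <- 1L
  types
}

#' Build a space-filling periodic cell tiling
#'
#' Tiles the torus exactly with `n_cells` square cells of `a0` sites each (no
#' medium), with exact-count random type assignment. The cell grid dimensions
#' default to the most nearly square divisor pair of `n_cells`.
#'
#' @param n_cells number of cells.
#' @param ratio_blue fraction of blue cells (default 0.5).
#' @param a0 sites per cell; must be a perfect square (default 100).
#' @param seed optional integer seed for the type assignment.
#' @param cell_dims optional `c(nx, ny)` cell-grid dimensions with
#'   `nx * ny == n_cells`.
#' @return a [cpm_state()] with `bc = "periodic"`.
#' @export
#' @examples
#' s <- build_periodic(24, seed = 1)
#' dim(s$grid)          # 60 x 40
#' sum(s$grid == 0)     # 0: no medium
build_periodic <- function(n_cells, ratio_blue = 0.5, a0 = 100, seed = NULL,
                           cell_dims = NULL) {
  side <- sqrt(a0)
  if (side != round(side)) stop("a0 must be a perfect square")
  side <- as.integer(side)
  if (is.null(cell_dims)) {
    divs <- which(n_cells %% seq_len(floor(sqrt(n_cells))) == 0)
    ny <- max(divs)
    cell_dims <- c(n_cells / ny, ny)
  }
  if (prod(cell_dims) != n_cells)
    stop("cell_dims do not factor n_cells: geometry not tileable")
  if (max(cell_dims) / min(cell_dims) > 8)
    warning("strongly anisotropic cell tiling (aspect ratio > 8)")
  if (!is.null(seed)) set.seed(seed)
  nx <- as.integer(cell_dims[1]); ny <- as.integer(cell_dims[2])
  grid <- matrix(0L, nx * side, ny * side)
  id <- 0L
  for (bj in seq_len(ny)) {
    for (bi in seq_len(nx)) {
      id <- id + 1L
      grid[((bi - 1L) * side + 1L):(bi * side),
           ((bj - 1L) * side + 1L):(bj * side)] <- id
    }
  }
  cpm_state(grid, types = assign_types(n_cells, ratio_blue), bc = "periodic")
}

#' Deterministic tiny lattice fixtures
#'
#' Hand-checkable states for tests and examples:
#' \describe{
#'   \item{`single_cell`}{one 10x10 blue cell filling a periodic 10x10
#'     lattice: H = 0 at defaults, boundary length 0.}
#'   \item{`two_cells_hetero`}{two 10x10 squares of types B and Y sharing a
#'     10-site edge, in medium: heterotypic order-1 contact count 10.}
#'   \item{`four_cell_checkerboard`}{four 5x5 cells in a 2x2 B/Y
#'     checkerboard, in medium.}
#'   \item{`cell_in_medium`}{one 10x10 blue cell alone in medium: a detached
#'     cell by construction.}
#'   \item{`split_cell_invalid`}{a deliberately broken state whose single
#'     cell occupies two distant blobs (2 components): fails the global
#'     connectivity audit.}
#' }
#'
#' @param name fixture name (see above).
#' @return a [cpm_state()].
#' @export
make_fixture <- function(name = c("single_cell", "two_cells_hetero",
                                  "four_cell_checkerboard", "cell_in_medium",
                                  "split_cell_invalid")) {
  name <- match.arg(name)
  switch(name,
    single_cell = cpm_state(matrix(1L, 10, 10), types = "B", bc = "periodic"),
    two_cells_hetero = {
      g <- matrix(0L, 20, 30)
      g[6:15, 6:15] <- 1L
      g[6:15, 16:25] <- 2L
      cpm_state(g, types = c("B", "Y"), bc = "free")
    },
    four_cell_checkerboard = {
      g <- matrix(0L, 20, 20)
      g[6:10, 6:10] <- 1L
      g[6:10, 11:15] <- 2L
      g[11:15, 6:10] <- 3L
      g[11:15, 11:15] <- 4L
      cpm_state(g, types = c(1L, 2L, 2L, 1L), bc = "free")
    },
    cell_in_medium = {
      g <- matrix(0L, 20, 20)
      g[6:15, 6:15] <- 1L
      cpm_state(g, types = "B", bc = "free")
    },
    split_cell_invalid = {
      g <- matrix(0L, 20, 20)
      g[3:5, 3:5] <- 1L
      g[14:16, 14:16] <- 1L
      cpm_state(g, types = "B", bc = "free")
    })
}
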