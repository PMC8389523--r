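#' Boundary length: heterotypic site contacts
#'
#' The sorting progress metric: the number of unordered order-1 (von Neumann)
#' neighboring site pairs whose two sites belong to cells of types B and Y
#' respectively. Cell-medium contacts are excluded by default (they would
#' never decay as sorting completes); set `gamma_include_medium` in the
#' parameters to include them for sensitivity checks.
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()]; only `gamma_include_medium` is used.
#' @return the contact count, a single number.
#' @export
#' @examples
#' boundary_length(make_fixture("two_cells_hetero"))  # 10
boundary_length <- function(state, params = cpm_params()) {
  cpp_boundary_length(state$grid, state$type_of, state$bc == "periodic",
                      params$gamma_include_medium)
}

#' Spatial autocorrelation of the cell-type spin field
#'
#' Computes `C(r, t) = <s(r0) s(r0 + r)> - <s(r0)>^2` for the spin field
#' `s = +1` (blue), `-1` (yellow), with medium sites excluded from all
#' averages. The pair average runs over all ordered site pairs whose offset
#' length falls in the unit-width bin around integer `r` and whose endpoints
#' are both non-medium; in periodic mode offsets wrap (minimum image). The
#' sums are evaluated by FFT over all offsets at once; results are exact
#' (integer pair counts are recovered by rounding).
#'
#' @param state a [cpm_state()] containing both cell types (a single-type
#'   state gives a degenerate flat curve).
#' @param max_r maximum distance in sites; default a quarter of the shorter
#'   lattice side. In periodic mode must not exceed half the shorter side.
#' @return a data frame with columns `r` (0..`max_r`), `C`, and `n_pairs`
#'   (ordered pairs in the bin); bins with no pairs are dropped.
#' @export
autocorrelation <- function(state, max_r = NULL) {
  grid <- state$grid
  nr <- nrow(grid); nc <- ncol(grid)
  periodic <- state$bc == "periodic"
  if (is.null(max_r)) max_r <- floor(min(nr, nc) / 4)
  max_r <- as.integer(max_r)
  if (max_r < 1) stop("max_r must be >= 1")
  if (periodic && max_r > floor(min(nr, nc) / 2))
    stop("max_r exceeds half the lattice side in periodic mode")

  code <- matrix(state$type_of[grid + 1L], nr, nc)
  s <- (code == 1L) - (code == 2L)      # +1 blue, -1 yellow, 0 medium
  mask <- (code != 0L) * 1
  n_sites <- sum(mask)
  if (n_sites == 0) stop("state contains no cells")

  if (periodic) {
    P1 <- nr; P2 <- nc
    S <- s; M <- mask
  } else {
    P1 <- nr + max_r; P2 <- nc + max_r
    S <- matrix(0, P1, P2); S[1:nr, 1:nc] <- s
    M <- matrix(0, P1, P2); M[1:nr, 1:nc] <- mask
  }
  num <- Re(fft(Mod(fft(S))^2, inverse = TRUE)) / (P1 * P2)
  den <- Re(fft(Mod(fft(M))^2, inverse = TRUE)) / (P1 * P2)

  # effective (minimum-image / linear-lag) offset components per FFT index
  eff <- function(idx, P) {
    d <- ifelse(idx <= max_r, idx, ifelse(idx >= P - max_r, idx - P, NA_real_))
    if (periodic) d[!is.na(d) & abs(d) > floor(P / 2)] <- NA_real_
    d
  }
  dre <- eff(0:(P1 - 1), P1)
  dce <- eff(0:(P2 - 1), P2)
  len <- sqrt(outer(dre^2, dce^2, "+"))
  rbin <- round(len)
  keep <- !is.na(rbin) & rbin <= max_r
  nums <- tapply(round(num[keep]), rbin[keep], sum)
  dens <- tapply(round(den[keep]), rbin[keep], sum)
  r <- as.integer(names(dens))
  ok <- dens > 0
  mean_s <- sum(s) / n_sites
  data.frame(r = r[ok], C = nums[ok] / dens[ok] - mean_s^2,
             n_pairs = dens[ok], row.names = NULL)
}

#' First zero of an autocorrelation curve
#'
#' The cluster size `R(t)` is defined as the position of the first zero of
#' `C(r, t)`, located by linear interpolation between the last positive and
#' the first non-positive bins. Returns `NA` when the curve never crosses
#' zero within its range (the caller should widen `max_r`).
#'
#' @param curve a data frame with columns `r` and `C`, `C[1] > 0`.
#' @return the crossing position in sites, or `NA_real_` if none.
#' @export
#' @examples
#' first_zero(data.frame(r = 0:2, C = c(1, 0.5, -0.5)))  # 1.5
first_zero <- function(curve) {
  r <- curve$r; C <- curve$C
  if (length(r) < 2) stop("curve needs at least two bins")
  if (C[1] <= 0) stop("curve must start positive")
  idx <- which(C <= 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  r[i - 1] + (r[i] - r[i - 1]) * C[i - 1] / (C[i - 1] - C[i])
}

#' Number of homotypic clusters
#'
#' Counts the connected components of the site sets of each cell type
#' (B-components plus Y-components) under 8-connectivity. Together with the
#' cluster size `R(t)` this links the boundary length to the coarsening
#' picture: for rounded clusters `Gamma ~ N R` while mass conservation gives
#' `N ~ R^-2`, hence `Gamma ~ R^-1`.
#'
#' @param state a [cpm_state()].
#' @return the total cluster count (B + Y), an integer.
#' @export
count_clusters <- function(state) {
  periodic <- state$bc == "periodic"
  cpp_count_type_clusters(state$grid, state$type_of, 1L, periodic) +
    cpp_count_type_clusters(state$grid, state$type_of, 2L, periodic)
}
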