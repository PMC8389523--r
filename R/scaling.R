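#' Power-law exponent fit on a log-log window
#'
#' Least-squares slope of `log y` versus `log t` over a time window. The
#' exponent is reported as the slope itself: negative for decays (e.g.
#' boundary length, `Gamma ~ t^-n` gives exponent `-n`), positive for growth
#' (cluster size, `R ~ t^m`). The default window is the last 1.5 decades of
#' the series.
#'
#' @param t,y positive numeric vectors (time in MCS and observable).
#' @param window `c(t_min, t_max)`; default `c(max(t)/10^1.5, max(t))`.
#' @return an object of class `power_law_fit`: list with `exponent`,
#'   `stderr`, `window`, `r_squared`, `n_points`.
#' @export
#' @examples
#' t <- 10^seq(1, 5, length.out = 20)
#' fit_exponent(t, 3 * t^-0.25)$exponent  # -0.25
fit_exponent <- function(t, y, window = NULL) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  keep <- is.finite(t) & is.finite(y) & t > 0
  t <- t[keep]; y <- y[keep]
  if (is.null(window)) window <- c(max(t) / 10^1.5, max(t))
  if (window[1] >= window[2]) stop("window must satisfy t_min < t_max")
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 5) stop("need at least 5 samples in the fit window")
  if (any(y[sel] <= 0)) stop("nonpositive y in the fit window")
  fit <- lm(log(y[sel]) ~ log(t[sel]))
  sm <- suppressWarnings(summary(fit))  # exact power laws trigger the
                                        # 'essentially perfect fit' warning
  structure(list(exponent = unname(coef(fit)[2]),
                 stderr = sm$coefficients[2, 2],
                 window = window,
                 r_squared = sm$r.squared,
                 n_points = sum(sel)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: exponent %.4f +/- %.4f (window [%g, %g], %d points, R^2 = %.4f)\n",
              x$exponent, x$stderr, x$window[1], x$window[2], x$n_points,
              x$r_squared))
  invisible(x)
}

#' Master-curve collapse deviation
#'
#' Quantifies dynamic self-similarity: each autocorrelation curve's abscissa
#' is rescaled by its own cluster size `R(t)`, all curves are interpolated
#' onto a common grid of `r/R` in `[0, 2]`, and the maximum over the grid of
#' the across-time standard deviation of `C` is returned. Perfectly
#' self-similar curves give 0 (up to interpolation error); comparing with the
#' same statistic at `sizes = 1` (no rescaling) measures how much the
#' rescaling improves superposition.
#'
#' @param curves a list of data frames with columns `r` and `C`.
#' @param sizes numeric vector of cluster sizes `R(t)`, one per curve (all
#'   finite and positive), or a single value recycled.
#' @param grid common rescaled-abscissa grid; default 81 points on `[0, 2]`.
#' @return the maximum across-time standard deviation, a single number.
#' @export
collapse_deviation <- function(curves, sizes,
                               grid = seq(0, 2, length.out = 81)) {
  if (length(curves) < 2) stop("need at least 2 curves")
  sizes <- rep_len(sizes, length(curves))
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("every curve needs a finite positive size R(t)")
  vals <- vapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    approx(cv$r / sizes[i], cv$C, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  max(apply(vals, 1, sd))
}

#' Diffusion-coalescence growth exponent
#'
#' Closed-form prediction for coarsening by diffusion and coalescence of
#' rounded domains: when domain mobility scales with domain mass as
#' `D ~ mass^alpha`, the domain size grows as `R ~ t^m` with
#' `m = 1 / (2 - d * alpha)` in `d` dimensions. For cells with no aligning
#' interactions `alpha = -1`, giving `m = 1/4` in 2D and `1/5` in 3D.
#'
#' @param d spatial dimension.
#' @param alpha mobility-mass scaling exponent.
#' @return the growth exponent `1 / (2 - d * alpha)`.
#' @export
#' @examples
#' coalescence_exponent(2, -1)  # 1/4
#' coalescence_exponent(3, -1)  # 1/5
coalescence_exponent <- function(d, alpha) {
  denom <- 2 - d * alpha
  if (any(abs(denom) < 1e-12)) stop("pole: 2 - d * alpha must be nonzero")
  1 / denom
}

#' Cell detachment probability
#'
#' Probability that a cell detaches from a homotypic cluster against an
#' adhesive energy barrier `dE_cell`: `p_cell = exp(-dE_cell / T)`. With the
#' default adhesion parameters the barrier-to-temperature ratio is about 7.5,
#' making detachment (the elementary step of evaporation-condensation
#' coarsening) negligibly rare.
#'
#' @param delta_e_over_t non-negative barrier-to-temperature ratio(s).
#' @return probability in `(0, 1]`.
#' @export
#' @examples
#' detachment_probability(7.5)  # ~5.5e-4
detachment_probability <- function(delta_e_over_t) {
  if (any(delta_e_over_t < 0)) stop("delta_e_over_t must be non-negative")
  exp(-delta_e_over_t)
}
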