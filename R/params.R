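#' Default contact-energy table
#'
#' The symmetric 3x3 table of contact energies per neighboring-site pair,
#' indexed by cell type (`M` medium, `B` blue, `Y` yellow). The default values
#' satisfy the differential-adhesion inequalities required for cell sorting:
#' the heterotypic energy exceeds the mean homotypic one
#' (J_YB > (J_BB + J_YY)/2), and yellow cells wet the medium better than blue
#' ones (J_YM < J_BM), so yellow engulfs blue.
#'
#' @param j_bb,j_yy homotypic contact energies (default 8).
#' @param j_yb heterotypic contact energy (default 14).
#' @param j_ym,j_bm cell-medium contact energies (defaults 10 and 22).
#' @param j_mm medium-medium contact energy (default 0).
#' @return a symmetric 3x3 numeric matrix with dimnames `M`, `B`, `Y`.
#' @export
#' @examples
#' default_J()
default_J <- function(j_bb = 8, j_yy = 8, j_yb = 14, j_ym = 10, j_bm = 22,
                      j_mm = 0) {
  J <- matrix(0, 3, 3, dimnames = list(c("M", "B", "Y"), c("M", "B", "Y")))
  J["M", "M"] <- j_mm
  J["B", "B"] <- j_bb
  J["Y", "Y"] <- j_yy
  J["B", "Y"] <- J["Y", "B"] <- j_yb
  J["Y", "M"] <- J["M", "Y"] <- j_ym
  J["B", "M"] <- J["M", "B"] <- j_bm
  J
}

#' Model parameters for the Potts Hamiltonian and dynamics
#'
#' Bundles the Hamiltonian parameters: contact-energy table `J`, bulk modulus
#' `B`, nominal cell area `A0`, effective temperature `T`, and the stencil
#' orders used for the boundary-energy sum (`hamiltonian_order`, 20 sites at
#' order 4 to smooth lattice anisotropy) and for target-value proposals
#' (`copy_order`, the 8-site Moore neighborhood at order 2).
#'
#' @param J symmetric 3x3 contact-energy matrix (see [default_J()]).
#' @param B bulk modulus (energy units); the stiffness of the quadratic area
#'   constraint. Default 200.
#' @param A0 nominal cell area in lattice sites. Default 100.
#' @param T effective temperature (energy units) of the Metropolis rule.
#'   Default 50.
#' @param hamiltonian_order neighbor order (1-4) of the boundary-energy
#'   stencil. Default 4 (20 sites).
#' @param copy_order neighbor order of the proposal stencil. Default 2
#'   (Moore, 8 sites).
#' @param medium_area_term include the medium in the area-elasticity sum?
#'   Default `FALSE`: the medium is a background phase with no nominal area.
#' @param medium_exempt exempt the medium from the local connectivity test?
#'   Default `TRUE`: an aggregate may enclose medium pockets.
#' @param gamma_include_medium count cell-medium contacts in the boundary
#'   length observable? Default `FALSE` (heterotypic B-Y contacts only).
#' @return an object of class `cpm_params`.
#' @export
#' @examples
#' p <- cpm_params()
#' p$J["Y", "B"]
cpm_params <- function(J = default_J(), B = 200, A0 = 100, T = 50,
                       hamiltonian_order = 4, copy_order = 2,
                       medium_area_term = FALSE, medium_exempt = TRUE,
                       gamma_include_medium = FALSE) {
  if (!is.matrix(J) || !all(dim(J) == c(3, 3)))
    stop("J must be a 3x3 matrix")
  if (max(abs(J - t(J))) > 1e-12)
    stop("J must be symmetric (J[t1, t2] == J[t2, t1])")
  if (is.null(dimnames(J)))
    dimnames(J) <- list(c("M", "B", "Y"), c("M", "B", "Y"))
  if (A0 <= 0) stop("A0 must be positive")
  if (T <= 0) stop("T must be positive")
  if (B < 0) stop("B must be non-negative")
  if (!hamiltonian_order %in% 1:4) stop("hamiltonian_order must be in 1..4")
  if (!copy_order %in% 1:4) stop("copy_order must be in 1..4")
  structure(list(J = J, B = B, A0 = A0, T = T,
                 hamiltonian_order = as.integer(hamiltonian_order),
                 copy_order = as.integer(copy_order),
                 medium_area_term = isTRUE(medium_area_term),
                 medium_exempt = isTRUE(medium_exempt),
                 gamma_include_medium = isTRUE(gamma_include_medium)),
            class = "cpm_params")
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("CPM parameters: T =", x$T, ", B =", x$B, ", A0 =", x$A0,
      ", H-order", x$hamiltonian_order, ", copy-order", x$copy_order, "\n")
  cat("J (contact energies):\n")
  print(x$J)
  invisible(x)
}

#' Check the differential-adhesion sorting inequalities
#'
#' Sorting of the binary mixture requires the heterotypic contact energy to
#' exceed the mean homotypic one, `J_YB > (J_BB + J_YY)/2` (demixing), and
#' engulfment of blue by yellow requires `J_YM < J_BM` (yellow wets the
#' medium). Violations are reported as human-readable warnings, not errors:
#' non-sorting parameter sets are legitimate control simulations.
#'
#' @param J symmetric 3x3 contact-energy matrix with dimnames `M`, `B`, `Y`.
#' @return a character vector of warnings; empty if all inequalities hold.
#' @export
#' @examples
#' check_sorting_inequalities(default_J())          # character(0)
#' check_sorting_inequalities(default_J(j_yb = 8))  # demixing warning
check_sorting_inequalities <- function(J) {
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric")
  out <- character(0)
  if (!(J["Y", "B"] > (J["B", "B"] + J["Y", "Y"]) / 2))
    out <- c(out, sprintf(
      "demixing inequality violated: J_YB = %g is not greater than (J_BB + J_YY)/2 = %g; the mixture will not sort",
      J["Y", "B"], (J["B", "B"] + J["Y", "Y"]) / 2))
  if (!(J["Y", "M"] < J["B", "M"]))
    out <- c(out, sprintf(
      "engulfment ordering violated: J_YM = %g is not less than J_BM = %g; yellow will not engulf blue",
      J["Y", "M"], J["B", "M"]))
  out
}
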