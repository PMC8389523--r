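#' Total Hamiltonian of a lattice state
#'
#' Evaluates the CPM energy
#' \deqn{H = \sum_{\langle k,l\rangle} J_{\tau,\tau'}\,(1-\delta_{\sigma_k,\sigma_l})
#'       + \frac{B}{2A_0}\sum_i (A_i - A_0)^2,}
#' where the first sum runs over unordered neighboring-site pairs of the
#' `hamiltonian_order` stencil and the second over non-medium cells (the
#' medium is a background phase with no nominal area unless
#' `params$medium_area_term` is set).
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()].
#' @return the energy, a single double.
#' @export
#' @examples
#' s <- make_fixture("single_cell")
#' total_energy(s, cpm_params())  # 0: no mismatched pair, A = A0
total_energy <- function(state, params = cpm_params()) {
  validate_state(state)
  cpp_total_energy(state$grid, state$type_of, state$area_of, params$J,
                   params$B, params$A0, params$hamiltonian_order,
                   state$bc == "periodic", params$medium_area_term)
}

#' Energy change of a single-site copy
#'
#' Returns `H(after) - H(before)` for overwriting `site` with `new_id`,
#' computed from local terms only: the boundary contributions of stencil
#' pairs involving `site`, plus the area-term changes of the two affected
#' cells. Exactly equal (to floating round-off) to recomputing
#' [total_energy()] before and after the copy.
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()].
#' @param site integer vector `c(row, col)`, 1-based.
#' @param new_id cell ID to copy onto the site; must differ from the current
#'   ID there and be a known ID (0 = medium allowed in free mode).
#' @return the energy change, a single double.
#' @export
delta_energy <- function(state, params, site, new_id) {
  site <- as.integer(site)
  if (length(site) != 2L) stop("site must be c(row, col)")
  cpp_delta_energy(state$grid, state$type_of, state$area_of, params$J,
                   params$B, params$A0, params$hamiltonian_order,
                   state$bc == "periodic", params$medium_area_term,
                   site[1], site[2], as.integer(new_id))
}
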