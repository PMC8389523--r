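#' Local connectivity test on the Moore ring
#'
#' The rejection rule at the heart of the non-fragmenting dynamics: a copy of
#' `new_id` onto `site` is locally admissible iff, among the 8 Moore neighbors
#' of the site, the sites holding the candidate (current) ID form a single
#' connected set and the sites holding the target ID (`new_id`) form a single
#' connected set. Connectivity among ring sites uses 8-adjacency (Chebyshev
#' distance 1) restricted to the ring. An empty candidate set — the copy would
#' erase the cell's last local presence — returns `FALSE` for non-medium
#' cells. When `params$medium_exempt` is `TRUE` (default) the medium is
#' exempt from both requirements, so an aggregate may enclose medium pockets.
#'
#' @param state a [cpm_state()].
#' @param site integer vector `c(row, col)`, 1-based.
#' @param new_id target cell ID; must differ from the ID at `site`.
#' @param medium_exempt exempt medium-ID sets from the test (default `TRUE`).
#' @return `TRUE` if the copy preserves local connectivity of both cells.
#' @export
local_connectivity_ok <- function(state, site, new_id, medium_exempt = TRUE) {
  site <- as.integer(site)
  if (length(site) != 2L) stop("site must be c(row, col)")
  cpp_local_connectivity_ok(state$grid, state$type_of,
                            state$bc == "periodic", isTRUE(medium_exempt),
                            site[1], site[2], as.integer(new_id))
}

#' Global connectivity audit by flood fill
#'
#' Counts the 8-connected components of every non-medium cell's site set. A
#' state is fragmentation-free iff every count equals 1. This is the
#' correctness oracle for the local connectivity test: starting from a valid
#' state, guard-enabled dynamics must keep all counts at 1 forever.
#'
#' @param state a [cpm_state()].
#' @return a named integer vector, cell ID -> component count, for all cells
#'   present in the table. Errors if a cell has zero sites (bookkeeping bug).
#' @export
audit_global_connectivity <- function(state) {
  max_id <- length(state$type_of) - 1L
  comps <- cpp_audit_components(state$grid, max_id, state$bc == "periodic")
  out <- comps[-1]  # drop medium
  names(out) <- as.character(seq_len(max_id))
  if (any(state$area_of[-1] == 0L))
    stop("cell(s) with zero sites: ",
         paste(which(state$area_of[-1] == 0L), collapse = ", "))
  out
}

#' Detached-cell audit
#'
#' IDs of non-medium cells entirely surrounded by medium: no order-1 site
#' adjacency to any other cell, homotypic or heterotypic. Detached single
#' cells would signal an evaporation-condensation channel; with the
#' connectivity guard and the default adhesion parameters they never appear.
#'
#' @param state a [cpm_state()].
#' @return an integer vector of detached cell IDs (empty if none).
#' @export
audit_detached_cells <- function(state) {
  max_id <- length(state$type_of) - 1L
  cpp_detached_cells(state$grid, max_id, state$bc == "periodic")
}
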