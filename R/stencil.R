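#' Neighborhood stencil on the square lattice
#'
#' Returns the lattice offsets of the given neighbor order: all offsets whose
#' squared Euclidean length is among the `order` smallest distinct nonzero
#' values on the square lattice (1, 2, 4, 5). Order 1 is the 4-site
#' von Neumann neighborhood, order 2 the 8-site Moore neighborhood, order 4
#' the 20-site neighborhood used in the boundary-energy sum.
#'
#' @param order integer in 1..4.
#' @return an integer matrix with columns `dr`, `dc`, one row per offset.
#' @export
#' @examples
#' nrow(build_stencil(2))  # 8
#' nrow(build_stencil(4))  # 20
build_stencil <- function(order) {
  if (length(order) != 1L || is.na(order) || order != round(order) ||
      order < 1 || order > 4)
    stop("order must be a single integer between 1 and 4")
  out <- cpp_build_stencil(as.integer(order))
  colnames(out) <- c("dr", "dc")
  out
}
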