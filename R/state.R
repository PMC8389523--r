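#' Construct a CPM lattice state
#'
#' A `cpm_state` bundles the complete Markov-chain state: the integer grid of
#' cell IDs (0 = medium), the per-cell type map, per-cell areas kept
#' consistent with the grid, and the boundary-condition mode.
#'
#' @param grid integer matrix of cell IDs; 0 is the medium.
#' @param types integer or character vector mapping cell ID 1..max(grid) to a
#'   type: `"B"`/1 (blue), `"Y"`/2 (yellow). Named by ID or positional.
#' @param bc boundary-condition mode, `"free"` (aggregate in medium) or
#'   `"periodic"` (space-filling torus).
#' @return an object of class `cpm_state` with elements `grid`, `bc`,
#'   `type_of` (integer codes indexed by ID + 1, medium first) and `area_of`
#'   (site counts, same indexing).
#' @export
#' @examples
#' g <- matrix(0L, 6, 6); g[3:4, 3:4] <- 1L
#' s <- cpm_state(g, types = "B", bc = "free")
#' cell_table(s)
cpm_state <- function(grid, types, bc = c("free", "periodic")) {
  bc <- match.arg(bc)
  storage.mode(grid) <- "integer"
  if (any(grid < 0)) stop("cell IDs must be non-negative (0 = medium)")
  max_id <- max(grid)
  type_codes <- encode_types(types, max_id)
  state <- structure(list(grid = grid, bc = bc,
                          type_of = c(0L, type_codes),
                          area_of = count_areas(grid, max_id)),
                     class = "cpm_state")
  validate_state(state)
  state
}

encode_types <- function(types, max_id) {
  if (max_id == 0L) return(integer(0))
  if (is.character(types)) {
    codes <- match(types, c("M", "B", "Y")) - 1L
    if (anyNA(codes)) stop("types must be 'B' or 'Y'")
  } else {
    codes <- as.integer(types)
  }
  if (length(codes) == 1L) codes <- rep(codes, max_id)
  if (length(codes) != max_id)
    stop("types must have one entry per cell ID 1..", max_id)
  if (any(!codes %in% 1:2)) stop("cell types must be B (1) or Y (2)")
  codes
}

count_areas <- function(grid, max_id) {
  as.integer(tabulate(as.vector(grid) + 1L, nbins = max_id + 1L))
}

validate_state <- function(state) {
  grid <- state$grid
  max_id <- length(state$type_of) - 1L
  if (max(grid) > max_id) stop("grid contains IDs absent from the cell table")
  recount <- count_areas(grid, max_id)
  if (!identical(recount, state$area_of))
    stop("area bookkeeping inconsistent with the grid")
  live <- which(state$area_of[-1] > 0L)
  if (state$bc == "free") {
    nr <- nrow(grid); nc <- ncol(grid)
    rim <- c(grid[1, ], grid[nr, ], grid[, 1], grid[, nc])
    if (any(rim != 0L))
      stop("free mode requires the outermost rows/columns to be medium")
  } else {
    if (any(grid == 0L)) stop("periodic mode admits no medium sites")
  }
  invisible(state)
}

#' Per-cell table of a lattice state
#'
#' @param state a [cpm_state()].
#' @return a data frame with columns `id`, `type` (`"B"`/`"Y"`), `area`
#'   (site count), one row per non-medium cell.
#' @export
cell_table <- function(state) {
  max_id <- length(state$type_of) - 1L
  if (max_id == 0L)
    return(data.frame(id = integer(0), type = character(0), area = integer(0)))
  data.frame(id = seq_len(max_id),
             type = c("M", "B", "Y")[state$type_of[-1] + 1L],
             area = state$area_of[-1])
}

n_cells <- function(state) sum(state$area_of[-1] > 0L)

#' @export
print.cpm_state <- function(x, ...) {
  tab <- cell_table(x)
  cat(sprintf("CPM state: %d x %d lattice (%s BC), %d cells (%d B, %d Y), %d medium sites\n",
              nrow(x$grid), ncol(x$grid), x$bc, sum(tab$area > 0),
              sum(tab$type == "B" & tab$area > 0),
              sum(tab$type == "Y" & tab$area > 0), x$area_of[1]))
  invisible(x)
}

# internal: force private copies of the mutable buffers so that C++ in-place
# updates can never alias a caller's state
duplicate_state <- function(state) {
  state$grid <- state$grid + 0L
  state$area_of <- state$area_of + 0L
  state
}
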