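# Independent brute-force oracles, written against the definitions rather
# than the package internals: plain R double loops and BFS, no calls into the
# compiled code paths they are meant to check.

stencil_offsets_oracle <- function(order) {
  d2s <- c(1, 2, 4, 5)[seq_len(order)]
  og <- expand.grid(dr = -2:2, dc = -2:2)
  og[(og$dr^2 + og$dc^2) %in% d2s, , drop = FALSE]
}

# Hamiltonian by enumeration of all neighboring site pairs (each ordered pair
# visited once, sum halved), plus the quadratic area term.
brute_total_energy <- function(state, params) {
  g <- state$grid
  nr <- nrow(g); nc <- ncol(g)
  periodic <- state$bc == "periodic"
  off <- stencil_offsets_oracle(params$hamiltonian_order)
  J <- params$J
  ty <- state$type_of
  E <- 0
  for (r in 1:nr) for (c in 1:nc) {
    a <- g[r, c]
    for (k in seq_len(nrow(off))) {
      r2 <- r + off$dr[k]; c2 <- c + off$dc[k]
      if (periodic) {
        r2 <- ((r2 - 1) %% nr) + 1; c2 <- ((c2 - 1) %% nc) + 1
      } else if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      b <- g[r2, c2]
      if (a != b) E <- E + J[ty[a + 1L] + 1L, ty[b + 1L] + 1L]
    }
  }
  E <- E / 2
  areas <- tabulate(as.vector(g) + 1L, nbins = length(ty))
  ids <- seq_along(areas)[-1]
  E + params$B / (2 * params$A0) * sum((areas[ids] - params$A0)^2)
}

brute_boundary_length <- function(state, include_medium = FALSE) {
  g <- state$grid
  nr <- nrow(g); nc <- ncol(g)
  periodic <- state$bc == "periodic"
  ty <- state$type_of
  count <- 0
  for (r in 1:nr) for (c in 1:nc) {
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (periodic) {
        r2 <- ((r2 - 1) %% nr) + 1; c2 <- ((c2 - 1) %% nc) + 1
      } else if (r2 > nr || c2 > nc) next
      ta <- ty[g[r, c] + 1L]; tb <- ty[g[r2, c2] + 1L]
      if ((ta == 1 && tb == 2) || (ta == 2 && tb == 1)) count <- count + 1
      else if (include_medium && ta != tb && (ta == 0 || tb == 0)) count <- count + 1
    }
  }
  count
}

# All-pairs autocorrelation by explicit offset shifts.
brute_autocorr <- function(state, max_r) {
  g <- state$grid
  nr <- nrow(g); nc <- ncol(g)
  periodic <- state$bc == "periodic"
  code <- matrix(state$type_of[g + 1L], nr, nc)
  s <- (code == 1L) - (code == 2L)
  mask <- (code != 0L) * 1
  sums <- numeric(max_r + 1); counts <- numeric(max_r + 1)
  for (dr in -max_r:max_r) for (dc in -max_r:max_r) {
    rb <- round(sqrt(dr^2 + dc^2))
    if (rb > max_r) next
    if (periodic) {
      ri <- ((1:nr - 1 + dr) %% nr) + 1
      ci <- ((1:nc - 1 + dc) %% nc) + 1
      s2 <- s[ri, ci, drop = FALSE]; m2 <- mask[ri, ci, drop = FALSE]
      sums[rb + 1] <- sums[rb + 1] + sum(s * s2 * mask * m2)
      counts[rb + 1] <- counts[rb + 1] + sum(mask * m2)
    } else {
      rs <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      if (length(rs) < 1 || length(cs) < 1) next
      s1 <- s[rs, cs, drop = FALSE]; m1 <- mask[rs, cs, drop = FALSE]
      s2 <- s[rs + dr, cs + dc, drop = FALSE]; m2 <- mask[rs + dr, cs + dc, drop = FALSE]
      sums[rb + 1] <- sums[rb + 1] + sum(s1 * s2 * m1 * m2)
      counts[rb + 1] <- counts[rb + 1] + sum(m1 * m2)
    }
  }
  mean_s <- sum(s * mask) / sum(mask)
  ok <- counts > 0
  data.frame(r = (0:max_r)[ok], C = sums[ok] / counts[ok] - mean_s^2,
             n_pairs = counts[ok])
}

# component count of the ring positions holding `value`, by BFS over the 8
# Moore offsets with Chebyshev-distance-1 adjacency
RING_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
                      dc = c(-1, 0, 1, 1, 1, 0, -1, -1))

ring_components_oracle <- function(ring_vals, value) {
  pos <- which(ring_vals == value)
  if (length(pos) == 0) return(0L)
  adj <- function(i, j) {
    max(abs(RING_OFFSETS[i, 1] - RING_OFFSETS[j, 1]),
        abs(RING_OFFSETS[i, 2] - RING_OFFSETS[j, 2])) <= 1
  }
  seen <- logical(length(pos))
  comps <- 0L
  for (start in seq_along(pos)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_along(pos)) {
        if (!seen[v] && adj(pos[u], pos[v])) { seen[v] <- TRUE; queue <- c(queue, v) }
      }
    }
  }
  comps
}

# 8-connectivity component counts per cell ID by plain R BFS
flood_fill_components_oracle <- function(state) {
  g <- state$grid
  nr <- nrow(g); nc <- ncol(g)
  periodic <- state$bc == "periodic"
  seen <- matrix(FALSE, nr, nc)
  ids <- sort(unique(as.vector(g)))
  comps <- setNames(integer(length(ids)), ids)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0]) next
    id <- g[r0, c0]
    comps[as.character(id)] <- comps[as.character(id)] + 1L
    queue <- matrix(c(r0, c0), 1)
    seen[r0, c0] <- TRUE
    while (nrow(queue)) {
      r <- queue[1, 1]; c <- queue[1, 2]; queue <- queue[-1, , drop = FALSE]
      for (k in 1:8) {
        r2 <- r + RING_OFFSETS[k, 1]; c2 <- c + RING_OFFSETS[k, 2]
        if (periodic) {
          r2 <- ((r2 - 1) %% nr) + 1; c2 <- ((c2 - 1) %% nc) + 1
        } else if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!seen[r2, c2] && g[r2, c2] == id) {
          seen[r2, c2] <- TRUE
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
  }
  comps
}

# Random small lattice states (valid bookkeeping, cells not necessarily
# connected) for energy-equivalence fuzzing: nearest-seed (Voronoi)
# assignment of k cells, medium margin in free mode.
random_state <- function(seed, nr = NULL, nc = NULL, k = NULL,
                         bc = c("free", "periodic")) {
  set.seed(seed)
  bc <- match.arg(bc)
  if (is.null(nr)) nr <- sample(10:18, 1)
  if (is.null(nc)) nc <- sample(10:18, 1)
  if (is.null(k)) k <- sample(3:6, 1)
  cr <- runif(k, 1, nr); cc <- runif(k, 1, nc)
  g <- matrix(0L, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (bc == "periodic") {
      dr <- pmin(abs(r - cr), nr - abs(r - cr))
      dc <- pmin(abs(c - cc), nc - abs(c - cc))
    } else {
      dr <- r - cr; dc <- c - cc
    }
    g[r, c] <- which.min(dr^2 + dc^2)
  }
  if (bc == "free") {
    # medium margin plus a few random medium pockets
    g[c(1, nr), ] <- 0L
    g[, c(1, nc)] <- 0L
    npock <- sample(0:3, 1)
    if (npock > 0) {
      idx <- sample(which(g > 0), min(npock, sum(g > 0) - k))
      for (i in idx) if (sum(g == g[i]) > 1L) g[i] <- 0L
    }
  }
  present <- sort(unique(as.vector(g[g > 0])))
  relab <- integer(max(present)); relab[present] <- seq_along(present)
  g[g > 0] <- relab[g[g > 0]]
  cpm_state(g, types = sample(1:2, length(present), replace = TRUE), bc = bc)
}
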