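test_that("boundary length counts heterotypic order-1 contacts", {
  expect_equal(boundary_length(make_fixture("two_cells_hetero")), 10)
  # monotypic aggregate -> 0
  g <- matrix(0L, 12, 12)
  g[3:6, 3:10] <- 1L
  g[7:10, 3:10] <- 2L
  s_mono <- cpm_state(g, types = c("B", "B"), bc = "free")
  expect_equal(boundary_length(s_mono), 0)
  # against the brute-force pair loop on random states, both flag settings
  for (seed in c(2, 5, 8, 11)) {
    s <- random_state(seed, bc = if (seed %% 2) "free" else "periodic")
    expect_equal(boundary_length(s), brute_boundary_length(s, FALSE))
    p_med <- cpm_params(gamma_include_medium = TRUE)
    expect_equal(boundary_length(s, p_med), brute_boundary_length(s, TRUE))
  }
})

test_that("gamma is invariant under within-type relabeling and torus translation", {
  s <- random_state(31, bc = "periodic")
  gam <- boundary_length(s)
  max_id <- length(s$type_of) - 1L
  perm <- rev(seq_len(max_id))
  g2 <- s$grid
  g2[] <- perm[s$grid]
  s2 <- cpm_state(g2, types = s$type_of[-1][order(perm)], bc = "periodic")
  expect_equal(boundary_length(s2), gam)
  g3 <- s$grid[c(4:nrow(s$grid), 1:3), c(2:ncol(s$grid), 1)]
  s3 <- cpm_state(g3, types = s$type_of[-1], bc = "periodic")
  expect_equal(boundary_length(s3), gam)
})

test_that("autocorrelation is flat zero for a single-type region and C(0) is the spin variance", {
  g <- matrix(1L, 16, 16)
  s <- cpm_state(g, types = "B", bc = "periodic")
  cc <- autocorrelation(s, max_r = 6)
  expect_true(all(abs(cc$C) < 1e-12))
  # mixed state: C(0) = 1 - mean(s)^2
  s2 <- random_state(13, bc = "periodic")
  code <- s2$type_of[s2$grid + 1L]
  spin <- (code == 1) - (code == 2)
  cc2 <- autocorrelation(s2, max_r = 5)
  expect_equal(cc2$C[cc2$r == 0], 1 - mean(spin)^2, tolerance = 1e-12)
})

test_that("autocorrelation matches the brute-force all-pairs oracle exactly", {
  for (seed in c(1, 4, 9, 16)) {
    bc <- if (seed %% 2) "free" else "periodic"
    s <- random_state(seed, nr = 14, nc = 14, bc = bc)
    got <- autocorrelation(s, max_r = 5)
    want <- brute_autocorr(s, max_r = 5)
    expect_equal(got$r, want$r, label = paste("seed", seed))
    expect_equal(got$C, want$C, tolerance = 1e-10, label = paste("seed", seed))
  }
  # larger periodic case
  set.seed(77)
  n <- 32
  ncell <- 16
  g <- matrix(0L, n, n)
  side <- n / 4
  for (bi in 1:4) for (bj in 1:4)
    g[((bi - 1) * side + 1):(bi * side), ((bj - 1) * side + 1):(bj * side)] <-
      (bi - 1) * 4 + bj
  s <- cpm_state(g, types = sample(1:2, ncell, replace = TRUE), bc = "periodic")
  got <- autocorrelation(s, max_r = 12)
  want <- brute_autocorr(s, max_r = 12)
  expect_equal(got$C, want$C, tolerance = 1e-10)
})

test_that("max_r beyond half the torus is rejected", {
  s <- make_fixture("single_cell")
  expect_error(autocorrelation(s, max_r = 6), "half the lattice")
})

test_that("stripe fields put the first zero where the brute-force curve does", {
  # alternating B/Y stripes of width w: C crosses zero near w
  for (w in c(4, 8)) {
    n <- 64
    g <- matrix(0L, n, n)
    stripe <- ((col(g) - 1) %/% w)
    ids <- stripe + 1L
    g[] <- ids
    types <- rep(c(1L, 2L), length.out = max(ids))
    s <- cpm_state(g, types = types, bc = "periodic")
    cc <- autocorrelation(s, max_r = 30)
    want <- brute_autocorr(s, max_r = 30)
    rz_got <- first_zero(cc)
    rz_want <- first_zero(want)
    expect_equal(rz_got, rz_want, tolerance = 1e-9)
    expect_gt(rz_got, 0.5 * w)
    expect_lt(rz_got, 1.5 * w)
  }
})

test_that("first_zero interpolates linearly and flags non-crossing curves", {
  expect_equal(first_zero(data.frame(r = 0:2, C = c(1, 0.5, -0.5))), 1.5)
  expect_true(is.na(first_zero(data.frame(r = 0:2, C = c(1, 0.2, 0.1)))))
  expect_error(first_zero(data.frame(r = 0:2, C = c(-1, 0.2, 0.1))),
               "start positive")
})

test_that("cluster counting matches a flood-fill oracle and sees sorted states", {
  # fully sorted two-blob state -> 2 clusters
  g <- matrix(0L, 14, 24)
  g[3:12, 3:12] <- 1L
  g[3:12, 13:22] <- 2L
  s <- cpm_state(g, types = c("B", "Y"), bc = "free")
  expect_equal(count_clusters(s), 2)
  # checkerboard of single-type cells: diagonal same-type touching merges
  # components under 8-connectivity
  s_cb <- make_fixture("four_cell_checkerboard")
  expect_equal(count_clusters(s_cb), 2)
  # random states against the oracle (components of each type's site set)
  for (seed in c(6, 15)) {
    s <- random_state(seed, bc = "periodic")
    code <- matrix(s$type_of[s$grid + 1L], nrow(s$grid))
    # oracle: binarize each type's mask into a one-cell state and flood fill
    cnt <- function(m) {
      if (!any(m)) return(0L)
      gg <- matrix(2L, nrow(m), ncol(m)); gg[m] <- 1L
      comp <- flood_fill_components_oracle(
        cpm_state(gg, types = c(1L, 2L), bc = "periodic"))
      unname(comp["1"])
    }
    oracle <- cnt(code == 1L) + cnt(code == 2L)
    expect_equal(count_clusters(s), oracle)
  }
})

test_that("digitized disks: gamma tracks perimeter and first zero grows with radius", {
  # k disjoint blue disks of radius R in a yellow sea, k R^2 fixed (constant
  # minority mass fraction) so the correlation structure is a pure dilation
  mk_disks <- function(radius, spacing, n = 128) {
    g <- matrix(0L, n, n)
    ctr <- seq(spacing / 2, n, by = spacing)
    i <- 0L
    for (cx in ctr) for (cy in ctr) {
      i <- i + 1L
      d2 <- (row(g) - cx)^2 + (col(g) - cy)^2
      g[d2 <= radius^2] <- i
    }
    bg <- max(g) + 1L
    g[g == 0L] <- bg
    cpm_state(g, types = c(rep(1L, bg - 1L), 2L), bc = "periodic")
  }
  for (cfg in list(list(R = 8, sp = 32), list(R = 16, sp = 64))) {
    s <- mk_disks(cfg$R, cfg$sp)
    k <- nrow(cell_table(s)) - 1L
    # realized disk radius: half the bounding-box extent of one disk
    occ <- which(s$grid == 1L, arr.ind = TRUE)
    r_eff <- (diff(range(occ[, 1])) + 1) / 2
    gam <- boundary_length(s)
    expect_gt(gam / (k * 2 * pi * r_eff), 0.7)
    expect_lt(gam / (k * 2 * pi * r_eff), 1.3)
  }
  # doubling R at fixed mass doubles the first zero (linearity)
  rz8 <- first_zero(autocorrelation(mk_disks(8, 32), max_r = 48))
  rz16 <- first_zero(autocorrelation(mk_disks(16, 64), max_r = 48))
  expect_gt(rz16 / rz8, 1.5)
  expect_lt(rz16 / rz8, 2.5)
})
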