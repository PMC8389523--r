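test_that("stencil sizes and offsets match the square-lattice shells", {
  expect_equal(nrow(build_stencil(1)), 4)
  expect_equal(nrow(build_stencil(2)), 8)
  expect_equal(nrow(build_stencil(3)), 12)
  expect_equal(nrow(build_stencil(4)), 20)
  st1 <- build_stencil(1)
  expect_setequal(paste(st1[, 1], st1[, 2]),
                  c("1 0", "-1 0", "0 1", "0 -1"))
  for (ord in 1:4) {
    st <- build_stencil(ord)
    # unique, no origin, symmetric under negation
    expect_equal(anyDuplicated(paste(st[, 1], st[, 2])), 0L)
    expect_false(any(st[, 1] == 0 & st[, 2] == 0))
    expect_setequal(paste(st[, 1], st[, 2]), paste(-st[, 1], -st[, 2]))
    expect_setequal(paste(st[, "dr"], st[, "dc"]),
                    paste(stencil_offsets_oracle(ord)$dr,
                          stencil_offsets_oracle(ord)$dc))
  }
  expect_error(build_stencil(0), "between 1 and 4")
  expect_error(build_stencil(5), "between 1 and 4")
})

test_that("a single space-filling cell at nominal area has zero energy", {
  s <- make_fixture("single_cell")
  expect_equal(total_energy(s, cpm_params()), 0)
})

test_that("two homotypic cells across a straight edge: energy equals the pair count times J", {
  # two 8x8 cells of the same type sharing an 8-site vertical edge, periodic
  g <- matrix(0L, 16, 8)
  g[1:8, ] <- 1L
  g[9:16, ] <- 2L
  s <- cpm_state(g, types = c("B", "B"), bc = "periodic")
  p <- cpm_params(A0 = 64)
  # order-1 sub-check: 2 edges x 8 contacts, J_BB = 8 each
  p1 <- cpm_params(A0 = 64, hamiltonian_order = 1)
  expect_equal(total_energy(s, p1), 2 * 8 * 8)
  # full order-4 stencil against brute-force pair enumeration
  expect_equal(total_energy(s, p), brute_total_energy(s, p))
})

test_that("total energy matches brute-force pair enumeration on random lattices", {
  for (seed in 1:8) {
    bc <- if (seed %% 2) "free" else "periodic"
    s <- random_state(seed, bc = bc)
    for (ord in c(1, 2, 4)) {
      p <- cpm_params(A0 = 20, hamiltonian_order = ord)
      expect_equal(total_energy(s, p), brute_total_energy(s, p),
                   tolerance = 1e-12, label = sprintf("seed %d order %d", seed, ord))
    }
  }
})

test_that("the default J table gives heterotypic excess 2 J_YB - J_YY - J_BB = 12", {
  J <- cpm_params()$J
  expect_equal(2 * J["Y", "B"] - J["Y", "Y"] - J["B", "B"], 12)
})

test_that("delta_energy equals the full-recompute difference for random copies", {
  n_checked <- 0
  for (seed in 1:20) {
    bc <- if (seed %% 2) "free" else "periodic"
    s <- random_state(seed, bc = bc)
    p <- cpm_params(A0 = 30)
    set.seed(1000 + seed)
    nr <- nrow(s$grid); nc <- ncol(s$grid)
    max_id <- length(s$type_of) - 1L
    E_before <- total_energy(s, p)
    for (i in 1:50) {
      # interior sites only in free mode so the medium rim stays intact
      site <- if (bc == "free")
        c(sample(2:(nr - 1), 1), sample(2:(nc - 1), 1))
      else c(sample.int(nr, 1), sample.int(nc, 1))
      ids <- if (bc == "periodic") 1:max_id else 0:max_id
      choices <- setdiff(ids, s$grid[site[1], site[2]])
      new_id <- choices[sample.int(length(choices), 1)]
      dE <- delta_energy(s, p, site, new_id)
      s2 <- s
      s2$grid[site[1], site[2]] <- as.integer(new_id)
      s2$area_of <- cpmsort:::count_areas(s2$grid, max_id)
      expect_equal(dE, total_energy(s2, p) - E_before, tolerance = 1e-9,
                   label = sprintf("seed %d copy %d", seed, i))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("area-term delta for a copy between two at-nominal cells is B/A0", {
  # two cells at exactly A0, flat interface: area part of dE is
  # B/(2 A0) * ((1)^2 + (-1)^2) = B/A0 = 2 at defaults
  g <- matrix(0L, 22, 12)
  g[2:11, 2:11] <- 1L
  g[12:21, 2:11] <- 2L
  s <- cpm_state(g, types = c("B", "B"), bc = "free")
  p0 <- cpm_params(B = 200, A0 = 100, J = matrix(0, 3, 3))  # boundary terms off
  expect_equal(delta_energy(s, p0, c(12, 5), 1L), 200 / 100)
})

test_that("delta_energy rejects a no-op copy", {
  s <- make_fixture("two_cells_hetero")
  expect_error(delta_energy(s, cpm_params(), c(8, 8), 1L), "equals the current")
})

test_that("energy is invariant under type-preserving relabeling and translation", {
  s <- random_state(42, bc = "periodic")
  p <- cpm_params(A0 = 25)
  E <- total_energy(s, p)
  # relabel: reverse the ID order, carrying types along
  max_id <- length(s$type_of) - 1L
  perm <- rev(seq_len(max_id))
  g2 <- s$grid
  g2[g2 > 0] <- perm[g2[g2 > 0]]
  s2 <- cpm_state(g2, types = s$type_of[-1][order(perm)], bc = "periodic")
  expect_equal(total_energy(s2, p), E)
  # translation on the torus
  g3 <- s$grid[c(5:nrow(s$grid), 1:4), c(3:ncol(s$grid), 1:2)]
  s3 <- cpm_state(g3, types = s$type_of[-1], bc = "periodic")
  expect_equal(total_energy(s3, p), E)
})

test_that("state invariants are enforced", {
  g <- matrix(1L, 4, 4)
  expect_error(cpm_state(g, types = "B", bc = "free"), "medium")
  g2 <- matrix(0L, 4, 4)
  expect_error(cpm_state(g2, types = integer(0), bc = "periodic"), "no medium")
  s <- make_fixture("two_cells_hetero")
  s$area_of[2] <- s$area_of[2] + 5L
  expect_error(cpmsort:::validate_state(s), "bookkeeping")
})
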