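test_that("acceptance probability follows min(1, exp(-dE/T))", {
  # forced copy with dE > 0 at a flat heterotypic interface, repeated trials
  g <- matrix(0L, 22, 12)
  g[2:11, 2:11] <- 1L
  g[12:21, 2:11] <- 2L
  s0 <- cpm_state(g, types = c("B", "Y"), bc = "free")
  p <- cpm_params()
  dE <- delta_energy(s0, p, c(12, 6), 1L)
  expect_gt(dE, 0)
  p_theory <- exp(-dE / p$T)
  set.seed(123)
  n <- 1e5
  acc <- 0L
  for (i in seq_len(n)) {
    res <- attempt_copy(s0, p, site = c(12, 6), new_id = 1L)
    if (res$status == "accepted") acc <- acc + 1L
  }
  # 3 sigma binomial band around the closed form
  sigma <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(acc / n - p_theory), 3 * sigma)
})

test_that("dE <= 0 with a passing guard is always accepted; dE/T = 7.5 gives p ~ 5.5e-4", {
  g <- matrix(0L, 22, 12)
  g[2:11, 2:11] <- 1L
  g[12:21, 2:11] <- 2L
  g[11, 6] <- 2L  # single-site protrusion of cell 2 into cell 1
  s0 <- cpm_state(g, types = c("B", "B"), bc = "free")
  p <- cpm_params()
  # retracting the protrusion smooths the interface and restores both areas
  # to A0: strictly downhill
  site <- c(11, 6)
  dE <- delta_energy(s0, p, site, 1L)
  expect_lt(dE, 0)
  for (i in 1:20) expect_equal(attempt_copy(s0, p, site = site, new_id = 1L)$status,
                               "accepted")
  expect_equal(exp(-7.5), 5.5e-4, tolerance = 0.01)
})

test_that("mcs_total = 0 yields only the initial sample", {
  init <- build_aggregate(10, 0.5, a0 = 16, seed = 1)
  run <- run_cpm(init, cpm_params(A0 = 16), mcs_total = 0, seed = 1)
  expect_equal(nrow(run$trace), 1L)
  expect_equal(run$trace$t_mcs, 0)
  expect_equal(run$attempts, 0)
})

test_that("T -> 0+ limit: total energy is non-increasing along the run", {
  init <- build_aggregate(12, 0.5, a0 = 16, margin = 4, seed = 3)
  p_cold <- cpm_params(A0 = 16, T = 1e-9)
  run <- run_cpm(init, p_cold, mcs_total = 50,
                 sample_times = seq(0, 50, by = 5), seed = 4)
  expect_true(all(diff(run$trace$energy) <= 1e-9))
})

test_that("one MCS performs width x height attempts and bookkeeping survives runs", {
  init <- build_periodic(16, 0.5, a0 = 25, seed = 6)
  p <- cpm_params(A0 = 25)
  run <- run_cpm(init, p, mcs_total = 20, sample_times = c(0, 7, 20), seed = 7)
  expect_equal(run$attempts, 20 * prod(dim(init$grid)))
  # stored areas equal recounted sites; running energy equals recompute
  s <- run$state
  expect_identical(s$area_of,
                   cpmsort:::count_areas(s$grid, length(s$type_of) - 1L))
  expect_equal(run$trace$energy[nrow(run$trace)], total_energy(s, p),
               tolerance = 1e-6)
})

test_that("identical (seed, config, initial state) give identical traces", {
  init <- build_aggregate(15, 0.5, a0 = 16, margin = 4, seed = 8)
  p <- cpm_params(A0 = 16)
  r1 <- run_cpm(init, p, mcs_total = 30, seed = 42)
  r2 <- run_cpm(init, p, mcs_total = 30, seed = 42)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state$grid, r2$state$grid)
  r3 <- run_cpm(init, p, mcs_total = 30, seed = 43)
  expect_false(identical(r3$state$grid, r1$state$grid))
})

test_that("run_cpm leaves the caller's initial state untouched", {
  init <- build_aggregate(10, 0.5, a0 = 16, seed = 9)
  snapshot <- init$grid + 0L
  invisible(run_cpm(init, cpm_params(A0 = 16), mcs_total = 10, seed = 1))
  expect_identical(init$grid, snapshot)
})

test_that("guarded runs keep every cell singly connected at every sample", {
  init <- build_aggregate(30, 0.5, a0 = 36, margin = 6, seed = 10)
  p <- cpm_params(A0 = 36)
  run <- run_cpm(init, p, mcs_total = 300, seed = 11, audit = TRUE)
  expect_true(all(run$trace$max_components == 1L))
})

test_that("standard (guard-off) dynamics fragment cells at T = 50 within 1e3 MCS", {
  init <- build_aggregate(30, 0.5, a0 = 36, margin = 6, seed = 12)
  p <- cpm_params(A0 = 36)
  run <- run_cpm(init, p, mcs_total = 1000, seed = 13, guard = FALSE,
                 sample_times = seq(0, 1000, by = 100), audit = TRUE)
  expect_gt(max(run$trace$max_components, na.rm = TRUE), 1L)
})

test_that("net transition rate and its small-dH linearization", {
  expect_equal(small_delta_rate(0)$net_rate, 0)
  r <- small_delta_rate(0.2)
  expect_equal(r$net_rate, 1 - exp(0.2), tolerance = 1e-12)
  expect_equal(r$linearized, -0.2)
  expect_equal(abs(r$net_rate - r$linearized) / abs(r$linearized), 0.107,
               tolerance = 0.01)
  expect_lt(abs(small_delta_rate(-0.01)$net_rate - 0.01), 1e-4)
})

test_that("checkpoint round-trip resumes the exact same chain", {
  init <- build_aggregate(10, 0.5, a0 = 16, seed = 14)
  p <- cpm_params(A0 = 16)
  # one continuous run
  full <- run_cpm(init, p, mcs_total = 40, sample_times = c(0, 20, 40), seed = 55)
  # split run with a checkpoint in the middle
  part1 <- run_cpm(init, p, mcs_total = 20, sample_times = c(0, 20), seed = 55)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(part1$state, ck, attempts = part1$attempts)
  restored <- load_checkpoint(ck)
  part2 <- run_cpm(restored$state, p, mcs_total = 20, sample_times = c(0, 20))
  expect_identical(part2$state$grid, full$state$grid)
  expect_equal(part1$attempts + part2$attempts, full$attempts)
})
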