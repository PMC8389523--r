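#' Log-spaced Monte Carlo sample times
#'
#' Default sampling schedule for [run_cpm()]: 0, then `n` log-spaced times up
#' to `mcs_total` (deduplicated after rounding).
#'
#' @param mcs_total run length in Monte Carlo steps.
#' @param n number of log-spaced points (default 30).
#' @return an increasing integer vector of MCS values starting at 0.
#' @export
log_sample_times <- function(mcs_total, n = 30) {
  if (mcs_total < 1) return(0)
  pts <- unique(round(10^seq(0, log10(mcs_total), length.out = n)))
  c(0, pts[pts >= 1 & pts <= mcs_total])
}

#' Single Metropolis copy attempt
#'
#' Performs one copy attempt: `site` (default: drawn uniformly over mutable
#' sites) takes the value of a uniformly drawn `copy_order`-stencil neighbor
#' (the target value), subject to the local connectivity test when
#' `guard = TRUE`, and accepted with probability `min(1, exp(-dE/T))`.
#' Functional interface: the input state is not modified.
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()].
#' @param site optional `c(row, col)` forcing the candidate site.
#' @param new_id optional target cell ID forcing the proposal.
#' @param guard apply the connectivity test (default `TRUE`).
#' @return a list with `status` (one of `"accepted"`, `"rejected_noop"`,
#'   `"rejected_connectivity"`, `"rejected_metropolis"`), `delta_energy`
#'   (`NA` unless evaluated), `site`, `new_id`, and `state` (the possibly
#'   updated state).
#' @export
attempt_copy <- function(state, params = cpm_params(), site = NULL,
                         new_id = NULL, guard = TRUE) {
  state <- duplicate_state(state)
  nr <- nrow(state$grid); nc <- ncol(state$grid)
  periodic <- state$bc == "periodic"
  if (is.null(site)) {
    if (periodic) {
      site <- c(sample.int(nr, 1), sample.int(nc, 1))
    } else {
      site <- c(1L + sample.int(nr - 2L, 1), 1L + sample.int(nc - 2L, 1))
    }
  }
  if (is.null(new_id)) {
    st <- build_stencil(params$copy_order)
    k <- sample.int(nrow(st), 1)
    r2 <- site[1] + st[k, 1]; c2 <- site[2] + st[k, 2]
    if (periodic) {
      r2 <- ((r2 - 1) %% nr) + 1; c2 <- ((c2 - 1) %% nc) + 1
      new_id <- state$grid[r2, c2]
    } else if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) {
      new_id <- 0L  # off-lattice proposes the medium
    } else {
      new_id <- state$grid[r2, c2]
    }
  }
  cur <- state$grid[site[1], site[2]]
  if (new_id == cur)
    return(list(status = "rejected_noop", delta_energy = NA_real_,
                site = site, new_id = new_id, state = state))
  res <- cpp_attempt_at(state$grid, state$type_of, state$area_of, params$J,
                        params$B, params$A0, params$T,
                        params$hamiltonian_order, periodic, isTRUE(guard),
                        params$medium_exempt, params$medium_area_term,
                        site[1], site[2], as.integer(new_id))
  status <- c("accepted", "rejected_noop", "rejected_connectivity",
              "rejected_metropolis")[res$status + 1L]
  list(status = status, delta_energy = res$delta_energy,
       site = site, new_id = as.integer(new_id), state = state)
}

#' Run the connectivity-preserving CPM dynamics
#'
#' Executes `mcs_total` Monte Carlo steps, one MCS being as many copy
#' attempts as there are lattice sites, recording observables at each sample
#' time. With `guard = TRUE` (the default) every copy attempt must pass the
#' local connectivity test, so cells can never fragment; `guard = FALSE`
#' gives the standard (fragmentation-permitting) CPM for algorithm
#' comparisons. Runs are deterministic given `(seed, config, initial state)`.
#'
#' @param state initial [cpm_state()]; with `guard = TRUE` every cell should
#'   be simply connected (checked when `audit = TRUE`).
#' @param params a [cpm_params()].
#' @param mcs_total number of Monte Carlo steps (>= 0).
#' @param sample_times increasing MCS values at which observables are
#'   recorded; default [log_sample_times()]. Time 0 is always included.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param guard enable the connectivity test (default `TRUE`).
#' @param audit run the flood-fill connectivity audit at every sample time;
#'   with `guard = TRUE` a violated audit aborts with an error (it would
#'   signal an engine bug). Default `TRUE`.
#' @param record_correlation also record the spatial autocorrelation curve at
#'   each sample time (needed for `r_first_zero` and collapse analysis).
#'   Default `FALSE`.
#' @param max_r maximum correlation distance in sites; default a quarter of
#'   the shorter lattice side.
#' @return an object of class `cpm_run`: a list with `trace` (data frame with
#'   columns `t_mcs`, `gamma`, `energy`, `n_clusters`, `r_first_zero`,
#'   `acceptance`, `max_components`), `correlations` (long data frame
#'   `t_mcs`, `r`, `C`, or `NULL`), `state` (final state), `attempts`
#'   (total copy attempts), and `config`.
#' @export
#' @examples
#' init <- build_aggregate(n_cells = 20, ratio_blue = 0.5, seed = 1)
#' run <- run_cpm(init, cpm_params(), mcs_total = 5, seed = 1)
#' head(run$trace)
run_cpm <- function(state, params = cpm_params(), mcs_total,
                    sample_times = NULL, seed = NULL, guard = TRUE,
                    audit = TRUE, record_correlation = FALSE, max_r = NULL) {
  if (mcs_total < 0) stop("mcs_total must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_times)) sample_times <- log_sample_times(mcs_total)
  sample_times <- sort(unique(c(0, as.numeric(sample_times))))
  if (any(sample_times > mcs_total) || any(sample_times < 0))
    stop("sample_times must lie in [0, mcs_total]")
  if (mcs_total > 0 && !mcs_total %in% sample_times)
    sample_times <- c(sample_times, mcs_total)

  validate_state(state)
  state <- duplicate_state(state)
  periodic <- state$bc == "periodic"
  sites_per_mcs <- as.numeric(nrow(state$grid)) * ncol(state$grid)
  if (is.null(max_r)) max_r <- floor(min(dim(state$grid)) / 4)

  energy <- total_energy(state, params)
  attempts <- 0
  rows <- list()
  corr <- list()

  record <- function(t, acc_rate) {
    comp <- NA_integer_
    if (audit) {
      comps <- audit_global_connectivity(state)
      comp <- max(comps)
      if (guard && comp != 1L)
        stop("connectivity audit failed at t = ", t,
             " with guard enabled: engine bug")
    }
    rfz <- NA_real_
    if (record_correlation) {
      cc <- autocorrelation(state, max_r = max_r)
      corr[[length(corr) + 1L]] <<-
        data.frame(t_mcs = t, r = cc$r, C = cc$C)
      rfz <- first_zero(cc)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      t_mcs = t,
      gamma = boundary_length(state, params),
      energy = energy,
      n_clusters = count_clusters(state),
      r_first_zero = rfz,
      acceptance = acc_rate,
      max_components = comp)
  }

  record(0, NA_real_)
  t_cur <- 0
  for (t_next in sample_times[sample_times > 0]) {
    n_att <- (t_next - t_cur) * sites_per_mcs
    res <- cpm_advance_cpp(state$grid, state$type_of, state$area_of,
                           params$J, params$B, params$A0, params$T,
                           params$hamiltonian_order, params$copy_order,
                           periodic, isTRUE(guard), params$medium_exempt,
                           params$medium_area_term, n_att)
    energy <- energy + res$delta_energy
    attempts <- attempts + n_att
    record(t_next, res$accepted / n_att)
    t_cur <- t_next
  }

  structure(list(trace = do.call(rbind, rows),
                 correlations = if (length(corr)) do.call(rbind, corr) else NULL,
                 state = state,
                 attempts = attempts,
                 config = list(mcs_total = mcs_total, seed = seed,
                               guard = guard, sample_times = sample_times,
                               max_r = max_r, params = params)),
            class = "cpm_run")
}

#' @export
print.cpm_run <- function(x, ...) {
  cat(sprintf("CPM run: %g MCS, %d samples, guard %s\n",
              x$config$mcs_total, nrow(x$trace),
              if (x$config$guard) "on" else "off"))
  tr <- x$trace
  cat(sprintf("  gamma: %g -> %g; energy: %g -> %g\n",
              tr$gamma[1], tr$gamma[nrow(tr)],
              tr$energy[1], tr$energy[nrow(tr)]))
  invisible(x)
}

#' Net transition rate for small energy changes
#'
#' Diagnostic for the temperature regime in which kinetics are
#' temperature-invariant: the net forward-minus-backward Metropolis
#' transition rate between two configurations differing by `dH` is
#' `1 - exp(dH/T)`, which linearizes to `-dH/T` for small relative changes.
#' When the linearization is accurate, a change of temperature uniformly
#' rescales all transition rates and leaves the sorting kinetics unchanged.
#'
#' @param deltaH_over_T dimensionless energy change(s) `dH/T`.
#' @return a data frame with columns `deltaH_over_T`, `net_rate`
#'   (`1 - exp(dH/T)`) and `linearized` (`-dH/T`).
#' @export
#' @examples
#' small_delta_rate(0.2)  # net rate -0.2214, linearization -0.2
small_delta_rate <- function(deltaH_over_T) {
  data.frame(deltaH_over_T = deltaH_over_T,
             net_rate = 1 - exp(deltaH_over_T),
             linearized = -deltaH_over_T)
}
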