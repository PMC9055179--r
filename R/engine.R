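# R surface of the compiled DPD engine: thermostat parameters, force
# evaluation, and time integration with the Groot-Warren modified
# velocity-Verlet scheme.

#' DPD run parameters
#'
#' The dissipative and random forces form the DPD thermostat; their strengths
#' are tied by the fluctuation--dissipation relation `sigma^2 = 2 gamma kBT`.
#' Give either `gamma` or `sigma` and the other is derived; if both are given
#' they must satisfy the relation.  With the standard `gamma = 4.5` and
#' `kBT = 1` this yields `sigma = 3` exactly.
#'
#' @param gamma friction coefficient of the dissipative force.
#' @param sigma noise amplitude of the random force.
#' @param kBT thermostat temperature (energy scale, 1 in reduced units).
#' @param dt integration time step in units of tau.
#' @param n_steps number of steps to integrate.
#' @param seed integer seed for the pairwise noise stream.
#' @param report_every energy-trace reporting interval (steps).
#' @param r_cut pair cut-off (the length scale; fixed at 1 r_c).
#' @return object of class `run_params`.
#' @export
run_params <- function(gamma = NULL, sigma = NULL, kBT = 1, dt = 0.01,
                       n_steps = 200000L, seed = 1L, report_every = 100L,
                       r_cut = 1) {
  if (is.null(gamma) && is.null(sigma)) gamma <- 4.5
  if (is.null(sigma)) sigma <- sqrt(2 * gamma * kBT)
  if (is.null(gamma)) gamma <- sigma^2 / (2 * kBT)
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-12 * max(1, sigma^2))
    stop("sigma^2 = 2 gamma kBT violated: sigma^2 = ", sigma^2,
         ", 2 gamma kBT = ", 2 * gamma * kBT)
  stopifnot(dt > 0, n_steps >= 0, report_every >= 1, r_cut == 1)
  structure(list(gamma = gamma, sigma = sigma, kBT = kBT, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 report_every = as.integer(report_every), r_cut = r_cut),
            class = "run_params")
}

#' DPD weight function
#'
#' Linear soft-repulsion weight `w(r) = 1 - r/r_cut` for `r < r_cut`, zero
#' beyond the cut-off.  The conservative force uses `w`, the random force
#' `w`, and the dissipative force `w^2` (the fluctuation--dissipation
#' requirement `w_D = w_R^2`).
#'
#' @param r distance(s), >= 0.
#' @param r_cut cut-off distance.
#' @return dimensionless weight(s).
#' @export
weight <- function(r, r_cut = 1) {
  stopifnot(all(r >= 0))
  ifelse(r < r_cut, 1 - r / r_cut, 0)
}

.bond_arrays <- function(state) {
  b <- state$bonds
  a <- state$angles
  list(bonds = if (nrow(b)) cbind(b$i - 1L, b$j - 1L) else matrix(0L, 0, 2),
       bks = as.numeric(b$k_s), brs = as.numeric(b$r_s),
       angles = if (nrow(a)) cbind(a$i - 1L, a$j - 1L, a$k - 1L) else matrix(0L, 0, 3),
       akth = as.numeric(a$k_theta), ath0 = as.numeric(a$theta0))
}

#' Evaluate forces on every bead
#'
#' Computes the pairwise DPD forces (conservative `a_ij w(r) r_hat`,
#' dissipative `-gamma w^2 (r_hat . v_ij) r_hat`, random
#' `sigma w zeta_ij dt^(-1/2) r_hat` with one symmetric Gaussian draw per
#' pair per step) plus harmonic-bond and angle-bending forces, using a
#' periodic cell list.  The pair potential energy is
#' `sum (a_ij r_cut / 2)(1 - r/r_cut)^2`.
#'
#' @param state a [dpd_state()].
#' @param interactions 5x5 repulsion matrix, see [default_interactions()].
#' @param params a [run_params()]; set `gamma`/`sigma` to zero for purely
#'   conservative forces.
#' @param step step label entering the pairwise noise stream.
#' @param conservative_only if TRUE, drop dissipative and random forces.
#' @return list with `force` (N x 3), `e_pair`, `e_bond`, `e_angle`,
#'   `n_overlap` (count of exactly overlapping pairs handled with a random
#'   contact direction).
#' @export
compute_forces <- function(state, interactions = default_interactions(),
                           params = run_params(), step = 0,
                           conservative_only = FALSE) {
  ba <- .bond_arrays(state)
  gamma <- if (conservative_only) 0 else params$gamma
  sigma <- if (conservative_only) 0 else params$sigma
  res <- cpp_forces(state$pos, state$vel, state$species - 1L, state$L,
                    interactions,
                    ba$bonds, ba$bks, ba$brs, ba$angles, ba$akth, ba$ath0,
                    gamma, sigma, params$dt,
                    as.double(params$seed), as.double(step))
  if (res$n_overlap > 0)
    message(res$n_overlap, " exactly overlapping pair(s): random contact direction used")
  res
}

#' Advance the system in time
#'
#' Integrates the equations of motion with the Groot--Warren modified
#' velocity-Verlet scheme (lambda = 0.5): positions are advanced with the
#' current force, a velocity predictor feeds the dissipative force at the new
#' positions, and the velocity is completed with the trapezoidal force
#' average.  The trajectory is deterministic for a given seed.
#'
#' @param state a [dpd_state()].
#' @param params a [run_params()].
#' @param interactions 5x5 repulsion matrix.
#' @param traj_every store a full (positions + velocities) frame every this
#'   many steps; 0 disables frame storage.
#' @return list with `state` (advanced [dpd_state()]), `trace` (data.frame
#'   `step, time_tau, E_pair, E_bond, E_angle, E_per_bead, T_kin` with
#'   per-bead potential energies in k_B T), and `frames` (list of
#'   `list(step, pos, vel)`).
#' @export
dpd_run <- function(state, params, interactions = default_interactions(),
                    traj_every = 0L) {
  if (params$n_steps == 0L) {
    return(list(state = state,
                trace = data.frame(step = integer(0), time_tau = numeric(0),
                                   E_pair = numeric(0), E_bond = numeric(0),
                                   E_angle = numeric(0), E_per_bead = numeric(0),
                                   T_kin = numeric(0)),
                frames = list()))
  }
  ba <- .bond_arrays(state)
  res <- cpp_run(state$pos, state$vel, state$species - 1L, state$L,
                 interactions,
                 ba$bonds, ba$bks, ba$brs, ba$angles, ba$akth, ba$ath0,
                 params$gamma, params$sigma, params$dt,
                 params$n_steps, as.double(params$seed),
                 params$report_every, as.integer(traj_every))
  N <- nrow(state$pos)
  tr <- res$trace
  trace <- data.frame(step = tr[, 1],
                      time_tau = tr[, 1] * params$dt,
                      E_pair = tr[, 2] / N,
                      E_bond = tr[, 3] / N,
                      E_angle = tr[, 4] / N,
                      E_per_bead = (tr[, 2] + tr[, 3] + tr[, 4]) / N,
                      T_kin = tr[, 5])
  out_state <- state
  out_state$pos <- res$pos
  out_state$vel <- res$vel
  list(state = out_state, trace = trace, frames = res$frames)
}

#' Late-window mean per-bead energy of a trace
#'
#' Structure selection compares runs by the time-averaged per-bead potential
#' energy over the final fraction of reports (default: final 10%).
#'
#' @param trace energy trace from [dpd_run()].
#' @param frac final fraction of reports to average.
#' @return mean per-bead energy (k_B T).
#' @export
late_energy <- function(trace, frac = 0.1) {
  n <- nrow(trace)
  if (n == 0) return(NA_real_)
  k <- max(1L, ceiling(frac * n))
  mean(trace$E_per_bead[(n - k + 1L):n])
}
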