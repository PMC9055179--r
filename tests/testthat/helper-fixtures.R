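# Shared fixtures and independent oracles, all built in code.

# empty bonded tables
empty_bonds <- function()
  data.frame(i = integer(0), j = integer(0), k_s = numeric(0), r_s = numeric(0))
empty_angles <- function()
  data.frame(i = integer(0), j = integer(0), k = integer(0),
             k_theta = numeric(0), theta0 = numeric(0))
empty_lipids <- function()
  data.frame(id = integer(0), type = integer(0), first = integer(0),
             n_hb = integer(0), n_tb = integer(0))

# bare bead state (all water unless species given)
plain_state <- function(pos, L, species = NULL, vel = NULL,
                        bonds = empty_bonds(), angles = empty_angles()) {
  N <- nrow(pos)
  dpd_state(L, pos,
            if (is.null(vel)) matrix(0, N, 3) else vel,
            if (is.null(species)) rep(5L, N) else species,
            bonds, angles, empty_lipids())
}

# state of n short lipids (2 head + 2x1 tail beads) whose head-chain
# direction vectors are the given unit rows; used for order-parameter tests
chain_state <- function(dirs, L = 20) {
  t1 <- lipid_template(1, 2, 1)
  n <- nrow(dirs)
  topo <- build_system_topology(t1, lipid_template(2, 2, 1), n, 0, L,
                                rho = max(0.1, n * 4 / L^3 * 1.5))
  pos <- matrix(0, topo$n_beads, 3)
  for (m in seq_len(n)) {
    first <- topo$lipids$first[m]
    o <- c(L, L, L) / 2 + (m %% 7) * 0.13
    pos[first, ] <- o
    pos[first + 1, ] <- o + 0.7 * dirs[m, ]
    pos[first + 2, ] <- o + 0.7 * dirs[m, ] + c(0.1, 0, 0.1)
    pos[first + 3, ] <- o + 0.7 * dirs[m, ] - c(0.1, 0, 0.1)
  }
  if (topo$n_water > 0)
    pos[seq.int(topo$n_beads - topo$n_water + 1, topo$n_beads), ] <-
      matrix(stats::runif(3 * topo$n_water, 0, L), ncol = 3)
  dpd_state(L, pos, matrix(0, topo$n_beads, 3), topo$species,
            topo$bonds, topo$angles, topo$lipids)
}

# independent all-pairs conservative DPD force (O(N^2), minimum image)
allpairs_conservative <- function(pos, L, a = 25) {
  N <- nrow(pos)
  F <- matrix(0, N, 3)
  for (i in seq_len(N - 1)) {
    d <- -sweep(pos[(i + 1):N, , drop = FALSE], 2, pos[i, ])  # r_i - r_j
    d <- min_image(d, L)
    r <- sqrt(rowSums(d^2))
    sel <- which(r < 1 & r > 1e-12)
    for (s in sel) {
      j <- i + s
      fv <- a * (1 - r[s]) * d[s, ] / r[s]
      F[i, ] <- F[i, ] + fv
      F[j, ] <- F[j, ] - fv
    }
  }
  F
}

# independent scalar energies for finite-difference force oracles
pair_energy_r <- function(r, a = 25) 0.5 * a * (1 - r)^2
bond_energy_r <- function(r, k_s = 100, r_s = 0.7) 0.5 * k_s * (r - r_s)^2
angle_energy_r <- function(p, k_theta, theta0) {
  u <- p[1, ] - p[2, ]; w <- p[3, ] - p[2, ]
  ct <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  k_theta * (acos(max(-1, min(1, ct))) - theta0)^2
}

# synthetic three-stage energy trace (steps at 26 and 400 tau)
synthetic_trace <- function(noise_sd = 0.05, report_tau = 2, t_end = 800,
                            levels = c(8.0, 6.5, 6.1), seed = 7) {
  set.seed(seed)
  tt <- seq(report_tau, t_end, by = report_tau)
  e <- ifelse(tt < 26, levels[1], ifelse(tt < 400, levels[2], levels[3])) +
    stats::rnorm(length(tt), 0, noise_sd)
  data.frame(time_tau = tt, E_per_bead = e)
}

params_cons <- function(n_steps = 0)
  run_params(gamma = 0, sigma = 0, n_steps = n_steps, seed = 1)
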