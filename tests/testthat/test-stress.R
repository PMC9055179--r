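# Irving-Kirkwood stress machinery: partition of unity, hand geometry,
# isotropy of homogeneous fluid, tension and osmotic baselines.

equilibrated_water <- function(L = 8, steps = 2000, seed = 5, frames = 4) {
  st <- init_state(init_spec("random", 0, 0, L, seed = seed),
                   lipid_template(1, 3, 4), lipid_template(2, 3, 9))
  dpd_run(st, run_params(n_steps = steps, seed = seed, report_every = 500),
          traj_every = steps / frames)
}

test_that("slab-integrated virial equals the whole-box virial exactly", {
  res <- equilibrated_water()
  for (ax in c("x", "z")) {
    sp <- local_pressure(res$frames, axis = ax, n_bins = 16, meta = res$state)
    expect_lt(max(abs(colMeans(sp$p) - sp$global)), 1e-10 * max(sp$global))
  }
})

test_that("partition of unity also holds with bonded terms and groups", {
  t1 <- lipid_template(1, 3, 4); t2 <- lipid_template(2, 3, 9)
  st <- init_state(init_spec("lamella", 20, 20, 10, seed = 6), t1, t2)
  res <- dpd_run(st, run_params(n_steps = 500, seed = 6, report_every = 100),
                 traj_every = 500)
  sp <- local_pressure(res$frames, axis = "z", n_bins = 20, meta = res$state,
                       groups = "species")
  expect_lt(max(abs(colMeans(sp$p) - sp$global)), 1e-10 * max(abs(sp$global)))
  # group profiles sum to the total
  expect_equal(apply(sp$p_group, c(1, 2), sum), unname(sp$p))
})

test_that("a single pair spanning several slabs splits its virial by path length", {
  st <- plain_state(rbind(c(1.0, 3, 3), c(1.9, 3, 3)), 6)
  sp <- local_pressure(st, axis = "x", n_bins = 12)   # slabs of 0.5 r_c
  vir_x <- sp$vir[, 1, 1] * (6^3 / 12)
  nz <- which(vir_x != 0)
  expect_equal(nz, c(3, 4))                            # [1.0,1.5) and [1.5,1.9]
  expect_equal(vir_x[3] / vir_x[4], 0.5 / 0.4)
  expect_equal(sum(vir_x), 25 * (1 - 0.9) * 0.9)       # F * x_ij
  # all weight goes to the bead's slab when the pair is perpendicular
  sp2 <- local_pressure(plain_state(rbind(c(1.2, 3, 3), c(1.2, 3.9, 3)), 6),
                        axis = "x", n_bins = 12)
  vir2 <- sp2$vir[, 2, 1] * (6^3 / 12)
  expect_equal(which(vir2 != 0), 3)
})

test_that("homogeneous fluid is isotropic: sigma and Pi vanish within noise", {
  res <- equilibrated_water(L = 8, steps = 4000, seed = 15, frames = 8)
  sp <- local_pressure(res$frames, axis = "z", n_bins = 8, meta = res$state)
  # per-frame spread of the tension estimator sets the sampling scale
  sig_f <- vapply(res$frames, function(fr) {
    s1 <- local_pressure(list(fr), axis = "z", n_bins = 8, meta = res$state)
    interface_tension(s1, "z")$sigma
  }, numeric(1))
  se <- stats::sd(sig_f) / sqrt(length(sig_f))
  expect_lt(abs(interface_tension(sp, "z")$sigma), 5 * se)
  os <- osmotic_pressure(sp, "z", bulk_window = c(0, 8))
  expect_lt(max(abs(os$profile$Pi)), 5 * stats::sd(sp$p[, 3]) + 1e-12)
  expect_equal(mean(os$profile$Pi), 0, tolerance = 1e-12)
})

test_that("osmotic pressure bulk-window mean is zero by construction", {
  res <- equilibrated_water(L = 6, steps = 1000, seed = 25, frames = 2)
  sp <- local_pressure(res$frames, axis = "x", n_bins = 12, meta = res$state,
                       groups = "species")
  os <- osmotic_pressure(sp, "x", bulk_window = c(1, 5))
  inb <- sp$centers >= 1 & sp$centers <= 5
  expect_equal(mean(os$profile$Pi[inb]), 0, tolerance = 1e-12)
  expect_equal(unname(colMeans(os$Pi_group[inb, , drop = FALSE])),
               rep(0, 5), tolerance = 1e-12)
  expect_error(osmotic_pressure(sp, "x", bulk_window = c(20, 30)),
               "bulk")
})

test_that("demixed soft blend localizes osmotic peaks at the interface", {
  # two-phase demixture: A beads left, B beads right, a_AB = 100
  set.seed(30)
  L <- 10; N <- round(3 * L^3 / 2)
  posA <- cbind(runif(N, 0, L / 2), runif(N, 0, L), runif(N, 0, L))
  posB <- cbind(runif(N, L / 2, L), runif(N, 0, L), runif(N, 0, L))
  st <- plain_state(rbind(posA, posB), L,
                    species = rep(c(1L, 3L), each = N))  # HB1 vs HB2
  res <- dpd_run(st, run_params(n_steps = 2000, seed = 31, report_every = 500),
                 traj_every = 500)
  sp <- local_pressure(res$frames, axis = "x", n_bins = 20, meta = res$state)
  # density gradient of species A along x
  dp <- density_profile(res$frames, "x", 20, meta = res$state)
  phiA <- dp$density[dp$species == "HB1"]
  grad <- abs(diff(phiA))
  os <- osmotic_pressure(sp, "x",
                         bulk_window = c(1, 2))  # inside the A phase
  # |Pi| maxima co-located with |grad phi| maxima (within 2 bins)
  top_pi <- order(abs(os$profile$Pi), decreasing = TRUE)[1:4]
  top_gr <- order(grad, decreasing = TRUE)[1:4]
  expect_lt(min(abs(outer(top_pi, top_gr, "-"))), 3)
})

test_that("too-thin slabs are refused", {
  st <- plain_state(matrix(runif(30, 0, 4), 10, 3), 4)
  expect_error(local_pressure(st, "z", n_bins = 50), "0.1 r_c")
})

test_that("temperature profile is uniform for a thermostatted water box", {
  res <- equilibrated_water(L = 8, steps = 3000, seed = 35, frames = 6)
  tp <- temperature_profile(res$frames, "z", 8, meta = res$state)
  se <- sqrt(2 / (3 * mean(tp$n) * length(res$frames)))   # chi^2 sampling scale
  expect_true(all(abs(tp$T_kin - 1) < 5 * se + 0.02))
})
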