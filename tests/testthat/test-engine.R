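# DPD engine: weight function, pair/bonded forces, cell list, integrator,
# thermostat properties.

test_that("weight function is linear with a sharp cut-off", {
  expect_equal(weight(0, 1), 1)
  expect_equal(weight(1, 1), 0)
  expect_equal(weight(0.25, 1), 0.75)
  expect_equal(weight(c(0.5, 2), 1), c(0.5, 0))
})

test_that("fluctuation-dissipation fixes sigma = 3 for gamma = 4.5", {
  p <- run_params(gamma = 4.5, kBT = 1)
  expect_identical(p$sigma, 3)
  p2 <- run_params(sigma = 2, kBT = 1)
  expect_equal(p2$gamma, 2)
  expect_error(run_params(gamma = 4.5, sigma = 1), "sigma\\^2")
})

test_that("two resting beads repel with a_ij w(r) along the pair axis", {
  st <- plain_state(rbind(c(1, 1, 1), c(1.5, 1, 1)), 6)
  f <- compute_forces(st, params = params_cons(), conservative_only = TRUE)
  expect_equal(f$force[1, ], c(-12.5, 0, 0))
  expect_equal(f$force[2, ], c(12.5, 0, 0))
  expect_equal(f$e_pair, pair_energy_r(0.5))
})

test_that("forces are pairwise antisymmetric: zero total force", {
  set.seed(11)
  for (rep in 1:3) {
    st <- plain_state(matrix(runif(3 * 120, 0, 5), 120, 3), 5)
    st$vel <- matrix(rnorm(3 * 120), 120, 3)
    f <- compute_forces(st, params = run_params(n_steps = 0), step = rep)
    expect_lt(max(abs(colSums(f$force))), 1e-10)
  }
})

test_that("conservative force matches the finite-difference pair-energy gradient", {
  set.seed(21)
  errs <- vapply(1:20, function(k) {
    r <- runif(1, 0.05, 0.95)
    st <- plain_state(rbind(c(2, 2, 2), c(2 + r, 2, 2)), 6)
    f <- compute_forces(st, params = params_cons(), conservative_only = TRUE)
    h <- 1e-6
    fd <- -(pair_energy_r(r + h) - pair_energy_r(r - h)) / (2 * h)
    abs(f$force[2, 1] - fd) / abs(fd)
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("bond force matches the finite-difference gradient and vanishes at r_s", {
  st0 <- plain_state(rbind(c(2, 2, 2), c(2.7, 2, 2)), 8,
                     bonds = data.frame(i = 1L, j = 2L, k_s = 100, r_s = 0.7))
  f0 <- compute_forces(st0, default_interactions(0, 0), params_cons(),
                       conservative_only = TRUE)
  expect_equal(max(abs(f0$force)), 0)
  set.seed(22)
  errs <- vapply(1:20, function(k) {
    r <- runif(1, 0.4, 1.6)
    st <- plain_state(rbind(c(3, 3, 3), c(3 + r, 3, 3)), 8,
                      bonds = data.frame(i = 1L, j = 2L, k_s = 100, r_s = 0.7))
    f <- compute_forces(st, default_interactions(0, 0), params_cons(),
                        conservative_only = TRUE)
    h <- 1e-6
    fd <- -(bond_energy_r(r + h) - bond_energy_r(r - h)) / (2 * h)
    abs(f$force[2, 1] - fd) / max(1e-12, abs(fd))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("angle force is the exact gradient of k_theta (theta - theta0)^2", {
  # equilibrium: straight triple under theta0 = pi gives zero force
  steq <- plain_state(rbind(c(2, 2, 2), c(2.7, 2, 2), c(3.4, 2, 2)), 8,
                      angles = data.frame(i = 1L, j = 2L, k = 3L,
                                          k_theta = 6, theta0 = pi))
  feq <- compute_forces(steq, default_interactions(0, 0), params_cons(),
                        conservative_only = TRUE)
  expect_lt(max(abs(feq$force)), 1e-10)
  set.seed(23)
  errs <- c()
  for (k in 1:20) {
    p <- matrix(runif(9, 2, 4), 3)
    # keep the triple well-conditioned (no near-collinear geometry)
    u <- p[1, ] - p[2, ]; w <- p[3, ] - p[2, ]
    ct <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
    if (abs(ct) > 0.95 || min(sqrt(sum(u^2)), sqrt(sum(w^2))) < 0.3) next
    kth <- sample(c(3, 4.5, 6), 1)
    st <- plain_state(p, 8,
                      angles = data.frame(i = 1L, j = 2L, k = 3L,
                                          k_theta = kth, theta0 = pi))
    f <- compute_forces(st, default_interactions(0, 0), params_cons(),
                        conservative_only = TRUE)
    h <- 1e-6
    for (b in 1:3) for (cc in 1:3) {
      pp <- p; pp[b, cc] <- pp[b, cc] + h
      pm <- p; pm[b, cc] <- pm[b, cc] - h
      fd <- -(angle_energy_r(pp, kth, pi) - angle_energy_r(pm, kth, pi)) / (2 * h)
      errs <- c(errs, abs(f$force[b, cc] - fd) / max(1, abs(fd)))
    }
    # net force and torque of the term vanish
    expect_lt(max(abs(colSums(f$force))), 1e-10)
    tq <- colSums(cbind(p[, 2] * f$force[, 3] - p[, 3] * f$force[, 2],
                        p[, 3] * f$force[, 1] - p[, 1] * f$force[, 3],
                        p[, 1] * f$force[, 2] - p[, 2] * f$force[, 1]))
    expect_lt(max(abs(tq)), 1e-9)
  }
  expect_gt(length(errs), 20 * 5)
  expect_lt(max(errs), 1e-6)
})

test_that("cell-list forces equal the all-pairs oracle to round-off", {
  set.seed(31)
  for (L in c(5.5, 8)) {
    N <- 500
    pos <- matrix(runif(3 * N, 0, L), N, 3)
    st <- plain_state(pos, L)
    f <- compute_forces(st, params = params_cons(), conservative_only = TRUE)
    expect_lt(max(abs(f$force - allpairs_conservative(pos, L))), 1e-11)
  }
})

test_that("symplectic limit: bounded secular energy drift without thermostat", {
  st <- plain_state(rbind(c(3, 3, 3), c(3.9, 3, 3)), 8,
                    vel = rbind(c(0.1, 0, 0), c(-0.1, 0, 0)),
                    bonds = data.frame(i = 1L, j = 2L, k_s = 100, r_s = 0.7))
  pr <- run_params(gamma = 0, sigma = 0, n_steps = 10000, seed = 1,
                   report_every = 1)
  res <- dpd_run(st, pr, default_interactions(0, 0))
  E <- 2 * res$trace$E_per_bead + 3 * res$trace$T_kin  # U + K for N = 2
  n <- length(E)
  drift <- abs(mean(E[(n - 999):n]) - mean(E[1:1000])) / abs(mean(E))
  expect_lt(drift, 1e-4)
})

test_that("momentum stays zero over a thermostatted run", {
  set.seed(41)
  st <- plain_state(matrix(runif(3 * 300, 0, 4.6), 300, 3), 4.6)
  st$vel <- matrix(rnorm(900), 300, 3)
  st$vel <- sweep(st$vel, 2, colMeans(st$vel))
  res <- dpd_run(st, run_params(n_steps = 2000, seed = 3, report_every = 500))
  expect_lt(max(abs(total_momentum(res$state))), 1e-8)
})

test_that("same seed and configuration give bit-identical trajectories", {
  set.seed(51)
  pos <- matrix(runif(3 * 200, 0, 4.1), 200, 3)
  vel <- matrix(rnorm(600), 200, 3)
  st <- plain_state(pos, 4.1, vel = vel)
  pr <- run_params(n_steps = 500, seed = 99, report_every = 100)
  r1 <- dpd_run(st, pr)
  r2 <- dpd_run(st, pr)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$vel, r2$state$vel)
  expect_identical(r1$trace, r2$trace)
  # a different seed decorrelates the noise stream
  r3 <- dpd_run(st, run_params(n_steps = 500, seed = 100, report_every = 100))
  expect_false(identical(r1$state$pos, r3$state$pos))
})

test_that("zero-step run returns the state unchanged", {
  st <- plain_state(matrix(runif(30, 0, 4), 10, 3), 4)
  res <- dpd_run(st, run_params(n_steps = 0))
  expect_identical(res$state$pos, st$pos)
  expect_equal(nrow(res$trace), 0)
})

test_that("thermostat holds the kinetic temperature near 1", {
  t1 <- lipid_template(1, 3, 4)
  st <- init_state(init_spec("random", 0, 0, 6, seed = 13), t1,
                   lipid_template(2, 3, 9))
  res <- dpd_run(st, run_params(n_steps = 3000, seed = 17, report_every = 100))
  late <- res$trace$T_kin[16:30]
  expect_equal(mean(late), 1.0, tolerance = 0.03)
})
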