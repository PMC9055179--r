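# Initial-condition construction and lowest-energy selection.

test_that("lamella puts type-1 heads below the midplane and type-2 above", {
  t1 <- lipid_template(1, 3, 4); t2 <- lipid_template(2, 3, 4)
  st <- init_state(init_spec("lamella", 8, 8, 8, seed = 1), t1, t2)
  sp <- bead_species()[st$species]
  expect_true(all(st$pos[sp == "HB1", 3] < 4))
  expect_true(all(st$pos[sp == "HB2", 3] > 4))
  # tails sit between the two head layers
  expect_true(max(st$pos[sp == "HB1", 3]) < min(st$pos[sp == "TB1", 3]))
  expect_true(min(st$pos[sp == "HB2", 3]) > max(st$pos[sp == "TB2", 3]))
})

test_that("every mode hits the rho L^3 bead count with zero net momentum", {
  t1 <- lipid_template(1, 3, 3); t2 <- lipid_template(2, 3, 3)
  for (mode in c("random", "lamella", "cylinder", "sphere")) {
    st <- init_state(init_spec(mode, 10, 10, 10, seed = 2), t1, t2)
    expect_equal(nrow(st$pos), round(3 * 10^3))
    expect_lt(max(abs(total_momentum(st))), 1e-10)
    expect_true(all(st$pos >= 0 & st$pos < 10))
  }
})

test_that("sphere mode orders leaflets radially: HB1 < TB1 < TB2 < HB2", {
  t1 <- lipid_template(1, 3, 2); t2 <- lipid_template(2, 3, 2)
  st <- init_state(init_spec("sphere", 30, 60, 16, seed = 3), t1, t2,
                   r_mid = 4.5)
  sp <- bead_species()[st$species]
  cen <- c(8, 8, 8)
  rad <- function(s) sqrt(rowSums(sweep(st$pos[sp == s, , drop = FALSE], 2, cen)^2))
  expect_lt(max(rad("HB1")), min(rad("TB1")))
  expect_lt(max(rad("TB1")), min(rad("TB2")))
  expect_lt(max(rad("TB2")), min(rad("HB2")))
})

test_that("overfull leaflets raise errors naming the limiting geometry", {
  # 410 minimal lipids per 10x10 leaflet would need a grid below 0.5 r_c
  tmin1 <- suppressWarnings(lipid_template(1, 1, 1))
  tmin2 <- suppressWarnings(lipid_template(2, 1, 1))
  expect_error(
    suppressWarnings(init_state(init_spec("lamella", 410, 410, 10, seed = 1),
                                tmin1, tmin2)),
    "overfull")
  # a tiny shell cannot host 100 lipids' head beads
  expect_error(init_state(init_spec("sphere", 100, 100, 10, seed = 1),
                          lipid_template(1, 3, 2), lipid_template(2, 3, 2),
                          r_mid = 2.6),
               "overfull|cannot fit")
})

test_that("lipid geometry is too large for the box only when truly infeasible", {
  # 11-segment chains cannot fit a tube in a tiny box even compressed
  t1 <- lipid_template(1, 3, 9); t2 <- lipid_template(2, 3, 9)
  expect_error(init_state(init_spec("cylinder", 10, 10, 8, seed = 1), t1, t2),
               "feasible|cannot fit")
})

test_that("select_stable picks the lowest late-window energy with index tie-break", {
  t1 <- lipid_template(1, 2, 2); t2 <- lipid_template(2, 2, 2)
  specs <- list(init_spec("random", 4, 4, 5, seed = 1),
                init_spec("random", 4, 4, 5, seed = 2),
                init_spec("random", 4, 4, 5, seed = 3))
  pr <- run_params(n_steps = 300, seed = 5, report_every = 30)
  sel <- select_stable(specs, t1, t2, pr)
  expect_length(sel$energies, 3)
  expect_equal(sel$index, which.min(sel$energies))
  expect_s3_class(sel$state, "dpd_state")
  # singleton candidate is returned unconditionally
  sel1 <- select_stable(specs[1], t1, t2, pr)
  expect_equal(sel1$index, 1)
})

test_that("candidates that abort are excluded with a warning", {
  t1 <- lipid_template(1, 3, 9); t2 <- lipid_template(2, 3, 9)
  # cylinder infeasible in this box; random is fine
  specs <- list(init_spec("cylinder", 6, 6, 8, seed = 1),
                init_spec("random", 6, 6, 8, seed = 1))
  pr <- run_params(n_steps = 100, seed = 5, report_every = 20)
  expect_warning(sel <- select_stable(specs, t1, t2, pr), "aborted")
  expect_equal(sel$index, 2)
  expect_true(is.na(sel$energies[1]))
})

test_that("optimize_box returns the argmin and a complete energy table", {
  t1 <- lipid_template(1, 2, 2); t2 <- lipid_template(2, 2, 2)
  pr <- run_params(n_steps = 200, seed = 9, report_every = 20)
  ob <- optimize_box(c(5, 6, 7), mode = "random", n1 = 3, n2 = 3,
                     template1 = t1, template2 = t2, params = pr)
  expect_equal(nrow(ob$table), 3)
  expect_equal(ob$L, ob$table$L[which.min(ob$table$energy)])
  expect_s3_class(ob$state, "dpd_state")
})
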