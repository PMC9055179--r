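# Morphology classifier and tail-length scans.

slab_fixture <- function() {
  t1 <- lipid_template(1, 3, 3); t2 <- lipid_template(2, 3, 3)
  init_state(init_spec("lamella", 144, 144, 10, seed = 1), t1, t2)
}
tube_fixture <- function() {
  t <- lipid_template(1, 2, 2)
  init_state(init_spec("cylinder", 660, 750, 18, seed = 1), t,
             lipid_template(2, 2, 2), r_mid = 5)
}
shell_fixture <- function() {
  t <- lipid_template(1, 2, 2)
  init_state(init_spec("sphere", 500, 500, 24, seed = 1), t,
             lipid_template(2, 2, 2), r_mid = 6)
}

test_that("constructed slab/tube/shell classify as membrane/tube/vesicle", {
  cl1 <- classify(slab_fixture())
  expect_equal(cl1$label, "membrane")
  expect_equal(cl1$spanning_dims, 2)
  expect_false(cl1$hollow)
  cl2 <- classify(tube_fixture())
  expect_equal(cl2$label, "tube")
  expect_equal(cl2$spanning_dims, 1)
  expect_true(cl2$hollow)
  cl3 <- classify(shell_fixture())
  expect_equal(cl3$label, "vesicle")
  expect_equal(cl3$spanning_dims, 0)
  expect_true(cl3$hollow)
  expect_gt(cl3$asymmetry_index, 0.9)   # type-1 heads line the cavity
})

test_that("classifier is invariant to rigid translation and axis permutation", {
  st <- shell_fixture()
  base <- classify(st)
  sh <- st
  sh$pos <- wrap_box(sweep(st$pos, 2, c(3.1, -2.7, 8.9), "+"), st$L)
  moved <- classify(sh)
  expect_equal(moved$label, base$label)
  expect_equal(moved$spanning_dims, base$spanning_dims)
  expect_equal(moved$hollow, base$hollow)
  # permute axes of a membrane: normal z -> normal x
  stm <- slab_fixture()
  pm <- stm
  pm$pos <- stm$pos[, c(3, 1, 2)]
  perm <- classify(pm)
  expect_equal(perm$label, "membrane")
  expect_equal(perm$spanning_dims, 2)
})

test_that("small aggregates fall through to label other", {
  t1 <- lipid_template(1, 2, 2)
  st <- init_state(init_spec("random", 4, 4, 12, seed = 3), t1,
                   lipid_template(2, 2, 2))
  cl <- classify(st)
  expect_true(cl$n_lipids_aggregate < 10 || cl$label == "other")
  expect_error(classify(plain_state(matrix(runif(30, 0, 4), 10, 3), 4)),
               "no lipids")
})

test_that("phase grid computes the half-grid and mirrors the rest", {
  pr <- run_params(n_steps = 200, seed = 2, report_every = 40)
  tab <- suppressWarnings(
    phase_grid(2:3, 2:3, n_hb = 2, n1 = 6, n2 = 6, L = 7, params = pr,
               modes = "random"))
  expect_equal(nrow(tab), 4)
  expect_setequal(paste(tab$N_TB1, tab$N_TB2),
                  c("2 2", "2 3", "3 2", "3 3"))
  expect_true(all(tab$label %in% c("membrane", "tube", "vesicle", "other")))
  # the mirrored point carries the computed point's label
  p23 <- tab[tab$N_TB1 == 2 & tab$N_TB2 == 3, ]
  p32 <- tab[tab$N_TB1 == 3 & tab$N_TB2 == 2, ]
  expect_equal(p23$label, p32$label)
  expect_false(p23$mirrored)
  expect_true(p32$mirrored)
})

test_that("rg scan reports one finite row per point", {
  pr <- run_params(n_steps = 200, seed = 4, report_every = 40)
  tab <- suppressWarnings(
    rg_scan(2, c(2, 3), n_hb = 2, n1 = 6, n2 = 6, L = 7, params = pr,
            modes = "random"))
  expect_equal(tab$N_TB2, c(2, 3))
  expect_true(all(is.finite(tab$Rg)))
  expect_true(all(tab$Rg > 0))
})

test_that("scalar Rg estimator is seed-consistent within resampling error", {
  pr1 <- run_params(n_steps = 400, seed = 11, report_every = 40)
  pr2 <- run_params(n_steps = 400, seed = 12, report_every = 40)
  run_rg <- function(pr, seed) {
    t1 <- lipid_template(1, 2, 2); t2 <- lipid_template(2, 2, 2)
    st <- init_state(init_spec("random", 12, 12, 7, seed = seed), t1, t2)
    res <- dpd_run(st, pr)
    gyration_tensor(res$state)
  }
  g1 <- run_rg(pr1, 21); g2 <- run_rg(pr2, 22)
  tr1 <- g1$tensors[, 1, 1] + g1$tensors[, 2, 2] + g1$tensors[, 3, 3]
  tr2 <- g2$tensors[, 1, 1] + g2$tensors[, 2, 2] + g2$tensors[, 3, 3]
  se <- sqrt(stats::var(tr1) / length(tr1) + stats::var(tr2) / length(tr2))
  expect_lt(abs(mean(tr1) - mean(tr2)), 5 * se)
})
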