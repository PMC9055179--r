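# Initial-condition builders: random, lamellar, cylindrical and spherical
# lipid arrangements, plus lowest-energy selection over initial conditions
# and over box sizes.

#' Specification of an initial configuration
#'
#' @param mode one of `"random"`, `"lamella"`, `"cylinder"`, `"sphere"`.
#'   The non-random modes build a pre-assembled bilayer slab / tube / shell
#'   with type-1 lipids on the lower/inner leaflet and type-2 on the
#'   upper/outer leaflet.
#' @param n1,n2 lipid counts of the two types.
#' @param L box edge length (r_c).
#' @param seed seed for bead placement and Maxwell--Boltzmann velocities.
#' @return object of class `init_spec`.
#' @export
init_spec <- function(mode = c("random", "lamella", "cylinder", "sphere"),
                      n1, n2, L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n1 >= 0, n2 >= 0, L > 0)
  structure(list(mode = mode, n1 = as.integer(n1), n2 = as.integer(n2),
                 L = L, seed = as.integer(seed)),
            class = "init_spec")
}

# straight-rod bead positions for one lipid:
# head chain along u from `origin`, the two tails continuing along u with a
# +/- 0.15 r_c offset along `vperp` so that no two bonded beads coincide.
# `spacing` may be below the equilibrium bond length when the geometry is
# tight; the soft potentials relax the compression within a few hundred
# steps.
.place_lipid <- function(template, origin, u, vperp, spacing) {
  nh <- template$n_hb; nt <- template$n_tb
  head <- t(vapply(seq_len(nh) - 1L,
                   function(m) origin + m * spacing * u, numeric(3)))
  junction <- origin + (nh - 1L) * spacing * u
  tail <- function(sgn) {
    off <- sgn * 0.15 * vperp
    t(vapply(seq_len(nt),
             function(m) junction + m * spacing * u + off, numeric(3)))
  }
  rbind(head, tail(+1), tail(-1))
}

.unit_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

# evenly spread directions on the unit sphere (Fibonacci lattice)
.fib_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * k * (2 / (1 + sqrt(5)))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build an initial system state
#'
#' Lipids are placed as straight rods without bonded-bead overlaps; water
#' fills the remaining volume up to `round(rho * L^3)` beads (overlap of
#' water with lipids is harmless under the soft DPD potential).  Velocities
#' are drawn from the Maxwell--Boltzmann distribution at `kBT` and shifted to
#' exactly zero net momentum.
#'
#' Pre-assembled geometries: `lamella` is a bilayer slab normal to z at the
#' box midplane with all type-1 lipids in the lower leaflet; `cylinder` is a
#' bilayer tube along z (type 1 inner); `sphere` is a bilayer shell (type 1
#' inner).
#'
#' @param spec an [init_spec()].
#' @param template1,template2 lipid blueprints ([lipid_template()]).
#' @param rho bead number density (beads / r_c^3).
#' @param kBT temperature for the initial velocities.
#' @param r_mid mid-surface radius for `cylinder`/`sphere` modes
#'   (default `L/4`).
#' @return a [dpd_state()].
#' @export
init_state <- function(spec, template1, template2, rho = 3, kBT = 1,
                       r_mid = NULL) {
  stopifnot(inherits(spec, "init_spec"))
  L <- spec$L
  r_s <- template1$bonded$r_s
  topo <- build_system_topology(template1, template2, spec$n1, spec$n2, L, rho)
  set.seed(spec$seed)
  N <- topo$n_beads
  pos <- matrix(NA_real_, N, 3)

  # rod segments per chain, and the placement spacing that fits `extent`
  n_seg <- function(tpl) tpl$n_hb + tpl$n_tb - 1L
  fit_spacing <- function(tpl, extent, what) {
    s <- min(r_s, extent / n_seg(tpl))
    if (s < 0.3)
      stop(sprintf("%s: chain of %d segments cannot fit %.2f r_c even at 0.3 r_c spacing",
                   what, n_seg(tpl), extent))
    s
  }

  # feasible mid-surface radius for tube/shell geometries: the inner leaflet
  # must keep its head beads off the axis/centre and the outer leaflet must
  # stay off the box boundary, both at >= 0.3 r_c chain spacing
  # minimum inner-head-sphere radius that gives each of n head chains a
  # 0.45 x 0.45 patch
  sphere_head_radius <- function(n) max(0.3, sqrt(0.21 * n / (4 * pi)))

  pick_r_mid <- function(what, r_need = 0.3) {
    r_lo <- if (spec$n1 > 0) 0.35 + r_need + 0.3 * n_seg(template1) + 1e-6
            else 0.95
    r_hi <- if (spec$n2 > 0) L / 2 - 0.85 - 0.3 * n_seg(template2) - 1e-6
            else L / 2 - 0.85
    if (r_lo > r_hi)
      stop(sprintf("%s: no feasible mid-surface radius in box L = %g (inner leaflet needs >= %.2f r_c, outer allows <= %.2f r_c)",
                   what, L, r_lo, r_hi))
    min(max(L / 4, r_lo), r_hi)
  }

  place_all <- function(origins, us, vperps, spacings) {
    # origins: n x 3; fills lipid bead positions in topology order
    stopifnot(nrow(origins) == nrow(topo$lipids))
    for (m in seq_len(nrow(topo$lipids))) {
      li <- topo$lipids[m, ]
      tpl <- if (li$type == 1L) template1 else template2
      beads <- .place_lipid(tpl, origins[m, ], us[m, ], vperps[m, ],
                            spacings[m])
      pos[seq.int(li$first, length.out = nrow(beads)), ] <<- beads
    }
  }

  n1 <- spec$n1; n2 <- spec$n2; nlip <- n1 + n2
  if (nlip > 0) {
    if (spec$mode == "random") {
      origins <- matrix(stats::runif(3 * nlip, 0, L), nlip, 3)
      us <- .fib_sphere(max(nlip, 2))[sample.int(max(nlip, 2), nlip), , drop = FALSE]
      # randomize orientation beyond the lattice directions
      rot <- matrix(stats::rnorm(3 * nlip), nlip, 3)
      us <- us + 0.5 * rot
      us <- us / sqrt(rowSums(us^2))
      vperps <- t(apply(us, 1, .unit_perp))
      place_all(origins, us, vperps, rep(r_s, nlip))
    } else if (spec$mode == "lamella") {
      mid <- L / 2
      leaflet <- function(n, tpl, lower) {
        if (n == 0) return(NULL)
        n_side <- ceiling(sqrt(n))
        grid_sp <- L / n_side
        if (grid_sp < 0.5)
          stop(sprintf("lamella leaflet overfull: %d lipids on %g x %g area gives grid spacing %.2f < 0.5 r_c",
                       n, L, L, grid_sp))
        s <- fit_spacing(tpl, L / 2 - 0.85, "lamella leaflet thickness")
        rod <- n_seg(tpl) * s
        g <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))[seq_len(n), ]
        x <- (g$ix - 0.5) * grid_sp; y <- (g$iy - 0.5) * grid_sp
        z0 <- if (lower) mid - 0.35 - rod else mid + 0.35 + rod
        u <- if (lower) c(0, 0, 1) else c(0, 0, -1)
        list(origins = cbind(x, y, z0),
             us = matrix(u, n, 3, byrow = TRUE),
             vperps = matrix(c(1, 0, 0), n, 3, byrow = TRUE),
             spacing = rep(s, n))
      }
      l1 <- leaflet(n1, template1, lower = TRUE)
      l2 <- leaflet(n2, template2, lower = FALSE)
      place_all(rbind(l1$origins, l2$origins), rbind(l1$us, l2$us),
                rbind(l1$vperps, l2$vperps), c(l1$spacing, l2$spacing))
    } else if (spec$mode == "cylinder") {
      if (is.null(r_mid)) r_mid <- pick_r_mid("cylinder")
      cen <- c(L / 2, L / 2)
      shell <- function(n, tpl, inner) {
        if (n == 0) return(NULL)
        s <- if (inner)
          fit_spacing(tpl, r_mid - 0.65,
                      sprintf("cylinder inner leaflet (tube radius %g)", r_mid))
        else
          fit_spacing(tpl, L / 2 - 0.85 - r_mid,
                      "cylinder outer leaflet (box boundary)")
        rod <- n_seg(tpl) * s
        r_head <- if (inner) r_mid - 0.35 - rod else r_mid + 0.35 + rod
        n_z <- max(1L, ceiling(sqrt(n * L / (2 * pi * r_head + 1e-9))))
        n_th <- ceiling(n / n_z)
        if (2 * pi * r_head / n_th < 0.45 || L / n_z < 0.45)
          stop(sprintf("cylinder leaflet overfull: %d lipids on a 2*pi*%.2f x %g surface",
                       n, r_head, L))
        g <- expand.grid(it = seq_len(n_th), iz = seq_len(n_z))[seq_len(n), ]
        th <- (g$it - 0.5) * 2 * pi / n_th
        z <- (g$iz - 0.5) * L / n_z
        dirs <- cbind(cos(th), sin(th), 0)
        u <- if (inner) dirs else -dirs
        list(origins = cbind(cen[1] + r_head * cos(th),
                             cen[2] + r_head * sin(th), z),
             us = u,
             vperps = matrix(c(0, 0, 1), n, 3, byrow = TRUE),
             spacing = rep(s, n))
      }
      s1 <- shell(n1, template1, inner = TRUE)
      s2 <- shell(n2, template2, inner = FALSE)
      place_all(rbind(s1$origins, s2$origins), rbind(s1$us, s2$us),
                rbind(s1$vperps, s2$vperps), c(s1$spacing, s2$spacing))
    } else {                                    # sphere
      if (is.null(r_mid))
        r_mid <- pick_r_mid("sphere", sphere_head_radius(spec$n1))
      cen <- c(L / 2, L / 2, L / 2)
      shell <- function(n, tpl, inner) {
        if (n == 0) return(NULL)
        s <- if (inner)
          fit_spacing(tpl, r_mid - 0.35 - sphere_head_radius(n),
                      sprintf("sphere inner leaflet (shell radius %g)", r_mid))
        else
          fit_spacing(tpl, L / 2 - 0.85 - r_mid,
                      "sphere outer leaflet (box boundary)")
        rod <- n_seg(tpl) * s
        r_head <- if (inner) r_mid - 0.35 - rod else r_mid + 0.35 + rod
        if (4 * pi * r_head^2 / n < 0.45^2)
          stop(sprintf("sphere leaflet overfull: %d lipids on a 4*pi*%.2f^2 surface", n, r_head))
        d <- .fib_sphere(n)
        u <- if (inner) d else -d
        list(origins = sweep(r_head * d, 2, cen, "+"),
             us = u,
             vperps = t(apply(u, 1, .unit_perp)),
             spacing = rep(s, n))
      }
      s1 <- shell(n1, template1, inner = TRUE)
      s2 <- shell(n2, template2, inner = FALSE)
      place_all(rbind(s1$origins, s2$origins), rbind(s1$us, s2$us),
                rbind(s1$vperps, s2$vperps), c(s1$spacing, s2$spacing))
    }
  }

  n_water <- topo$n_water
  if (n_water > 0) {
    widx <- seq.int(N - n_water + 1L, N)
    pos[widx, ] <- matrix(stats::runif(3 * n_water, 0, L), n_water, 3)
  }

  vel <- matrix(stats::rnorm(3 * N, sd = sqrt(kBT)), N, 3)
  vel <- sweep(vel, 2, colMeans(vel))           # exactly zero net momentum

  dpd_state(L = L, pos = pos, vel = vel, species = topo$species,
            bonds = topo$bonds, angles = topo$angles, lipids = topo$lipids)
}

#' Select the stable structure among candidate initial conditions
#'
#' Runs every candidate with identical physical parameters and returns the
#' final state whose time-averaged per-bead potential energy over the late
#' window (final 10% of reports) is lowest.  Ties within `1e-9` go to the
#' lowest candidate index.  Candidates whose run aborts are excluded with a
#' warning; if all abort, an error is raised.
#'
#' @param specs list of [init_spec()] candidates.
#' @param template1,template2 lipid blueprints.
#' @param params a [run_params()].
#' @param interactions repulsion matrix.
#' @param rho bead density.
#' @param frac late-window fraction for the energy comparison.
#' @param traj_every forwarded to [dpd_run()] for the winning candidate's
#'   frames (all candidates store frames at this interval).
#' @return list with `state` (winner), `index`, `energies` (late-window means,
#'   NA for aborted runs), `traces` (list of energy traces) and `frames`
#'   (winner's frames).
#' @export
select_stable <- function(specs, template1, template2, params,
                          interactions = default_interactions(), rho = 3,
                          frac = 0.1, traj_every = 0L) {
  stopifnot(length(specs) >= 1)
  runs <- vector("list", length(specs))
  energies <- rep(NA_real_, length(specs))
  for (k in seq_along(specs)) {
    runs[[k]] <- tryCatch({
      st <- init_state(specs[[k]], template1, template2, rho = rho)
      dpd_run(st, params, interactions, traj_every = traj_every)
    }, error = function(e) {
      warning(sprintf("candidate %d (%s) aborted: %s", k, specs[[k]]$mode,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(runs[[k]]))
      energies[k] <- late_energy(runs[[k]]$trace, frac)
  }
  ok <- which(!is.na(energies))
  if (!length(ok)) stop("all candidate runs aborted")
  best <- ok[which(energies[ok] <= min(energies[ok]) + 1e-9)][1]
  list(state = runs[[best]]$state, index = best, energies = energies,
       traces = lapply(runs, function(r) if (is.null(r)) NULL else r$trace),
       frames = runs[[best]]$frames)
}

#' Optimize the box size by lowest late-window energy
#'
#' Repeats the same run over a sweep of box edges `L` (default 25 to 35 r_c)
#' at fixed bead density and lipid counts -- the water count adjusts with the
#' box volume -- and returns the `L` with the lowest late-window per-bead
#' energy together with the full (L, energy) table.
#'
#' @param L_values box edges to sweep; default `25:35`.
#' @param mode initial arrangement used at every L.
#' @param n1,n2 lipid counts.
#' @param template1,template2 lipid blueprints.
#' @param params a [run_params()].
#' @param interactions repulsion matrix.
#' @param rho bead density.
#' @param seed placement seed.
#' @param frac late-window fraction.
#' @return list with `L` (best edge), `table` (data.frame `L, energy`),
#'   `state` (final state at the best L).
#' @export
optimize_box <- function(L_values = 25:35, mode = "lamella", n1, n2,
                         template1, template2, params,
                         interactions = default_interactions(), rho = 3,
                         seed = 1L, frac = 0.1) {
  stopifnot(length(L_values) >= 1)
  energies <- rep(NA_real_, length(L_values))
  states <- vector("list", length(L_values))
  for (k in seq_along(L_values)) {
    res <- tryCatch({
      st <- init_state(init_spec(mode, n1, n2, L_values[k], seed),
                       template1, template2, rho = rho)
      dpd_run(st, params, interactions)
    }, error = function(e) {
      warning(sprintf("L = %g aborted: %s", L_values[k], conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      energies[k] <- late_energy(res$trace, frac)
      states[[k]] <- res$state
    }
  }
  ok <- which(!is.na(energies))
  if (!length(ok)) stop("all box-sweep runs aborted")
  best <- ok[which.min(energies[ok])]
  list(L = L_values[best],
       table = data.frame(L = L_values, energy = energies),
       state = states[[best]])
}
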