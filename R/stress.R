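# Irving-Kirkwood local pressure tensors, interface tension and
# osmotic-pressure profiles.

.frames_of <- function(x, meta) {
  if (inherits(x, "dpd_state")) return(list(frames = list(list(pos = x$pos, vel = x$vel)),
                                            meta = x))
  if (is.null(meta)) stop("frame-list input needs `meta` (a dpd_state)")
  list(frames = x, meta = meta)
}

#' Slab-resolved pressure tensor (Irving--Kirkwood)
#'
#' For every frame the diagonal pressure-tensor components are resolved into
#' equal slabs along an axis: the kinetic part `m v_a^2` is assigned to the
#' slab holding each bead, and the virial of every pairwise term
#' `F_ij,a * a_ij` is distributed over the slabs crossed by the i-j
#' minimum-image segment in proportion to the path length in each slab
#' (IK-1 contour).  Only conservative and bonded forces enter: the
#' dissipative and random pair forces cancel on average by construction of
#' the thermostat.  Angle terms enter through their exact pairwise
#' decomposition about the apex bead.  The slab-volume-weighted mean of each
#' component equals the whole-box virial pressure to round-off.
#'
#' @param x a [dpd_state()] or a list of frames (`list(pos, vel)`).
#' @param axis profile axis `"x"`, `"y"` or `"z"`.
#' @param n_bins number of slabs; slabs thinner than 0.1 r_c are refused.
#' @param interactions repulsion matrix.
#' @param meta [dpd_state()] supplying box/species/topology for frame lists.
#' @param groups optional per-bead integer grouping (1..G) for a partial
#'   pressure decomposition, or `"species"` for the five bead species; each
#'   pair term is split half/half between its two beads' groups.
#' @return object of class `stress_profile`: list with `axis`, `bin_edges`,
#'   `centers`, `p` (n_bins x 3 matrix, columns `p_xx, p_yy, p_zz`),
#'   `p_group` (n_bins x 3 x G array), `group_labels`, `global`
#'   (whole-box virial pressure components), `L`, `n_frames`.
#' @export
local_pressure <- function(x, axis = "z", n_bins = 40,
                           interactions = default_interactions(),
                           meta = NULL, groups = NULL) {
  fx <- .frames_of(x, meta)
  st <- fx$meta
  ax <- .axis_index(axis)
  L <- st$L
  if (L / n_bins < 0.1)
    stop("slabs thinner than 0.1 r_c: statistics unusable; reduce n_bins")
  N <- length(st$species)
  if (is.null(groups)) {
    g0 <- rep(0L, N); glab <- "all"
  } else if (identical(groups, "species")) {
    g0 <- st$species - 1L; glab <- bead_species()
  } else {
    stopifnot(length(groups) == N, all(groups >= 1))
    g0 <- as.integer(groups) - 1L
    glab <- as.character(seq_len(max(groups)))
  }
  G <- length(glab)
  ba <- .bond_arrays(st)
  kin <- vir <- array(0, c(n_bins, 3, G))
  gkin <- gvir <- numeric(3)
  for (fr in fx$frames) {
    r <- cpp_stress_frame(fr$pos, fr$vel, st$species - 1L, L, interactions,
                          ba$bonds, ba$bks, ba$brs,
                          ba$angles, ba$akth, ba$ath0,
                          ax - 1L, as.integer(n_bins), g0, G)
    kin <- kin + r$kin; vir <- vir + r$vir
    gkin <- gkin + r$global_kin; gvir <- gvir + r$global_vir
  }
  nf <- length(fx$frames)
  kin <- kin / nf; vir <- vir / nf
  v_slab <- L^3 / n_bins
  p_group <- (kin + vir) / v_slab
  p <- apply(p_group, c(1, 2), sum)
  colnames(p) <- c("p_xx", "p_yy", "p_zz")
  structure(list(axis = axis, n_bins = n_bins,
                 bin_edges = seq(0, L, length.out = n_bins + 1),
                 centers = (seq_len(n_bins) - 0.5) * L / n_bins,
                 p = p, p_group = p_group, group_labels = glab,
                 kin = kin / v_slab, vir = vir / v_slab,
                 global = (gkin + gvir) / (nf * L^3),
                 L = L, n_frames = nf),
            class = "stress_profile")
}

#' Interface tension profile from a stress profile
#'
#' The tension integrand in each slab is the normal-minus-tangential pressure
#' anisotropy `t(bin) = p_N - (p_T1 + p_T2)/2`, where `p_N` is the component
#' along `normal_axis`; the accumulated tension is `sigma = sum(t * dbin)`.
#' When the stress profile is binned along the membrane normal this resolves
#' where the tension lives across the bilayer; binned along an in-plane axis
#' it gives the laterally resolved total tension, which is near zero for a
#' free membrane.  A per-group decomposition is returned when the stress
#' profile carries one.
#'
#' @param stress a `stress_profile` from [local_pressure()].
#' @param normal_axis axis of the membrane normal (`"x"`, `"y"`, `"z"`).
#' @return list with `profile` (data.frame `center, integrand, cumulative`),
#'   `sigma` (total tension), `integrand_group` (n_bins x G), `sigma_group`.
#' @export
interface_tension <- function(stress, normal_axis = "z") {
  stopifnot(inherits(stress, "stress_profile"))
  nrm <- .axis_index(normal_axis)
  tng <- setdiff(1:3, nrm)
  db <- stress$L / stress$n_bins
  integ <- stress$p[, nrm] - rowMeans(stress$p[, tng, drop = FALSE])
  ig <- stress$p_group[, nrm, , drop = FALSE] -
    (stress$p_group[, tng[1], , drop = FALSE] +
     stress$p_group[, tng[2], , drop = FALSE]) / 2
  ig <- array(ig, c(stress$n_bins, length(stress$group_labels)),
              dimnames = list(NULL, stress$group_labels))
  list(profile = data.frame(center = stress$centers, integrand = integ,
                            cumulative = cumsum(integ * db)),
       sigma = sum(integ * db),
       integrand_group = ig,
       sigma_group = colSums(ig * db))
}

#' Osmotic-pressure profile
#'
#' The osmotic pressure in each slab is the deviation of the normal pressure
#' component from its mean over a bulk-water reference window on the profile
#' axis: `Pi(bin) = p_N(bin) - mean(p_N over bulk)`.  Per-group partial
#' contributions subtract each group's own bulk mean, so the bulk-window mean
#' of every profile is zero by construction.
#'
#' @param stress a `stress_profile` from [local_pressure()].
#' @param normal_axis component to use as the normal pressure.
#' @param bulk_window length-2 vector of coordinates (r_c) bracketing bulk
#'   water on the profile axis.
#' @return list with `profile` (data.frame `center, Pi`), `Pi_group`
#'   (n_bins x G), `bulk_mean`.
#' @export
osmotic_pressure <- function(stress, normal_axis = "z", bulk_window) {
  stopifnot(inherits(stress, "stress_profile"), length(bulk_window) == 2)
  nrm <- .axis_index(normal_axis)
  inb <- stress$centers >= min(bulk_window) & stress$centers <= max(bulk_window)
  if (!any(inb))
    stop("no profile bins fall inside the bulk window [",
         min(bulk_window), ", ", max(bulk_window),
         "]: a bulk-water reference window on the profile axis is required")
  pN <- stress$p[, nrm]
  Pi <- pN - mean(pN[inb])
  pg <- array(stress$p_group[, nrm, ],
              c(stress$n_bins, length(stress$group_labels)),
              dimnames = list(NULL, stress$group_labels))
  Pig <- sweep(pg, 2, colMeans(pg[inb, , drop = FALSE]))
  list(profile = data.frame(center = stress$centers, Pi = Pi),
       Pi_group = Pig, bulk_mean = mean(pN[inb]))
}

#' Kinetic-temperature profile along an axis
#'
#' Mean `m v^2 / 3` per bead in each slab, averaged over frames -- the
#' spatially resolved counterpart of [kinetic_temperature()], used to check
#' that the thermostat keeps the temperature uniform across the box.
#'
#' @param x a [dpd_state()] or list of frames.
#' @param axis profile axis.
#' @param n_bins number of slabs.
#' @param meta metadata state for frame lists.
#' @return data.frame `bin, center, T_kin, n` (bead count per slab, averaged).
#' @export
temperature_profile <- function(x, axis = "z", n_bins = 8, meta = NULL) {
  fx <- .frames_of(x, meta)
  st <- fx$meta
  ax <- .axis_index(axis)
  L <- st$L
  dz <- L / n_bins
  acc_T <- acc_n <- numeric(n_bins)
  for (fr in fx$frames) {
    b <- pmin(floor(wrap_box(fr$pos[, ax], L) / dz) + 1L, n_bins)
    v2 <- rowSums(fr$vel^2)
    acc_T <- acc_T + vapply(seq_len(n_bins),
                            function(k) sum(v2[b == k]), numeric(1))
    acc_n <- acc_n + tabulate(b, n_bins)
  }
  data.frame(bin = seq_len(n_bins), center = (seq_len(n_bins) - 0.5) * dz,
             T_kin = ifelse(acc_n > 0, acc_T / (3 * acc_n), NA_real_),
             n = acc_n / length(fx$frames))
}
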