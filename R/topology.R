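# Bead species, per-lipid bonded topology, and whole-system parameter sets.

#' Bead species of the two-lipid DPD model
#'
#' The model distinguishes five bead species: hydrophilic head beads and
#' hydrophobic tail beads of each of the two phospholipid types, plus water.
#' All beads carry the same (unit) mass, which sets the mass scale of the
#' reduced-unit system.
#'
#' @return Character vector of the five species labels, in canonical order:
#'   `HB1`, `TB1`, `HB2`, `TB2`, `W`.
#' @export
bead_species <- function() c("HB1", "TB1", "HB2", "TB2", "W")

#' Bonded-interaction parameter set
#'
#' Defaults are the model values: harmonic bonds with `k_s = 100`
#' (energy/length^2) and equilibrium length `r_s = 0.7` r_c; bending constants
#' `k_theta = 6.0` for three consecutive beads within one chain, `3.0` at the
#' head--tail junction, and `4.5` for the tail--tail split at the last head
#' bead.  All equilibrium angles default to pi (straight); the junction and
#' split angles are exposed separately so they can be bent via configuration.
#'
#' @param k_s bond spring constant.
#' @param r_s equilibrium bond length (r_c units).
#' @param k_theta_chain,k_theta_junction,k_theta_split bending constants for
#'   the three angle classes (energy/rad^2).
#' @param theta0_chain,theta0_junction,theta0_split equilibrium angles (rad).
#' @return A list of bonded parameters with class `dpd_bonded`.
#' @export
bonded_params <- function(k_s = 100, r_s = 0.7,
                          k_theta_chain = 6.0,
                          k_theta_junction = 3.0,
                          k_theta_split = 4.5,
                          theta0_chain = pi,
                          theta0_junction = pi,
                          theta0_split = pi) {
  stopifnot(k_s > 0, r_s > 0,
            k_theta_chain >= 0, k_theta_junction >= 0, k_theta_split >= 0)
  for (t0 in c(theta0_chain, theta0_junction, theta0_split))
    if (t0 < 0 || t0 > pi) stop("equilibrium angles must lie in [0, pi]")
  structure(list(k_s = k_s, r_s = r_s,
                 k_theta_chain = k_theta_chain,
                 k_theta_junction = k_theta_junction,
                 k_theta_split = k_theta_split,
                 theta0_chain = theta0_chain,
                 theta0_junction = theta0_junction,
                 theta0_split = theta0_split),
            class = "dpd_bonded")
}

#' Per-species lipid blueprint
#'
#' A lipid of either type has one linear head chain of `n_hb` hydrophilic
#' beads and two linear tail chains of `n_tb` hydrophobic beads each, so a
#' lipid carries `n_hb + 2 * n_tb` beads.
#'
#' @param type lipid type, 1 or 2; selects the head/tail species pair
#'   (`HB1`/`TB1` or `HB2`/`TB2`).
#' @param n_hb head beads per head chain (>= 1).
#' @param n_tb tail beads per tail chain (>= 1).
#' @param bonded bonded parameters, see [bonded_params()].
#' @return A `lipid_template` list.
#' @export
lipid_template <- function(type, n_hb = 3, n_tb, bonded = bonded_params()) {
  stopifnot(type %in% c(1L, 2L), n_hb >= 1, n_tb >= 1)
  structure(list(type = as.integer(type),
                 n_hb = as.integer(n_hb), n_tb = as.integer(n_tb),
                 head_species = if (type == 1) "HB1" else "HB2",
                 tail_species = if (type == 1) "TB1" else "TB2",
                 bonded = bonded),
            class = "lipid_template")
}

#' Number of beads in one lipid
#' @param template a [lipid_template()].
#' @return integer bead count `n_hb + 2 * n_tb`.
#' @export
lipid_size <- function(template) template$n_hb + 2L * template$n_tb

#' Build the bonded topology of a single lipid
#'
#' Beads are numbered contiguously from `first_index`: head chain first, then
#' the two tail chains.  Bonds connect consecutive beads within each chain and
#' the last head bead to the first bead of each tail chain.  Three angle
#' classes are produced: (a) every three consecutive beads within one chain
#' (`k_theta_chain`); (b) the last two head beads plus the first bead of each
#' tail chain (`k_theta_junction`, one term per tail chain); (c) the two first
#' tail beads with the last head bead at the apex (`k_theta_split`).  Class
#' (b) needs at least two head beads and is omitted with a warning otherwise;
#' class (a) triples are omitted for chains shorter than three beads.
#'
#' @param template a [lipid_template()].
#' @param first_index index of the lipid's first bead (1-based).
#' @return list with `species` (integer codes into [bead_species()]),
#'   `bonds` (data.frame `i, j, k_s, r_s`) and `angles`
#'   (data.frame `i, j, k, k_theta, theta0, class`; `j` is the apex).
#' @export
build_lipid <- function(template, first_index = 1L) {
  stopifnot(inherits(template, "lipid_template"))
  nh <- template$n_hb; nt <- template$n_tb
  bp <- template$bonded
  sp_codes <- match(c(template$head_species, template$tail_species),
                    bead_species())

  head <- seq.int(first_index, length.out = nh)
  tail1 <- seq.int(first_index + nh, length.out = nt)
  tail2 <- seq.int(first_index + nh + nt, length.out = nt)
  hl <- head[nh]                              # last head bead (junction)

  chain_bonds <- function(idx) {
    if (length(idx) < 2) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }
  bm <- rbind(chain_bonds(head), chain_bonds(tail1), chain_bonds(tail2),
              c(hl, tail1[1]), c(hl, tail2[1]))
  bonds <- data.frame(i = bm[, 1], j = bm[, 2], k_s = bp$k_s, r_s = bp$r_s)

  chain_triples <- function(idx) {
    if (length(idx) < 3) return(NULL)
    n <- length(idx)
    cbind(idx[1:(n - 2)], idx[2:(n - 1)], idx[3:n])
  }
  a_cls <- rbind(chain_triples(head), chain_triples(tail1),
                 chain_triples(tail2))
  ang <- list()
  if (!is.null(a_cls))
    ang$a <- data.frame(i = a_cls[, 1], j = a_cls[, 2], k = a_cls[, 3],
                        k_theta = bp$k_theta_chain, theta0 = bp$theta0_chain,
                        class = "intra_chain")
  if (nh >= 2) {
    bm2 <- rbind(c(head[nh - 1], hl, tail1[1]),
                 c(head[nh - 1], hl, tail2[1]))
    ang$b <- data.frame(i = bm2[, 1], j = bm2[, 2], k = bm2[, 3],
                        k_theta = bp$k_theta_junction,
                        theta0 = bp$theta0_junction,
                        class = "head_tail_junction")
  } else {
    warning("n_hb < 2: head-tail junction angle terms omitted (triple undefined)")
  }
  ang$c <- data.frame(i = tail1[1], j = hl, k = tail2[1],
                      k_theta = bp$k_theta_split, theta0 = bp$theta0_split,
                      class = "tail_tail_split")
  angles <- do.call(rbind, ang)
  rownames(angles) <- NULL

  list(species = rep(sp_codes, c(nh, 2L * nt)),
       bonds = bonds, angles = angles)
}

#' Flory--Huggins parameter from DPD repulsion amplitudes
#'
#' Maps the difference between the cross and like repulsion amplitudes to the
#' Flory--Huggins chi parameter, `chi = 0.286 * (a_ij - a_ii)`.
#'
#' @param a_ij cross-species repulsion amplitude.
#' @param a_ii like-species repulsion amplitude.
#' @return chi (dimensionless).
#' @export
chi_from_a <- function(a_ij, a_ii) 0.286 * (a_ij - a_ii)

#' Default DPD repulsion matrix
#'
#' `a_ii = 25` between beads of the same species and `a_ij = 100` between
#' different species, over the five species of [bead_species()].  The five
#' species are treated as mutually distinct, so the two head species (and the
#' two tail species) also repel at 100 -- this is what drives the two lipid
#' types into separate leaflets.  Individual entries can be overridden; the
#' matrix is kept symmetric.
#'
#' @param a_same like-species amplitude (diagonal).
#' @param a_diff unlike-species amplitude (off-diagonal).
#' @param overrides optional data.frame with columns `i, j, a` (species labels
#'   and amplitude) applied symmetrically.
#' @return 5x5 symmetric numeric matrix with species dimnames.
#' @export
default_interactions <- function(a_same = 25, a_diff = 100, overrides = NULL) {
  sp <- bead_species()
  a <- matrix(a_diff, 5, 5, dimnames = list(sp, sp))
  diag(a) <- a_same
  if (!is.null(overrides)) {
    stopifnot(all(c("i", "j", "a") %in% names(overrides)))
    for (r in seq_len(nrow(overrides))) {
      i <- as.character(overrides$i[r]); j <- as.character(overrides$j[r])
      if (!(i %in% sp) || !(j %in% sp))
        stop("interaction override names unknown species: ", i, "-", j)
      a[i, j] <- a[j, i] <- overrides$a[r]
    }
  }
  if (any(a < 0)) stop("repulsion amplitudes must be >= 0")
  a
}

#' Assemble the bonded topology and species of a whole system
#'
#' Lays out `n1` lipids of type 1, then `n2` of type 2, then water beads up to
#' the target total `round(rho * L^3)`.
#'
#' @param template1,template2 lipid blueprints for the two types.
#' @param n1,n2 lipid counts.
#' @param L box edge length (r_c units).
#' @param rho target bead number density (beads / r_c^3).
#' @return list with `species` (integer codes), `bonds`, `angles`,
#'   `lipids` (data.frame `id, type, first, n_hb, n_tb`), `n_water`,
#'   `n_beads`.
#' @export
build_system_topology <- function(template1, template2, n1, n2, L, rho = 3) {
  stopifnot(n1 >= 0, n2 >= 0, L > 0, rho > 0)
  n_total <- round(rho * L^3)
  sizes <- c(rep(lipid_size(template1), n1), rep(lipid_size(template2), n2))
  n_lipid_beads <- sum(sizes)
  if (n_lipid_beads > n_total)
    stop(sprintf("lipids need %d beads but rho*L^3 provides only %d",
                 n_lipid_beads, n_total))
  firsts <- cumsum(c(1L, sizes))[seq_along(sizes)]
  types <- c(rep(1L, n1), rep(2L, n2))
  species <- integer(0); bonds <- list(); angles <- list()
  if ((n1 > 0 && template1$n_hb < 2) || (n2 > 0 && template2$n_hb < 2))
    warning("n_hb < 2: head-tail junction angle terms omitted (triple undefined)")
  withCallingHandlers({
    for (m in seq_along(sizes)) {
      tpl <- if (types[m] == 1L) template1 else template2
      part <- build_lipid(tpl, firsts[m])
      species <- c(species, part$species)
      bonds[[m]] <- part$bonds
      angles[[m]] <- part$angles
    }
  }, warning = function(w) invokeRestart("muffleWarning"))
  n_water <- n_total - n_lipid_beads
  species <- c(species, rep(5L, n_water))
  lipids <- if (length(sizes))
    data.frame(id = seq_along(sizes), type = types, first = firsts,
               n_hb = ifelse(types == 1L, template1$n_hb, template2$n_hb),
               n_tb = ifelse(types == 1L, template1$n_tb, template2$n_tb))
  else
    data.frame(id = integer(0), type = integer(0), first = integer(0),
               n_hb = integer(0), n_tb = integer(0))
  list(species = species,
       bonds = if (length(bonds)) do.call(rbind, bonds) else
         data.frame(i = integer(0), j = integer(0), k_s = numeric(0), r_s = numeric(0)),
       angles = if (length(angles)) do.call(rbind, angles) else
         data.frame(i = integer(0), j = integer(0), k = integer(0),
                    k_theta = numeric(0), theta0 = numeric(0), class = character(0)),
       lipids = lipids, n_water = n_water, n_beads = n_total)
}
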