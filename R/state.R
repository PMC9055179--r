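# SystemState container and small geometry helpers.

#' Construct a DPD system state
#'
#' The single mutable object of the simulator: positions, velocities and
#' species of all beads, the bonded topology, the lipid map and the periodic
#' cubic box.  Positions are wrapped into the primary box `[0, L)` on
#' construction.
#'
#' @param L box edge length (r_c units).
#' @param pos N x 3 matrix of bead positions.
#' @param vel N x 3 matrix of bead velocities.
#' @param species integer codes into [bead_species()] (length N).
#' @param bonds data.frame `i, j, k_s, r_s` (1-based indices).
#' @param angles data.frame `i, j, k, k_theta, theta0` (`j` apex).
#' @param lipids data.frame `id, type, first, n_hb, n_tb` mapping each lipid
#'   to its contiguous bead block.
#' @return object of class `dpd_state`.
#' @export
dpd_state <- function(L, pos, vel, species, bonds, angles, lipids) {
  pos <- as.matrix(pos); vel <- as.matrix(vel)
  stopifnot(L > 0, ncol(pos) == 3, ncol(vel) == 3,
            nrow(pos) == nrow(vel), nrow(pos) == length(species),
            all(species %in% seq_along(bead_species())))
  if (nrow(bonds)) stopifnot(max(bonds$i, bonds$j) <= nrow(pos))
  if (nrow(angles)) stopifnot(max(angles$i, angles$j, angles$k) <= nrow(pos))
  pos <- wrap_box(pos, L)
  structure(list(L = L, pos = pos, vel = vel,
                 species = as.integer(species),
                 bonds = bonds, angles = angles, lipids = lipids),
            class = "dpd_state")
}

#' @export
print.dpd_state <- function(x, ...) {
  sp <- table(factor(bead_species()[x$species], levels = bead_species()))
  cat(sprintf("DPD state: %d beads in L = %g box (%d lipids, %d bonds, %d angles)\n",
              nrow(x$pos), x$L, nrow(x$lipids), nrow(x$bonds), nrow(x$angles)))
  print(sp)
  invisible(x)
}

#' Wrap coordinates into the primary box
#' @param x matrix or vector of coordinates.
#' @param L box edge.
#' @return wrapped coordinates in `[0, L)`.
#' @export
wrap_box <- function(x, L) {
  x <- x - L * floor(x / L)
  x[x >= L] <- 0          # guard against x/L rounding
  x
}

#' Minimum-image displacement
#' @param d raw displacement(s).
#' @param L box edge.
#' @return displacement folded into `(-L/2, L/2]`.
#' @export
min_image <- function(d, L) d - L * round(d / L)

#' Bead indices of one lipid
#'
#' @param state a [dpd_state()].
#' @param id lipid id.
#' @return list with `head`, `tail1`, `tail2` index vectors and `all`.
#' @export
lipid_beads <- function(state, id) {
  li <- state$lipids[state$lipids$id == id, ]
  if (nrow(li) != 1) stop("unknown lipid id: ", id)
  head <- seq.int(li$first, length.out = li$n_hb)
  tail1 <- seq.int(li$first + li$n_hb, length.out = li$n_tb)
  tail2 <- seq.int(li$first + li$n_hb + li$n_tb, length.out = li$n_tb)
  list(head = head, tail1 = tail1, tail2 = tail2,
       all = c(head, tail1, tail2))
}

#' Unwrap the beads of one lipid across periodic boundaries
#'
#' Rebuilds the lipid as a connected object by walking the chains from the
#' first head bead and accumulating minimum-image steps, so that bonded
#' neighbours are never split by the box.
#'
#' @param state a [dpd_state()].
#' @param id lipid id.
#' @return n_beads x 3 matrix of unwrapped positions (rows ordered head,
#'   tail1, tail2).
#' @export
unwrap_lipid <- function(state, id) {
  idx <- lipid_beads(state, id)
  L <- state$L
  p <- state$pos
  # head chain from its first bead
  nh <- length(idx$head)
  uh <- matrix(0, nh, 3)
  uh[1, ] <- p[idx$head[1], ]
  if (nh > 1) for (m in 2:nh)
    uh[m, ] <- uh[m - 1, ] + min_image(p[idx$head[m], ] - p[idx$head[m - 1], ], L)
  anchor <- uh[nh, ]; anchor_w <- p[idx$head[nh], ]
  unwrap_tail <- function(tail) {
    nt <- length(tail)
    ut <- matrix(0, nt, 3)
    ut[1, ] <- anchor + min_image(p[tail[1], ] - anchor_w, L)
    if (nt > 1) for (m in 2:nt)
      ut[m, ] <- ut[m - 1, ] + min_image(p[tail[m], ] - p[tail[m - 1], ], L)
    ut
  }
  rbind(uh, unwrap_tail(idx$tail1), unwrap_tail(idx$tail2))
}

#' Total momentum of the system
#' @param state a [dpd_state()].
#' @return 3-vector of summed bead momenta (unit mass).
#' @export
total_momentum <- function(state) colSums(state$vel)

#' Instantaneous kinetic temperature
#' @param state a [dpd_state()].
#' @return `sum(m v^2) / (3 N)` in k_B T units.
#' @export
kinetic_temperature <- function(state) sum(state$vel^2) / (3 * nrow(state$vel))
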