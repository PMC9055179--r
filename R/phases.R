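# Morphology classification (membrane / tube / vesicle) and tail-length
# scans that build the phase diagram and the radius-of-gyration scan.

#' Classify the self-assembled aggregate of a state
#'
#' Algorithmic replacement for visual phase assignment.  A periodic contact
#' graph (cutoff `contact_cutoff`) is built over all lipid beads and its
#' largest connected component taken as the aggregate.  `spanning_dims`
#' counts the box axes along which the component connects to its own periodic
#' image (detected through inconsistent image offsets along graph cycles).
#' `hollow` is decided by flood-filling the free cells of an occupancy grid
#' (cell edge `grid`, occupancy dilated by one cell): an interior free-space
#' pocket disconnected from the majority free region marks an enclosed
#' water compartment.  Labels follow: membrane = spans 2 axes; tube = spans
#' 1 axis and hollow; vesicle = spans 0 axes and hollow; anything else
#' (including aggregates of fewer than `min_lipids` lipids) = other.
#'
#' @param state a [dpd_state()].
#' @param contact_cutoff contact-graph distance cutoff (r_c).
#' @param min_lipids minimum aggregate size, in lipids.
#' @param grid occupancy-grid cell edge (r_c).
#' @param min_cavity_cells smallest free-cell cluster accepted as a cavity.
#' @return object of class `phase_label`: list with `label`
#'   (`membrane`/`tube`/`vesicle`/`other`), `spanning_dims`, `hollow`,
#'   `asymmetry_index` (fraction of type-1 head beads on the inner/lower
#'   side), `n_lipids_aggregate`, `span_axes` (logical 3-vector),
#'   `normal_axis` (membranes: the non-spanning axis index), `tube_axis`
#'   (tubes: the spanning axis index).
#' @export
classify <- function(state, contact_cutoff = 1, min_lipids = 10, grid = 0.5,
                     min_cavity_cells = 4) {
  if (!nrow(state$lipids)) stop("state contains no lipids")
  L <- state$L
  sp <- bead_species()[state$species]
  lip_beads <- which(sp != "W")
  # map bead -> lipid id
  bead_lipid <- integer(length(state$species))
  for (m in seq_len(nrow(state$lipids))) {
    li <- state$lipids[m, ]
    bead_lipid[seq.int(li$first, length.out = li$n_hb + 2L * li$n_tb)] <- li$id
  }

  cp <- cpp_contact_pairs(state$pos, L, contact_cutoff, lip_beads - 1L)
  n <- length(lip_beads)
  ei <- cp$i; ej <- cp$j
  shift <- as.matrix(cp$shift)

  # connected components + periodic spanning via image-offset consistency
  adj_from <- c(ei, ej); adj_to <- c(ej, ei)
  adj_shift <- rbind(shift, -shift)     # r_from = r_to + min_image + shift*L
  ord <- order(adj_from)
  adj_to <- adj_to[ord]; adj_shift <- adj_shift[ord, , drop = FALSE]
  ptr <- c(0L, cumsum(tabulate(adj_from[ord], n)))

  comp <- integer(n); offs <- matrix(0L, n, 3)
  span <- list()
  ncomp <- 0L
  for (s0 in seq_len(n)) {
    if (comp[s0] != 0L) next
    ncomp <- ncomp + 1L
    sp_ax <- c(FALSE, FALSE, FALSE)
    queue <- s0; comp[s0] <- ncomp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (ptr[v + 1L] > ptr[v]) {
        ix <- (ptr[v] + 1L):ptr[v + 1L]
        for (q in ix) {
          w <- adj_to[q]
          want <- offs[v, ] - adj_shift[q, ]   # r_w image offset consistent with v
          if (comp[w] == 0L) {
            comp[w] <- ncomp
            offs[w, ] <- want
            queue <- c(queue, w)
          } else {
            sp_ax <- sp_ax | (offs[w, ] != want)
          }
        }
      }
    }
    span[[ncomp]] <- sp_ax
  }

  # largest component by number of distinct lipids
  comp_lipids <- tapply(bead_lipid[lip_beads], comp,
                        function(z) length(unique(z)))
  big <- as.integer(names(which.max(comp_lipids)))
  n_lip_agg <- max(comp_lipids)
  agg_beads <- lip_beads[comp == big]
  spanning <- sum(span[[big]])

  # hollowness: occupancy grid of the aggregate, dilated by one cell
  ng <- max(3L, round(L / grid))
  cell <- L / ng
  cidx <- pmin(floor(wrap_box(state$pos[agg_beads, , drop = FALSE], L) / cell),
               ng - 1L)
  occ <- array(FALSE, c(ng, ng, ng))
  for (d in -1:1) for (e in -1:1) for (f in -1:1) {
    ii <- (cidx[, 1] + d) %% ng + 1L
    jj <- (cidx[, 2] + e) %% ng + 1L
    kk <- (cidx[, 3] + f) %% ng + 1L
    occ[cbind(ii, jj, kk)] <- TRUE
  }
  lab <- cpp_free_components(as.vector(occ), ng, ng, ng)
  free_sizes <- tabulate(lab[lab > 0])
  cavities <- which(free_sizes >= min_cavity_cells)
  hollow <- length(cavities) >= 2

  label <- if (n_lip_agg < min_lipids) "other"
           else if (spanning == 2) "membrane"
           else if (spanning == 1 && hollow) "tube"
           else if (spanning == 0 && hollow) "vesicle"
           else "other"

  asym <- .asymmetry_index(state, agg_beads, label, spanning, span[[big]],
                           lab, free_sizes, ng, cell)
  normal_axis <- if (label == "membrane") which(!span[[big]])[1] else NA_integer_
  axis_of <- if (label == "tube") which(span[[big]])[1] else NA_integer_

  structure(list(label = label, spanning_dims = spanning, hollow = hollow,
                 asymmetry_index = asym, n_lipids_aggregate = n_lip_agg,
                 span_axes = span[[big]], normal_axis = normal_axis,
                 tube_axis = axis_of),
            class = "phase_label")
}

# fraction of type-1 head beads on the inner (hollow structures) or lower
# (membranes) side of the aggregate
.asymmetry_index <- function(state, agg_beads, label, spanning, span_ax,
                             lab, free_sizes, ng, cell) {
  L <- state$L
  sp <- bead_species()[state$species]
  h1 <- which(sp == "HB1"); h2 <- which(sp == "HB2")
  heads <- c(h1, h2)
  if (!length(h1) || !length(heads)) return(NA_real_)
  circ_mean <- function(x) {
    th <- x / L * 2 * pi
    (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% 1 * L
  }
  if (label %in% c("tube", "vesicle")) {
    # cavity centre from the second-largest free component
    cav <- order(free_sizes, decreasing = TRUE)[2]
    cells <- which(lab == cav, arr.ind = TRUE)
    cen <- (apply(cells - 0.5, 2, function(ix) circ_mean(ix * cell)))
    rad <- function(idx) {
      d <- sweep(state$pos[idx, , drop = FALSE], 2, cen)
      sqrt(rowSums(min_image(d, L)^2))
    }
    r_all <- rad(heads)
    r1 <- rad(h1)
    mean(r1 < stats::median(r_all))
  } else if (label == "membrane" && spanning == 2) {
    nrm <- which(!span_ax)[1]
    z0 <- circ_mean(state$pos[agg_beads, nrm])
    dz1 <- min_image(state$pos[h1, nrm] - z0, L)
    mean(dz1 < 0)
  } else NA_real_
}

#' @export
print.phase_label <- function(x, ...) {
  cat(sprintf("phase: %s (spans %d axes, hollow = %s, asymmetry index = %s, aggregate = %d lipids)\n",
              x$label, x$spanning_dims, x$hollow,
              ifelse(is.na(x$asymmetry_index), "NA",
                     sprintf("%.2f", x$asymmetry_index)),
              x$n_lipids_aggregate))
  invisible(x)
}

#' Phase diagram over tail-chain lengths
#'
#' For every grid point `(N_TB1, N_TB2)` with `N_TB2 >= N_TB1`, runs the
#' lowest-energy selection over the candidate initial arrangements and
#' classifies the winner; the symmetric half of the grid is mirrored from the
#' computed half with the lipid types swapped.  Individual point failures are
#' recorded as label `other` and the grid continues.
#'
#' @param ntb1_values,ntb2_values tail-length ranges.
#' @param n_hb head beads per chain (both types).
#' @param n1,n2 lipid counts.
#' @param L box edge.
#' @param params a [run_params()].
#' @param interactions repulsion matrix.
#' @param modes initial arrangements passed to the per-point selection.
#' @param rho bead density.
#' @param bonded bonded parameter set.
#' @return data.frame with columns `N_TB1, N_TB2, label, spanning_dims,
#'   hollow, E_final, seed, mirrored`.
#' @export
phase_grid <- function(ntb1_values = 2:10, ntb2_values = 2:10, n_hb = 3,
                       n1, n2, L, params,
                       interactions = default_interactions(),
                       modes = c("lamella", "cylinder", "sphere"),
                       rho = 3, bonded = bonded_params()) {
  stopifnot(length(ntb1_values) >= 1, length(ntb2_values) >= 1)
  rows <- list()
  for (a in ntb1_values) for (b in ntb2_values) {
    if (b < a && (a %in% ntb2_values) && (b %in% ntb1_values)) next # mirrored later
    res <- tryCatch({
      t1 <- lipid_template(1, n_hb, a, bonded)
      t2 <- lipid_template(2, n_hb, b, bonded)
      specs <- lapply(modes, function(m) init_spec(m, n1, n2, L, params$seed))
      sel <- select_stable(specs, t1, t2, params, interactions, rho = rho)
      cl <- classify(sel$state)
      list(label = cl$label, span = cl$spanning_dims, hollow = cl$hollow,
           E = min(sel$energies, na.rm = TRUE))
    }, error = function(e) {
      warning(sprintf("grid point (%d, %d) failed: %s", a, b,
                      conditionMessage(e)))
      list(label = "other", span = NA_integer_, hollow = NA, E = NA_real_)
    })
    rows[[length(rows) + 1L]] <-
      data.frame(N_TB1 = a, N_TB2 = b, label = res$label,
                 spanning_dims = res$span, hollow = res$hollow,
                 E_final = res$E, seed = params$seed, mirrored = FALSE)
    if (a != b && (b %in% ntb1_values) && (a %in% ntb2_values))
      rows[[length(rows) + 1L]] <-
        data.frame(N_TB1 = b, N_TB2 = a, label = res$label,
                   spanning_dims = res$span, hollow = res$hollow,
                   E_final = res$E, seed = params$seed, mirrored = TRUE)
  }
  out <- do.call(rbind, rows)
  out[order(out$N_TB1, out$N_TB2), ]
}

#' Radius-of-gyration scan along one tail length
#'
#' Runs the same selection as [phase_grid()] at fixed `N_TB1` for a series of
#' `N_TB2` values and reports the mean scalar radius of gyration
#' `sqrt(mean trace)` over all lipid chains of the final state.
#'
#' @param n_tb1 fixed tail length of type 1.
#' @param ntb2_values scanned tail lengths of type 2.
#' @param n_hb head beads per chain.
#' @param n1,n2 lipid counts.
#' @param L box edge.
#' @param params a [run_params()].
#' @param interactions repulsion matrix.
#' @param modes initial arrangements.
#' @param rho bead density.
#' @param bonded bonded parameter set.
#' @return data.frame `N_TB2, Rg, label`.
#' @export
rg_scan <- function(n_tb1 = 3, ntb2_values, n_hb = 3, n1, n2, L, params,
                    interactions = default_interactions(),
                    modes = c("lamella", "cylinder", "sphere"),
                    rho = 3, bonded = bonded_params()) {
  rows <- lapply(ntb2_values, function(b) {
    tryCatch({
      t1 <- lipid_template(1, n_hb, n_tb1, bonded)
      t2 <- lipid_template(2, n_hb, b, bonded)
      specs <- lapply(modes, function(m) init_spec(m, n1, n2, L, params$seed))
      sel <- select_stable(specs, t1, t2, params, interactions, rho = rho)
      gt <- gyration_tensor(sel$state)
      data.frame(N_TB2 = b, Rg = gt$Rg, label = classify(sel$state)$label)
    }, error = function(e) {
      warning(sprintf("scan point N_TB2 = %d failed: %s", b,
                      conditionMessage(e)))
      data.frame(N_TB2 = b, Rg = NA_real_, label = "other")
    })
  })
  do.call(rbind, rows)
}
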