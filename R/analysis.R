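# Structural and kinetic observables: per-species density profiles,
# orientational order, gyration tensors, shape factors, and three-stage
# segmentation of energy traces.

.axis_index <- function(axis) {
  ax <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
  ax
}

#' Per-species number-density profile along a box axis
#'
#' Bins bead counts into equal slabs along the chosen axis and divides by the
#' slab volume.  A list of frames is averaged frame-by-frame.  Per frame the
#' profile is exactly normalized: `sum(phi_s * V_bin)` equals the bead count
#' of species s.
#'
#' @param state a [dpd_state()], or a list of frames (`list(pos = ...)`) with
#'   `L` and `species` taken from `meta`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param n_bins number of slabs (>= 2).
#' @param meta optional [dpd_state()] supplying `L`/`species` when `state` is
#'   a list of frames.
#' @return data.frame with columns `bin`, `center`, `species`, `density`
#'   (beads / r_c^3), class `dpd_profile`; attributes `axis`, `L`, `n_frames`.
#' @export
density_profile <- function(state, axis = "z", n_bins = 50, meta = NULL) {
  stopifnot(n_bins >= 2)
  ax <- .axis_index(axis)
  if (inherits(state, "dpd_state")) {
    frames <- list(list(pos = state$pos))
    L <- state$L; species <- state$species
  } else {
    if (is.null(meta)) stop("frame-list input needs `meta` (a dpd_state)")
    frames <- state
    L <- meta$L; species <- meta$species
  }
  dz <- L / n_bins
  v_bin <- dz * L^2
  sp <- bead_species()
  counts <- matrix(0, n_bins, length(sp))
  for (fr in frames) {
    x <- wrap_box(fr$pos[, ax], L)
    b <- pmin(floor(x / dz) + 1L, n_bins)
    counts <- counts + table(factor(b, levels = seq_len(n_bins)),
                             factor(sp[species], levels = sp))
  }
  counts <- counts / length(frames)
  out <- data.frame(bin = rep(seq_len(n_bins), length(sp)),
                    center = rep((seq_len(n_bins) - 0.5) * dz, length(sp)),
                    species = rep(sp, each = n_bins),
                    density = as.vector(counts) / v_bin)
  structure(out, class = c("dpd_profile", "data.frame"),
            axis = axis, L = L, n_frames = length(frames))
}

#' Second-Legendre orientational order parameter of lipid chains
#'
#' For every selected lipid the chain direction is the minimum-image vector
#' from the first to the last bead of the head chain (optionally the whole
#' lipid end-to-end vector), and the per-chain order value is
#' `(3 cos^2(theta) - 1) / 2` with `theta` the angle to the reference axis:
#' 1 for a chain parallel to the axis, -0.5 for a chain perpendicular to it.
#' Chains with a zero-length direction vector are skipped and counted.
#'
#' @param state a [dpd_state()].
#' @param type lipid type(s) to include (default both).
#' @param reference_axis `"x"`, `"y"` or `"z"`.
#' @param direction `"head"` (head-chain first-to-last bead) or `"lipid"`
#'   (first head bead to last bead of the first tail chain).
#' @param n_bins histogram bins over `[-0.5, 1]`.
#' @return list with `values` (per-chain), `mean`, `histogram` (data.frame
#'   `center, count`), `fit` (least-squares Gaussian `mean, sd, amplitude`,
#'   NAs if the fit fails), `n_skipped`.
#' @export
order_parameter <- function(state, type = c(1, 2), reference_axis = "z",
                            direction = c("head", "lipid"), n_bins = 30) {
  direction <- match.arg(direction)
  ax <- .axis_index(reference_axis)
  lip <- state$lipids[state$lipids$type %in% type, ]
  if (!nrow(lip)) stop("no lipids of the selected type(s) in the state")
  L <- state$L
  vals <- rep(NA_real_, nrow(lip))
  for (m in seq_len(nrow(lip))) {
    u <- unwrap_lipid(state, lip$id[m])
    nh <- lip$n_hb[m]
    v <- if (direction == "head") u[nh, ] - u[1, ]
         else u[nh + lip$n_tb[m], ] - u[1, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    ct <- v[ax] / nv
    vals[m] <- (3 * ct^2 - 1) / 2
  }
  n_skipped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  h <- graphics::hist(vals, breaks = seq(-0.5, 1, length.out = n_bins + 1),
                      plot = FALSE)
  hd <- data.frame(center = h$mids, count = h$counts)
  fit <- c(mean = NA_real_, sd = NA_real_, amplitude = NA_real_)
  if (length(vals) >= 3 && stats::sd(vals) > 0) {
    st <- list(mu = mean(vals), s = max(stats::sd(vals), 1e-3),
               A = max(h$counts))
    f <- tryCatch(
      suppressWarnings(
        stats::nls(count ~ A * exp(-(center - mu)^2 / (2 * s^2)), data = hd,
                   start = st,
                   control = stats::nls.control(warnOnly = TRUE, maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(f)) {
      cf <- stats::coef(f)
      fit <- c(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
               amplitude = unname(cf["A"]))
    }
  }
  list(values = vals, mean = mean(vals), histogram = hd, fit = fit,
       n_skipped = n_skipped)
}

#' Per-chain gyration tensors
#'
#' Each selected lipid is unwrapped across the periodic boundaries and its
#' second-moment tensor about the chain's centre of mass is formed:
#' `R2[a,b] = mean_i (r_ia - rbar_a)(r_ib - rbar_b)`.  The reported ensemble
#' components are `<R_g,aa> = sqrt(mean over chains of R2[a,a])` and the
#' scalar `<R_g> = sqrt(mean trace)`.
#'
#' @param state a [dpd_state()].
#' @param type lipid type(s) to include.
#' @return list with `tensors` (n x 3 x 3 array), `components` (named
#'   3-vector `<R_gxx>, <R_gyy>, <R_gzz>`), `Rg` (scalar mean radius of
#'   gyration), `ids` (lipid ids).
#' @export
gyration_tensor <- function(state, type = c(1, 2)) {
  lip <- state$lipids[state$lipids$type %in% type, ]
  if (!nrow(lip)) stop("no lipids of the selected type(s) in the state")
  tensors <- array(0, c(nrow(lip), 3, 3))
  for (m in seq_len(nrow(lip))) {
    u <- unwrap_lipid(state, lip$id[m])
    c0 <- colMeans(u)
    d <- sweep(u, 2, c0)
    tensors[m, , ] <- crossprod(d) / nrow(u)
  }
  comp <- sqrt(colMeans(cbind(tensors[, 1, 1], tensors[, 2, 2], tensors[, 3, 3])))
  names(comp) <- c("Rgxx", "Rgyy", "Rgzz")
  list(tensors = tensors, components = comp,
       Rg = sqrt(mean(tensors[, 1, 1] + tensors[, 2, 2] + tensors[, 3, 3])),
       ids = lip$id)
}

#' Shape factor (asphericity) from gyration tensors
#'
#' With the three eigenvalues of each chain's gyration tensor sorted as
#' `L1^2 <= L2^2 <= L3^2`, the per-chain shape factor is
#' `delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L3^2 L1^2) / (L1^2+L2^2+L3^2)^2`,
#' which is 0 for an isotropic conformation and 1 for a rod; chains with a
#' zero-trace tensor contribute 0.  The ensemble value is the mean of the
#' per-chain factors.
#'
#' @param tensors n x 3 x 3 array from [gyration_tensor()], or its full
#'   result list.
#' @return list with `values` (per chain) and `mean`.
#' @export
shape_factor <- function(tensors) {
  if (is.list(tensors)) tensors <- tensors$tensors
  n <- dim(tensors)[1]
  vals <- vapply(seq_len(n), function(m) {
    ev <- sort(eigen(tensors[m, , ], symmetric = TRUE,
                     only.values = TRUE)$values)
    ev <- pmax(ev, 0)
    s <- sum(ev)
    if (s <= 0) return(0)
    1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / s^2
  }, numeric(1))
  list(values = vals, mean = mean(vals))
}

#' Segment an energy trace into the three self-assembly stages
#'
#' The per-bead energy series is split by two change-points chosen to
#' minimize the total within-stage variance (exact dynamic-programming search
#' over all report-index pairs), matching the random-generation /
#' mutual-adaptation / formation decomposition of the self-assembly process.
#' A flat trace yields boundaries at 1/3 and 2/3 with a `degenerate` flag;
#' stage means that are not non-increasing raise a warning, not an error.
#'
#' @param trace energy trace from [dpd_run()] (needs `time_tau` and
#'   `E_per_bead`), with at least 30 reports.
#' @return object of class `stage_segmentation`: list with `boundaries_tau`
#'   (2 change-point times), `boundaries_index`, `stage_means`, `durations_tau`,
#'   `labels`, `degenerate`.
#' @export
segment_stages <- function(trace) {
  e <- trace$E_per_bead
  t_tau <- trace$time_tau
  n <- length(e)
  if (n < 30) stop("need at least 30 reports to segment stages")
  degenerate <- stats::sd(e) < 1e-12
  if (degenerate) {
    b <- c(floor(n / 3), floor(2 * n / 3))
  } else {
    s1 <- cumsum(e); s2 <- cumsum(e^2)
    seg_cost <- function(i, j) {
      # SSE of e[i..j], vectorized over j
      n_ij <- j - i + 1
      su <- s1[j] - if (i > 1) s1[i - 1] else 0
      sq <- s2[j] - if (i > 1) s2[i - 1] else 0
      sq - su^2 / n_ij
    }
    cost_to_end <- vapply(seq_len(n), function(k) seg_cost(k, n), numeric(1))
    # best placement of the second change-point for every start i of the tail
    best2 <- rep(Inf, n); arg2 <- rep(NA_integer_, n)
    for (i in 2:(n - 1)) {
      js <- i:(n - 1)
      tot <- seg_cost(i, js) + cost_to_end[js + 1L]
      k <- which.min(tot)
      best2[i] <- tot[k]; arg2[i] <- js[k]
    }
    c1s <- 1:(n - 2)
    tot <- vapply(c1s, function(c1) seg_cost(1, c1) + best2[c1 + 1L], numeric(1))
    c1 <- c1s[which.min(tot)]
    b <- c(c1, arg2[c1 + 1L])
  }
  seg_idx <- list(1:b[1], (b[1] + 1):b[2], (b[2] + 1):n)
  means <- vapply(seg_idx, function(ix) mean(e[ix]), numeric(1))
  # a boundary is the time of the first report of the new stage
  b_tau <- t_tau[pmin(b + 1L, n)]
  t0 <- c(0, b_tau)
  t1 <- c(b_tau, t_tau[n])
  if (any(diff(means) > 1e-9))
    warning("stage means are not non-increasing")
  structure(list(boundaries_tau = b_tau, boundaries_index = b,
                 stage_means = means, durations_tau = t1 - t0,
                 labels = c("random_generation", "mutual_adaptation", "formation"),
                 degenerate = degenerate),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("Stage segmentation", if (x$degenerate) "(degenerate: flat trace)", "\n")
  df <- data.frame(stage = x$labels,
                   mean_E_per_bead = round(x$stage_means, 4),
                   duration_tau = round(x$durations_tau, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
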