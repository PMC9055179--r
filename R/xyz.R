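# Trajectory serialization: extended-XYZ frames (species, position,
# velocity, box in the comment line) at full double precision, and CSV
# energy traces.

.fmt_g17 <- function(x) sprintf("%.17g", x)

#' Write extended-XYZ trajectory frames
#'
#' One frame per block: bead count, a comment line carrying the cubic box as
#' a `Lattice="..."` triple and the column schema
#' `Properties=species:S:1:pos:R:3:vel:R:3`, then one line per bead with the
#' species label, position and velocity printed at full precision (17
#' significant digits), so that write -> read round-trips bit-identically.
#'
#' @param x a [dpd_state()], or a list of frames (`list(pos, vel)`), with
#'   `meta` supplying box and species for frame lists.
#' @param path output file.
#' @param meta metadata state for frame lists.
#' @param append append to an existing trajectory file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, meta = NULL, append = FALSE) {
  fx <- .frames_of(x, meta)
  st <- fx$meta
  sp <- bead_species()[st$species]
  L <- .fmt_g17(st$L)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (fr in fx$frames) {
    writeLines(as.character(nrow(fr$pos)), con)
    writeLines(sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3:vel:R:3',
                       L, L, L), con)
    writeLines(paste(sp,
                     .fmt_g17(fr$pos[, 1]), .fmt_g17(fr$pos[, 2]), .fmt_g17(fr$pos[, 3]),
                     .fmt_g17(fr$vel[, 1]), .fmt_g17(fr$vel[, 2]), .fmt_g17(fr$vel[, 3])),
               con)
  }
  invisible(path)
}

#' Read extended-XYZ trajectory frames
#'
#' Inverse of [write_xyz()]: returns every frame with its species labels,
#' positions, velocities and box edge.  Malformed input raises a parse error
#' naming the offending line.
#'
#' @param path trajectory file.
#' @return list of frames: `list(species, pos, vel, L)`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln]))
      stop("xyz parse error at line ", ln, ": expected bead count, got '",
           lines[ln], "'")
    n <- as.integer(lines[ln])
    if (ln + 1L > length(lines))
      stop("xyz parse error at line ", ln + 1L, ": missing comment line")
    m <- regmatches(lines[ln + 1L],
                    regexec('Lattice="([^"]+)"', lines[ln + 1L]))[[1]]
    if (length(m) < 2)
      stop("xyz parse error at line ", ln + 1L, ": missing Lattice=\"...\"")
    lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(lat) != 9 || anyNA(lat))
      stop("xyz parse error at line ", ln + 1L, ": Lattice needs 9 numbers")
    if (ln + 1L + n > length(lines))
      stop("xyz parse error at line ", length(lines),
           ": frame truncated (expected ", n, " bead lines)")
    block <- lines[(ln + 2L):(ln + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) != 7)
    if (length(bad))
      stop("xyz parse error at line ", ln + 1L + bad[1],
           ": expected 7 fields (species x y z vx vy vz)")
    tab <- matrix(unlist(parts), ncol = 7, byrow = TRUE)
    num <- matrix(as.numeric(tab[, 2:7]), ncol = 6)
    if (anyNA(num))
      stop("xyz parse error near line ", ln + 2L, ": non-numeric coordinate")
    frames[[length(frames) + 1L]] <-
      list(species = tab[, 1],
           pos = num[, 1:3, drop = FALSE],
           vel = num[, 4:6, drop = FALSE],
           L = lat[1])
    ln <- ln + 2L + n
  }
  frames
}

#' Write an energy trace as CSV
#'
#' Columns: `step, time_tau, E_pair, E_bond, E_angle, E_per_bead, T_kin`
#' (per-bead potential energies in k_B T).
#'
#' @param trace energy trace from [dpd_run()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an observable table as tidy CSV
#'
#' Generic helper for profile/series outputs: one row per bin or time point.
#'
#' @param df data.frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
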