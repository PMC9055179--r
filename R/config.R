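# Configuration: defaults, file loading (YAML/JSON), validation and
# round-trip serialization.  All defaults are the model's standard values in
# reduced units (r_c = m = k_B T = 1).

#' Default full parameter set
#'
#' Model defaults: two lipid species with 3-bead head chains and tail lengths
#' 4 and 9 (the flagship asymmetric-membrane composition); repulsions
#' `a_ii = 25` / `a_ij = 100`; bonds `k_s = 100`, `r_s = 0.7`; bending
#' constants 6.0 / 3.0 / 4.5 with straight equilibrium angles; thermostat
#' `gamma = 4.5`, `sigma = 3.0` at `kBT = 1`; `dt = 0.01` tau; density
#' `rho = 3`; 600 + 600 lipids, 200 000 steps; box edge 30 r_c with a 25-35
#' optimization sweep.
#'
#' @return nested configuration list of class `dpd_config`.
#' @export
default_config <- function() {
  structure(list(
    lipid1 = list(n_hb = 3L, n_tb = 4L),
    lipid2 = list(n_hb = 3L, n_tb = 9L),
    interactions = list(a_same = 25, a_diff = 100),
    bonded = list(k_s = 100, r_s = 0.7,
                  k_theta_chain = 6.0, k_theta_junction = 3.0,
                  k_theta_split = 4.5,
                  theta0_chain = pi, theta0_junction = pi, theta0_split = pi),
    run = list(gamma = 4.5, sigma = 3.0, kBT = 1, dt = 0.01,
               n_steps = 200000L, seed = 1L, report_every = 200L, rho = 3),
    box = list(L = 30, sweep_from = 25, sweep_to = 35),
    init = list(mode = "lamella", n1 = 600L, n2 = 600L)
  ), class = "dpd_config")
}

.merge_config <- function(base, user, path = character()) {
  for (k in names(user)) {
    key <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base))
      stop("unknown config key: ", key)
    if (is.list(base[[k]])) {
      if (!is.list(user[[k]]))
        stop("config key ", key, " must be a section (got a scalar)")
      base[[k]] <- .merge_config(base[[k]], user[[k]], c(path, k))
    } else {
      v <- user[[k]]
      if (length(v) != 1 || is.list(v))
        stop("config key ", key, " must be a single value")
      # keep the default's storage type so load -> dump -> load round-trips
      d <- base[[k]]
      if (is.integer(d)) v <- as.integer(v)
      else if (is.numeric(d)) v <- as.double(v)
      else if (is.character(d)) v <- as.character(v)
      if (anyNA(v)) stop("config key ", key, " has an invalid value")
      base[[k]] <- v
    }
  }
  base
}

.validate_config <- function(cfg, user = list()) {
  chk <- function(cond, key, constraint) {
    if (!cond) stop("config key ", key, ": ", constraint)
  }
  for (lp in c("lipid1", "lipid2")) {
    chk(cfg[[lp]]$n_hb >= 1, paste0(lp, ".n_hb"), "must be >= 1")
    chk(cfg[[lp]]$n_tb >= 1, paste0(lp, ".n_tb"), "must be >= 1")
  }
  chk(cfg$interactions$a_same >= 0, "interactions.a_same", "must be >= 0")
  chk(cfg$interactions$a_diff >= 0, "interactions.a_diff", "must be >= 0")
  chk(cfg$bonded$k_s > 0, "bonded.k_s", "must be > 0")
  chk(cfg$bonded$r_s > 0, "bonded.r_s", "must be > 0")
  chk(cfg$run$dt > 0, "run.dt", "must be > 0")
  chk(cfg$run$rho > 0, "run.rho", "must be > 0")
  chk(cfg$run$n_steps >= 0, "run.n_steps", "must be >= 0")
  chk(cfg$box$L > 0, "box.L", "must be > 0")
  chk(cfg$init$n1 >= 0 && cfg$init$n2 >= 0, "init.n1/n2", "must be >= 0")
  chk(cfg$init$mode %in% c("random", "lamella", "cylinder", "sphere"),
      "init.mode", "must be one of random/lamella/cylinder/sphere")
  # fluctuation-dissipation closure: derive whichever of gamma/sigma the
  # user did not set, then enforce sigma^2 = 2 gamma kBT
  urun <- if (is.list(user$run)) names(user$run) else character()
  if ("gamma" %in% urun && !("sigma" %in% urun))
    cfg$run$sigma <- sqrt(2 * cfg$run$gamma * cfg$run$kBT)
  if ("sigma" %in% urun && !("gamma" %in% urun))
    cfg$run$gamma <- cfg$run$sigma^2 / (2 * cfg$run$kBT)
  chk(abs(cfg$run$sigma^2 - 2 * cfg$run$gamma * cfg$run$kBT) <
        1e-9 * max(1, cfg$run$sigma^2),
      "run.sigma", "must satisfy sigma^2 = 2 gamma kBT")
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration, applies the
#' model defaults for every unset key, rejects unknown keys, and closes the
#' fluctuation--dissipation relation: setting only `run.gamma` recomputes
#' `run.sigma = sqrt(2 gamma kBT)` and vice versa.  `path = NULL` returns the
#' full default set.
#'
#' @param path configuration file path, or NULL for defaults.
#' @return validated `dpd_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      stop("unsupported config format '.", ext, "' (use .yaml/.yml/.json)"))
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(default_config(), user)
  cfg <- .validate_config(cfg, user)
  structure(cfg, class = "dpd_config")
}

#' Write a configuration file
#'
#' Serializes a configuration to YAML or JSON (by file extension) at full
#' numeric precision, so that load -> dump -> load round-trips to an
#' identical parameter set.
#'
#' @param cfg a `dpd_config` list.
#' @param path output path (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 17),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml/.yml/.json)"))
  invisible(path)
}

#' Lipid templates from a configuration
#' @param cfg a `dpd_config`.
#' @return list with `template1`, `template2`.
#' @export
config_templates <- function(cfg) {
  bp <- do.call(bonded_params, cfg$bonded)
  list(template1 = lipid_template(1, cfg$lipid1$n_hb, cfg$lipid1$n_tb, bp),
       template2 = lipid_template(2, cfg$lipid2$n_hb, cfg$lipid2$n_tb, bp))
}

#' Run parameters from a configuration
#' @param cfg a `dpd_config`.
#' @param seed,n_steps optional overrides.
#' @return a [run_params()].
#' @export
config_params <- function(cfg, seed = NULL, n_steps = NULL) {
  run_params(gamma = cfg$run$gamma, sigma = cfg$run$sigma, kBT = cfg$run$kBT,
             dt = cfg$run$dt,
             n_steps = if (is.null(n_steps)) cfg$run$n_steps else n_steps,
             seed = if (is.null(seed)) cfg$run$seed else seed,
             report_every = cfg$run$report_every)
}

#' Interaction matrix from a configuration
#' @param cfg a `dpd_config`.
#' @return 5x5 repulsion matrix.
#' @export
config_interactions <- function(cfg) {
  default_interactions(cfg$interactions$a_same, cfg$interactions$a_diff)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version and the output
#' files of a run as JSON; every listed file must exist.
#'
#' @param cfg the configuration used.
#' @param seed the seed used.
#' @param outputs named character vector of produced file paths.
#' @param path manifest destination (`.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, seed, outputs, path) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  jsonlite::write_json(
    list(config = unclass(cfg), seed = seed,
         package_version = as.character(utils::packageVersion("lipiddpd")),
         outputs = as.list(outputs),
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
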