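#' Dimensional parameter set
#'
#' The dimensional material and kinetic constants of the cortex model, from
#' which the non-dimensional groups are derived: unit length
#' `l = sqrt(eta/gamma)` (hydrodynamic screening length), time unit
#' `tau = l^2 / D`, concentration unit `s / k`.
#'
#' @param eta Cortex viscosity.
#' @param gamma Friction coefficient with the surrounding medium.
#' @param D Cortical diffusion coefficient (both species).
#' @param sigma_max Maximal active stress (saturation value).
#' @param Delta Stress half-saturation concentration (dimensional).
#' @param s Cortical recruitment (saturation) rate.
#' @param k Cortical dissociation rate.
#' @return An object of class `nondim_map`.
#' @export
nondim_map <- function(eta, gamma, D, sigma_max, Delta, s, k) {
  vals <- c(eta = eta, gamma = gamma, D = D, Delta = Delta, s = s, k = k)
  if (any(vals <= 0)) {
    stop("all dimensional parameters must be positive (sigma_max may be 0)",
      call. = FALSE
    )
  }
  if (sigma_max < 0) stop("sigma_max must be non-negative", call. = FALSE)
  structure(
    list(
      eta = eta, gamma = gamma, D = D, sigma_max = sigma_max,
      Delta = Delta, s = s, k = k
    ),
    class = "nondim_map"
  )
}

#' Non-dimensional groups from dimensional parameters
#'
#' Derives the model's non-dimensional parameters: `Pe = sigma_max /
#' (gamma * D)` (advection strength relative to diffusion), `K = Delta *
#' k / s` (stress half-saturation in units of the saturation concentration
#' `s/k`) and `alpha = (eta / (gamma * D)) * k` (diffusion time over
#' reaction time; the formula used is reported in the result so the
#' convention is always explicit).
#'
#' @param dim A [nondim_map()] object.
#' @return A list with `alpha`, `pe`, `K`, the units `length_unit`,
#'   `time_unit`, `conc_unit`, and `alpha_formula` (a string documenting the
#'   adopted convention).
#' @examples
#' nondimensionalize(nondim_map(
#'   eta = 1, gamma = 1, D = 1,
#'   sigma_max = 12, Delta = 1, s = 1, k = 1
#' ))
#' @export
nondimensionalize <- function(dim) {
  stopifnot(inherits(dim, "nondim_map"))
  l <- sqrt(dim$eta / dim$gamma)
  tau <- l^2 / dim$D
  list(
    alpha = (dim$eta / (dim$gamma * dim$D)) * dim$k,
    pe = dim$sigma_max / (dim$gamma * dim$D),
    K = dim$Delta * dim$k / dim$s,
    length_unit = l,
    time_unit = tau,
    conc_unit = dim$s / dim$k,
    alpha_formula = "alpha = (eta / (gamma * D)) * k  (diffusion time x dissociation rate)"
  )
}

config_defaults <- function() {
  list(
    kinetics = list(alpha = 1, kappa1 = 0.2, kappa2 = 0.2, n = 4L),
    mechanics = list(pe = 12, K = 1, advection_mode = "both"),
    grid = list(length = 40, n_cells = 400L, bc = "noflux_rigid"),
    init = list(
      amplitude = NULL, half_width = 1, species = "rho",
      shape = "tophat"
    ),
    protocol = NULL,
    t_end = 200, record_every = 1, scheme = "muscl", seed = 1L
  )
}

merge_config <- function(defaults, user, path = character()) {
  # YAML 1.1 parses a bare `n` key as a boolean: map it back
  names(user)[names(user) == "FALSE"] <- "n"
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      stop(
        "unknown configuration key: ",
        paste(c(path, nm), collapse = "$"),
        call. = FALSE
      )
    }
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[nm] <- list(user[[nm]]) # preserves explicit NULLs
    }
  }
  defaults
}

#' Read a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema (unknown
#' keys are an error, never silently defaulted), and fills unset fields with
#' the documented defaults.  The `protocol` block, when present, maps to a
#' [perturbation_protocol()] (keys `t_switch`, `pe_after`,
#' `nmiia_decay_factor`, `rho_decay_factor`).
#'
#' @param path YAML file path.
#' @return A `run_config` list with components `kinetics`, `mechanics`,
#'   `grid`, `init`, `protocol`, `t_end`, `record_every`, `scheme`, `seed`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- config_defaults()
  if (!is.null(user$protocol)) {
    cfg$protocol <- list(
      t_switch = 40, pe_after = 0,
      nmiia_decay_factor = 1, rho_decay_factor = 1
    )
  }
  cfg <- merge_config(cfg, user)
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg A `run_config` (or plain list following the schema).
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg A [read_run_config()] result.
#' @return A list with `kp`, `mp`, `grid`, `init` (a [cortex_state()]) and
#'   `protocol` (possibly `NULL`).
#' @export
config_to_objects <- function(cfg) {
  kp <- kinetic_params(
    cfg$kinetics$alpha, cfg$kinetics$kappa1,
    cfg$kinetics$kappa2, cfg$kinetics$n
  )
  mp <- mech_params(cfg$mechanics$pe, cfg$mechanics$K, cfg$mechanics$advection_mode)
  grid <- grid_1d(cfg$grid$length, cfg$grid$n_cells, cfg$grid$bc)
  amp <- cfg$init$amplitude
  if (is.null(amp)) amp <- high_state(kp)
  init <- make_pulse(grid, amp, cfg$init$half_width,
    species = cfg$init$species, shape = cfg$init$shape
  )
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    protocol <- perturbation_protocol(
      cfg$protocol$t_switch, cfg$protocol$pe_after,
      cfg$protocol$nmiia_decay_factor, cfg$protocol$rho_decay_factor
    )
  }
  list(kp = kp, mp = mp, grid = grid, init = init, protocol = protocol)
}

#' Persist a space-time record
#'
#' Writes the record as a long-format CSV (`time, x, rho, m, v`) together
#' with a JSON sidecar (`<path>.json`) carrying the full parameter echo
#' needed to re-run the simulation.
#'
#' @param rec A `spacetime_record`.
#' @param path CSV output path.
#' @return Invisibly, the paths written.
#' @export
write_record_csv <- function(rec, path) {
  stopifnot(inherits(rec, "spacetime_record"))
  utils::write.csv(tidy(rec), path, row.names = FALSE)
  echo <- list(
    kinetics = unclass(rec$kp),
    mechanics = unclass(rec$mp),
    grid = unclass(rec$grid)[c("length", "n_cells", "bc")],
    record_every = rec$record_every,
    scheme = rec$scheme,
    decay = rec$decay,
    aborted = rec$aborted
  )
  json_path <- paste0(path, ".json")
  jsonlite::write_json(echo, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}

#' Read back a persisted space-time record
#'
#' @param path CSV path previously written by [write_record_csv()] (the
#'   JSON sidecar must sit next to it).
#' @return A `spacetime_record`.
#' @export
read_record_csv <- function(path) {
  long <- utils::read.csv(path)
  echo <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_1d(echo$grid$length, echo$grid$n_cells, echo$grid$bc)
  kp <- kinetic_params(
    echo$kinetics$alpha, echo$kinetics$kappa1,
    echo$kinetics$kappa2, echo$kinetics$n
  )
  mp <- mech_params(
    echo$mechanics$pe, echo$mechanics$K,
    echo$mechanics$advection_mode
  )
  times <- unique(long$time)
  nf <- length(times)
  nx <- grid$n_cells
  core <- list(
    times = times,
    rho_xt = matrix(long$rho, nrow = nf, ncol = nx, byrow = TRUE),
    m_xt = matrix(long$m, nrow = nf, ncol = nx, byrow = TRUE),
    v_xt = matrix(long$v, nrow = nf, ncol = nx, byrow = TRUE),
    aborted = as.integer(isTRUE(echo$aborted))
  )
  new_spacetime_record(
    core, grid, kp, mp, echo$record_every, echo$scheme,
    echo$decay
  )
}
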