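#' Default run configuration
#'
#' A nested list mirroring every tunable of the pipeline, round-trippable
#' through YAML. Unknown keys are rejected when reading, so configs cannot
#' silently drift from the implementation.
#'
#' @param ... overrides as `section = list(key = value)`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    model = list(I_b = 10, gNa = 120, gK = 36, gL = 0.3, V_Na = 50,
                 V_K = -77, V_L = -54.4, c = 1, K = 100),
    grid = list(x_min = -1.0, x_max = 0.55, y_min = 0.0, y_max = 0.9,
                nx = 320, ny = 320),
    cost = list(gamma = 1000, sigma_x2 = 0.001, sigma_y2 = 0.001, T_end = 7),
    solver = list(D = 0, u_max = 10, cfl = 0.5, store_dt = 0.01),
    sde = list(dt = 0.005),
    network = list(N = 100, kind = "homogeneous", alpha_bar = 0.25,
                   D = 15, threshold = -20),
    experiment = list(T = 425, n_realizations = 20),
    master_seed = 1,
    out_dir = "."
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(ov[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key(s) in ", nm, ": ",
                            paste(bad, collapse = ", "))
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- run_config()
  bad <- setdiff(names(raw), names(template))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  args <- raw[vapply(raw, is.list, logical(1))]
  scalars <- raw[!vapply(raw, is.list, logical(1))]
  cfg <- do.call(run_config, args)
  for (nm in names(scalars)) cfg[[nm]] <- scalars[[nm]]
  cfg
}

#' Persist a value function with a JSON sidecar
#'
#' The array goes to an RDS file (a runtime artifact, not a fixture); the
#' sidecar records solver settings for provenance.
#'
#' @param vf an `hh_value_function`.
#' @param path output `.rds` path; the sidecar is `path` + `.json`.
#' @export
write_value_function <- function(vf, path) {
  saveRDS(vf, path)
  side <- list(D = vf$D, u_max = vf$u_max, gamma = vf$cost$gamma,
               sigma_x2 = vf$cost$sigma_x2, sigma_y2 = vf$cost$sigma_y2,
               T_end = vf$cost$T_end,
               grid = list(nx = vf$grid$nx, ny = vf$grid$ny,
                           x_min = vf$grid$x_min, x_max = vf$grid$x_max,
                           y_min = vf$grid$y_min, y_max = vf$grid$y_max),
               dt_pde = vf$dt_pde, n_steps = vf$n_steps,
               n_slices = length(vf$times))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate small test assets
#'
#' Deterministic fixtures for integration testing: a 32 x 32 value function
#' (solved, not synthesized), a 7 ms control waveform extracted from it,
#' 5-neuron coupling matrices of each kind, and an Ornstein-Uhlenbeck
#' moment reference table (closed-form mean and variance over time).
#' Regenerates bit-identically from the same seed.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the objects and file paths.
#' @export
generate_fixtures <- function(seed = 1, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- neuron_params()
  vf <- solve_hjb(p, grid_spec(nx = 32, ny = 32), D = 1, store_dt = 0.05)
  wave <- control_waveform(hh_policy(vf, "stochastic-on-deterministic"))
  wpath <- file.path(dir, "waveform_D1.csv")
  write_waveform_csv(wave, wpath)

  nets <- lapply(c(homogeneous = "homogeneous",
                   heterogeneous = "heterogeneous",
                   `sparse-heterogeneous` = "sparse-heterogeneous"),
                 function(k) build_coupling(k, N = 5, alpha_bar = 0.2,
                                            seed = seed))
  npaths <- character(0)
  for (nm in names(nets)) {
    f <- file.path(dir, paste0("network_", gsub("-", "_", nm), ".csv"))
    write_network_csv(nets[[nm]], f)
    npaths <- c(npaths, f)
  }

  tt <- seq(0, 1, by = 0.05)
  ou <- data.frame(t = tt, mean = 2 * exp(-tt),
                   var = 1 * (1 - exp(-2 * tt)))
  opath <- file.path(dir, "ou_reference.csv")
  write.csv(ou, opath, row.names = FALSE)

  invisible(list(value_function = vf, waveform = wave, networks = nets,
                 ou_reference = ou,
                 paths = c(wpath, npaths, opath)))
}
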