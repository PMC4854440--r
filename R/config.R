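# Run configuration: a serializable description (recipe + force-field
# override + ensemble + integration parameters + seed) from which a run is
# exactly reproducible.

#' Create, write and read run configurations
#'
#' A run config bundles a builder recipe, optional force-field overrides,
#' the ensemble, integration parameters, output strides and the seed. A run
#' is reproducible from (config, seed) alone; `parse(serialize(x))` is the
#' identity.
#'
#' @param recipe List describing the build: `kind` (`"bulk"`,
#'   `"binary_slab"`, `"bilayer"`, `"vesicle_start"`) plus the matching
#'   builder arguments.
#' @param ensemble `"nvt"` or `"npt"`.
#' @param dt Time step in tau.
#' @param n_steps Steps to run.
#' @param temperature Reduced temperature.
#' @param p_target Barostat target pressure (npt only).
#' @param piston Langevin piston parameters.
#' @param sample_stride,frame_stride Output strides.
#' @param seed Integer seed.
#' @param forcefield_file Optional path to a force-field YAML overriding the
#'   packaged default.
#' @return An object of class `dpd_config`.
#' @export
run_config <- function(recipe, ensemble = "nvt", dt = 0.02, n_steps = 1000,
                       temperature = 1, p_target = 89,
                       piston = list(mass = 500, gamma = 1),
                       sample_stride = 10, frame_stride = 0, seed = 1,
                       forcefield_file = NULL) {
  stopifnot(is.list(recipe), !is.null(recipe$kind))
  structure(list(recipe = recipe, ensemble = ensemble, dt = dt,
                 n_steps = n_steps, temperature = temperature,
                 p_target = p_target, piston = piston,
                 sample_stride = sample_stride, frame_stride = frame_stride,
                 seed = seed, forcefield_file = forcefield_file),
            class = "dpd_config")
}

#' @rdname run_config
#' @param config A `dpd_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

#' Build a system from a config recipe
#'
#' @param config A `dpd_config`.
#' @return A `dpd_state`.
#' @export
build_from_config <- function(config) {
  r <- config$recipe
  seed <- if (!is.null(r$seed)) r$seed else config$seed
  switch(r$kind,
    bulk = build_bulk(unlist(r$box), composition = unlist(r$composition),
                      temperature = config$temperature, seed = seed),
    binary_slab = build_binary_slab(r$nA, r$nB, unlist(r$box),
                                    temperature = config$temperature,
                                    seed = seed),
    bilayer = build_bilayer(r$species, r$n_lipids, r$a_prj,
                            Lz = if (is.null(r$Lz)) 24 else r$Lz,
                            temperature = config$temperature, seed = seed),
    vesicle_start = build_vesicle_start(r$species, r$n_lipids, r$a_prj,
                                        margin = if (is.null(r$margin)) 12 else r$margin,
                                        temperature = config$temperature,
                                        seed = seed),
    stop("unknown recipe kind: ", r$kind)
  )
}

config_forcefield <- function(config) {
  ff <- if (is.null(config$forcefield_file)) {
    default_forcefield(temperature = config$temperature)
  } else {
    read_forcefield(config$forcefield_file)
  }
  ff$temperature <- config$temperature
  ff
}

#' Run a simulation described by a config
#'
#' @param config A `dpd_config`.
#' @param state Optional starting state (default: built from the recipe).
#' @return The [run_dpd()] result list.
#' @export
run_from_config <- function(config, state = NULL) {
  if (is.null(state)) state <- build_from_config(config)
  ff <- config_forcefield(config)
  run_dpd(state, ff, steps = config$n_steps, dt = config$dt,
          ensemble = config$ensemble, seed = config$seed,
          sample_stride = config$sample_stride,
          frame_stride = config$frame_stride,
          p_target = config$p_target, piston = config$piston)
}
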